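# Native JSON network dialect.
#
# Schema (all keys required unless noted):
# {
#   "id": "TOY3",
#   "objective": "BIOMASS",
#   "genes": ["g1", ...],
#   "metabolites": [
#     {"id": "A_c", "name": "A (cytosol)", "compartment": "c"}, ...],
#   "reactions": [
#     {"id": "R1",
#      "stoichiometry": {"A_c": -1, "B_c": 1},
#      "lower_bound": 0, "upper_bound": 1000,
#      "gpr": "g2",                  # "" for no gene association
#      "subsystem": "chain",         # optional, default ""
#      "is_exchange": false}, ...]
# }
# Reversibility is encoded solely through lower_bound < 0. Writing is
# canonical (fixed key order, fixed number formatting), so
# write(read(x)) is byte-identical for files produced by write_network().

#' Read a metabolic network
#'
#' @param path file path.
#' @param format `"json"` (native dialect) or `"sbml"` (SBML Level 3
#'   with the FBC extension, compatibility import).
#' @return a validated `metabolic_network`.
#' @export
read_network <- function(path, format = c("json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(cf_error(paste0("network file not found: ", path),
                  "cf_parse_error"))
  }
  net <- switch(format,
                json = read_network_json(path),
                sbml = read_network_sbml(path))
  validate_network(net)
  net
}

read_network_json <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      stop(cf_error(paste0("cannot parse network JSON: ",
                           conditionMessage(e)), "cf_parse_error"))
    })
  need <- c("id", "objective", "metabolites", "reactions")
  missing <- setdiff(need, names(doc))
  if (length(missing)) {
    stop(cf_error(paste0("network JSON missing key(s): ",
                         paste(missing, collapse = ", ")),
                  "cf_parse_error"))
  }
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment, stringsAsFactors = FALSE)
  }))
  rxns <- do.call(rbind, lapply(doc$reactions, function(r) {
    data.frame(id = r$id, lower_bound = as.numeric(r$lower_bound),
               upper_bound = as.numeric(r$upper_bound),
               gpr = r$gpr %||% "", subsystem = r$subsystem %||% "",
               is_exchange = isTRUE(r$is_exchange),
               stringsAsFactors = FALSE)
  }))
  sto <- lapply(doc$reactions, function(r) {
    v <- unlist(r$stoichiometry)
    storage.mode(v) <- "double"
    v
  })
  names(sto) <- rxns$id
  metabolic_network(
    id = doc$id,
    metabolites = mets %||% data.frame(id = character(),
                                       name = character(),
                                       compartment = character()),
    reactions = rxns, stoich = sto,
    genes = if (!is.null(doc$genes)) unlist(doc$genes) else NULL,
    objective_id = doc$objective, validate = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a metabolic network
#'
#' The JSON writer is canonical: a write/read/write round trip
#' reproduces the file byte for byte.
#'
#' @param net a `metabolic_network`.
#' @param path output file path.
#' @param format `"json"` or `"sbml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("json", "sbml")) {
  format <- match.arg(format)
  validate_network(net)
  switch(format,
         json = write_network_json(net, path),
         sbml = write_network_sbml(net, path))
  invisible(path)
}

fmt_num <- function(x) {
  # shortest decimal form that round-trips; canonical for the writer
  vapply(x, function(v) {
    s <- format(v, digits = 15, scientific = FALSE, trim = TRUE)
    if (as.numeric(s) != v) s <- format(v, digits = 17, scientific = FALSE,
                                        trim = TRUE)
    s
  }, character(1))
}

json_str <- function(x) {
  vapply(x, function(s) as.character(jsonlite::toJSON(s, auto_unbox = TRUE)),
         character(1))
}

write_network_json <- function(net, path) {
  m <- net$metabolites
  r <- net$reactions
  lines <- c("{",
             sprintf('  "id": %s,', json_str(net$id)),
             sprintf('  "objective": %s,', json_str(net$objective_id)),
             sprintf('  "genes": [%s],',
                     paste(json_str(net$genes), collapse = ", ")),
             '  "metabolites": [')
  mlines <- sprintf('    {"id": %s, "name": %s, "compartment": %s}',
                    json_str(m$id), json_str(m$name), json_str(m$compartment))
  lines <- c(lines, paste0(mlines, c(rep(",", max(0, nrow(m) - 1)), "")),
             "  ],", '  "reactions": [')
  rlines <- vapply(seq_len(nrow(r)), function(i) {
    sto <- net$stoich[[r$id[i]]]
    sto_s <- paste(sprintf("%s: %s", json_str(names(sto)), fmt_num(sto)),
                   collapse = ", ")
    paste0('    {"id": ', json_str(r$id[i]),
           ', "stoichiometry": {', sto_s, "}",
           ', "lower_bound": ', fmt_num(r$lower_bound[i]),
           ', "upper_bound": ', fmt_num(r$upper_bound[i]),
           ', "gpr": ', json_str(r$gpr[i]),
           ', "subsystem": ', json_str(r$subsystem[i]),
           ', "is_exchange": ', tolower(as.character(r$is_exchange[i])), "}")
  }, character(1))
  lines <- c(lines, paste0(rlines, c(rep(",", max(0, nrow(r) - 1)), "")),
             "  ]", "}")
  writeLines(lines, path)
}

#' Export the reaction and metabolite tables as TSV
#'
#' @param net a `metabolic_network`.
#' @param reactions_path,metabolites_path output paths (`NULL` skips).
#' @return invisibly, a list with both data.frames.
#' @export
export_network_tables <- function(net, reactions_path = NULL,
                                  metabolites_path = NULL) {
  r <- net$reactions
  r$equation <- vapply(r$id, function(rid) {
    sto <- net$stoich[[rid]]
    lhs <- sto[sto < 0]; rhs <- sto[sto > 0]
    side <- function(s, sgn) paste(sprintf("%s %s", fmt_num(abs(s)),
                                           names(s)), collapse = " + ")
    arrow <- if (r$lower_bound[match(rid, r$id)] < 0) "<=>" else "-->"
    paste(side(lhs), arrow, side(rhs))
  }, character(1))
  if (!is.null(reactions_path)) {
    utils::write.table(r, reactions_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(metabolites_path)) {
    utils::write.table(net$metabolites, metabolites_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(list(reactions = r, metabolites = net$metabolites))
}
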