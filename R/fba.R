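# Flux balance analysis, rich-media bounds and demand reactions.

#' One-letter amino-acid code to metabolite id prefix
#'
#' Cytosolic amino-acid species are named `<prefix>_c` (e.g. `gly_c`).
#' @export
AA_METABOLITE_PREFIX <- c(
  A = "ala", R = "arg", N = "asn", D = "asp", C = "cys",
  E = "glu", Q = "gln", G = "gly", H = "his", I = "ile",
  L = "leu", K = "lys", M = "met", F = "phe", P = "pro",
  S = "ser", T = "thr", W = "trp", Y = "tyr", V = "val")

#' Flux balance analysis
#'
#' Solves the LP `optimise v[objective]` subject to `S v = 0` and the
#' reaction bounds, with the package's deterministic bounded-variable
#' simplex. Infeasibility and unboundedness are reported in the status
#' field, not raised.
#'
#' @param net a `metabolic_network`.
#' @param objective_id reaction to optimise (defaults to the network's
#'   biomass objective).
#' @param sense `"max"` or `"min"`.
#' @return list with `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"`), `objective` and `fluxes` (named vector, `NULL`
#'   unless optimal).
#' @examples
#' net <- set_bounds(toy3_network(), "EX_A", lower = -10)
#' fba(net)$objective   # 10, the uptake bottleneck
#' @export
fba <- function(net, objective_id = net$objective_id,
                sense = c("max", "min")) {
  sense <- match.arg(sense)
  i <- reaction_index(net, objective_id)
  S <- stoichiometric_matrix(net)
  obj <- numeric(ncol(S)); obj[i] <- 1
  res <- solve_lp(obj, S, rep(0, nrow(S)),
                  net$reactions$lower_bound, net$reactions$upper_bound,
                  maximize = sense == "max")
  fluxes <- if (res$status == "optimal") {
    stats::setNames(res$x, net$reactions$id)
  } else NULL
  list(status = res$status, objective = res$objective, fluxes = fluxes)
}

#' Flux variability bounds of one reaction
#' @keywords internal
flux_range <- function(net, rid) {
  c(min = fba(net, rid, "min")$objective,
    max = fba(net, rid, "max")$objective)
}

#' Open all exchange reactions to a common uptake magnitude
#'
#' "Rich media": every exchange reaction's lower bound is set to `-U`
#' so any extracellular metabolite can be imported at up to `U` flux
#' units. Non-exchange bounds are untouched. The same bounds are meant
#' to be applied to every experimental condition.
#'
#' @param net a `metabolic_network`.
#' @param uptake non-negative uptake magnitude `U`.
#' @param overrides optional named numeric: exchange reaction id ->
#'   specific lower bound, applied after the blanket `-U`.
#' @return the modified network.
#' @export
apply_rich_media <- function(net, uptake = 1000, overrides = NULL) {
  stopifnot(uptake >= 0)
  ex <- net$reactions$id[net$reactions$is_exchange]
  if (length(ex)) net <- set_bounds(net, ex, lower = -uptake)
  if (!is.null(overrides)) {
    net <- set_bounds(net, names(overrides), lower = unname(overrides))
  }
  net
}

#' Build a protein demand from an amino-acid sequence
#'
#' The demand consumes free cytosolic amino acids with coefficients
#' equal to the residue counts of the sequence (no polymerisation energy
#' cost), the standard way to probe a model's capability to supply a
#' protein's composition.
#'
#' @param sequence amino-acid sequence (one-letter codes), a character
#'   scalar or anything coercible via `as.character` (e.g. a
#'   `Biostrings::AAString`).
#' @param name demand name.
#' @param compartment compartment code for the consumed species.
#' @param met_ids optional named map residue letter -> metabolite id,
#'   defaulting to `<prefix>_<compartment>` from [AA_METABOLITE_PREFIX].
#' @return a `demand_spec`: list with `name`, `metabolites` (named
#'   positive coefficients), `lower_bound`, `upper_bound`.
#' @examples
#' protein_demand_from_sequence("MKW", "demo")$metabolites
#' @export
protein_demand_from_sequence <- function(sequence, name,
                                         compartment = "c",
                                         met_ids = NULL) {
  sequence <- toupper(as.character(sequence))
  stopifnot(length(sequence) == 1L)
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(res), names(AA_METABOLITE_PREFIX))
  if (length(bad)) {
    stop(cf_error(paste0("unknown residue letter(s): ",
                         paste(bad, collapse = ", ")),
                  "cf_demand_error"))
  }
  counts <- table(factor(res, levels = names(AA_METABOLITE_PREFIX)))
  counts <- counts[counts > 0]
  ids <- if (is.null(met_ids)) {
    paste0(AA_METABOLITE_PREFIX[names(counts)], "_", compartment)
  } else unname(met_ids[names(counts)])
  structure(list(name = name,
                 metabolites = stats::setNames(as.numeric(counts), ids),
                 lower_bound = 0, upper_bound = 1000),
            class = "demand_spec")
}

#' Construct a plain demand specification
#'
#' Convenience constructor for metabolite demands such as ATP
#' maintenance (`atp_c + h2o_c -> adp_c + pi_c + h_c`, expressed here as
#' consumption of the listed species) or a reduced-glutathione sink.
#'
#' @param name demand name.
#' @param metabolites named numeric vector of consumed metabolites
#'   (positive coefficients).
#' @param lower_bound,upper_bound demand flux bounds.
#' @return a `demand_spec`.
#' @export
demand_spec <- function(name, metabolites, lower_bound = 0,
                        upper_bound = 1000) {
  stopifnot(length(metabolites) >= 1, all(metabolites > 0))
  structure(list(name = name, metabolites = metabolites,
                 lower_bound = lower_bound, upper_bound = upper_bound),
            class = "demand_spec")
}

#' Attach a demand reaction to a network
#'
#' Adds one sink reaction consuming the demand's metabolites. Used with
#' a small positive lower bound before GIMME extraction to force
#' production capability (e.g. a protein demand forced at 1e-6), then
#' reset to 0 for all subsequent simulations.
#'
#' @param net a `metabolic_network`.
#' @param demand a `demand_spec`.
#' @param lower_bound overrides the demand's stored lower bound if not
#'   `NULL`.
#' @return the network with reaction `DM_<name>` appended.
#' @export
add_demand <- function(net, demand, lower_bound = NULL) {
  stopifnot(inherits(demand, "demand_spec"))
  missing <- setdiff(names(demand$metabolites), net$metabolites$id)
  if (length(missing)) {
    stop(cf_error(paste0("demand references missing metabolite(s): ",
                         paste(missing, collapse = ", ")),
                  "cf_dangling_metabolite_error"))
  }
  rid <- paste0("DM_", demand$name)
  lb <- if (is.null(lower_bound)) demand$lower_bound else lower_bound
  net$reactions <- rbind(net$reactions, data.frame(
    id = rid, lower_bound = lb, upper_bound = demand$upper_bound,
    gpr = "", subsystem = "demand", is_exchange = FALSE,
    stringsAsFactors = FALSE))
  rownames(net$reactions) <- NULL
  net$stoich[[rid]] <- -demand$metabolites
  validate_network(net)
  net
}

#' Read the first sequence of a FASTA file
#'
#' @param path FASTA file.
#' @return character scalar sequence.
#' @export
read_demand_sequence <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) {
    stop(cf_error("empty FASTA file", "cf_parse_error"))
  }
  as.character(seqs[[1]])
}

#' Mean sampled flux of treated relative to control
#'
#' For each requested reaction, the ratio of mean sampled flux in the
#' treated condition to the mean in control. A zero control mean is
#' flagged `undefined`; a reaction missing from either sample matrix is
#' flagged `absent`.
#'
#' @param treated,control `flux_samples` objects (see [achr_sample()]).
#' @param reactions reaction ids; defaults to those shared.
#' @return data.frame with columns `reaction`, `mean_treated`,
#'   `mean_control`, `ratio`, `status`.
#' @export
relative_mean_flux <- function(treated, control, reactions = NULL) {
  mt <- sample_matrix(treated); mc <- sample_matrix(control)
  if (is.null(reactions)) {
    reactions <- intersect(colnames(mt), colnames(mc))
  }
  out <- data.frame(reaction = reactions,
                    mean_treated = NA_real_, mean_control = NA_real_,
                    ratio = NA_real_, status = "ok",
                    stringsAsFactors = FALSE)
  for (i in seq_along(reactions)) {
    r <- reactions[i]
    if (!(r %in% colnames(mt)) || !(r %in% colnames(mc))) {
      out$status[i] <- "absent"
      next
    }
    a <- mean(mt[, r]); b <- mean(mc[, r])
    out$mean_treated[i] <- a; out$mean_control[i] <- b
    if (b == 0) {
      out$status[i] <- "undefined"
    } else {
      out$ratio[i] <- a / b
    }
  }
  out
}
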