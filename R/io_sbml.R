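# SBML Level 3 (+ FBC version 2) import/export. This is a compatibility
# path for the subset of SBML used by flux-balance models: species,
# compartments, reactions with stoichiometry, FBC flux bounds, FBC gene
# product associations and the FBC objective. The native store is the
# JSON dialect in io_json.R.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

read_network_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop(cf_error(paste0("cannot parse SBML: ", conditionMessage(e)),
                  "cf_parse_error"))
  })
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  model <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model, "xml_missing")) {
    stop(cf_error("no <model> element in SBML file", "cf_parse_error"))
  }
  # FBC attributes are namespaced; accept both prefixed and plain forms
  a <- function(node, name) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) v <- xml2::xml_attr(node, paste0("fbc:", name), ns = ns)
    v
  }

  params <- xml2::xml_find_all(model, ".//s:listOfParameters/s:parameter", ns)
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))

  sp <- xml2::xml_find_all(model, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)

  gps <- xml2::xml_find_all(
    model, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gene_by_gpid <- stats::setNames(
    vapply(gps, a, character(1), name = "label"),
    vapply(gps, a, character(1), name = "id"))

  parse_assoc <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      gp <- a(node, "geneProduct")
      return(if (gp %in% names(gene_by_gpid)) unname(gene_by_gpid[[gp]])
             else sub("^gp_", "", gp))
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, parse_assoc, character(1))
    op <- if (nm == "and") " and " else " or "
    paste0("(", paste(parts, collapse = op), ")")
  }

  rx <- xml2::xml_find_all(model, ".//s:listOfReactions/s:reaction", ns)
  rids <- xml2::xml_attr(rx, "id")
  sto <- vector("list", length(rx))
  rows <- vector("list", length(rx))
  for (i in seq_along(rx)) {
    node <- rx[[i]]
    reac <- xml2::xml_find_all(node, "./s:listOfReactants/s:speciesReference", ns)
    prod <- xml2::xml_find_all(node, "./s:listOfProducts/s:speciesReference", ns)
    v <- c(
      stats::setNames(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
                      xml2::xml_attr(reac, "species")),
      stats::setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")),
                      xml2::xml_attr(prod, "species")))
    v <- tapply(v, names(v), sum)          # merge duplicated species refs
    sto[[i]] <- stats::setNames(as.numeric(v), names(v))
    lb_ref <- a(node, "lowerFluxBound"); ub_ref <- a(node, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pvals)) pvals[[lb_ref]]
          else as.numeric(lb_ref)
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pvals)) pvals[[ub_ref]]
          else as.numeric(ub_ref)
    assoc <- xml2::xml_find_first(
      node, "./fbc:geneProductAssociation/*", ns)
    gpr <- if (inherits(assoc, "xml_missing")) "" else parse_assoc(assoc)
    comp <- mets$compartment[match(names(sto[[i]]), mets$id)]
    rows[[i]] <- data.frame(
      id = rids[i], lower_bound = lb, upper_bound = ub, gpr = gpr,
      subsystem = "",
      is_exchange = length(sto[[i]]) == 1L && identical(comp, "e"),
      stringsAsFactors = FALSE)
  }
  names(sto) <- rids

  obj_ref <- xml2::xml_find_first(
    model, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  if (inherits(obj_ref, "xml_missing")) {
    stop(cf_error("SBML file has no FBC objective", "cf_missing_objective_error"))
  }
  objective_id <- a(obj_ref, "reaction")

  metabolic_network(
    id = a(model, "id") %||% "sbml_model",
    metabolites = mets,
    reactions = do.call(rbind, rows),
    stoich = sto,
    genes = if (length(gene_by_gpid)) sort(unique(unname(gene_by_gpid))) else NULL,
    objective_id = objective_id, validate = FALSE)
}

write_network_sbml <- function(net, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  m <- net$metabolites
  r <- net$reactions
  comps <- sort(unique(m$compartment))

  # flux bound parameters, deduplicated by value
  bvals <- sort(unique(c(r$lower_bound, r$upper_bound)))
  pid <- stats::setNames(sprintf("fb_%d", seq_along(bvals)),
                         fmt_num(bvals))
  pref <- function(v) unname(pid[fmt_num(v)])

  assoc_xml <- function(gpr, indent) {
    tree <- parse_gpr(gpr)
    render <- function(node, ind) {
      pad <- strrep(" ", ind)
      if (is.character(node)) {
        return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="gp_%s"/>',
                       pad, node))
      }
      tag <- if (node$op == "and") "fbc:and" else "fbc:or"
      c(sprintf("%s<%s>", pad, tag),
        unlist(lapply(node$args, render, ind = ind + 2)),
        sprintf("%s</%s>", pad, tag))
    }
    render(tree, indent)
  }

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            SBML_NS, FBC_NS),
    sprintf('  <model id="%s" fbc:strict="true">', esc(net$id)),
    "    <listOfCompartments>",
    sprintf('      <compartment id="%s" constant="true"/>', comps),
    "    </listOfCompartments>",
    "    <listOfSpecies>",
    sprintf(paste0('      <species id="%s" name="%s" compartment="%s" ',
                   'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
                   'constant="false"/>'),
            esc(m$id), esc(m$name), m$compartment),
    "    </listOfSpecies>",
    "    <listOfParameters>",
    sprintf('      <parameter id="%s" value="%s" constant="true"/>',
            unname(pid), names(pid)),
    "    </listOfParameters>")

  lines <- c(lines, "    <listOfReactions>")
  for (i in seq_len(nrow(r))) {
    sto <- net$stoich[[r$id[i]]]
    reac <- sto[sto < 0]; prod <- sto[sto > 0]
    lines <- c(lines, sprintf(
      '      <reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      esc(r$id[i]), tolower(as.character(r$lower_bound[i] < 0)),
      pref(r$lower_bound[i]), pref(r$upper_bound[i])))
    if (nzchar(r$gpr[i])) {
      lines <- c(lines, "        <fbc:geneProductAssociation>",
                 assoc_xml(r$gpr[i], 10),
                 "        </fbc:geneProductAssociation>")
    }
    if (length(reac)) {
      lines <- c(lines, "        <listOfReactants>",
                 sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                         esc(names(reac)), fmt_num(abs(reac))),
                 "        </listOfReactants>")
    }
    if (length(prod)) {
      lines <- c(lines, "        <listOfProducts>",
                 sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                         esc(names(prod)), fmt_num(prod)),
                 "        </listOfProducts>")
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>")

  if (length(net$genes)) {
    lines <- c(lines, "    <fbc:listOfGeneProducts>",
               sprintf('      <fbc:geneProduct fbc:id="gp_%s" fbc:label="%s"/>',
                       esc(net$genes), esc(net$genes)),
               "    </fbc:listOfGeneProducts>")
  }
  lines <- c(lines,
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    "        <fbc:listOfFluxObjectives>",
    sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
            esc(net$objective_id)),
    "        </fbc:listOfFluxObjectives>",
    "      </fbc:objective>",
    "    </fbc:listOfObjectives>",
    "  </model>",
    "</sbml>")
  writeLines(lines, path)
}
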