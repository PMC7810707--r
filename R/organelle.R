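# Organelle enrichment profiles of differentially expressed
# sub-networks: DE genes are mapped to reactions through the GPR rules,
# the metabolites of those reactions are collected, and distinct
# metabolites are counted per sub-cellular compartment.

#' Reactions associated with a set of DE genes
#'
#' By default a reaction is selected when any gene of its GPR rule is in
#' `de_genes` (any-occurrence rule, matching the loci-to-reaction
#' mapping); `mode = "strict"` instead requires the GPR to evaluate TRUE
#' with `de_genes` as the present set, and never selects gene-free
#' reactions.
#'
#' @param net a `metabolic_network`.
#' @param de_genes character vector of gene ids; ids outside the gene
#'   universe are ignored with a message.
#' @param mode `"any"` or `"strict"`.
#' @return character vector of reaction ids (network order).
#' @export
de_reaction_subnetwork <- function(net, de_genes, mode = c("any", "strict")) {
  mode <- match.arg(mode)
  unknown <- setdiff(de_genes, net$genes)
  if (length(unknown)) {
    message("ignoring ", length(unknown),
            " gene id(s) absent from the network gene universe")
    de_genes <- intersect(de_genes, net$genes)
  }
  hit <- vapply(net$reactions$gpr, function(g) {
    if (!nzchar(g)) return(FALSE)
    if (mode == "any") length(intersect(gpr_genes(g), de_genes)) > 0
    else evaluate_gpr(g, de_genes)
  }, logical(1), USE.NAMES = FALSE)
  net$reactions$id[hit]
}

#' Per-compartment metabolite (or reaction) counts of a reaction set
#'
#' Counts, for every compartment of the network, the distinct
#' metabolites participating in any of the selected reactions; each
#' metabolite belongs to exactly one compartment. `count = "reactions"`
#' instead counts selected reactions per compartment (a reaction spanning
#' several compartments counts once in each).
#'
#' @param net a `metabolic_network`.
#' @param reaction_ids subset of the network's reaction ids.
#' @param direction label stored in the output (`"up"`, `"down"`,
#'   `"combined"`, ...).
#' @param count `"metabolites"` (default) or `"reactions"`.
#' @param exclude optional metabolite ids to ignore (e.g. currency
#'   metabolites such as protons, water or ATP).
#' @return data.frame with columns `direction`, `compartment`,
#'   `count`, `network_total`, `network_fraction`; one row per
#'   compartment code present in the network.
#' @export
organelle_profile <- function(net, reaction_ids, direction = "combined",
                              count = c("metabolites", "reactions"),
                              exclude = NULL) {
  count <- match.arg(count)
  stopifnot(all(reaction_ids %in% net$reactions$id))
  comp_of <- stats::setNames(net$metabolites$compartment,
                             net$metabolites$id)
  comps <- sort(unique(net$metabolites$compartment))
  mets_of <- function(rids) {
    m <- unique(unlist(lapply(net$stoich[rids], names), use.names = FALSE))
    setdiff(m, exclude)
  }
  if (count == "metabolites") {
    sel <- mets_of(reaction_ids)
    tot <- mets_of(net$reactions$id)
    cnt <- table(factor(comp_of[sel], levels = comps))
    net_tot <- table(factor(comp_of[tot], levels = comps))
  } else {
    comp_of_rxn <- lapply(net$stoich, function(s) {
      unique(comp_of[setdiff(names(s), exclude)])
    })
    cnt <- table(factor(unlist(comp_of_rxn[reaction_ids]), levels = comps))
    net_tot <- table(factor(unlist(comp_of_rxn), levels = comps))
  }
  data.frame(direction = direction, compartment = comps,
             count = as.integer(cnt),
             network_total = as.integer(net_tot),
             network_fraction = ifelse(net_tot > 0,
                                       as.integer(cnt) / as.integer(net_tot),
                                       NA_real_),
             stringsAsFactors = FALSE)
}

#' Up / down / combined organelle profiles for one condition
#'
#' @param net a `metabolic_network`.
#' @param up_genes,down_genes DE gene sets.
#' @param ... passed to [de_reaction_subnetwork()] and
#'   [organelle_profile()] (`mode`, `count`, `exclude`).
#' @return data.frame stacking the three profiles.
#' @export
condition_organelle_profiles <- function(net, up_genes, down_genes,
                                         mode = "any",
                                         count = "metabolites",
                                         exclude = NULL) {
  r_up <- de_reaction_subnetwork(net, up_genes, mode = mode)
  r_down <- de_reaction_subnetwork(net, down_genes, mode = mode)
  rbind(
    organelle_profile(net, r_up, "up", count = count, exclude = exclude),
    organelle_profile(net, r_down, "down", count = count, exclude = exclude),
    organelle_profile(net, union(r_up, r_down), "combined",
                      count = count, exclude = exclude))
}
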