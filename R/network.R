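# Compartmentalised constraint-based metabolic network: data model,
# validation, stoichiometric matrix and null-space dimension.

#' Recognised compartment codes
#'
#' The fixed eight-code organelle set: cytosol (`c`), extracellular
#' (`e`), golgi (`g`), lysosome (`l`), mitochondria (`m`), nucleus (`n`),
#' endoplasmic reticulum (`r`) and peroxisome (`p`).
#' @export
COMPARTMENT_CODES <- c(
  c = "cytosol", e = "extracellular", g = "golgi", l = "lysosome",
  m = "mitochondria", n = "nucleus", r = "endoplasmic reticulum",
  p = "peroxisome"
)

cf_error <- function(msg, class) {
  errorCondition(msg, class = c(class, "cf_error"))
}

#' Construct a metabolic network
#'
#' @param id network identifier.
#' @param metabolites data.frame with columns `id`, `name`,
#'   `compartment` (one of [COMPARTMENT_CODES]).
#' @param reactions data.frame with columns `id`, `lower_bound`,
#'   `upper_bound`, `gpr` (rule string, `""` for none), `subsystem`,
#'   `is_exchange`.
#' @param stoich named list mapping reaction id to a named numeric vector
#'   of metabolite coefficients (negative = consumed).
#' @param genes character vector, the gene universe; defaults to the
#'   union of all GPR leaves.
#' @param objective_id id of the biomass (objective) pseudo-reaction.
#' @param validate run [validate_network()] on the result.
#' @return An object of class `metabolic_network`.
#' @export
metabolic_network <- function(id, metabolites, reactions, stoich,
                              genes = NULL, objective_id, validate = TRUE) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(reactions$gpr, gpr_genes))))
  }
  net <- structure(
    list(id = id, metabolites = metabolites, reactions = reactions,
         stoich = stoich, genes = as.character(genes),
         objective_id = objective_id),
    class = "metabolic_network")
  if (validate) validate_network(net)
  net
}

#' Validate a metabolic network
#'
#' Checks id uniqueness, compartment codes, bound ordering, non-empty
#' stoichiometries, metabolite references, GPR well-formedness against
#' the gene universe, and that the objective resolves to a reaction.
#' Violations raise classed conditions (`cf_compartment_error`,
#' `cf_dangling_metabolite_error`, `cf_missing_objective_error`,
#' `cf_network_error`).
#'
#' @param net a `metabolic_network`.
#' @return `net`, invisibly.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  m <- net$metabolites
  r <- net$reactions
  if (anyDuplicated(m$id)) {
    stop(cf_error("duplicate metabolite ids", "cf_network_error"))
  }
  if (anyDuplicated(r$id)) {
    stop(cf_error("duplicate reaction ids", "cf_network_error"))
  }
  bad <- setdiff(unique(m$compartment), names(COMPARTMENT_CODES))
  if (length(bad)) {
    stop(cf_error(paste0("unknown compartment code(s): ",
                         paste(bad, collapse = ", ")),
                  "cf_compartment_error"))
  }
  if (any(r$lower_bound > r$upper_bound)) {
    stop(cf_error("lower_bound > upper_bound", "cf_network_error"))
  }
  if (any(!is.finite(r$lower_bound)) || any(!is.finite(r$upper_bound))) {
    stop(cf_error("reaction bounds must be finite", "cf_network_error"))
  }
  if (!setequal(names(net$stoich), r$id) && nrow(r) > 0) {
    stop(cf_error("stoichiometry list does not match reaction ids",
                  "cf_network_error"))
  }
  for (rid in r$id) {
    sto <- net$stoich[[rid]]
    if (length(sto) == 0L) {
      stop(cf_error(paste0("empty stoichiometry in reaction ", rid),
                    "cf_network_error"))
    }
    if (any(sto == 0)) {
      stop(cf_error(paste0("zero coefficient in reaction ", rid),
                    "cf_network_error"))
    }
    missing <- setdiff(names(sto), m$id)
    if (length(missing)) {
      stop(cf_error(paste0("reaction ", rid,
                           " references unknown metabolite(s): ",
                           paste(missing, collapse = ", ")),
                    "cf_dangling_metabolite_error"))
    }
  }
  gpr_leaves <- unlist(lapply(r$gpr, gpr_genes))
  outside <- setdiff(gpr_leaves, net$genes)
  if (length(outside)) {
    stop(cf_error(paste0("GPR gene(s) outside the gene universe: ",
                         paste(outside, collapse = ", ")),
                  "cf_network_error"))
  }
  if (!(net$objective_id %in% r$id)) {
    stop(cf_error(paste0("objective reaction not found: ", net$objective_id),
                  "cf_missing_objective_error"))
  }
  invisible(net)
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("<metabolic_network> %s: %d metabolites x %d reactions, %d genes\n",
              x$id, nrow(x$metabolites), nrow(x$reactions), length(x$genes)))
  cat(sprintf("  objective: %s\n", x$objective_id))
  comps <- table(x$metabolites$compartment)
  if (length(comps)) {
    cat("  compartments:",
        paste(sprintf("%s=%d", names(comps), comps), collapse = " "), "\n")
  }
  invisible(x)
}

#' Stoichiometric matrix
#'
#' Dense matrix S with one row per metabolite and one column per
#' reaction; entry (i, j) is the coefficient of metabolite i in reaction
#' j (negative = consumed).
#'
#' @param net a `metabolic_network`.
#' @return numeric matrix with dimnames (metabolite ids x reaction ids).
#' @export
stoichiometric_matrix <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  mids <- net$metabolites$id
  rids <- net$reactions$id
  S <- matrix(0, nrow = length(mids), ncol = length(rids),
              dimnames = list(mids, rids))
  for (rid in rids) {
    sto <- net$stoich[[rid]]
    S[names(sto), rid] <- sto
  }
  S
}

#' Dimension of the null space of S
#'
#' Computes `ncol(S) - rank(S)` with the rank taken as the number of
#' singular values above `max(dim(S)) * .Machine$double.eps * max(sv)`
#' (standard numerical rank). This counts the independent steady-state
#' flux degrees of freedom.
#'
#' @param net a `metabolic_network`.
#' @return non-negative integer.
#' @export
nullspace_dimension <- function(net) {
  S <- stoichiometric_matrix(net)
  if (ncol(S) == 0L) return(0L)
  if (nrow(S) == 0L) return(ncol(S))
  sv <- svd(S, nu = 0, nv = 0)$d
  tol <- max(dim(S)) * .Machine$double.eps * max(sv)
  as.integer(ncol(S) - sum(sv > tol))
}

# orthonormal null-space basis of a stoichiometric matrix (columns span
# {v : S v = 0}); NULL when the null space is trivial
nullspace_basis <- function(S) {
  if (ncol(S) == 0L) return(NULL)
  if (nrow(S) == 0L) return(diag(ncol(S)))
  dec <- svd(S, nu = 0, nv = ncol(S))
  tol <- max(dim(S)) * .Machine$double.eps * max(dec$d)
  rank <- sum(dec$d > tol)
  if (rank == ncol(S)) return(NULL)
  dec$v[, (rank + 1L):ncol(S), drop = FALSE]
}

#' Restrict a network to a subset of reactions
#'
#' Keeps the given reactions and drops metabolites that no longer occur
#' in any retained reaction. The objective reaction is kept if present in
#' `keep`; otherwise `objective_id` is preserved but the result will not
#' validate, so callers extracting sub-models should retain it.
#'
#' @param net a `metabolic_network`.
#' @param keep character vector of reaction ids to retain.
#' @param id id for the sub-network.
#' @return a `metabolic_network`.
#' @export
subset_network <- function(net, keep, id = paste0(net$id, "_sub")) {
  stopifnot(all(keep %in% net$reactions$id))
  keep <- net$reactions$id[net$reactions$id %in% keep]  # preserve order
  r <- net$reactions[match(keep, net$reactions$id), , drop = FALSE]
  rownames(r) <- NULL
  sto <- net$stoich[keep]
  used <- unique(unlist(lapply(sto, names)))
  m <- net$metabolites[net$metabolites$id %in% used, , drop = FALSE]
  rownames(m) <- NULL
  metabolic_network(id = id, metabolites = m, reactions = r, stoich = sto,
                    genes = net$genes, objective_id = net$objective_id,
                    validate = FALSE)
}

#' Reorder the reaction columns of a network
#'
#' Used by the GIMME consensus machinery: different column orders can
#' steer a degenerate LP to different optima.
#'
#' @param net a `metabolic_network`.
#' @param perm integer permutation of `seq_len(nrow(net$reactions))`.
#' @return a `metabolic_network` with permuted reaction order.
#' @export
permute_reactions <- function(net, perm) {
  stopifnot(sort(perm) == seq_len(nrow(net$reactions)))
  r <- net$reactions[perm, , drop = FALSE]
  rownames(r) <- NULL
  metabolic_network(id = net$id, metabolites = net$metabolites,
                    reactions = r, stoich = net$stoich[r$id],
                    genes = net$genes, objective_id = net$objective_id,
                    validate = FALSE)
}

# bounds lookup helpers
reaction_index <- function(net, rid) {
  i <- match(rid, net$reactions$id)
  if (any(is.na(i))) {
    stop(cf_error(paste0("unknown reaction id(s): ",
                         paste(rid[is.na(i)], collapse = ", ")),
                  "cf_network_error"))
  }
  i
}

#' Set reaction bounds
#' @param net a `metabolic_network`.
#' @param rid reaction id(s).
#' @param lower,upper replacement bounds (recycled); `NULL` leaves a
#'   bound untouched.
#' @return the modified network.
#' @export
set_bounds <- function(net, rid, lower = NULL, upper = NULL) {
  i <- reaction_index(net, rid)
  if (!is.null(lower)) net$reactions$lower_bound[i] <- lower
  if (!is.null(upper)) net$reactions$upper_bound[i] <- upper
  validate_network(net)
  net
}
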