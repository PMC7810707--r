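# GIMME context-specific model extraction.
#
# Given presence/absence calls, GIMME keeps all expressed and
# non-gene-associated reactions and asks which "absent" reactions must
# nevertheless carry flux for the network to attain a required fraction
# of its maximal objective. It solves
#
#   min  sum_i penalty_i * |v_i|
#   s.t. S v = 0,  bounds,  v_objective >= f * Z*
#
# with binary penalties (absent = 1, present or no GPR = 0) and Z* the
# parent FBA optimum. Reversible reactions are split into forward and
# backward non-negative components for the absolute value and re-merged
# on output. The retained set is {penalty-0 reactions} plus {absent
# reactions with |v*| above the activity tolerance}; the attained
# penalty sum is the inconsistency score.

#' GIMME configuration
#'
#' @param required_fraction fraction `f` of the parent objective optimum
#'   the extracted model must retain (0 < f <= 1).
#' @param activity_tol absolute flux above which an absent reaction
#'   counts as flux-carrying.
#' @param iterations number of reaction-reordering iterations for
#'   [gimme_consensus()].
#' @param seed integer seed driving the reorderings.
#' @return a `gimme_config` list.
#' @export
gimme_config <- function(required_fraction = 0.5, activity_tol = 1e-9,
                         iterations = 3L, seed = 1L) {
  stopifnot(required_fraction > 0, required_fraction <= 1, iterations >= 1)
  structure(list(required_fraction = required_fraction,
                 activity_tol = activity_tol,
                 iterations = as.integer(iterations),
                 seed = as.integer(seed)),
            class = "gimme_config")
}

present_gene_set <- function(presence) {
  if (is.logical(presence)) names(presence)[presence] else as.character(presence)
}

#' Extract a context-specific model with GIMME
#'
#' @param net parent `metabolic_network` (forced demands, if any, must
#'   already be attached with their pre-extraction lower bounds).
#' @param presence named logical vector (gene -> present) or character
#'   vector of present gene ids; must cover every gene the GPRs use.
#' @param config a [gimme_config()].
#' @param iteration label stored on the result.
#' @param verify re-run FBA on the extracted sub-network to confirm the
#'   objective floor.
#' @return a `context_model`: list with `retained` (reaction ids, parent
#'   order), `inconsistency`, `floor`, `parent_optimum`,
#'   `attained_objective`, `feasible`, `iteration`.
#' @export
gimme_extract <- function(net, presence, config = gimme_config(),
                          iteration = 1L, verify = TRUE) {
  present <- present_gene_set(presence)
  r <- net$reactions
  penalty <- vapply(r$gpr, function(g) {
    if (!nzchar(g)) 0 else if (evaluate_gpr(g, present)) 0 else 1
  }, numeric(1), USE.NAMES = FALSE)

  parent <- fba(net)
  if (parent$status != "optimal") {
    stop(cf_error(paste0("objective floor unattainable: parent FBA ",
                         parent$status),
                  "cf_gimme_floor_error"))
  }
  floor_val <- config$required_fraction * parent$objective

  S <- stoichiometric_matrix(net)
  n <- ncol(S)
  lbf <- pmax(r$lower_bound, 0); ubf <- pmax(r$upper_bound, 0)
  lbb <- pmax(-r$upper_bound, 0); ubb <- pmax(-r$lower_bound, 0)
  iobj <- reaction_index(net, net$objective_id)
  cobj <- numeric(n); cobj[iobj] <- 1
  # variables: [vf, vb, slack]; constraint rows: S(vf - vb) = 0 and
  # objective flux - slack = floor
  A <- rbind(cbind(S, -S, 0),
             c(cobj, -cobj, -1))
  b <- c(rep(0, nrow(S)), floor_val)
  lower <- c(lbf, lbb, 0)
  upper <- c(ubf, ubb, Inf)
  objv <- c(penalty, penalty, 0)
  res <- solve_lp(objv, A, b, lower, upper, maximize = FALSE)
  if (res$status != "optimal") {
    stop(cf_error(paste0("GIMME LP not optimal: ", res$status),
                  "cf_gimme_floor_error"))
  }
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  names(v) <- r$id
  retained <- r$id[penalty == 0 | abs(v) > config$activity_tol]

  attained <- NA_real_; feasible <- NA
  if (verify) {
    sub <- subset_network(net, retained)
    chk <- fba(sub)
    attained <- chk$objective
    feasible <- chk$status == "optimal" &&
      chk$objective >= floor_val - 1e-6
  }
  structure(list(network_id = net$id, retained = retained,
                 inconsistency = res$objective, floor = floor_val,
                 parent_optimum = parent$objective,
                 attained_objective = attained, feasible = feasible,
                 iteration = iteration, fluxes = v,
                 config = config),
            class = "context_model")
}

#' @export
print.context_model <- function(x, ...) {
  cat(sprintf("<context_model> %s [%s]: %d reactions retained\n",
              x$network_id, as.character(x$iteration), length(x$retained)))
  cat(sprintf("  inconsistency %.6g; floor %.6g; attained %.6g; feasible: %s\n",
              x$inconsistency, x$floor, x$attained_objective,
              as.character(x$feasible)))
  invisible(x)
}

#' Consensus GIMME extraction over random reaction reorderings
#'
#' Runs [gimme_extract()] `iterations` times, each on a copy of the
#' network whose reaction columns are permuted by the seeded generator.
#' Because the LP can be degenerate, different column orders may retain
#' different alternative pathways; the consensus model keeps only the
#' reactions present in every iteration. A consensus that loses the
#' objective floor is flagged (`feasible = FALSE`) with a warning, never
#' silently used.
#'
#' @inheritParams gimme_extract
#' @return a `context_model` with `iteration = "consensus"` and an
#'   `iterations` field holding the per-iteration models and their
#'   permutation seeds.
#' @export
gimme_consensus <- function(net, presence, config = gimme_config()) {
  k <- config$iterations
  iters <- vector("list", k)
  for (i in seq_len(k)) {
    pseed <- derive_seed(config$seed, 97L, i)
    perm <- with_seed(pseed, sample.int(nrow(net$reactions)))
    pnet <- permute_reactions(net, perm)
    cm <- gimme_extract(pnet, presence, config, iteration = i)
    cm$permutation_seed <- pseed
    iters[[i]] <- cm
  }
  consensus <- Reduce(intersect, lapply(iters, `[[`, "retained"))
  consensus <- net$reactions$id[net$reactions$id %in% consensus]
  sub <- subset_network(net, consensus)
  chk <- fba(sub)
  floor_val <- iters[[1]]$floor
  feasible <- chk$status == "optimal" && chk$objective >= floor_val - 1e-6
  if (!feasible) {
    warning(warningCondition(
      "consensus model does not attain the objective floor",
      class = "cf_consensus_floor_warning"))
  }
  structure(list(network_id = net$id, retained = consensus,
                 inconsistency = max(vapply(iters, `[[`, numeric(1),
                                            "inconsistency")),
                 floor = floor_val,
                 parent_optimum = iters[[1]]$parent_optimum,
                 attained_objective = chk$objective,
                 feasible = feasible, iteration = "consensus",
                 iterations = iters, config = config),
            class = "context_model")
}

#' Serialise a context model to JSON
#'
#' @param cm a `context_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_context_model <- function(cm, path) {
  x <- list(network_id = cm$network_id, iteration = cm$iteration,
            retained = cm$retained, inconsistency = cm$inconsistency,
            floor = cm$floor, parent_optimum = cm$parent_optimum,
            attained_objective = cm$attained_objective,
            feasible = cm$feasible)
  if (!is.null(cm$iterations)) {
    x$iterations <- lapply(cm$iterations, function(it) {
      list(iteration = it$iteration, retained = it$retained,
           inconsistency = it$inconsistency,
           permutation_seed = it$permutation_seed)
    })
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
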