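# Correlated reaction sets (co-sets) from sampled fluxes.
#
# Two reactions belong to the same co-set when their sampled fluxes are
# correlated at |r| >= threshold (default 0.975, i.e. R^2 about 0.95).
# Grouping is by single-linkage connected components of the thresholded
# correlation graph; complete-linkage clique finding is offered for
# small inputs.

#' Pairwise Pearson correlations of sampled fluxes
#'
#' Zero-variance (constant) reactions cannot be correlated and are
#' excluded and listed.
#'
#' @param fs a `flux_samples` or points x reactions matrix (>= 2 points).
#' @return list with `correlation` (matrix over retained reactions) and
#'   `excluded` (ids of constant reactions).
#' @export
flux_correlation_matrix <- function(fs) {
  m <- sample_matrix(fs)
  if (nrow(m) < 2L) {
    stop(cf_error("need at least 2 sampled points", "cf_coset_error"))
  }
  sds <- apply(m, 2, stats::sd)
  excluded <- colnames(m)[sds == 0]
  keep <- m[, sds > 0, drop = FALSE]
  cc <- if (ncol(keep)) stats::cor(keep) else
    matrix(numeric(), 0, 0)
  list(correlation = cc, excluded = excluded)
}

#' Group reactions into co-sets
#'
#' Builds the graph with an edge wherever `|r| >= threshold` (or
#' `r >= threshold` in signed mode) and reports its connected components
#' of size >= 2 as co-sets; singleton components are returned separately.
#'
#' @param correlation square correlation matrix (or the list returned by
#'   [flux_correlation_matrix()]).
#' @param threshold correlation threshold in (0, 1].
#' @param signed if `TRUE`, only positive correlations link reactions;
#'   by default anticorrelated pairs (r <= -threshold) are grouped too.
#' @param method `"component"` (single-linkage connected components,
#'   default) or `"clique"` (maximal cliques, complete linkage; small
#'   inputs only). With cliques, overlapping cliques are reduced to
#'   disjoint sets greedily by decreasing size, so the result is still a
#'   partition.
#' @return list with `cosets` (list of `coset` objects: `members`,
#'   `size`), `singletons` (character), `excluded` (from the input, if
#'   given as a list).
#' @export
build_cosets <- function(correlation, threshold = 0.975, signed = FALSE,
                         method = c("component", "clique")) {
  method <- match.arg(method)
  excluded <- character()
  if (is.list(correlation) && !is.data.frame(correlation)) {
    excluded <- correlation$excluded
    correlation <- correlation$correlation
  }
  stopifnot(threshold > 0, threshold <= 1)
  ids <- colnames(correlation)
  if (is.null(ids)) {
    stop(cf_error("correlation matrix must have reaction column names",
                  "cf_coset_error"))
  }
  strength <- if (signed) correlation else abs(correlation)
  adj <- strength >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  groups <- if (method == "component") {
    comp <- igraph::components(g)
    split(ids, comp$membership)
  } else {
    cl <- igraph::max_cliques(g, min = 1)
    cl <- lapply(cl, function(v) ids[as.integer(v)])
    cl <- cl[order(-vapply(cl, length, integer(1)),
                   vapply(cl, function(x) min(x), character(1)))]
    taken <- character(); out <- list()
    for (memb in cl) {
      memb <- setdiff(memb, taken)
      if (length(memb)) { out <- c(out, list(memb)); taken <- c(taken, memb) }
    }
    out
  }
  sizes <- vapply(groups, length, integer(1))
  singles <- unlist(groups[sizes == 1L], use.names = FALSE)
  cosets <- lapply(groups[sizes >= 2L], function(memb) {
    memb <- ids[ids %in% memb]          # stable matrix-column order
    structure(list(members = memb, size = length(memb)), class = "coset")
  })
  # deterministic order: by first member's column position
  if (length(cosets)) {
    first <- vapply(cosets, function(cs) match(cs$members[1], ids), integer(1))
    cosets <- cosets[order(first)]
    names(cosets) <- sprintf("coset_%03d", seq_along(cosets))
  }
  list(cosets = cosets, singletons = sort(c(singles, character())),
       excluded = excluded)
}

#' Filter co-sets by minimum size
#'
#' @param cosets the `cosets` element of [build_cosets()] (or the whole
#'   list).
#' @param min_size smallest member count retained (default 6, the usual
#'   "large co-set" focus).
#' @return list of `coset` objects, input order preserved.
#' @export
large_cosets <- function(cosets, min_size = 6) {
  stopifnot(min_size >= 2)
  if (!is.null(cosets$cosets)) cosets <- cosets$cosets
  cosets[vapply(cosets, function(cs) cs$size >= min_size, logical(1))]
}

#' Per-condition relative flux profile of co-sets
#'
#' For each co-set a representative reaction is chosen (largest mean
#' absolute flux in the reference condition among members present in
#' every condition); its mean absolute sampled flux per condition is
#' expressed as a percentage of the sum across conditions, so each
#' profile row sums to 100 when defined.
#'
#' @param cosets list of `coset` objects (or [build_cosets()] output).
#' @param fs_by_condition named list of `flux_samples`, one per
#'   condition; the first (or one named `control`) is the reference.
#' @return data.frame with one row per co-set: `coset`, `representative`,
#'   `flag`, one `value_<cond>` and one `pct_<cond>` column per
#'   condition.
#' @export
coset_relative_profile <- function(cosets, fs_by_condition) {
  if (!is.null(cosets$cosets)) cosets <- cosets$cosets
  conds <- names(fs_by_condition)
  ref <- if ("control" %in% conds) "control" else conds[1]
  mats <- lapply(fs_by_condition, sample_matrix)
  rows <- lapply(seq_along(cosets), function(i) {
    cs <- cosets[[i]]
    everywhere <- cs$members[vapply(cs$members, function(r) {
      all(vapply(mats, function(m) r %in% colnames(m), logical(1)))
    }, logical(1))]
    flag <- "ok"
    if (length(everywhere) == 0L) {
      # no member shared by all conditions: profile over members present
      # in the reference only, absent conditions contribute 0
      everywhere <- cs$members[cs$members %in% colnames(mats[[ref]])]
      flag <- "partial"
      if (length(everywhere) == 0L) everywhere <- cs$members[1]
    }
    refmeans <- vapply(everywhere, function(r) {
      if (r %in% colnames(mats[[ref]])) mean(abs(mats[[ref]][, r])) else 0
    }, numeric(1))
    rep_id <- everywhere[which.max(refmeans)]
    vals <- vapply(conds, function(cd) {
      m <- mats[[cd]]
      if (rep_id %in% colnames(m)) mean(abs(m[, rep_id])) else 0
    }, numeric(1))
    tot <- sum(vals)
    pct <- if (tot > 0) vals / tot * 100 else {
      flag <- "all_zero"
      rep(NA_real_, length(vals))
    }
    row <- data.frame(coset = names(cosets)[i] %||% sprintf("coset_%03d", i),
                      representative = rep_id, flag = flag,
                      stringsAsFactors = FALSE)
    for (cd in conds) row[[paste0("value_", cd)]] <- vals[[cd]]
    for (cd in conds) row[[paste0("pct_", cd)]] <- unname(pct[match(cd, conds)])
    row
  })
  do.call(rbind, rows)
}

#' Cluster co-set profiles
#'
#' Agglomerative (average-linkage) hierarchical clustering of the
#' percentage profiles under Euclidean distance. Rows with undefined
#' percentages are dropped. Leaf order is made deterministic by seriating
#' ties on the co-set id.
#'
#' @param profile output of [coset_relative_profile()].
#' @return an object of class `hclust` (with co-set ids as labels), or
#'   `NULL` if fewer than 2 usable profiles.
#' @export
cluster_profiles <- function(profile) {
  pct <- as.matrix(profile[, grep("^pct_", names(profile)), drop = FALSE])
  rownames(pct) <- profile$coset
  keep <- stats::complete.cases(pct)
  pct <- pct[keep, , drop = FALSE]
  # stable tie-break: order rows by id before clustering
  pct <- pct[order(rownames(pct)), , drop = FALSE]
  if (nrow(pct) < 2L) return(NULL)
  stats::hclust(stats::dist(pct, method = "euclidean"), method = "average")
}

#' Write a co-set membership table
#'
#' @param cosets [build_cosets()] output (or its `cosets` element).
#' @param path TSV output path.
#' @return the table, invisibly.
#' @export
write_coset_table <- function(cosets, path) {
  if (!is.null(cosets$cosets)) cosets <- cosets$cosets
  tab <- do.call(rbind, lapply(seq_along(cosets), function(i) {
    data.frame(coset = names(cosets)[i] %||% sprintf("coset_%03d", i),
               size = cosets[[i]]$size,
               members = paste(cosets[[i]]$members, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(tab)) {
    tab <- data.frame(coset = character(), size = integer(),
                      members = character())
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
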