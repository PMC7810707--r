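# Expression intensities, presence/absence calls, differential-gene
# thresholding, Venn partitioning and fold-change rank statistics.

#' Read an expression table (gene, intensity) from TSV
#' @param path TSV file with header columns `gene` and `intensity`.
#' @return data.frame.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "intensity")
  if (!all(need %in% names(tab))) {
    stop(cf_error("expression TSV must have columns 'gene' and 'intensity'",
                  "cf_parse_error"))
  }
  tab
}

#' Read a differential-expression table from TSV
#' @param path TSV with header columns `gene`, `fold_change`, `p_value`,
#'   `fdr_q`.
#' @return data.frame.
#' @export
read_de_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "fold_change", "p_value", "fdr_q")
  if (!all(need %in% names(tab))) {
    stop(cf_error(paste0("DE TSV must have columns: ",
                         paste(need, collapse = ", ")), "cf_parse_error"))
  }
  tab
}

#' Presence/absence calls from intensities
#'
#' A gene is present when its intensity is at or above the cutoff
#' (boundary inclusive). The default cutoff of 11 intensity units
#' corresponds to the largest incremental change in transcript counts on
#' the scale the calls were designed for.
#'
#' @param profile data.frame with columns `gene`, `intensity`, or a
#'   named numeric vector of intensities.
#' @param cutoff non-negative presence threshold.
#' @return named logical vector (gene -> present).
#' @export
call_presence <- function(profile, cutoff = 11) {
  stopifnot(cutoff >= 0)
  if (is.data.frame(profile)) {
    intensity <- stats::setNames(profile$intensity, profile$gene)
  } else intensity <- profile
  if (any(intensity < 0)) {
    stop(cf_error("negative intensity", "cf_expression_error"))
  }
  if (anyDuplicated(names(intensity))) {
    stop(cf_error("duplicated gene ids in expression profile",
                  "cf_expression_error"))
  }
  intensity >= cutoff
}

#' Threshold a differential-expression table
#'
#' Up-regulated: linear fold change strictly above `up_threshold`;
#' down-regulated: strictly below `down_threshold`; both additionally
#' require `p <= p_max` and FDR `q < q_max`. The defaults are the
#' 1.75 / 0.55-fold, p <= 0.05, FDR q < 0.1 scheme; the log2-based
#' alternative (|log2 fold| > 0.8, i.e. 1.741 / 0.574) is available by
#' passing those thresholds.
#'
#' @param records data.frame with columns `gene`, `fold_change`,
#'   `p_value`, `fdr_q`.
#' @param up_threshold,down_threshold linear fold-change cuts
#'   (`up_threshold > down_threshold > 0`).
#' @param p_max,q_max p-value and FDR caps.
#' @return list with character vectors `up` and `down` (disjoint).
#' @export
call_de <- function(records, up_threshold = 1.75, down_threshold = 0.55,
                    p_max = 0.05, q_max = 0.1) {
  stopifnot(up_threshold > down_threshold, down_threshold > 0)
  if (any(records$fold_change <= 0)) {
    stop(cf_error("non-positive fold change", "cf_de_error"))
  }
  keep <- records$p_value <= p_max & records$fdr_q < q_max
  list(up = records$gene[keep & records$fold_change > up_threshold],
       down = records$gene[keep & records$fold_change < down_threshold])
}

#' Occupancy partition of k sets (generalised Venn counts)
#'
#' Splits the union of the input sets into the `2^k - 1` disjoint
#' occupancy strata (members of exactly one set, each pairwise overlap,
#' ..., common to all) and counts each.
#'
#' @param sets named list of >= 2 character vectors (unnamed lists get
#'   `set1`, `set2`, ... labels).
#' @return data.frame with columns `stratum` (set names joined by `&`),
#'   `degree` (number of sets in the stratum) and `count`; the counts
#'   sum to `length(union)`. Convenience attributes `exclusive` (named
#'   per-set exclusive counts) and `common` (count shared by all sets)
#'   are attached.
#' @export
venn_partition <- function(sets) {
  k <- length(sets)
  stopifnot(k >= 2)
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("set", seq_len(k))
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1)
  combos <- unlist(lapply(seq_len(k), function(r) {
    utils::combn(seq_len(k), r, simplify = FALSE)
  }), recursive = FALSE)
  rows <- lapply(combos, function(idx) {
    inside <- if (length(universe)) {
      rowSums(member[, idx, drop = FALSE]) == length(idx) &
        rowSums(member[, -idx, drop = FALSE]) == 0
    } else logical(0)
    data.frame(stratum = paste(names(sets)[idx], collapse = "&"),
               degree = length(idx), count = sum(inside),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "exclusive") <- stats::setNames(
    out$count[out$degree == 1], names(sets))
  attr(out, "common") <- out$count[out$degree == k]
  attr(out, "union_size") <- length(universe)
  out
}

#' Kruskal-Wallis rank test across groups
#'
#' Mid-rank, tie-corrected H statistic with a chi-square reference on
#' k - 1 degrees of freedom (delegates to `stats::kruskal.test`).
#'
#' @param groups list of >= 2 non-empty numeric vectors (e.g. per-toxin
#'   fold changes of differentially regulated genes).
#' @return list with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) == 0L)) {
    stop(cf_error("empty group in Kruskal-Wallis input", "cf_stat_error"))
  }
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

#' Dunn's post-hoc pairwise comparisons with Bonferroni adjustment
#'
#' For each pair of groups, the standardised difference of mean
#' mid-ranks
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' with the tie correction `T = sum(t^3 - t)` over tied values, two-sided
#' normal p, and Bonferroni adjustment over the `k(k-1)/2` comparisons.
#'
#' @param groups named list of >= 2 non-empty numeric vectors.
#' @return data.frame with columns `group1`, `group2`, `z`, `p_raw`,
#'   `p_adj`.
#' @export
dunn_posthoc <- function(groups) {
  stopifnot(length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) == 0L)) {
    stop(cf_error("empty group in Dunn input", "cf_stat_error"))
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), vapply(groups, length, integer(1)))
  N <- length(x)
  rk <- rank(x)                           # mid-ranks
  rbar <- tapply(rk, g, mean)
  n <- tapply(rk, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties)
  var_base <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  m <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    se <- sqrt(var_base * (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
    z <- if (se > 0) (rbar[[pr[1]]] - rbar[[pr[2]]]) / se else 0
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = pr[1], group2 = pr[2], z = z, p_raw = p,
               p_adj = min(1, p * m), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full three-way (or k-way) DE comparison
#'
#' Applies [call_de()] per toxin, partitions the up and down sets with
#' [venn_partition()], and compares the pooled linear fold changes of
#' each toxin's differentially regulated genes (up and down together)
#' with [kruskal_wallis()] and [dunn_posthoc()].
#'
#' @param de_tables named list of per-toxin DE data.frames.
#' @param ... thresholds passed to [call_de()].
#' @return list with `up_sets`, `down_sets`, `venn_up`, `venn_down`,
#'   `kruskal`, `dunn`.
#' @export
compare_de_conditions <- function(de_tables, ...) {
  stopifnot(length(de_tables) >= 2)
  calls <- lapply(de_tables, call_de, ...)
  up_sets <- lapply(calls, `[[`, "up")
  down_sets <- lapply(calls, `[[`, "down")
  fold_groups <- lapply(names(de_tables), function(tx) {
    tab <- de_tables[[tx]]
    tab$fold_change[tab$gene %in% c(up_sets[[tx]], down_sets[[tx]])]
  })
  names(fold_groups) <- names(de_tables)
  list(up_sets = up_sets, down_sets = down_sets,
       venn_up = venn_partition(up_sets),
       venn_down = venn_partition(down_sets),
       kruskal = kruskal_wallis(fold_groups),
       dunn = dunn_posthoc(fold_groups))
}
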