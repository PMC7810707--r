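# Differential reaction-flux calling between conditions.
#
# A reaction is called differentially active when (i) a t-test on its
# sampled flux distributions is significant after Bonferroni correction
# over all tested reactions, (ii) the mean flux differs by at least the
# minimum fold in either direction (computed on absolute means), and
# (iii) both absolute means are below the magnitude ceiling (very large
# fluxes ride artificial bounds and carry no biological contrast).

#' Differential-flux configuration
#'
#' @param alpha family-wise significance level before Bonferroni
#'   division.
#' @param min_fold minimum fold difference between absolute mean fluxes
#'   (> 1).
#' @param magnitude_ceiling reactions with absolute mean flux at or
#'   above this value (arbitrary flux units) are filtered out.
#' @param pairing `"unpaired"` (Welch) or `"paired"` (by sample index;
#'   requires equal point counts).
#' @param zero_tol means below this are treated as exactly zero when
#'   forming fold ratios.
#' @return a `diff_flux_config` list.
#' @export
diff_flux_config <- function(alpha = 0.05, min_fold = 2,
                             magnitude_ceiling = 1000,
                             pairing = c("unpaired", "paired"),
                             zero_tol = 1e-7) {
  pairing <- match.arg(pairing)
  stopifnot(alpha > 0, alpha < 1, min_fold > 1)
  structure(list(alpha = alpha, min_fold = min_fold,
                 magnitude_ceiling = magnitude_ceiling,
                 pairing = pairing, zero_tol = zero_tol),
            class = "diff_flux_config")
}

#' Call differentially active reactions between two conditions
#'
#' @param treated,control `flux_samples` (or matrices) for the two
#'   conditions.
#' @param config a [diff_flux_config()].
#' @return data.frame with one row per shared reaction: means, fold
#'   ratio (treated/control on absolute means; `Inf` when only one side
#'   is zero), raw p, `tested`, the three filter flags and `significant`.
#'   The Bonferroni denominator (`n_tested`) is attached as an
#'   attribute.
#' @export
differential_reactions <- function(treated, control,
                                   config = diff_flux_config()) {
  mt <- sample_matrix(treated); mc <- sample_matrix(control)
  shared <- intersect(colnames(mt), colnames(mc))
  if (length(shared) == 0L) {
    stop(cf_error("no shared reactions between conditions",
                  "cf_diffflux_error"))
  }
  if (config$pairing == "paired" && nrow(mt) != nrow(mc)) {
    stop(cf_error("paired mode requires equal point counts",
                  "cf_diffflux_error"))
  }
  rows <- lapply(shared, function(r) {
    a <- mt[, r]; b <- mc[, r]
    ma <- mean(a); mb <- mean(b)
    tested <- TRUE; p <- NA_real_
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      tested <- FALSE                     # no variance anywhere: p undefined
    } else {
      p <- if (config$pairing == "paired") {
        d <- a - b
        if (stats::sd(d) == 0) { tested <- FALSE; NA_real_ }
        else stats::t.test(d)$p.value
      } else {
        stats::t.test(a, b)$p.value
      }
    }
    aa <- abs(ma); ab <- abs(mb)
    if (aa < config$zero_tol) aa <- 0
    if (ab < config$zero_tol) ab <- 0
    fold <- if (aa == 0 && ab == 0) 1
            else if (ab == 0 || aa == 0) Inf
            else aa / ab
    fold_sym <- if (is.infinite(fold)) Inf else max(fold, 1 / fold)
    data.frame(reaction = r, mean_treated = ma, mean_control = mb,
               fold = fold, p = p, tested = tested,
               pass_fold = fold_sym >= config$min_fold,
               pass_magnitude = aa < config$magnitude_ceiling &&
                 ab < config$magnitude_ceiling,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  n_tested <- sum(out$tested)
  thr <- config$alpha / max(n_tested, 1L)
  out$pass_p <- out$tested & !is.na(out$p) & out$p < thr
  out$significant <- out$pass_p & out$pass_fold & out$pass_magnitude
  attr(out, "n_tested") <- n_tested
  attr(out, "bonferroni_threshold") <- thr
  out
}

#' Venn partition of per-toxin significant reaction sets
#'
#' Thin delegate to [venn_partition()], kept as the named entry point of
#' the differential-flux stage.
#'
#' @param sets named list (>= 2) of significant reaction id vectors.
#' @return see [venn_partition()].
#' @export
significant_set_venn <- function(sets) {
  venn_partition(sets)
}
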