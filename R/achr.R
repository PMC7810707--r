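# Artificially-centred hit-and-run sampling of the steady-state flux
# polytope {v : S v = 0, lb <= v <= ub}.
#
# Warm-up points are the flux-variability corners (FBA min and max of
# every reaction). Each step picks a random previously seen point
# (warm-up or accepted), takes the direction from the running centre
# through it, and moves to a uniform point on the feasible chord. Every
# candidate direction is projected onto an orthonormal null-space basis
# of S before use: normalising a difference of two nearly coincident
# feasible points would otherwise amplify rounding noise that lies
# outside the null space, and long chord steps compound that drift.
# With the projection only the box bounds limit the chord and steady
# state holds to machine precision.

#' Container for sampled flux points
#'
#' @param samples numeric matrix, points x reactions, with reaction ids
#'   as column names.
#' @param condition condition label.
#' @param provenance free-form list (model ids, seeds).
#' @return a `flux_samples` object.
#' @export
flux_samples <- function(samples, condition = "unknown",
                         provenance = list()) {
  stopifnot(is.matrix(samples), !is.null(colnames(samples)))
  structure(list(samples = samples, condition = condition,
                 provenance = provenance),
            class = "flux_samples")
}

#' Extract the points x reactions matrix
#' @param fs a `flux_samples` object (a bare matrix passes through).
#' @return numeric matrix.
#' @export
sample_matrix <- function(fs) {
  if (is.matrix(fs)) fs else fs$samples
}

#' @export
print.flux_samples <- function(x, ...) {
  cat(sprintf("<flux_samples> %s: %d points x %d reactions\n",
              x$condition, nrow(x$samples), ncol(x$samples)))
  invisible(x)
}

#' Flux-variability warm-up points
#'
#' FBA minimum and maximum flux vectors for every reaction,
#' deduplicated. All returned points are steady-state feasible.
#'
#' @param net a `metabolic_network`.
#' @return numeric matrix, points x reactions.
#' @export
warmup_points <- function(net) {
  rids <- net$reactions$id
  pts <- matrix(NA_real_, 2L * length(rids), length(rids),
                dimnames = list(NULL, rids))
  k <- 0L
  for (rid in rids) {
    for (sense in c("min", "max")) {
      sol <- fba(net, rid, sense)
      if (sol$status != "optimal") {
        stop(cf_error(paste0("infeasible model during warm-up (", rid,
                             " ", sense, ")"), "cf_sample_error"))
      }
      k <- k + 1L
      pts[k, ] <- sol$fluxes
    }
  }
  pts <- pts[seq_len(k), , drop = FALSE]
  pts[!duplicated(round(pts, 9)), , drop = FALSE]
}

#' Sample the flux polytope with ACHR
#'
#' @param net a `metabolic_network` (the context model to sample).
#' @param n_points points to return.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param burn_in steps discarded before recording.
#' @param thin record every `thin`-th step.
#' @param condition label stored on the result.
#' @param warmup optional precomputed [warmup_points()] matrix.
#' @return a `flux_samples` object.
#' @export
achr_sample <- function(net, n_points = 5000, seed, burn_in = 0L,
                        thin = 1L, condition = net$id, warmup = NULL) {
  stopifnot(n_points >= 1, thin >= 1)
  if (is.null(warmup)) warmup <- warmup_points(net)
  lb <- net$reactions$lower_bound
  ub <- net$reactions$upper_bound
  nr <- length(lb)
  N <- nullspace_basis(stoichiometric_matrix(net))
  out <- matrix(NA_real_, n_points, nr,
                dimnames = list(NULL, net$reactions$id))
  with_seed(seed, {
    centre <- colMeans(warmup)
    x <- centre
    seen <- nrow(warmup)
    recorded <- 0L
    step <- 0L
    total <- burn_in + n_points * thin
    while (step < total) {
      step <- step + 1L
      # direction through a random previously seen point
      u <- NULL
      for (try in 1:50) {
        j <- sample.int(seen + recorded, 1L)
        w <- if (j <= seen) warmup[j, ] else out[j - seen, ]
        cand <- w - centre
        if (!is.null(N)) cand <- drop(N %*% crossprod(N, cand))
        nrm <- sqrt(sum(cand^2))
        if (nrm > 1e-10) { u <- cand / nrm; break }
      }
      if (!is.null(u)) {
        pos <- u > 1e-12; neg <- u < -1e-12
        amax <- min(c((ub[pos] - x[pos]) / u[pos],
                      (lb[neg] - x[neg]) / u[neg], Inf))
        amin <- max(c((lb[pos] - x[pos]) / u[pos],
                      (ub[neg] - x[neg]) / u[neg], -Inf))
        if (is.finite(amin) && is.finite(amax) && amax > amin) {
          x <- x + stats::runif(1, amin, amax) * u
        }
        # degenerate chords leave x unchanged (fully fixed polytope)
      }
      centre <- centre + (x - centre) / (seen + step)
      if (step > burn_in && (step - burn_in) %% thin == 0L) {
        recorded <- recorded + 1L
        out[recorded, ] <- x
      }
    }
  })
  flux_samples(out, condition = condition,
               provenance = list(model_id = net$id, seed = seed,
                                 burn_in = burn_in, thin = thin))
}

#' Merge sample matrices from several iteration models
#'
#' Keeps only the reactions present in every matrix and concatenates the
#' points unchanged (no normalisation: all iterations share the same
#' uptake conditions).
#'
#' @param fs_list list of `flux_samples` for one condition.
#' @return a merged `flux_samples`.
#' @export
merge_samples <- function(fs_list) {
  stopifnot(length(fs_list) >= 1)
  mats <- lapply(fs_list, sample_matrix)
  shared <- Reduce(intersect, lapply(mats, colnames))
  if (length(shared) == 0L) {
    stop(cf_error("no reaction shared by all sample matrices",
                  "cf_sample_error"))
  }
  merged <- do.call(rbind, lapply(mats, function(m) m[, shared, drop = FALSE]))
  conds <- unique(vapply(fs_list, function(f) {
    if (is.matrix(f)) "unknown" else f$condition
  }, character(1)))
  flux_samples(merged, condition = conds[1],
               provenance = list(sources = lapply(fs_list, function(f) {
                 if (is.matrix(f)) NULL else f$provenance
               })))
}

#' Zero out numerically negligible sampled fluxes
#'
#' Entries with absolute value strictly below the cutoff become exactly
#' 0; everything else is untouched.
#'
#' @param fs a `flux_samples` or bare matrix.
#' @param cutoff non-negative numerical cutoff.
#' @return same type as the input.
#' @export
apply_cutoff <- function(fs, cutoff = 1e-7) {
  stopifnot(cutoff >= 0)
  m <- sample_matrix(fs)
  m[abs(m) < cutoff] <- 0
  if (is.matrix(fs)) m else { fs$samples <- m; fs }
}

#' Check sampled points against the model constraints
#'
#' @param fs a `flux_samples` or matrix.
#' @param net the sampled `metabolic_network`.
#' @param tol_steady,tol_bounds tolerances.
#' @return list with `steady_ok`, `bounds_ok` (fractions in [0, 1]) and
#'   `max_residual`.
#' @export
check_sample_feasibility <- function(fs, net, tol_steady = 1e-6,
                                     tol_bounds = 1e-9) {
  m <- sample_matrix(fs)
  S <- stoichiometric_matrix(net)[, colnames(m), drop = FALSE]
  resid <- abs(S %*% t(m))
  lb <- net$reactions$lower_bound[match(colnames(m), net$reactions$id)]
  ub <- net$reactions$upper_bound[match(colnames(m), net$reactions$id)]
  steady <- apply(resid, 2, max) < tol_steady
  bok <- apply(m, 1, function(v) {
    all(v >= lb - tol_bounds) && all(v <= ub + tol_bounds)
  })
  list(steady_ok = mean(steady), bounds_ok = mean(bok),
       max_residual = max(resid))
}
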