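# Deterministic bounded-variable primal simplex.
#
# Solves   min c'x   s.t.  A x = b,  l <= x <= u
# with a two-phase method. Entering and leaving variables are chosen by
# Bland's rule (smallest index), which guarantees finite termination on
# degenerate problems and makes the solution a deterministic function of
# the column order -- a property the GIMME consensus machinery relies on
# (reordering reaction columns can legitimately land on a different
# degenerate optimum).
#
# Scale target: dense problems up to a few hundred variables, as produced
# by toy and mid-sized compartmentalised networks. The basis is
# refactorised with solve() at every iteration; no effort is made to be
# competitive with industrial LP codes.

#' Solve a bounded-variable linear program
#'
#' Minimises (or maximises) `obj' x` subject to `A x = b` and
#' `lower <= x <= upper`. All lower bounds must be finite; upper bounds
#' may be `Inf`.
#'
#' @param obj numeric objective coefficient vector.
#' @param A constraint matrix (may have zero rows).
#' @param b right-hand side vector, `length(b) == nrow(A)`.
#' @param lower,upper variable bounds, same length as `obj`.
#' @param maximize logical; maximise instead of minimise.
#' @param tol numerical tolerance for pricing and ratio tests.
#' @param max_iter iteration cap per phase.
#' @return A list with elements `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), `objective` (the optimum, `NA` unless optimal) and
#'   `x` (an optimal point, `NA` unless optimal).
#' @keywords internal
solve_lp <- function(obj, A, b, lower, upper, maximize = FALSE,
                     tol = 1e-9, max_iter = 20000L) {
  n <- length(obj)
  if (!is.matrix(A)) A <- matrix(A, nrow = length(b), ncol = n)
  stopifnot(ncol(A) == n, nrow(A) == length(b),
            length(lower) == n, length(upper) == n)
  if (any(!is.finite(lower))) {
    stop("solve_lp requires finite lower bounds")
  }
  if (any(lower > upper + tol)) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  upper <- pmax(upper, lower)
  cc <- if (maximize) -obj else obj

  m <- nrow(A)
  if (m == 0L) {
    # box problem: each variable independently at its best bound
    x <- ifelse(cc >= 0, lower, upper)
    if (any(cc < 0 & !is.finite(upper))) {
      return(list(status = "unbounded", objective = NA_real_, x = NULL))
    }
    f <- sum(cc * x)
    return(list(status = "optimal",
                objective = if (maximize) -f else f, x = x))
  }

  # phase 1: artificial identity basis
  x0 <- lower
  resid <- b - as.vector(A %*% x0)
  art_sign <- ifelse(resid >= 0, 1, -1)
  Afull <- cbind(A, diag(art_sign, m))
  lo <- c(lower, rep(0, m))
  hi <- c(upper, rep(Inf, m))
  ntot <- n + m
  basis <- (n + 1L):ntot
  # nonbasic status: TRUE = at upper bound
  at_upper <- rep(FALSE, ntot)
  xval <- c(x0, abs(resid))

  run_phase <- function(cvec, basis, at_upper, xval, lo, hi) {
    for (iter in seq_len(max_iter)) {
      B <- Afull[, basis, drop = FALSE]
      y <- tryCatch(solve(t(B), cvec[basis]),
                    error = function(e) NULL)
      if (is.null(y)) {
        return(list(status = "singular"))
      }
      nonbasic <- setdiff(seq_len(ntot), basis)
      nonbasic <- nonbasic[hi[nonbasic] - lo[nonbasic] > tol]  # skip fixed
      if (length(nonbasic) == 0L) {
        return(list(status = "optimal", basis = basis,
                    at_upper = at_upper, xval = xval))
      }
      d <- cvec[nonbasic] - as.vector(crossprod(Afull[, nonbasic, drop = FALSE], y))
      cand <- nonbasic[(d < -tol & !at_upper[nonbasic]) |
                       (d > tol & at_upper[nonbasic])]
      if (length(cand) == 0L) {
        return(list(status = "optimal", basis = basis,
                    at_upper = at_upper, xval = xval))
      }
      j <- min(cand)                          # Bland: smallest index enters
      delta <- if (at_upper[j]) -1 else 1     # direction of change of x_j
      w <- solve(B, Afull[, j])
      # basic vars move as xB - t * delta * w, t >= 0
      step <- hi[j] - lo[j]                   # bound-flip limit
      leave <- 0L                             # 0 = bound flip
      dw <- delta * w
      xb <- xval[basis]
      for (i in seq_len(m)) {
        if (dw[i] > tol) {
          ti <- (xb[i] - lo[basis[i]]) / dw[i]
        } else if (dw[i] < -tol) {
          ti <- (hi[basis[i]] - xb[i]) / (-dw[i])
        } else next
        if (ti < step - tol || (ti < step + tol && leave != 0L &&
                                basis[i] < basis[leave])) {
          step <- ti
          leave <- i
        }
      }
      if (!is.finite(step)) {
        return(list(status = "unbounded"))
      }
      step <- max(step, 0)
      xval[basis] <- xb - step * dw
      xval[j] <- xval[j] + delta * step
      if (leave == 0L) {
        at_upper[j] <- !at_upper[j]           # bound flip, basis unchanged
      } else {
        lv <- basis[leave]
        # leaving variable parks at whichever bound it hit
        at_upper[lv] <- dw[leave] < 0
        xval[lv] <- if (at_upper[lv]) hi[lv] else lo[lv]
        basis[leave] <- j
      }
    }
    list(status = "maxiter")
  }

  c1 <- c(rep(0, n), rep(1, m))
  ph1 <- run_phase(c1, basis, at_upper, xval, lo, hi)
  if (ph1$status != "optimal") {
    stop("LP phase 1 failed: ", ph1$status)
  }
  if (sum(ph1$xval[(n + 1L):ntot]) > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  # phase 2: freeze artificials at zero, restore true objective
  lo[(n + 1L):ntot] <- 0
  hi[(n + 1L):ntot] <- 0
  ph1$xval[(n + 1L):ntot] <- pmax(0, pmin(ph1$xval[(n + 1L):ntot], 0))
  c2 <- c(cc, rep(0, m))
  ph2 <- run_phase(c2, ph1$basis, ph1$at_upper, ph1$xval, lo, hi)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", objective = NA_real_, x = NULL))
  }
  if (ph2$status != "optimal") {
    stop("LP phase 2 failed: ", ph2$status)
  }
  x <- ph2$xval[seq_len(n)]
  f <- sum(cc * x)
  list(status = "optimal", objective = if (maximize) -f else f, x = x)
}
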