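# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths: the co-set oracle is a naive union-find
# over explicit pairwise edges, the FBA oracle is the closed-form
# bottleneck capacity of a generated chain network, and the Dunn oracle
# re-derives the z statistics from first principles.

# union-find grouping of |r| >= threshold pairs (single linkage)
oracle_cosets <- function(cormat, threshold = 0.975) {
  ids <- colnames(cormat)
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && abs(cormat[i, j]) >= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(ids, roots)
  groups <- groups[vapply(groups, length, integer(1)) >= 2]
  # canonical form for comparison: sorted members, sorted by first member
  groups <- lapply(unname(groups), sort)
  groups[order(vapply(groups, `[`, character(1), 1))]
}

canonical_cosets <- function(build_result) {
  groups <- lapply(unname(build_result$cosets),
                   function(cs) sort(cs$members))
  groups[order(vapply(groups, `[`, character(1), 1))]
}

# closed-form FBA optimum for chain 1 of a make_toy_network() result:
# the biomass flux is limited by the weakest step of the chain, where a
# bypassed step has the summed capacity of both parallel routes
oracle_chain_capacity <- function(net, gt) {
  ch <- gt$chains[[1]]
  r <- net$reactions
  cap_of <- function(rid) {
    i <- match(rid, r$id)
    if (r$is_exchange[i]) -r$lower_bound[i] else r$upper_bound[i]
  }
  caps <- vapply(ch$reactions, function(rid) {
    extra <- if (paste0(rid, "b") %in% r$id) cap_of(paste0(rid, "b")) else 0
    cap_of(rid) + extra
  }, numeric(1))
  max(0, min(caps))
}

# first-principles Dunn z statistics (tie-corrected)
oracle_dunn_z <- function(groups) {
  x <- unlist(groups); g <- rep(seq_along(groups),
                                vapply(groups, length, integer(1)))
  N <- length(x)
  rk <- rank(x)
  tie <- table(x)
  v <- (N * (N + 1) / 12) - sum(tie^3 - tie) / (12 * (N - 1))
  out <- c()
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (i < j) {
        ni <- sum(g == i); nj <- sum(g == j)
        z <- (mean(rk[g == i]) - mean(rk[g == j])) /
          sqrt(v * (1 / ni + 1 / nj))
        out <- c(out, z)
      }
    }
  }
  out
}

# small random feasible LPs with a known feasible interior point,
# cross-checked against an external simplex implementation
random_feasible_lp <- function(seed) {
  set.seed(seed)
  m <- sample(2:5, 1); n <- m + sample(2:6, 1)
  A <- matrix(sample(-2:2, m * n, TRUE), m, n)
  xf <- runif(n, 0, 5)
  list(A = A, b = as.vector(A %*% xf), lb = rep(0, n),
       ub = runif(n, 5, 10), obj = runif(n, -1, 1))
}
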