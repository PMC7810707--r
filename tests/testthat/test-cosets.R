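test_that("correlation matrix excludes constant reactions", {
  set.seed(1)
  m <- cbind(r1 = rnorm(100), r2 = rnorm(100), const = rep(2, 100))
  cc <- flux_correlation_matrix(m)
  expect_equal(cc$excluded, "const")
  expect_equal(colnames(cc$correlation), c("r1", "r2"))
  expect_error(flux_correlation_matrix(m[1, , drop = FALSE]),
               class = "cf_coset_error")
  # independent columns at large n stay far below the threshold
  big <- matrix(rnorm(15000 * 6), ncol = 6,
                dimnames = list(NULL, paste0("x", 1:6)))
  cb <- flux_correlation_matrix(big)$correlation
  expect_lt(max(abs(cb[upper.tri(cb)])), 0.05)
})

test_that("single-linkage components define the co-sets", {
  cm <- diag(3)
  dimnames(cm) <- list(c("A", "B", "C"), c("A", "B", "C"))
  cm["A", "B"] <- cm["B", "A"] <- 0.98
  cm["B", "C"] <- cm["C", "B"] <- 0.98
  cm["A", "C"] <- cm["C", "A"] <- 0.90
  cs <- build_cosets(cm, threshold = 0.975)
  expect_length(cs$cosets, 1)
  expect_setequal(cs$cosets[[1]]$members, c("A", "B", "C"))
  # complete-linkage alternative splits the weak triangle
  cl <- build_cosets(cm, threshold = 0.975, method = "clique")
  expect_true(all(vapply(cl$cosets, function(x) x$size, integer(1)) == 2))
  # nothing above threshold: no co-sets, all singletons
  eye <- diag(3); dimnames(eye) <- list(c("A", "B", "C"), c("A", "B", "C"))
  none <- build_cosets(eye, threshold = 0.975)
  expect_length(none$cosets, 0)
  expect_setequal(none$singletons, c("A", "B", "C"))
  # an unnamed matrix is rejected rather than silently mislabelled
  expect_error(build_cosets(diag(3)), class = "cf_coset_error")
  # anticorrelation groups by default, not in signed mode
  cm2 <- diag(2); dimnames(cm2) <- list(c("A", "B"), c("A", "B"))
  cm2["A", "B"] <- cm2["B", "A"] <- -0.99
  expect_length(build_cosets(cm2)$cosets, 1)
  expect_length(build_cosets(cm2, signed = TRUE)$cosets, 0)
})

test_that("components match a brute-force union-find oracle exactly", {
  for (seed in 1:8) {
    set.seed(seed)
    n_rxn <- sample(5:30, 1)
    n_grp <- sample(1:4, 1)
    base <- matrix(rnorm(200 * n_grp), ncol = n_grp)
    assign <- sample(n_grp, n_rxn, replace = TRUE)
    m <- base[, assign] + matrix(rnorm(200 * n_rxn, sd = 0.02), 200)
    colnames(m) <- sprintf("r%02d", seq_len(n_rxn))
    cc <- flux_correlation_matrix(m)$correlation
    expect_identical(canonical_cosets(build_cosets(cc, 0.975)),
                     oracle_cosets(cc, 0.975))
  }
})

test_that("raising the threshold only refines the partition", {
  set.seed(9)
  m <- matrix(rnorm(300 * 10), ncol = 10)
  m[, 2] <- m[, 1] + rnorm(300, sd = 0.05)
  m[, 3] <- m[, 1] + rnorm(300, sd = 0.2)
  colnames(m) <- paste0("r", 1:10)
  cc <- flux_correlation_matrix(m)$correlation
  for (pair in list(c(0.5, 0.8), c(0.8, 0.95), c(0.95, 0.99))) {
    lo <- build_cosets(cc, pair[1])
    hi <- build_cosets(cc, pair[2])
    for (cs_hi in hi$cosets) {
      containing <- Filter(function(cs_lo) {
        all(cs_hi$members %in% cs_lo$members)
      }, lo$cosets)
      expect_length(containing, 1)
    }
  }
})

test_that("co-set grouping partitions the non-excluded reactions", {
  net <- set_bounds(toy_bypass_network(), "EX_A", lower = -10)
  fs <- achr_sample(net, 800, seed = 3)
  cc <- flux_correlation_matrix(fs)
  cs <- build_cosets(cc)
  covered <- c(unlist(lapply(cs$cosets, `[[`, "members")), cs$singletons)
  expect_setequal(covered, colnames(cc$correlation))
  expect_equal(length(covered), ncol(cc$correlation))
})

test_that("large co-sets are filtered by an inclusive size boundary", {
  mk <- function(members) structure(list(members = members,
                                         size = length(members)),
                                    class = "coset")
  sets <- list(mk(letters[1:2]), mk(letters[1:6]), mk(letters[1:7]),
               mk(letters[1:5]))
  out <- large_cosets(sets, 6)
  expect_length(out, 2)
  expect_equal(vapply(out, `[[`, integer(1), "size"), c(6L, 7L))
  expect_length(large_cosets(list(), 6), 0)
})

test_that("relative profiles express the representative flux as percentages", {
  mk_fs <- function(vals) {
    flux_samples(matrix(rep(vals, each = 4), nrow = 4,
                        dimnames = list(NULL, c("rA", "rB"))), "x")
  }
  cs <- list(coset_001 = structure(list(members = c("rA", "rB"), size = 2L),
                                   class = "coset"))
  even <- coset_relative_profile(
    cs, list(control = mk_fs(c(2, 1)), c1 = mk_fs(c(2, 1)),
             c2 = mk_fs(c(2, 1)), c3 = mk_fs(c(2, 1))))
  expect_equal(unlist(even[grep("^pct_", names(even))], use.names = FALSE),
               rep(25, 4))
  expect_equal(even$representative, "rA")   # largest control mean
  skew <- coset_relative_profile(
    cs, list(control = mk_fs(c(0, 0)), c1 = mk_fs(c(0, 0)),
             c2 = mk_fs(c(0, 0)), c3 = mk_fs(c(6, 0))))
  expect_equal(unlist(skew[grep("^pct_", names(skew))], use.names = FALSE),
               c(0, 0, 0, 100))
  allzero <- coset_relative_profile(
    cs, list(control = mk_fs(c(0, 0)), c1 = mk_fs(c(0, 0))))
  expect_equal(allzero$flag, "all_zero")
  expect_true(all(is.na(unlist(allzero[grep("^pct_", names(allzero))]))))
})

test_that("profile clustering separates opposite profiles last", {
  prof <- data.frame(
    coset = c("cs1", "cs2", "cs3", "cs4"),
    representative = "r", flag = "ok",
    pct_a = c(100, 0, 25, 25), pct_b = c(0, 0, 25, 25),
    pct_c = c(0, 0, 25, 25), pct_d = c(0, 100, 25, 25))
  hc <- cluster_profiles(prof)
  expect_s3_class(hc, "hclust")
  # identical profiles merge at distance 0; the opposed profiles are
  # separated at every cut of the tree that keeps >= 2 clusters
  expect_equal(min(hc$height), 0)
  k3 <- cutree(hc, k = 3)
  expect_equal(k3[["cs3"]], k3[["cs4"]])
  expect_length(unique(k3[c("cs1", "cs2", "cs3")]), 3)
  k2 <- cutree(hc, k = 2)
  expect_false(k2[["cs1"]] == k2[["cs2"]])
  single <- cluster_profiles(prof[1, ])
  expect_null(single)
})
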