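planted_samples <- function(n, means_t, means_c, sd = 0.01, seed = 1) {
  with_seed(seed, {
    ids <- sprintf("r%02d", seq_along(means_t))
    mt <- sapply(means_t, function(m) stats::rnorm(n, m, sd))
    mc <- sapply(means_c, function(m) stats::rnorm(n, m, sd))
    colnames(mt) <- colnames(mc) <- ids
    list(treated = flux_samples(mt, "t"), control = flux_samples(mc, "c"))
  })
}

test_that("identical flux distributions yield no differential calls", {
  ps <- planted_samples(500, rep(2, 6), rep(2, 6), seed = 3)
  out <- differential_reactions(ps$treated, ps$control)
  expect_false(any(out$significant))
  expect_equal(attr(out, "n_tested"), 6)
  expect_equal(attr(out, "bonferroni_threshold"), 0.05 / 6)
})

test_that("a planted three-fold shift is called and sub-threshold shifts are not", {
  # 10 reactions: 3 shifted three-fold, 3 shifted 1.5-fold (below the
  # fold filter), 4 unshifted
  ps <- planted_samples(1000,
                        means_t = c(3, 3, 3, 1.5, 1.5, 1.5, 1, 1, 1, 1),
                        means_c = rep(1, 10), seed = 7)
  out <- differential_reactions(ps$treated, ps$control)
  sig <- out$reaction[out$significant]
  expect_setequal(sig, c("r01", "r02", "r03"))
  # the 1.5-fold reactions fail the fold filter, not the test
  mid <- out[out$reaction %in% c("r04", "r05", "r06"), ]
  expect_true(all(mid$pass_p))
  expect_false(any(mid$pass_fold))
})

test_that("the magnitude ceiling excludes bound-riding fluxes", {
  ps <- planted_samples(400, c(1200, 3), c(400, 1), seed = 5)
  out <- differential_reactions(ps$treated, ps$control)
  big <- out[out$reaction == "r01", ]
  expect_true(big$pass_p && big$pass_fold)
  expect_false(big$pass_magnitude)
  expect_false(big$significant)
  expect_true(out$significant[out$reaction == "r02"])
})

test_that("the fold filter is symmetric under condition swap", {
  ps <- planted_samples(600, c(4, 0.5, 2), c(1, 1, 1), seed = 9)
  fwd <- differential_reactions(ps$treated, ps$control)
  rev <- differential_reactions(ps$control, ps$treated)
  expect_identical(fwd$pass_fold, rev$pass_fold)
  expect_identical(fwd$significant, rev$significant)
  expect_equal(fwd$fold[1] * rev$fold[1], 1, tolerance = 1e-12)
})

test_that("zero-variance reactions are excluded from the Bonferroni family", {
  m_t <- cbind(r1 = rep(2, 50), r2 = rnorm(50, 5, 0.1))
  m_c <- cbind(r1 = rep(2, 50), r2 = rnorm(50, 1, 0.1))
  out <- differential_reactions(flux_samples(m_t, "t"),
                                flux_samples(m_c, "c"))
  expect_false(out$tested[out$reaction == "r1"])
  expect_equal(attr(out, "n_tested"), 1)
  expect_equal(attr(out, "bonferroni_threshold"), 0.05)
  expect_true(out$significant[out$reaction == "r2"])
})

test_that("activation from exact zero gives an infinite fold ratio", {
  set.seed(2)
  m_t <- cbind(r1 = rnorm(200, 3, 0.05))
  m_c <- cbind(r1 = rnorm(200, 0, 1e-9))     # mean below zero_tol
  out <- differential_reactions(flux_samples(m_t, "t"),
                                flux_samples(m_c, "c"))
  expect_true(is.infinite(out$fold))
  expect_true(out$pass_fold)
  expect_true(out$significant)
  # both sides at zero: fold 1, never called
  z <- differential_reactions(
    flux_samples(cbind(r1 = rnorm(50, 0, 1e-10)), "t"),
    flux_samples(cbind(r1 = rnorm(50, 0, 1e-10)), "c"))
  expect_equal(z$fold, 1)
  expect_false(z$significant)
})

test_that("paired mode uses within-pair differences and checks point counts", {
  set.seed(6)
  base <- rnorm(100, 5, 2)                  # large shared variance
  m_c <- cbind(r1 = base)
  m_t <- cbind(r1 = base * 3 + rnorm(100, 0, 0.01))
  paired <- differential_reactions(
    flux_samples(m_t, "t"), flux_samples(m_c, "c"),
    diff_flux_config(pairing = "paired"))
  expect_true(paired$significant)
  expect_error(
    differential_reactions(flux_samples(m_t, "t"),
                           flux_samples(m_c[1:50, , drop = FALSE], "c"),
                           diff_flux_config(pairing = "paired")),
    class = "cf_diffflux_error")
})

test_that("disjoint reaction sets cannot be compared", {
  a <- flux_samples(cbind(x = rnorm(10)), "t")
  b <- flux_samples(cbind(y = rnorm(10)), "c")
  expect_error(differential_reactions(a, b), class = "cf_diffflux_error")
})

test_that("the significant-set Venn partitions overlapping toxin sets", {
  v <- significant_set_venn(list(t1 = c("r1", "r2"), t2 = c("r2", "r3"),
                                 t3 = "r2"))
  expect_equal(attr(v, "common"), 1)                    # r2 everywhere
  ex <- attr(v, "exclusive")
  expect_equal(unname(ex[c("t1", "t2", "t3")]), c(1, 1, 0))
  expect_equal(attr(v, "union_size"), 3)
})
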