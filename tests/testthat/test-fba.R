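test_that("FBA finds the chain bottleneck optimum", {
  net <- set_bounds(toy3_network(), "EX_A", lower = -10)
  sol <- fba(net)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 10)
  expect_lt(max(abs(stoichiometric_matrix(net) %*% sol$fluxes)), 1e-6)
  expect_true(all(sol$fluxes >= net$reactions$lower_bound - 1e-9))
  expect_true(all(sol$fluxes <= net$reactions$upper_bound + 1e-9))

  zero <- net
  zero$reactions$lower_bound <- 0
  zero$reactions$upper_bound <- 0
  expect_equal(fba(zero)$objective, 0)

  blocked <- set_bounds(net, "EX_A", lower = 0)   # no uptake
  forced <- set_bounds(blocked, "BIOMASS", lower = 1)
  expect_equal(fba(forced)$status, "infeasible")
})

test_that("FBA optimum is invariant under reaction reordering", {
  toy <- make_toy_network(2, 5, bypasses = list(c(1L, 2L)), seed = 8)
  net <- toy$network
  base <- fba(net)$objective
  for (s in 1:5) {
    set.seed(s)
    perm <- sample.int(nrow(net$reactions))
    expect_equal(fba(permute_reactions(net, perm))$objective, base,
                 tolerance = 1e-9)
  }
})

test_that("FBA matches the closed-form bottleneck on seeded toy networks", {
  for (seed in 1:6) {
    toy <- make_toy_network(n_chains = 2, chain_length = 5,
                            bypasses = if (seed %% 2) list(c(1L, 3L)) else list(),
                            seed = seed)
    net <- toy$network
    # randomise the capacities of chain 1
    set.seed(seed + 100)
    ch <- toy$ground_truth$chains[[1]]$reactions
    for (rid in ch) {
      cap <- round(runif(1, 1, 50), 3)
      i <- match(rid, net$reactions$id)
      if (net$reactions$is_exchange[i]) {
        net <- set_bounds(net, rid, lower = -cap)
      } else {
        net <- set_bounds(net, rid, upper = cap)
      }
    }
    expect_equal(fba(net)$objective,
                 oracle_chain_capacity(net, toy$ground_truth),
                 tolerance = 1e-8)
  }
})

test_that("the LP solver agrees with an external simplex on random problems", {
  agree <- 0L; total <- 0L
  for (seed in 1:60) {
    lp <- random_feasible_lp(seed)
    mine <- contextflux:::solve_lp(lp$obj, lp$A, lp$b, lp$lb, lp$ub,
                                   maximize = TRUE)
    ext <- tryCatch(
      suppressWarnings(pracma::linprog(lp$obj, Aeq = lp$A, beq = lp$b,
                                       ub = lp$ub, maximize = TRUE,
                                       maxiter = 1000)),
      error = function(e) NULL)
    if (!is.null(ext) && identical(ext$errno, 1)) {
      total <- total + 1L
      if (mine$status == "optimal" &&
          abs(ext$fval - mine$objective) < 1e-6) agree <- agree + 1L
    }
  }
  expect_gt(total, 20)
  expect_equal(agree, total)
})

test_that("rich media opens every exchange bound and nothing else", {
  net <- toy3_network()
  rich <- apply_rich_media(net, 1000)
  expect_equal(rich$reactions$lower_bound[rich$reactions$id == "EX_A"],
               -1000)
  inner <- rich$reactions$id != "EX_A"
  expect_equal(rich$reactions$lower_bound[inner],
               net$reactions$lower_bound[inner])
  expect_equal(rich$reactions$upper_bound, net$reactions$upper_bound)
  # no uptake, no growth
  starved <- apply_rich_media(net, 0)
  expect_equal(fba(starved)$objective, 0)
  # per-exchange override
  over <- apply_rich_media(net, 1000, overrides = c(EX_A = -3))
  expect_equal(fba(over)$objective, 3)
})

test_that("protein demands count residues and preserve sequence length", {
  d <- protein_demand_from_sequence("MKW", "demo")
  expect_equal(sort(names(d$metabolites)),
               sort(c("met_c", "lys_c", "trp_c")))
  expect_true(all(d$metabolites == 1))
  d2 <- protein_demand_from_sequence("GG", "demo")
  expect_equal(d2$metabolites, c(gly_c = 2))
  set.seed(5)
  seqs <- replicate(5, paste(sample(names(AA_METABOLITE_PREFIX), 30,
                                    TRUE), collapse = ""))
  for (s in seqs) {
    expect_equal(sum(protein_demand_from_sequence(s, "x")$metabolites),
                 nchar(s))
  }
  expect_error(protein_demand_from_sequence("MKZ", "bad"),
               class = "cf_demand_error")
})

test_that("demand attachment forces production pre-extraction and is inert at zero", {
  toy <- make_toy_network(1, 4, amino_acids = c("G", "A"), seed = 12)
  net <- apply_rich_media(toy$network, 10)
  d <- protein_demand_from_sequence("GGA", "p")
  base <- fba(net)$objective
  with0 <- add_demand(net, d, lower_bound = 0)
  expect_equal(fba(with0)$objective, base)
  expect_equal(nrow(with0$reactions), nrow(net$reactions) + 1)
  withf <- add_demand(net, d, lower_bound = 1e-6)
  sol <- fba(withf)
  expect_equal(sol$status, "optimal")
  expect_gte(sol$fluxes[["DM_p"]], 1e-6)
  expect_error(add_demand(toy3_network(), d),
               class = "cf_dangling_metabolite_error")
})

test_that("FASTA demand sequences are read through Biostrings", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">seq1 synthetic demand", "MKWGG", "AAK"), f)
  expect_equal(read_demand_sequence(f), "MKWGGAAK")
})

test_that("relative mean flux flags undefined and absent reactions", {
  m <- matrix(c(1, 2, 3, 0, 0, 0), ncol = 2,
              dimnames = list(NULL, c("r1", "r2")))
  a <- flux_samples(m, "t")
  b <- flux_samples(m, "c")
  same <- relative_mean_flux(a, b)
  expect_equal(same$ratio[same$reaction == "r1"], 1)
  expect_equal(same$status[same$reaction == "r2"], "undefined")
  doubled <- flux_samples(m * 2, "t")
  expect_equal(relative_mean_flux(doubled, b)$ratio[1], 2)
  other <- flux_samples(matrix(1:3, ncol = 1,
                               dimnames = list(NULL, "r9")), "t")
  res <- relative_mean_flux(other, b, reactions = c("r9", "r1"))
  expect_equal(res$status, c("absent", "absent"))
})
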