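test_that("toy network generation is seed-deterministic and validated", {
  a <- make_toy_network(3, 5, bypasses = list(c(1L, 2L)),
                        amino_acids = "G", seed = 17)
  b <- make_toy_network(3, 5, bypasses = list(c(1L, 2L)),
                        amino_acids = "G", seed = 17)
  expect_identical(a, b)
  c <- make_toy_network(3, 5, bypasses = list(c(1L, 2L)),
                        amino_acids = "G", seed = 18)
  expect_false(identical(a$network$metabolites$compartment,
                         c$network$metabolites$compartment) &&
               identical(a, c))
  expect_silent(validate_network(a$network))
})

test_that("planted ground truth matches the network's algebra", {
  for (args in list(list(n_chains = 1, chain_length = 3, seed = 1),
                    list(n_chains = 2, chain_length = 5,
                         bypasses = list(c(2L, 3L)), seed = 2),
                    list(n_chains = 3, chain_length = 4,
                         bypasses = list(c(1L, 2L), c(3L, 2L)), seed = 3))) {
    toy <- do.call(make_toy_network, args)
    gt <- toy$ground_truth
    expect_equal(nullspace_dimension(toy$network), gt$nullspace_dim)
    # compartment totals count every metabolite exactly once
    expect_equal(sum(gt$compartment_totals),
                 nrow(toy$network$metabolites))
    # every chain reaction exists and the sink of chain 1 is the objective
    for (ch in gt$chains) {
      expect_true(all(ch$reactions %in% toy$network$reactions$id))
    }
    expect_true("BIOMASS" %in% gt$chains[[1]]$reactions)
  }
})

test_that("composite GPR style writes evaluable isozyme rules", {
  toy <- make_toy_network(1, 4, gpr_style = "composite", seed = 4)
  gprs <- Filter(nzchar, toy$network$reactions$gpr)
  expect_true(all(grepl(" or ", gprs)))
  for (g in gprs) {
    genes <- gpr_genes(g)
    expect_length(genes, 2)
    expect_true(evaluate_gpr(parse_gpr(g), genes[1]))
    expect_false(evaluate_gpr(parse_gpr(g), character()))
  }
})

test_that("invalid bypass coordinates are rejected", {
  expect_error(make_toy_network(2, 5, bypasses = list(c(3L, 2L)), seed = 1),
               class = "cf_network_error")
  expect_error(make_toy_network(2, 5, bypasses = list(c(1L, 1L)), seed = 1),
               class = "cf_network_error")
  expect_error(make_toy_network(2, 5, bypasses = list(c(1L, 5L)), seed = 1),
               class = "cf_network_error")
  expect_error(make_toy_network(1, 4, amino_acids = "Z", seed = 1),
               class = "cf_network_error")
})

test_that("expression generation silences exactly the requested genes", {
  toy <- make_toy_network(2, 5, seed = 6)
  silenced <- list(condA = c("C1g2"), condB = c("C2g1", "C2g3"))
  prof <- make_expression(toy$network, silenced, seed = 10)
  expect_named(prof, c("control", "condA", "condB"))
  for (cond in names(prof)) {
    calls <- call_presence(prof[[cond]])
    off <- if (cond == "control") character() else silenced[[cond]]
    expect_setequal(names(calls)[!calls], off)
  }
  # a different seed moves intensities but never the calls
  prof2 <- make_expression(toy$network, silenced, seed = 11)
  expect_false(identical(prof$condA$intensity, prof2$condA$intensity))
  expect_identical(call_presence(prof$condA), call_presence(prof2$condA))
  expect_error(make_expression(toy$network, list(x = "nope"), seed = 1),
               class = "cf_expression_error")
})

test_that("DE tables reproduce the configured occupancy partition exactly", {
  toxins <- c("t1", "t2", "t3")
  up <- stats::setNames(c(40, 15, 12, 8, 5),
                        c("t1", "t2", "t3", "t1&t2", "t1&t2&t3"))
  down <- stats::setNames(c(20, 9, 7, 3), c("t1", "t2", "t3", "t1&t2&t3"))
  gen <- make_de_tables(toxins, up, down, n_null = 60, seed = 23)
  cmp <- compare_de_conditions(gen$tables)
  vu <- stats::setNames(cmp$venn_up$count, cmp$venn_up$stratum)
  vd <- stats::setNames(cmp$venn_down$count, cmp$venn_down$stratum)
  for (nm in names(up)) expect_equal(vu[[nm]], unname(up[[nm]]))
  for (nm in names(down)) expect_equal(vd[[nm]], unname(down[[nm]]))
  expect_equal(sum(vu), sum(up))
  expect_equal(sum(vd), sum(down))
  # recovered sets equal the planted ground truth per toxin
  for (tx in toxins) {
    expect_setequal(cmp$up_sets[[tx]], gen$ground_truth$up[[tx]])
    expect_setequal(cmp$down_sets[[tx]], gen$ground_truth$down[[tx]])
  }
  expect_error(make_de_tables(toxins, c(bogus = 3), down, seed = 1),
               class = "cf_de_error")
})

test_that("a planted fold-shift gives the rank test reliable power", {
  shifted <- stats::setNames(c(0.4, 0, 0), c("t1", "t2", "t3"))
  strata <- stats::setNames(c(30, 30, 30), c("t1", "t2", "t3"))
  hits <- 0L; reps <- 40L
  for (i in seq_len(reps)) {
    gen <- make_de_tables(c("t1", "t2", "t3"), strata, strata,
                          fold_shift = shifted, n_null = 20,
                          seed = 1000 + i)
    cmp <- compare_de_conditions(gen$tables)
    if (cmp$kruskal$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.9)
})

test_that("the bundled study is deterministic and internally consistent", {
  s1 <- synthetic_study(5)
  s2 <- synthetic_study(5)
  expect_identical(s1$network, s2$network)
  expect_identical(s1$de$tables, s2$de$tables)
  expect_named(s1$expression, c("control", s1$toxins))
  # silenced genes live in the network gene universe
  expect_true(all(unlist(s1$silenced) %in% s1$network$genes))
  # the demand sequence maps onto metabolites present in the network
  d <- protein_demand_from_sequence(s1$demand_sequence, "p")
  expect_true(all(names(d$metabolites) %in% s1$network$metabolites$id))
  # round-trip through the on-disk schema preserves the network
  f <- withr::local_tempfile(fileext = ".json")
  write_network(s1$network, f)
  expect_identical(read_network(f), s1$network)
})
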