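test_that("TOY3 fixture has the documented structure", {
  net <- toy3_network()
  expect_equal(nrow(net$metabolites), 5)
  expect_equal(nrow(net$reactions), 6)
  S <- stoichiometric_matrix(net)
  expect_equal(dim(S), c(5, 6))
  expect_equal(S["A_c", "R1"], -1)
  expect_equal(S["B_c", "R1"], 1)
  expect_equal(sum(S[, "R1"] != 0), 2)
})

test_that("JSON write/read round trip is the identity", {
  net <- toy_bypass_network()
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_network(net, f1)
  back <- read_network(f1)
  expect_equal(back$metabolites, net$metabolites)
  expect_equal(back$reactions, net$reactions)
  expect_equal(back$stoich, net$stoich)
  expect_equal(back$genes, net$genes)
  expect_equal(back$objective_id, net$objective_id)
  write_network(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("SBML-FBC encoding preserves the stoichiometric matrix and GPRs", {
  for (net in list(toy3_network(), toy_bypass_network(),
                   make_toy_network(2, 4, seed = 11)$network)) {
    f <- withr::local_tempfile(fileext = ".xml")
    write_network(net, f, format = "sbml")
    back <- read_network(f, format = "sbml")
    expect_identical(stoichiometric_matrix(back),
                     stoichiometric_matrix(net))
    expect_equal(back$reactions$lower_bound, net$reactions$lower_bound)
    expect_equal(back$reactions$upper_bound, net$reactions$upper_bound)
    expect_equal(lapply(back$reactions$gpr, gpr_genes),
                 lapply(net$reactions$gpr, gpr_genes))
  }
})

test_that("network validation raises distinct named errors", {
  net <- toy3_network()
  bad <- net
  bad$stoich$R1 <- c(A_c = -1, GHOST = 1)
  expect_error(validate_network(bad), class = "cf_dangling_metabolite_error")
  bad <- net
  bad$objective_id <- "NOPE"
  expect_error(validate_network(bad), class = "cf_missing_objective_error")
  bad <- net
  bad$metabolites$compartment[1] <- "x"
  expect_error(validate_network(bad), class = "cf_compartment_error")
  f <- withr::local_tempfile(fileext = ".json")
  writeLines("{ not json", f)
  expect_error(read_network(f), class = "cf_parse_error")
  expect_error(read_network(file.path(tempdir(), "missing_net.json")),
               class = "cf_parse_error")
})

test_that("null-space dimension matches hand elimination and rank identity", {
  expect_equal(nullspace_dimension(toy3_network()), 1L)
  expect_equal(nullspace_dimension(toy_bypass_network()), 2L)
  empty <- metabolic_network(
    "empty", data.frame(id = character(), name = character(),
                        compartment = character()),
    data.frame(id = character(), lower_bound = numeric(),
               upper_bound = numeric(), gpr = character(),
               subsystem = character(), is_exchange = logical()),
    stoich = list(), objective_id = "none", validate = FALSE)
  expect_equal(nullspace_dimension(empty), 0L)
  # rank + nullity = number of reactions on generated networks
  for (seed in c(3, 17, 91)) {
    toy <- make_toy_network(n_chains = sample(1:3, 1), chain_length = 5,
                            seed = seed)
    S <- stoichiometric_matrix(toy$network)
    expect_equal(nullspace_dimension(toy$network) + qr(S)$rank, ncol(S))
    expect_equal(nullspace_dimension(toy$network),
                 toy$ground_truth$nullspace_dim)
  }
})

test_that("GPR parsing, evaluation and gene extraction follow boolean semantics", {
  expect_false(evaluate_gpr("g1 AND g2", "g1"))
  expect_true(evaluate_gpr("g1 OR g2", "g1"))
  expect_true(evaluate_gpr("", character()))
  expect_true(evaluate_gpr(NULL, character()))
  expect_equal(gpr_genes("g1 and (g2 or g3)"), c("g1", "g2", "g3"))
  expect_equal(gpr_genes(""), character())
  expect_equal(gpr_genes("g1"), "g1")
  expect_error(parse_gpr("g1 and (g2"), class = "cf_gpr_error")
  expect_error(parse_gpr("and g1"), class = "cf_gpr_error")

  # a rule always holds under its full gene set; AND-only rules fail
  # with any leaf missing, OR-only rules hold with any single leaf
  rules <- c("g1", "g1 and g2 and g3", "g1 or g2 or g3",
             "(g1 or g2) and g3", "g1 and (g2 or (g3 and g4))")
  for (rule in rules) {
    genes <- gpr_genes(rule)
    expect_true(evaluate_gpr(rule, genes))
    expect_identical(gpr_genes(deparse_gpr(rule)), genes)
  }
  and_only <- "g1 and g2 and g3"
  for (drop in gpr_genes(and_only)) {
    expect_false(evaluate_gpr(and_only, setdiff(gpr_genes(and_only), drop)))
  }
  or_only <- "g1 or g2 or g3"
  for (keep in gpr_genes(or_only)) {
    expect_true(evaluate_gpr(or_only, keep))
  }
  expect_false(evaluate_gpr(or_only, character()))
})

test_that("table export writes readable reaction and metabolite TSVs", {
  net <- toy3_network()
  fr <- withr::local_tempfile(fileext = ".tsv")
  fm <- withr::local_tempfile(fileext = ".tsv")
  export_network_tables(net, fr, fm)
  rt <- read.delim(fr)
  expect_equal(rt$id, net$reactions$id)
  expect_match(rt$equation[rt$id == "R1"], "A_c --> .*B_c")
  mt <- read.delim(fm)
  expect_equal(nrow(mt), 5)
})
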