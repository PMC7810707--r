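# Synthetic-data generators with planted ground truth.
#
# Toy compartmentalised networks are built from linear pathway chains:
# each chain imports an extracellular metabolite, converts it through a
# series of compartment-hopping steps and drains it through a sink (the
# first chain's sink doubles as the biomass objective). Every reaction
# of an unbranched chain must carry the same steady-state flux, so each
# chain is a planted fully-coupled reaction set and contributes exactly
# one null-space dimension; a parallel "bypass" path splits the coupling
# at the duplicated step and adds one more dimension. This gives exact,
# hand-checkable expectations for the stoichiometric rank, FBA optimum
# (bottleneck capacity), sampler coupling structure and co-set recovery.

#' The TOY3 fixture network
#'
#' A single five-metabolite chain: `A_e -> A_c -> B_c -> B_m -> C_m`,
#' imported by exchange `EX_A`, converted by `T_A` (gene g1), `R1` (g2),
#' `T_B` (g3), `R2` (g4) and drained by the gene-free `BIOMASS` sink.
#' Six reactions, five metabolites, null-space dimension 1.
#'
#' @return a `metabolic_network`.
#' @export
toy3_network <- function() {
  mets <- data.frame(
    id = c("A_e", "A_c", "B_c", "B_m", "C_m"),
    name = c("A (extracellular)", "A (cytosol)", "B (cytosol)",
             "B (mitochondria)", "C (mitochondria)"),
    compartment = c("e", "c", "c", "m", "m"),
    stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("EX_A", "T_A", "R1", "T_B", "R2", "BIOMASS"),
    lower_bound = c(-1000, 0, 0, 0, 0, 0),
    upper_bound = rep(1000, 6),
    gpr = c("", "g1", "g2", "g3", "g4", ""),
    subsystem = c("exchange", "transport", "chain", "transport", "chain",
                  "biomass"),
    is_exchange = c(TRUE, rep(FALSE, 5)),
    stringsAsFactors = FALSE)
  sto <- list(
    EX_A = c(A_e = -1),
    T_A = c(A_e = -1, A_c = 1),
    R1 = c(A_c = -1, B_c = 1),
    T_B = c(B_c = -1, B_m = 1),
    R2 = c(B_m = -1, C_m = 1),
    BIOMASS = c(C_m = -1))
  metabolic_network("TOY3", mets, rxns, sto,
                    genes = c("g1", "g2", "g3", "g4"),
                    objective_id = "BIOMASS")
}

#' The TOY-BYPASS fixture network
#'
#' [toy3_network()] plus a parallel cytosolic route `R1b` (gene g2b)
#' duplicating `R1: A_c -> B_c`. The bypass breaks the full coupling of
#' the chain at that step and raises the null-space dimension to 2.
#'
#' @return a `metabolic_network`.
#' @export
toy_bypass_network <- function() {
  net <- toy3_network()
  net$id <- "TOY_BYPASS"
  net$reactions <- rbind(
    net$reactions[1:3, ],
    data.frame(id = "R1b", lower_bound = 0, upper_bound = 1000,
               gpr = "g2b", subsystem = "chain", is_exchange = FALSE,
               stringsAsFactors = FALSE),
    net$reactions[4:6, ])
  rownames(net$reactions) <- NULL
  net$stoich <- c(net$stoich[1:3], list(R1b = c(A_c = -1, B_c = 1)),
                  net$stoich[4:6])
  net$genes <- c("g1", "g2", "g2b", "g3", "g4")
  validate_network(net)
  net
}

# compartments available for interior chain segments
INTERIOR_COMPARTMENTS <- c("m", "r", "g", "l", "n", "p")

#' Generate a toy compartmentalised network with planted ground truth
#'
#' Builds `n_chains` independent pathway chains of `chain_length`
#' metabolites each. Chain metabolites start extracellular, enter the
#' cytosol, and interior segments are assigned organelle compartments
#' (drawn from the seeded generator unless `compartments` fixes them).
#' Every non-boundary reaction carries a single-gene GPR (style
#' `"single"`) or a two-gene isozyme rule `gA or gB` (style
#' `"composite"`). Optional `bypasses` insert a parallel path for one
#' conversion step of a chain. Optional `amino_acids` add import routes
#' for cytosolic amino-acid metabolites so protein demand reactions can
#' be attached.
#'
#' @param n_chains number of independent chains (>= 1).
#' @param chain_length metabolites per chain (>= 3).
#' @param bypasses list of `c(chain, step)` pairs; step `k` duplicates
#'   the conversion from metabolite `k` to `k + 1` (`2 <= k <=
#'   chain_length - 1`, i.e. an interior conversion).
#' @param amino_acids one-letter residue codes to make importable.
#' @param gpr_style `"single"` or `"composite"`.
#' @param compartments optional character vector of interior compartment
#'   codes, recycled across segments; overrides the seeded draw.
#' @param default_bound flux bound magnitude for all reactions.
#' @param seed mandatory integer seed.
#' @return list with elements `network` and `ground_truth`; the ground
#'   truth records per-chain ordered reaction ids, planted fully-coupled
#'   reaction sets, the expected null-space dimension and per-compartment
#'   metabolite totals.
#' @export
make_toy_network <- function(n_chains = 2, chain_length = 5,
                             bypasses = list(), amino_acids = character(),
                             gpr_style = c("single", "composite"),
                             compartments = NULL, default_bound = 1000,
                             seed) {
  gpr_style <- match.arg(gpr_style)
  stopifnot(n_chains >= 1, chain_length >= 3)
  for (bp in bypasses) {
    if (bp[1] > n_chains || bp[2] < 2 || bp[2] > chain_length - 1) {
      stop(cf_error(sprintf("invalid bypass (%d, %d)", bp[1], bp[2]),
                    "cf_network_error"))
    }
  }
  with_seed(seed, {
    mets <- list(); rxns <- list(); sto <- list()
    chains <- list()
    for (ci in seq_len(n_chains)) {
      comp <- c("e", "c")
      n_int <- chain_length - 2
      comp <- c(comp, if (!is.null(compartments)) {
        rep(compartments, length.out = n_int)
      } else {
        sample(INTERIOR_COMPARTMENTS, n_int, replace = TRUE)
      })
      mid <- sprintf("C%dM%d_%s", ci, seq_len(chain_length), comp)
      mets[[ci]] <- data.frame(
        id = mid, name = sprintf("chain %d metabolite %d", ci,
                                 seq_len(chain_length)),
        compartment = comp, stringsAsFactors = FALSE)
      ex_id <- sprintf("C%dEX", ci)
      conv_id <- sprintf("C%dR%d", ci, seq_len(chain_length - 1))
      sink_id <- if (ci == 1L) "BIOMASS" else sprintf("C%dDM", ci)
      gene_of <- function(step) {
        if (gpr_style == "single") sprintf("C%dg%d", ci, step)
        else sprintf("C%dg%da or C%dg%db", ci, step, ci, step)
      }
      ids <- c(ex_id, conv_id, sink_id)
      rxns[[ci]] <- data.frame(
        id = ids,
        lower_bound = c(-default_bound, rep(0, chain_length)),
        upper_bound = rep(default_bound, chain_length + 1),
        gpr = c("", vapply(seq_len(chain_length - 1), gene_of,
                           character(1)), ""),
        subsystem = sprintf("chain%d", ci),
        is_exchange = c(TRUE, rep(FALSE, chain_length)),
        stringsAsFactors = FALSE)
      s <- c(list(stats::setNames(-1, mid[1])),
             lapply(seq_len(chain_length - 1), function(k) {
               stats::setNames(c(-1, 1), mid[k + 0:1])
             }),
             list(stats::setNames(-1, mid[chain_length])))
      names(s) <- ids
      sto <- c(sto, s)
      chains[[ci]] <- list(reactions = ids, metabolites = mid,
                           genes = unique(unlist(lapply(rxns[[ci]]$gpr,
                                                        gpr_genes))))
    }
    mets <- do.call(rbind, mets)
    rxns <- do.call(rbind, rxns)

    # bypasses: duplicate a conversion step with an isozyme-style gene
    for (bp in bypasses) {
      ci <- bp[1]; k <- bp[2]
      orig <- sprintf("C%dR%d", ci, k)
      bid <- paste0(orig, "b")
      row <- rxns[rxns$id == orig, , drop = FALSE]
      row$id <- bid
      row$gpr <- if (nzchar(row$gpr)) paste0(gpr_genes(row$gpr)[1], "b") else ""
      rxns <- rbind(rxns, row)
      sto[[bid]] <- sto[[orig]]
      chains[[ci]]$bypassed <- c(chains[[ci]]$bypassed, orig)
    }
    rownames(rxns) <- NULL

    # amino-acid import routes for demand construction (gene-free)
    for (aa in amino_acids) {
      if (!aa %in% names(AA_METABOLITE_PREFIX)) {
        stop(cf_error(paste0("unknown amino-acid code: ", aa),
                      "cf_network_error"))
      }
      base <- AA_METABOLITE_PREFIX[[aa]]
      me <- paste0(base, "_e"); mc <- paste0(base, "_c")
      mets <- rbind(mets, data.frame(
        id = c(me, mc), name = paste(base, c("(extracellular)", "(cytosol)")),
        compartment = c("e", "c"), stringsAsFactors = FALSE))
      exid <- paste0("EX_", base); tid <- paste0("T_", base)
      rxns <- rbind(rxns, data.frame(
        id = c(exid, tid), lower_bound = c(-default_bound, 0),
        upper_bound = default_bound, gpr = "",
        subsystem = "amino acid supply",
        is_exchange = c(TRUE, FALSE), stringsAsFactors = FALSE))
      sto[[exid]] <- stats::setNames(-1, me)
      sto[[tid]] <- stats::setNames(c(-1, 1), c(me, mc))
    }

    net <- metabolic_network(
      id = sprintf("toy_%dx%d", n_chains, chain_length),
      metabolites = mets, reactions = rxns, stoich = sto,
      objective_id = "BIOMASS")

    coupled <- lapply(chains, function(ch) {
      if (is.null(ch$bypassed)) ch$reactions
      else setdiff(ch$reactions, ch$bypassed)
    })
    gt <- list(
      chains = chains,
      coupled_sets = coupled,
      nullspace_dim = n_chains + length(bypasses),
      compartment_totals = table(mets$compartment))
    list(network = net, ground_truth = gt)
  })
}

#' Generate per-condition expression profiles with planted silencing
#'
#' Control and every toxin condition share the network's gene universe.
#' Non-silenced genes draw log-normal intensities clamped at or above the
#' presence cutoff; genes silenced in a condition draw low intensities
#' clamped strictly below it. Presence calls are therefore exact by
#' construction while the intensity noise still varies with the seed.
#'
#' @param network a `metabolic_network` supplying the gene universe.
#' @param silenced named list: condition label -> character vector of
#'   silenced gene ids (each must be in the gene universe).
#' @param cutoff presence threshold the profiles are built around.
#' @param present_median,silenced_median medians of the two log-normal
#'   intensity components (arbitrary intensity units).
#' @param seed integer seed.
#' @return named list of profiles (`control` first), each a data.frame
#'   with columns `gene`, `intensity`.
#' @export
make_expression <- function(network, silenced = list(), cutoff = 11,
                            present_median = 150, silenced_median = 3,
                            seed) {
  genes <- network$genes
  for (cond in names(silenced)) {
    bad <- setdiff(silenced[[cond]], genes)
    if (length(bad)) {
      stop(cf_error(paste0("silenced gene(s) not in network: ",
                           paste(bad, collapse = ", ")),
                    "cf_expression_error"))
    }
  }
  with_seed(seed, {
    profiles <- list()
    for (cond in c("control", names(silenced))) {
      off <- if (cond == "control") character() else silenced[[cond]]
      hi <- pmax(stats::rlnorm(length(genes), log(present_median), 0.6),
                 cutoff)
      lo <- pmin(stats::rlnorm(length(genes), log(silenced_median), 0.5),
                 cutoff * 0.95)
      intensity <- ifelse(genes %in% off, lo, hi)
      profiles[[cond]] <- data.frame(gene = genes, intensity = intensity,
                                     stringsAsFactors = FALSE)
    }
    profiles
  })
}

#' Generate differential-expression tables with a configured Venn structure
#'
#' Plants an exact occupancy partition: for each stratum (a subset of
#' toxins, e.g. `"toxinA"`, `"toxinA&toxinC"`, `"toxinA&toxinB&toxinC"`)
#' the requested number of genes is differentially expressed in exactly
#' those toxins. Member records satisfy the standard thresholds (fold >
#' `1.75` up / < `0.55` down, p <= 0.05, FDR q < 0.1); non-member records
#' fail the p filter with a near-unit fold change, so running
#' [call_de()] followed by [venn_partition()] recovers the configured
#' counts exactly. Per-toxin multiplicative fold shifts move the whole
#' fold-change distribution of one toxin, giving the Kruskal-Wallis
#' comparison a known location effect.
#'
#' @param toxins condition labels (>= 2).
#' @param up_strata,down_strata named non-negative integer vectors;
#'   names are stratum labels built by joining toxin labels with `"&"`
#'   in `toxins` order. Missing strata default to 0.
#' @param fold_shift named numeric, per-toxin log-scale location shift
#'   applied to its DE fold changes (0 = reference distribution).
#' @param n_null background genes that are DE in no toxin.
#' @param up_threshold,down_threshold,p_max,q_max thresholds the planted
#'   records are built to respect.
#' @param seed integer seed.
#' @return list with `tables` (named list of per-toxin data.frames with
#'   columns `gene`, `fold_change`, `p_value`, `fdr_q`) and
#'   `ground_truth` (per-toxin up/down gene sets and the stratum counts).
#' @export
make_de_tables <- function(toxins = c("toxinA", "toxinB", "toxinC"),
                           up_strata, down_strata,
                           fold_shift = stats::setNames(rep(0, length(toxins)),
                                                        toxins),
                           n_null = 100,
                           up_threshold = 1.75, down_threshold = 0.55,
                           p_max = 0.05, q_max = 0.1, seed) {
  k <- length(toxins)
  stopifnot(k >= 2)
  strata_names <- function(x) {
    combos <- unlist(lapply(seq_len(k), function(r) {
      utils::combn(toxins, r, paste, collapse = "&", simplify = FALSE)
    }))
    full <- stats::setNames(rep(0L, length(combos)), combos)
    if (!missing(x) && length(x)) {
      bad <- setdiff(names(x), combos)
      if (length(bad)) {
        stop(cf_error(paste0("unknown stratum label(s): ",
                             paste(bad, collapse = ", ")),
                      "cf_de_error"))
      }
      full[names(x)] <- x
    }
    full
  }
  up_strata <- strata_names(up_strata)
  down_strata <- strata_names(down_strata)

  with_seed(seed, {
    n_up <- sum(up_strata); n_down <- sum(down_strata)
    gene_ids <- sprintf("deg_%05d", seq_len(n_up + n_down + n_null))
    up_ids <- gene_ids[seq_len(n_up)]
    down_ids <- gene_ids[n_up + seq_len(n_down)]
    assign_strata <- function(ids, strata) {
      rep(names(strata), times = strata)[seq_along(ids)]
    }
    up_members <- split(up_ids, assign_strata(up_ids, up_strata))
    down_members <- split(down_ids, assign_strata(down_ids, down_strata))
    in_stratum <- function(stratum, toxin) {
      toxin %in% strsplit(stratum, "&", fixed = TRUE)[[1]]
    }

    tables <- list(); gt_up <- list(); gt_down <- list()
    for (tx in toxins) {
      sh <- if (tx %in% names(fold_shift)) fold_shift[[tx]] else 0
      up_set <- unlist(up_members[vapply(names(up_members), in_stratum,
                                         logical(1), toxin = tx)],
                       use.names = FALSE)
      down_set <- unlist(down_members[vapply(names(down_members), in_stratum,
                                             logical(1), toxin = tx)],
                         use.names = FALSE)
      n <- length(gene_ids)
      fold <- pmin(pmax(exp(stats::rnorm(n, 0, 0.08)),
                        down_threshold * 1.1), up_threshold * 0.95)
      p <- stats::runif(n, p_max * 4, 0.9)
      q <- stats::runif(n, q_max * 2, 1)
      iu <- match(up_set, gene_ids)
      fold[iu] <- up_threshold *
        exp(0.02 + sh + abs(stats::rnorm(length(iu), 0, 0.35)))
      idn <- match(down_set, gene_ids)
      fold[idn] <- pmin(down_threshold *
                          exp(-(0.02 + abs(stats::rnorm(length(idn), 0, 0.35)))) *
                          exp(sh), down_threshold * 0.999)
      im <- c(iu, idn)
      p[im] <- stats::runif(length(im), 0, p_max)
      q[im] <- stats::runif(length(im), 0, q_max * 0.999)
      tables[[tx]] <- data.frame(gene = gene_ids, fold_change = fold,
                                 p_value = p, fdr_q = q,
                                 stringsAsFactors = FALSE)
      gt_up[[tx]] <- up_set
      gt_down[[tx]] <- down_set
    }
    list(tables = tables,
         ground_truth = list(up = gt_up, down = gt_down,
                             up_strata = up_strata,
                             down_strata = down_strata))
  })
}

#' Bundle a complete synthetic study
#'
#' Produces every input the pipeline consumes: a toy network with a
#' bypass and amino-acid supply, per-condition expression profiles in
#' which each toxin silences one pathway gene (the first toxin's target
#' has a bypass, so its context model can adapt; the second's does not),
#' per-toxin DE tables with a configured Venn structure, and a short
#' protein demand sequence. All derived from one seed.
#'
#' @param seed master integer seed.
#' @param toxins three condition labels.
#' @param n_points retained for callers configuring downstream sampling;
#'   stored in the returned config echo.
#' @return list with `network`, `ground_truth`, `expression`, `silenced`,
#'   `de`, `demand_sequence`, `toxins`.
#' @export
synthetic_study <- function(seed, toxins = c("toxinA", "toxinB", "toxinC"),
                            n_points = 1000) {
  toy <- make_toy_network(
    n_chains = 3, chain_length = 5,
    bypasses = list(c(1L, 2L)),
    amino_acids = c("G", "A", "K"),
    compartments = c("m", "r"),
    seed = derive_seed(seed, 1L))
  silenced <- stats::setNames(list("C1g2", "C2g2", character()), toxins)
  expr <- make_expression(toy$network, silenced,
                          seed = derive_seed(seed, 2L))
  de <- make_de_tables(
    toxins = toxins,
    up_strata = stats::setNames(
      c(50, 20, 20, 10),
      c(toxins, paste(toxins, collapse = "&"))),
    down_strata = stats::setNames(
      c(25, 10, 10, 5),
      c(toxins, paste(toxins, collapse = "&"))),
    fold_shift = stats::setNames(c(0.4, 0, 0), toxins),
    seed = derive_seed(seed, 3L))
  list(network = toy$network, ground_truth = toy$ground_truth,
       expression = expr, silenced = silenced, de = de,
       demand_sequence = "GGAKGAKAGG", toxins = toxins,
       n_points = n_points, seed = seed)
}
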