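# End-to-end orchestration: presence calls -> GIMME consensus ->
# demand handling -> ACHR sampling -> merge -> numerical cutoff ->
# co-sets -> profile clustering -> differential flux -> organelle
# profiles -> DE comparison, with one master seed and reproducible
# tabular outputs.

#' Pipeline configuration
#'
#' Builds the full parameter set with the standard defaults (presence
#' cutoff 11; DE thresholds 1.75 / 0.55 with p <= 0.05, q < 0.1; GIMME
#' floor 0.5 with 3 reordering iterations; 5000 sampled points per
#' model with numerical cutoff 1e-7; co-set threshold 0.975 with large
#' co-sets at >= 6 members; differential flux at Bonferroni alpha 0.05,
#' fold 2, magnitude ceiling 1000; rich-media uptake 1000; forced
#' demand lower bound 1e-6). Values in a YAML `file` override defaults;
#' `...` overrides both.
#'
#' @param ... named overrides.
#' @param file optional YAML file.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(..., file = NULL) {
  cfg <- list(
    synthetic = TRUE,
    network_path = NULL, network_format = "json",
    expression_paths = NULL,      # named TSVs: control + toxins
    de_paths = NULL,              # named TSVs: toxins
    demand_fasta = NULL,
    demand_sequence = NULL,
    presence_cutoff = 11,
    up_threshold = 1.75, down_threshold = 0.55,
    p_max = 0.05, q_max = 0.1,
    gimme_fraction = 0.5, gimme_iterations = 3L,
    n_points = 5000L, burn_in = 0L, thin = 1L,
    numerical_cutoff = 1e-7,
    coset_threshold = 0.975, coset_min_size = 6L,
    diff_alpha = 0.05, diff_min_fold = 2,
    diff_magnitude_ceiling = 1000,
    diff_pairing = "unpaired",
    rich_media_uptake = 1000,
    demand_lower_bound = 1e-6,
    write_samples = FALSE,
    seed = 1L)
  if (!is.null(file)) {
    if (!file.exists(file)) {
      stop(cf_error(paste0("config file not found: ", file),
                    "cf_config_error"))
    }
    over <- yaml::read_yaml(file)
    cfg[names(over)] <- over
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  if (!isTRUE(cfg$synthetic)) {
    paths <- c(cfg$network_path, unlist(cfg$expression_paths),
               unlist(cfg$de_paths), cfg$demand_fasta)
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop(cf_error(paste0("input file(s) not found: ",
                           paste(missing, collapse = ", ")),
                    "cf_config_error"))
    }
  }
  stopifnot(cfg$presence_cutoff >= 0, cfg$gimme_fraction > 0,
            cfg$gimme_fraction <= 1, cfg$n_points >= 1,
            cfg$numerical_cutoff >= 0, cfg$coset_threshold > 0,
            cfg$coset_threshold <= 1, cfg$coset_min_size >= 2,
            cfg$diff_alpha > 0, cfg$diff_alpha < 1,
            cfg$diff_min_fold > 1, cfg$rich_media_uptake >= 0)
  invisible(cfg)
}

write_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Stage order: input loading (or synthetic generation) -> presence
#' calls -> DE comparison (thresholding, Venn, Kruskal-Wallis + Dunn)
#' -> organelle profiles -> rich media + forced protein demand -> GIMME
#' consensus per condition -> demand release -> ACHR sampling of each
#' iteration model -> merge + numerical cutoff -> co-sets, large co-set
#' profiles, clustering -> differential flux per toxin vs control ->
#' relative mean fluxes. All tabular artefacts are written under
#' `outdir` with stable ordering, so identical configs give
#' byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return the report bundle (named list), invisibly; the `manifest`
#'   element echoes every parameter actually used.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  validate_pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  report <- list()

  # --- stage 1: inputs ------------------------------------------------
  if (isTRUE(config$synthetic)) {
    study <- synthetic_study(derive_seed(seed, 1L),
                             n_points = config$n_points)
    network <- study$network
    expr <- study$expression
    de_tables <- study$de$tables
    demand_seq <- study$demand_sequence
    report$ground_truth <- study$ground_truth
    report$de_ground_truth <- study$de$ground_truth
  } else {
    network <- read_network(config$network_path, config$network_format)
    expr <- lapply(config$expression_paths, read_expression)
    de_tables <- lapply(config$de_paths, read_de_table)
    demand_seq <- if (!is.null(config$demand_fasta)) {
      read_demand_sequence(config$demand_fasta)
    } else config$demand_sequence
  }
  conditions <- names(expr)
  toxins <- setdiff(conditions, "control")

  # --- stage 2: presence calls ---------------------------------------
  presence <- lapply(expr, call_presence, cutoff = config$presence_cutoff)
  report$presence <- presence

  # --- stage 3: DE comparison ----------------------------------------
  de_cmp <- compare_de_conditions(
    de_tables, up_threshold = config$up_threshold,
    down_threshold = config$down_threshold,
    p_max = config$p_max, q_max = config$q_max)
  report$de <- de_cmp
  write_tsv(de_cmp$venn_up, file.path(outdir, "de_venn_up.tsv"))
  write_tsv(de_cmp$venn_down, file.path(outdir, "de_venn_down.tsv"))
  write_tsv(de_cmp$dunn, file.path(outdir, "de_dunn.tsv"))
  write_tsv(data.frame(statistic = "kruskal_wallis_H",
                       value = de_cmp$kruskal$H,
                       p = de_cmp$kruskal$p, df = de_cmp$kruskal$df),
            file.path(outdir, "de_kruskal.tsv"))

  # --- stage 4: organelle profiles (DE genes present in the network) --
  org <- list()
  for (tx in names(de_tables)) {
    up <- intersect(de_cmp$up_sets[[tx]], network$genes)
    down <- intersect(de_cmp$down_sets[[tx]], network$genes)
    prof <- condition_organelle_profiles(network, up, down)
    prof <- cbind(condition = tx, prof)
    org[[tx]] <- prof
  }
  org_tab <- do.call(rbind, c(org, list(make.row.names = FALSE)))
  report$organelle <- org_tab
  write_tsv(org_tab, file.path(outdir, "organelle_profiles.tsv"))

  # --- stage 5: media and demand -------------------------------------
  net_rich <- apply_rich_media(network, config$rich_media_uptake)
  demand <- NULL
  if (!is.null(demand_seq)) {
    demand <- protein_demand_from_sequence(demand_seq, "protein")
    avail <- names(demand$metabolites) %in% net_rich$metabolites$id
    if (!all(avail)) {
      stop(cf_error(paste0("demand metabolite(s) missing from network: ",
                           paste(names(demand$metabolites)[!avail],
                                 collapse = ", ")),
                    "cf_dangling_metabolite_error"))
    }
  }
  net_gimme <- if (is.null(demand)) net_rich else
    add_demand(net_rich, demand, lower_bound = config$demand_lower_bound)
  net_sample <- if (is.null(demand)) net_rich else
    add_demand(net_rich, demand, lower_bound = 0)

  # --- stage 6-8: GIMME consensus, sampling, merge, cutoff -----------
  samples <- list(); models <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    gcfg <- gimme_config(required_fraction = config$gimme_fraction,
                         iterations = config$gimme_iterations,
                         seed = derive_seed(seed, 6L, ci))
    cm <- gimme_consensus(net_gimme, presence[[cond]], gcfg)
    models[[cond]] <- cm
    write_context_model(cm, file.path(outdir,
                                      sprintf("gimme_%s.json", cond)))
    per_iter <- lapply(seq_along(cm$iterations), function(ii) {
      sub <- subset_network(net_sample, cm$iterations[[ii]]$retained,
                            id = sprintf("%s_iter%d", cond, ii))
      achr_sample(sub, n_points = config$n_points,
                  seed = derive_seed(seed, 7L, ci * 100L + ii),
                  burn_in = config$burn_in, thin = config$thin,
                  condition = cond)
    })
    merged <- merge_samples(per_iter)
    samples[[cond]] <- apply_cutoff(merged, config$numerical_cutoff)
    if (isTRUE(config$write_samples)) {
      write_tsv(as.data.frame(sample_matrix(samples[[cond]])),
                file.path(outdir, sprintf("samples_%s.tsv", cond)))
    }
  }
  report$models <- models
  report$samples <- samples

  # --- stage 9: co-sets ----------------------------------------------
  cosets <- list()
  coset_counts <- list()
  for (cond in conditions) {
    cs <- build_cosets(flux_correlation_matrix(samples[[cond]]),
                       threshold = config$coset_threshold)
    cosets[[cond]] <- cs
    coset_counts[[cond]] <- data.frame(
      condition = cond,
      n_cosets = length(cs$cosets),
      n_singletons = length(cs$singletons),
      n_large = length(large_cosets(cs, config$coset_min_size)),
      stringsAsFactors = FALSE)
    write_coset_table(cs, file.path(outdir,
                                    sprintf("cosets_%s.tsv", cond)))
  }
  report$cosets <- cosets
  count_tab <- do.call(rbind, c(coset_counts, list(make.row.names = FALSE)))
  report$coset_counts <- count_tab
  write_tsv(count_tab, file.path(outdir, "coset_counts.tsv"))

  large_ctrl <- large_cosets(cosets[[conditions[1]]],
                             config$coset_min_size)
  if (length(large_ctrl)) {
    profile <- coset_relative_profile(large_ctrl, samples)
    report$coset_profile <- profile
    write_tsv(profile, file.path(outdir, "coset_profile.tsv"))
    hc <- cluster_profiles(profile)
    if (!is.null(hc)) {
      report$coset_clustering <- hc
      jsonlite::write_json(
        list(labels = hc$labels, merge = hc$merge, height = hc$height,
             order = hc$order),
        file.path(outdir, "coset_dendrogram.json"), digits = NA)
    }
  }

  # --- stage 10: differential flux -----------------------------------
  dcfg <- diff_flux_config(alpha = config$diff_alpha,
                           min_fold = config$diff_min_fold,
                           magnitude_ceiling = config$diff_magnitude_ceiling,
                           pairing = config$diff_pairing)
  diff_tabs <- list(); sig_sets <- list()
  for (tx in toxins) {
    dt <- differential_reactions(samples[[tx]], samples[["control"]], dcfg)
    dt <- cbind(condition = tx, dt)
    diff_tabs[[tx]] <- dt
    sig_sets[[tx]] <- dt$reaction[dt$significant]
    write_tsv(dt, file.path(outdir, sprintf("diff_flux_%s.tsv", tx)))
  }
  report$diff_flux <- diff_tabs
  report$diff_sig_sets <- sig_sets
  if (length(sig_sets) >= 2) {
    dv <- significant_set_venn(sig_sets)
    report$diff_venn <- dv
    write_tsv(dv, file.path(outdir, "diff_flux_venn.tsv"))
  }

  # --- stage 11: relative mean fluxes --------------------------------
  rel <- list()
  for (tx in toxins) {
    rf <- relative_mean_flux(samples[[tx]], samples[["control"]])
    rel[[tx]] <- cbind(condition = tx, rf)
  }
  rel_tab <- do.call(rbind, c(rel, list(make.row.names = FALSE)))
  report$relative_flux <- rel_tab
  write_tsv(rel_tab, file.path(outdir, "relative_flux.tsv"))

  # --- manifest -------------------------------------------------------
  manifest <- list(
    package = "contextflux",
    version = as.character(utils::packageVersion("contextflux")),
    master_seed = seed,
    parameters = unclass(config),
    conditions = conditions,
    stage_seeds = list(
      inputs = derive_seed(seed, 1L),
      gimme = vapply(seq_along(conditions), function(ci)
        derive_seed(seed, 6L, ci), integer(1)),
      sampling = "derive_seed(seed, 7, condition_index * 100 + iteration)"),
    artefacts = sort(unique(c(list.files(outdir), "manifest.json"))))
  report$manifest <- manifest
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}
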