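#' Run the full trait-to-ecosystem pipeline
#'
#' Executes the analysis chain end to end: (optionally) simulate growth
#' plates and community counts, blank-correct and fit logistic growth
#' curves, fit Sharpe-Schoolfield thermal performance curves and derive
#' thermal traits, compute diversity metrics with the prevalence filter,
#' and run the inferential layer (polynomial model selection for
#' richness/evenness/function, trait-abundance ANCOVA, PCA, PERMANOVA with
#' pairwise Bonferroni tests). Every artifact is written under `out_dir`
#' together with a JSON manifest recording the configuration hash, seed,
#' package version, and per-stage record counts.
#'
#' @param config A [run_config()] (or path handled by
#'   [read_run_config()]).
#' @param out_dir Output directory (created if absent).
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the main tables and fitted objects:
#'   `params` (simulated truth, when simulating), `rates`, `traits`,
#'   `diversity`, `rel_abund`, `stats`, and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("thermotrait_run_"),
                         quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  counts_log <- list()

  ## --- stage: inputs (simulate or read) -------------------------------
  params <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    scfg <- do.call(sim_config, sim_args)
    params <- gen_taxon_params(scfg)
    plate <- gen_growth_plate(params, scfg)
    counts <- gen_community_counts(params, scfg)
    write_table_csv(params, file.path(out_dir, "true_params.csv"))
    write_table_csv(plate, file.path(out_dir, "plate.csv"))
    write_table_csv(counts, file.path(out_dir, "counts.csv"))
    say("simulate: %d plate records, %d count records",
      nrow(plate), nrow(counts))
  } else {
    plate <- read_plate_csv(config$plate_csv)
    counts <- read_counts_csv(config$counts_csv)
    say("read: %d plate records, %d count records",
      nrow(plate), nrow(counts))
  }
  counts_log$plate_records <- nrow(plate)
  counts_log$count_records <- nrow(counts)

  ## --- stage: growth fitting ------------------------------------------
  corrected <- blank_correct(plate)
  counts_log$blank_records_removed <- nrow(plate) - nrow(corrected)
  rates <- growth_rate_table(
    corrected,
    n_starts = config$growth_n_starts,
    seed = derive_seed(config$seed, "growth")
  )
  counts_log$rate_groups <- nrow(rates)
  counts_log$rate_groups_failed <- sum(rates$n_reps_used == 0)
  write_table_csv(rates, file.path(out_dir, "growth_rates.csv"))
  say("fit-growth: %d taxon x temperature groups (%d with no usable fit)",
    nrow(rates), sum(rates$n_reps_used == 0))

  ## --- stage: thermal traits ------------------------------------------
  usable <- rates[!is.na(rates$mean_r_per_h), ]
  traits <- fit_tpc_table(
    usable,
    n_starts = config$n_starts,
    seed = derive_seed(config$seed, "tpc"),
    tref_c = config$tref_c
  )
  write_table_csv(traits, file.path(out_dir, "thermal_traits.csv"))
  counts_log$taxa_fitted <- nrow(traits)
  say("fit-tpc: %d taxa fitted", nrow(traits))

  ## --- stage: diversity -----------------------------------------------
  ## diversity and composition use the raw counts; the prevalence filter
  ## applies only to the trait-abundance analyses, where rare taxa would
  ## otherwise drive the regressions
  filtered <- filter_rare(counts, config$min_prevalence)
  counts_log$rare_records_removed <- nrow(counts) - nrow(filtered)
  div <- diversity_table(counts)
  rel <- relative_abundance_table(counts)
  rel_filtered <- relative_abundance_table(filtered)
  counts_log$undefined_evenness <- sum(is.na(div$pielou_j))
  write_table_csv(div, file.path(out_dir, "diversity.csv"))
  write_table_csv(rel, file.path(out_dir, "relative_abundance.csv"))
  say("diversity: %d communities (%d with undefined evenness), %d rare records removed",
    nrow(div), sum(is.na(div$pielou_j)), nrow(counts) - nrow(filtered))

  ## --- stage: stats ----------------------------------------------------
  stats_seed <- derive_seed(config$seed, "stats")

  richness_model <- polynomial_lrt(div$temp_c, div$richness)
  evenness_model <- polynomial_lrt(div$temp_c, div$pielou_j)

  ## trait-abundance ANCOVA (thermal optimum as the covariate), on the
  ## prevalence-filtered abundances
  rel_tr <- dplyr::inner_join(
    rel_filtered, traits[, c("taxon", "topt_c")], by = "taxon"
  )
  ancova_topt <- ancova_trait_abundance(
    rel_tr$rel_abund, rel_tr$topt_c, rel_tr$temp_c
  )

  ## growth rate at the assay temperature as the covariate
  rel_rt <- rel_tr
  rel_rt$r_at_temp <- exp(ss_ln_rate(
    rel_rt$temp_c,
    traits$ea_ev[match(rel_rt$taxon, traits$taxon)],
    traits$eh_ev[match(rel_rt$taxon, traits$taxon)],
    traits$th_k[match(rel_rt$taxon, traits$taxon)],
    traits$ln_r_tc[match(rel_rt$taxon, traits$taxon)],
    tc_k = config$tref_c + C_TO_K
  ))
  ancova_rate <- ancova_trait_abundance(
    rel_rt$rel_abund, rel_rt$r_at_temp, rel_rt$temp_c
  )

  ## composition: PCA + PERMANOVA on Bray-Curtis
  comp <- rel |>
    tidyr::pivot_wider(
      names_from = "taxon", values_from = "rel_abund", values_fill = 0
    )
  comp_mat <- as.matrix(comp[, setdiff(names(comp), c("temp_c", "replicate"))])
  pca <- pca_composition(comp_mat)
  d <- bray_curtis(comp_mat)
  perm <- permanova(d, factor(comp$temp_c),
    n_perm = config$n_perm, seed = stats_seed
  )
  pairwise <- pairwise_permanova(d, factor(comp$temp_c),
    n_perm = config$n_perm, seed = stats_seed
  )

  stats_out <- list(
    richness_model = richness_model,
    evenness_model = evenness_model,
    ancova_topt = ancova_topt,
    ancova_rate = ancova_rate,
    pca = pca,
    permanova = perm,
    pairwise_permanova = pairwise
  )
  say("stats: richness model '%s', evenness model '%s', PERMANOVA F = %.2f (p = %.3g)",
    richness_model$chosen, evenness_model$chosen,
    perm$pseudo_f, perm$p_perm)

  report <- list(
    richness_model = list(
      chosen = richness_model$chosen,
      coefficients = as.list(richness_model$coefficients),
      r2 = richness_model$r2
    ),
    evenness_model = list(
      chosen = evenness_model$chosen,
      coefficients = as.list(evenness_model$coefficients),
      r2 = evenness_model$r2
    ),
    ancova_topt = list(
      f = unname(ancova_topt$overall_f[["F"]]),
      df1 = unname(ancova_topt$overall_f[["df1"]]),
      df2 = unname(ancova_topt$overall_f[["df2"]]),
      p = unname(ancova_topt$overall_f[["p"]]),
      r2 = ancova_topt$r2
    ),
    permanova = list(
      pseudo_f = perm$pseudo_f, p = perm$p_perm,
      df = as.list(perm$df), n_perm = perm$n_perm
    ),
    pca_var_explained = pca$var_explained
  )
  jsonlite::write_json(
    report, file.path(out_dir, "stats_report.json"),
    auto_unbox = TRUE, digits = NA
  )

  manifest <- list(
    package = "thermotrait",
    version = as.character(packageVersion("thermotrait")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    record_counts = counts_log
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )

  invisible(list(
    params = params, rates = rates, traits = traits,
    diversity = div, rel_abund = rel, stats = stats_out,
    manifest = manifest, out_dir = out_dir
  ))
}
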