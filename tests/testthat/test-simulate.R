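test_that("drawn parameter sets respect the trait ranges and Eh > Ea", {
  cfg <- sim_config(seed = 1, n_taxa = 8)
  p <- gen_taxon_params(cfg)
  expect_identical(nrow(p), 8L)
  expect_true(all(p$eh_ev > p$ea_ev))
  expect_true(all(p$ea_ev > 0))
  expect_true(all(p$th_k > 273.15))
  expect_true(all(p$topt_c >= 18.7 & p$topt_c <= 35.3))
  expect_true(all(p$ea_ev >= 0.23 & p$ea_ev <= 1.06))
  ## the closed-form optimum never errors on generator output
  expect_true(all(is.finite(compute_topt(p$ea_ev, p$eh_ev, p$th_k))))
})

test_that("generation is deterministic given the seed", {
  cfg <- sim_config(seed = 42)
  expect_identical(gen_taxon_params(cfg), gen_taxon_params(cfg))
  p <- gen_taxon_params(cfg)
  expect_identical(gen_growth_plate(p, cfg), gen_growth_plate(p, cfg))
  expect_identical(
    gen_community_counts(p, cfg), gen_community_counts(p, cfg)
  )
  ## a single taxon is a valid degenerate pool
  p1 <- gen_taxon_params(sim_config(seed = 3, n_taxa = 1))
  expect_identical(nrow(p1), 1L)
  expect_gt(p1$eh_ev, p1$ea_ev)
})

test_that("implied optimum matches the drawn target exactly", {
  p <- gen_taxon_params(sim_config(seed = 9))
  expect_equal(
    compute_topt(p$ea_ev, p$eh_ev, p$th_k) - 273.15, p$topt_c
  )
})

test_that("noiseless wells trace the logistic curve over the baseline", {
  cfg <- sim_config(
    seed = 1, n_taxa = 2, noise_sd_od = 0, n_tech_reps = 1,
    assay_temps_c = c(20, 30)
  )
  p <- gen_taxon_params(cfg)
  plate <- gen_growth_plate(p, cfg)
  sub <- plate[plate$taxon == p$taxon_id[1] & plate$temp_c == 20, ]
  r <- true_growth_rate(p[1, ], 20)
  expect_equal(
    sub$od600,
    cfg$baseline_od + logistic_od(sub$time_h, r, cfg$K, cfg$N0)
  )
  expect_equal(sub$od600[sub$time_h == 0], cfg$N0 + cfg$baseline_od)
  ## trajectories are run long enough to approach the asymptote K
  expect_gt(max(sub$od600) - cfg$baseline_od, 0.98 * cfg$K)
  ## after blank correction the series is exactly logistic
  corrected <- blank_correct(plate)
  csub <- corrected[
    corrected$taxon == p$taxon_id[1] & corrected$temp_c == 20,
  ]
  expect_equal(
    csub$od600, logistic_od(csub$time_h, r, cfg$K, cfg$N0),
    tolerance = 1e-12
  )
})

test_that("well noise is unbiased around the noiseless curve", {
  cfg <- sim_config(
    seed = 5, n_taxa = 1, noise_sd_od = 0.01, n_tech_reps = 100,
    assay_temps_c = 25
  )
  p <- gen_taxon_params(cfg)
  plate <- gen_growth_plate(p, cfg)
  samples <- plate[!plate$is_blank, ]
  r <- true_growth_rate(p, 25)
  means <- tapply(samples$od600, samples$time_h, mean)
  times <- as.numeric(names(means))
  truth <- cfg$baseline_od + logistic_od(times, r, cfg$K, cfg$N0)
  expect_true(all(abs(means - truth) < 3 * 0.01 / sqrt(100)))
})

test_that("selection exponent controls the expected proportions", {
  cfg0 <- sim_config(seed = 2, selection_exponent = 0)
  p <- gen_taxon_params(cfg0)
  p0 <- expected_proportions(p, cfg0, 25)
  expect_equal(unname(p0), rep(1 / 8, 8))

  ## strong selection concentrates on a strictly fastest taxon: flat
  ## curves (negligible Ea, distant Th) isolate the weighting itself
  flat <- tibble::tibble(
    taxon_id = c("slow", "mid", "fast"),
    ea_ev = 1e-9, eh_ev = 2, th_k = 1e6,
    ln_r_tc = log(c(0.3, 0.4, 0.5)), tc_k = 291.15
  )
  cfg_strong <- sim_config(seed = 2, selection_exponent = 60)
  p_strong <- expected_proportions(flat, cfg_strong, 25)
  expect_gt(p_strong[["fast"]], 0.999)
  ## proportions always sum to one
  for (t in c(10, 20, 35)) {
    expect_equal(sum(expected_proportions(p, cfg0, t)), 1)
  }
})

test_that("counts are multinomial with the configured total", {
  cfg <- sim_config(seed = 4, total_colonies = 250, n_community_reps = 5)
  p <- gen_taxon_params(cfg)
  counts <- gen_community_counts(p, cfg)
  totals <- counts |>
    dplyr::group_by(temp_c, replicate) |>
    dplyr::summarise(total = sum(count), .groups = "drop")
  expect_true(all(totals$total == 250))
  expect_true(all(counts$count >= 0 & counts$count == round(counts$count)))
})

test_that("selection lowers richness and evenness at 35 C relative to 20 C", {
  cfg <- sim_config(
    seed = 6, selection_exponent = 3, n_community_reps = 200,
    community_temps_c = c(20, 35)
  )
  p <- paper_like_taxa()
  counts <- gen_community_counts(p, cfg)
  div <- diversity_table(counts)
  by_temp <- div |>
    dplyr::group_by(temp_c) |>
    dplyr::summarise(
      richness = mean(richness),
      evenness = mean(pielou_j, na.rm = TRUE)
    )
  expect_lt(by_temp$richness[2], by_temp$richness[1])
  expect_lt(by_temp$evenness[2], by_temp$evenness[1])
})

test_that("noiseless end-to-end fitting recovers the true thermal traits", {
  cfg <- sim_config(
    seed = 8, n_taxa = 5, noise_sd_od = 0, n_tech_reps = 1
  )
  p <- gen_taxon_params(cfg)
  plate <- blank_correct(gen_growth_plate(p, cfg))
  rates <- growth_rate_table(plate, n_starts = 15, seed = 1)
  traits <- fit_tpc_table(
    rates[!is.na(rates$mean_r_per_h), ], n_starts = 150, seed = 2
  )
  traits <- traits[match(p$taxon_id, traits$taxon), ]
  expect_true(all(abs(traits$ea_ev - p$ea_ev) / p$ea_ev < 0.01))
  expect_true(all(abs(traits$eh_ev - p$eh_ev) / p$eh_ev < 0.01))
  expect_true(all(abs(traits$th_k - p$th_k) / p$th_k < 0.01))
  expect_true(all(abs(traits$topt_c - p$topt_c) < 0.35))
})

test_that("invalid configurations are rejected up front", {
  expect_error(sim_config(n_taxa = 0), "n_taxa")
  expect_error(sim_config(noise_sd_od = -1), "noise_sd_od")
  expect_error(sim_config(selection_exponent = -0.1), "selection_exponent")
  expect_error(sim_config(N0 = 2, K = 1), "K > N0")
  expect_error(sim_config(topt_range_c = c(30, 20)), "ranges")
})
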