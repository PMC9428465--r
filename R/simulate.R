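#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults mirror the
#' study design the package targets: 8 taxa assayed at 9 temperatures
#' (0-50 C) in 6 technical replicates, and 20 replicate communities
#' assembled at each of 6 temperatures (10-35 C).
#'
#' @param n_taxa Number of taxa in the pool.
#' @param assay_temps_c Growth-assay temperatures (Celsius).
#' @param community_temps_c Community-incubation temperatures (Celsius).
#' @param n_tech_reps Technical replicates per taxon x assay temperature.
#' @param n_community_reps Replicate communities per temperature.
#' @param noise_sd_od SD of additive Gaussian OD noise (OD600 units),
#'   truncated so OD stays non-negative.
#' @param selection_exponent Strength of fitness-weighted selection; 0
#'   means neutral (uniform) assembly.
#' @param total_colonies Colonies counted per replicate community.
#' @param seed Integer seed; fixes all generator output.
#' @param K,N0 Logistic carrying capacity and inoculum (OD600) for
#'   simulated wells.
#' @param baseline_od Medium baseline OD added to every well (blanks read
#'   this baseline plus noise).
#' @param topt_range_c Range the implied thermal optima are drawn to span.
#' @param ea_range_ev Range the activation energies are drawn from.
#' @param tref_c Reference temperature for `ln r(Tc)` (Celsius).
#' @param time_step_h Plate-reader read interval (hours).
#' @param max_hours Cap on the simulated incubation length (hours); each
#'   well is read until its noiseless curve reaches 99% of `K`, at least
#'   24 h and at most this cap.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_taxa = 8,
                       assay_temps_c = c(0, 15, 20, 25, 30, 35, 40, 45, 50),
                       community_temps_c = c(10, 15, 20, 25, 30, 35),
                       n_tech_reps = 6,
                       n_community_reps = 20,
                       noise_sd_od = 0.005,
                       selection_exponent = 3,
                       total_colonies = 100,
                       seed = 1,
                       K = 1.0,
                       N0 = 0.01,
                       baseline_od = 0.05,
                       topt_range_c = c(18.7, 35.3),
                       ea_range_ev = c(0.23, 1.06),
                       tref_c = 18,
                       time_step_h = 2,
                       max_hours = 168) {
  cfg <- list(
    n_taxa = n_taxa, assay_temps_c = assay_temps_c,
    community_temps_c = community_temps_c, n_tech_reps = n_tech_reps,
    n_community_reps = n_community_reps, noise_sd_od = noise_sd_od,
    selection_exponent = selection_exponent,
    total_colonies = total_colonies, seed = seed,
    K = K, N0 = N0, baseline_od = baseline_od,
    topt_range_c = topt_range_c, ea_range_ev = ea_range_ev,
    tref_c = tref_c, time_step_h = time_step_h, max_hours = max_hours
  )
  counts <- c(
    "n_taxa", "n_tech_reps", "n_community_reps", "total_colonies"
  )
  for (nm in counts) {
    if (cfg[[nm]] < 1) stop_input("%s must be >= 1", nm)
  }
  if (noise_sd_od < 0) stop_input("noise_sd_od must be >= 0")
  if (selection_exponent < 0) stop_input("selection_exponent must be >= 0")
  if (K <= 0 || N0 <= 0 || N0 >= K) stop_input("need K > N0 > 0")
  if (diff(topt_range_c) < 0 || diff(ea_range_ev) <= 0) {
    stop_input("trait ranges must be non-empty")
  }
  structure(cfg, class = "sim_config")
}

#' Draw ground-truth thermal-trait parameter sets
#'
#' Draws `n_taxa` Sharpe-Schoolfield parameter sets whose implied thermal
#' optima span `topt_range_c` and whose activation energies span
#' `ea_range_ev` (defaults cover the observed ranges 18.7-35.3 C and
#' 0.23-1.06 eV). Both traits are drawn by stratified uniform sampling -
#' one value per equal-width stratum, uniform within it, with the pairing
#' between the two traits randomised - so the marginals stay uniform while
#' every draw genuinely covers the range, as the assembled isolate pool
#' does. `Eh` is drawn as a multiple of `Ea` in (2, 6), guaranteeing
#' `Eh > Ea`, and `Th` is solved from the closed-form optimum so that each
#' taxon attains its drawn `Topt` exactly.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `taxon_id`, `ea_ev`, `eh_ev`, `th_k`,
#'   `ln_r_tc`, `tc_k`, `topt_c`.
#' @export
gen_taxon_params <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_taxa
  k <- BOLTZMANN_EV_K
  stratified_unif <- function(n, lo, hi) {
    w <- (hi - lo) / n
    lo + (seq_len(n) - 1 + runif(n)) * w
  }
  with_seed(derive_seed(config$seed, "simulate"), {
    ea <- sample(stratified_unif(
      n, config$ea_range_ev[1], config$ea_range_ev[2]
    ))
    eh <- ea * runif(n, 2, 6)
    topt_k <- stratified_unif(
      n, config$topt_range_c[1], config$topt_range_c[2]
    ) + C_TO_K
    ## invert Topt = Eh Th / (Eh + k Th ln(Eh/Ea - 1)) for Th
    ln_term <- log(eh / ea - 1)
    th_k <- topt_k * eh / (eh - k * topt_k * ln_term)
    ## modest baseline-fitness spread (0.3-1.0 1/h at the reference
    ## temperature): community structure is then shaped by thermal
    ## selection rather than by temperature-independent rate differences
    ln_r_tc <- runif(n, log(0.3), log(1))
    tibble::tibble(
      taxon_id = sprintf("taxon_%02d", seq_len(n)),
      ea_ev = ea, eh_ev = eh, th_k = th_k, ln_r_tc = ln_r_tc,
      tc_k = config$tref_c + C_TO_K,
      topt_c = compute_topt(ea, eh, th_k) - C_TO_K
    )
  })
}

#' True growth rate of a simulated taxon
#'
#' Forward evaluation of the Sharpe-Schoolfield model for ground-truth
#' parameter sets; strictly positive for all physical temperatures.
#'
#' @param params One or more rows of [gen_taxon_params()] output (columns
#'   `ea_ev`, `eh_ev`, `th_k`, `ln_r_tc`, `tc_k`).
#' @param temp_c Temperature(s), Celsius.
#' @return Growth rate(s), 1/h. If `params` has one row the result is
#'   vectorised over `temp_c`; otherwise `temp_c` must be scalar or match
#'   the row count.
#' @export
true_growth_rate <- function(params, temp_c) {
  exp(ss_ln_rate(
    temp_c, params$ea_ev, params$eh_ev, params$th_k, params$ln_r_tc,
    tc_k = params$tc_k
  ))
}

#' Simulate a growth plate
#'
#' Generates logistic OD600 trajectories for each taxon x assay temperature
#' x technical replicate, with the growth rate set by [true_growth_rate()],
#' carrying capacity and inoculum from the config, a medium baseline added
#' to every well, and additive Gaussian noise truncated at zero. Four blank
#' wells per temperature read the baseline plus noise on the same schedule.
#' Each temperature's series runs until the slowest taxon's noiseless curve
#' reaches 99% of `K` (within `max_hours`), emulating incubation to
#' carrying capacity.
#'
#' @param params Output of [gen_taxon_params()].
#' @param config A [sim_config()].
#' @return A tibble with columns `taxon`, `temp_c`, `replicate`, `time_h`,
#'   `od600`, `is_blank` (blanks carry `taxon = "blank"`).
#' @export
gen_growth_plate <- function(params, config) {
  stopifnot(inherits(config, "sim_config"), nrow(params) >= 1)
  n_blanks <- 4L
  with_seed(derive_seed(config$seed, "growth"), {
    out <- purrr::map(config$assay_temps_c, function(tc) {
      rates <- true_growth_rate(params, tc)
      ## hours for the slowest grower to reach 99% K: logistic inversion
      A <- (config$K - config$N0) / config$N0
      t99 <- (log(A) + log(99)) / pmax(rates, 1e-9)
      t_end <- min(max(24, max(pmin(t99, config$max_hours))),
        config$max_hours)
      t_end <- ceiling(t_end / config$time_step_h) * config$time_step_h
      times <- seq(0, t_end, by = config$time_step_h)
      wells <- tidyr::expand_grid(
        taxon = params$taxon_id,
        replicate = seq_len(config$n_tech_reps)
      )
      samp <- purrr::pmap(wells, function(taxon, replicate) {
        r <- rates[match(taxon, params$taxon_id)]
        mu <- config$baseline_od +
          logistic_od(times, r, config$K, config$N0)
        tibble::tibble(
          taxon = taxon, temp_c = tc, replicate = replicate,
          time_h = times,
          od600 = pmax(mu + rnorm(length(times), 0, config$noise_sd_od), 0),
          is_blank = FALSE
        )
      })
      blanks <- purrr::map(seq_len(n_blanks), function(b) {
        tibble::tibble(
          taxon = "blank", temp_c = tc, replicate = b, time_h = times,
          od600 = pmax(
            config$baseline_od +
              rnorm(length(times), 0, config$noise_sd_od),
            0
          ),
          is_blank = TRUE
        )
      })
      dplyr::bind_rows(c(samp, blanks))
    })
    dplyr::bind_rows(out)
  })
}

#' Simulate colony counts under thermal selection
#'
#' At each community temperature the expected taxon proportions are
#' proportional to `max(r_i(T), eps)^selection_exponent`, the
#' fitness-power model of temperature-driven selection: exponent 0 gives
#' neutral (uniform) assembly, larger exponents concentrate the community
#' on the fastest growers. Counts are drawn multinomially with
#' `total_colonies` per replicate. `eps = 1e-6` floors non-positive rates;
#' if every taxon's rate is non-positive at some temperature the weights
#' fall back to uniform with a warning.
#'
#' @inheritParams gen_growth_plate
#' @return A tibble with columns `temp_c`, `replicate`, `taxon`, `count`.
#' @export
gen_community_counts <- function(params, config) {
  stopifnot(inherits(config, "sim_config"))
  eps <- 1e-6
  with_seed(derive_seed(config$seed, "community"), {
    out <- purrr::map(config$community_temps_c, function(tc) {
      rates <- true_growth_rate(params, tc)
      if (all(rates <= 0)) {
        warning(sprintf(
          "all taxa have non-positive rates at %g C; using uniform weights",
          tc
        ), call. = FALSE)
        w <- rep(1, nrow(params))
      } else {
        w <- pmax(rates, eps)^config$selection_exponent
      }
      p <- w / sum(w)
      counts <- rmultinom(config$n_community_reps, config$total_colonies, p)
      tidyr::expand_grid(
        replicate = seq_len(config$n_community_reps),
        taxon = params$taxon_id
      ) |>
        dplyr::mutate(
          temp_c = tc,
          count = as.vector(counts[
            cbind(match(.data$taxon, params$taxon_id), .data$replicate)
          ])
        ) |>
        dplyr::select("temp_c", "replicate", "taxon", "count")
    })
    dplyr::bind_rows(out)
  })
}

#' Expected taxon proportions under the selection model
#'
#' The noiseless proportions [gen_community_counts()] samples from, exposed
#' for testing and diagnostics.
#'
#' @inheritParams gen_growth_plate
#' @param temp_c Single community temperature (Celsius).
#' @return Named numeric vector of proportions summing to 1.
#' @export
expected_proportions <- function(params, config, temp_c) {
  rates <- true_growth_rate(params, temp_c)
  w <- pmax(rates, 1e-6)^config$selection_exponent
  setNames(w / sum(w), params$taxon_id)
}
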