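#' Fit a Sharpe-Schoolfield thermal performance curve
#'
#' Fits the Sharpe-Schoolfield model ([ss_ln_rate()]) to log growth rate as
#' a function of assay temperature by nonlinear least squares, restarting
#' from `n_starts` random initial parameter sets drawn from uniform
#' distributions and retaining the converged fit with the lowest AIC. Pairs
#' with non-positive rates are excluded before fitting (the response is a
#' logarithm); their temperatures are reported in the result.
#'
#' Restart sampling bounds: `Ea` in (0.05, 2) eV, `Eh` in (0.2, 10) eV,
#' `Th` in (min assay T, max assay T + 20) K, `ln r(Tc)` in
#' (log(min rate) - 2, log(max rate) + 2). Starts violating `Eh > Ea` are
#' projected to `Eh = 1.05 Ea`; fitted parameter sets violating it are
#' flagged invalid and not retained while any valid fit exists.
#'
#' @param temp_c Assay temperatures (Celsius); distinct values.
#' @param rate_per_h Growth rates (1/h), same length.
#' @param n_starts Number of random restarts (default 1000).
#' @param seed Integer seed making the restarts reproducible.
#' @param tref_c Reference temperature (Celsius) for `r(Tc)`; default 18.
#' @return An object of class `"tpc_fit"`: a list with elements `ea_ev`,
#'   `eh_ev`, `th_k`, `ln_r_tc`, `tc_k`, `topt_c`, `aic`, `quasi_r2`,
#'   `n_temps_used`, `rss`, `k_ev_per_k`, `n_converged`,
#'   `converged_aics` (AIC of every converged restart), and
#'   `excluded_temp_c`.
#' @examples
#' temps <- c(0, 15, 20, 25, 30, 35, 40, 45, 50)
#' rates <- exp(ss_ln_rate(temps, 0.58, 2.5, 308, -1.2))
#' fit <- fit_tpc(temps, rates, n_starts = 50, seed = 1)
#' fit$topt_c
#' @export
fit_tpc <- function(temp_c, rate_per_h, n_starts = 1000, seed = NULL,
                    tref_c = 18) {
  if (length(temp_c) != length(rate_per_h)) {
    stop_input("temp_c and rate_per_h must have equal length")
  }
  keep <- is.finite(rate_per_h) & rate_per_h > 0 & is.finite(temp_c)
  excluded <- unique(temp_c[!keep])
  temp_c <- temp_c[keep]
  rate <- rate_per_h[keep]
  if (anyDuplicated(temp_c)) {
    stop_input("temperatures must be distinct (average replicate rates first)")
  }
  if (length(temp_c) < 5) {
    stop_input(
      "fit_tpc needs >= 5 usable (temperature, rate > 0) pairs; got %d",
      length(temp_c)
    )
  }
  tc_k <- tref_c + C_TO_K
  ln_rate <- log(rate)
  dat <- data.frame(temp_c = temp_c, ln_rate = ln_rate)

  t_k <- temp_c + C_TO_K
  lower <- c(ea_ev = 1e-3, eh_ev = 2e-3, th_k = 250, ln_r_tc = min(ln_rate) - 10)
  upper <- c(ea_ev = 10, eh_ev = 40, th_k = 420, ln_r_tc = max(ln_rate) + 10)

  starts <- with_seed(seed, {
    data.frame(
      ea_ev = runif(n_starts, 0.05, 2),
      eh_ev = runif(n_starts, 0.2, 10),
      th_k = runif(n_starts, min(t_k), max(t_k) + 20),
      ln_r_tc = runif(n_starts, min(ln_rate) - 2, max(ln_rate) + 2)
    )
  })
  bad <- starts$eh_ev <= starts$ea_ev
  starts$eh_ev[bad] <- starts$ea_ev[bad] * 1.05

  best <- NULL
  best_aic <- Inf
  converged_aics <- numeric(0)
  n_par <- 4L
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        ln_rate ~ ss_ln_rate(temp_c, ea_ev, eh_ev, th_k, ln_r_tc,
          tc_k = tc_k
        ),
        data = dat,
        start = as.list(starts[i, ]),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-10, ptol = 1e-10
        )
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    cf <- coef(fit)
    if (cf[["eh_ev"]] <= cf[["ea_ev"]]) next
    rss <- sum(stats::resid(fit)^2)
    aic <- aic_from_rss(max(rss, .Machine$double.xmin), length(ln_rate), n_par)
    converged_aics <- c(converged_aics, aic)
    if (aic < best_aic) {
      best_aic <- aic
      best <- list(cf = cf, rss = rss)
    }
  }

  if (is.null(best)) {
    stop_input(
      "no Sharpe-Schoolfield restart converged with Eh > Ea (%d starts)",
      n_starts
    )
  }

  cf <- best$cf
  fitted_ln <- ss_ln_rate(temp_c, cf[["ea_ev"]], cf[["eh_ev"]],
    cf[["th_k"]], cf[["ln_r_tc"]],
    tc_k = tc_k
  )
  structure(
    list(
      ea_ev = unname(cf[["ea_ev"]]),
      eh_ev = unname(cf[["eh_ev"]]),
      th_k = unname(cf[["th_k"]]),
      ln_r_tc = unname(cf[["ln_r_tc"]]),
      tc_k = tc_k,
      topt_c = compute_topt(cf[["ea_ev"]], cf[["eh_ev"]], cf[["th_k"]]) -
        C_TO_K,
      aic = best_aic,
      quasi_r2 = quasi_r2(ln_rate, fitted_ln),
      n_temps_used = length(temp_c),
      rss = best$rss,
      k_ev_per_k = BOLTZMANN_EV_K,
      n_converged = length(converged_aics),
      converged_aics = converged_aics,
      excluded_temp_c = excluded
    ),
    class = "tpc_fit"
  )
}

#' @export
print.tpc_fit <- function(x, ...) {
  cat("Sharpe-Schoolfield fit (", x$n_temps_used, " temperatures)\n",
    sep = ""
  )
  cat(sprintf(
    "  Ea = %.3f eV, Eh = %.3f eV, Th = %.2f K, ln r(Tc) = %.3f\n",
    x$ea_ev, x$eh_ev, x$th_k, x$ln_r_tc
  ))
  cat(sprintf(
    "  Topt = %.2f C, AIC = %.2f, quasi-R2 = %.3f\n",
    x$topt_c, x$aic, x$quasi_r2
  ))
  invisible(x)
}

#' Fit thermal performance curves for every taxon in a rate table
#'
#' Applies [fit_tpc()] to each taxon of a growth-rate table (as produced by
#' [growth_rate_table()]) and assembles the fitted thermal traits into a
#' tidy table. Taxa with too few usable rates are skipped with a warning
#' naming them; an error is raised only if no taxon can be fitted.
#'
#' @param rates Data frame with columns `taxon`, `temp_c`, `mean_r_per_h`.
#' @inheritParams fit_tpc
#' @return A tibble with one row per taxon and columns `taxon`, `ea_ev`,
#'   `eh_ev`, `th_k`, `ln_r_tc`, `topt_c`, `aic`, `quasi_r2`,
#'   `n_temps_used`.
#' @export
fit_tpc_table <- function(rates, n_starts = 1000, seed = NULL, tref_c = 18) {
  assert_columns(rates, c("taxon", "temp_c", "mean_r_per_h"), "rate table")
  taxa <- unique(rates$taxon)
  rows <- purrr::imap(
    setNames(taxa, taxa),
    function(tx, i) {
      sub <- rates[rates$taxon == tx, ]
      sub_seed <- if (is.null(seed)) NULL else seed + match(tx, taxa)
      fit <- tryCatch(
        fit_tpc(sub$temp_c, sub$mean_r_per_h,
          n_starts = n_starts, seed = sub_seed, tref_c = tref_c
        ),
        error = function(e) {
          warning(sprintf(
            "skipping taxon %s: %s", tx, conditionMessage(e)
          ), call. = FALSE)
          NULL
        }
      )
      if (is.null(fit)) {
        return(NULL)
      }
      tibble::tibble(
        taxon = tx,
        ea_ev = fit$ea_ev, eh_ev = fit$eh_ev, th_k = fit$th_k,
        ln_r_tc = fit$ln_r_tc, topt_c = fit$topt_c,
        aic = fit$aic, quasi_r2 = fit$quasi_r2,
        n_temps_used = fit$n_temps_used
      )
    }
  )
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    stop_input("no taxon had enough usable rates for a thermal-curve fit")
  }
  out
}
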