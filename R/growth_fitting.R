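#' Logistic growth curve
#'
#' Biomass under logistic growth,
#' `N(t) = K / (1 + A exp(-r t))` with `A = (K - N0) / N0`, so that
#' `N(0) = N0` and `N(t) -> K`.
#'
#' @param time_h Time (hours).
#' @param r Exponential growth rate (1/h).
#' @param K Carrying capacity (OD600).
#' @param N0 Initial biomass (OD600).
#' @return Predicted OD600, vectorised over `time_h`.
#' @export
logistic_od <- function(time_h, r, K, N0) {
  A <- (K - N0) / N0
  K / (1 + A * exp(-r * time_h))
}

#' Blank-correct a plate series
#'
#' Subtracts the mean blank OD at the matching temperature and nearest time
#' point from every sample well, floors the result at zero, and drops the
#' blank records. Nearest-time matching tolerates ragged read schedules.
#'
#' @param plate Data frame with columns `taxon`, `temp_c`, `replicate`,
#'   `time_h`, `od600`, `is_blank`.
#' @return The corrected plate series (blanks removed), same columns.
#' @export
blank_correct <- function(plate) {
  assert_columns(
    plate, c("taxon", "temp_c", "replicate", "time_h", "od600", "is_blank"),
    "plate series"
  )
  blanks <- plate[plate$is_blank, ]
  samples <- plate[!plate$is_blank, ]
  temps <- unique(samples$temp_c)
  missing <- setdiff(temps, unique(blanks$temp_c))
  if (length(missing) > 0) {
    stop_input(
      "no blank wells at temperature(s): %s",
      paste(missing, collapse = ", ")
    )
  }
  blank_means <- blanks |>
    dplyr::group_by(.data$temp_c, .data$time_h) |>
    dplyr::summarise(blank_od = mean(.data$od600), .groups = "drop")

  corrected <- samples |>
    dplyr::group_by(.data$temp_c) |>
    dplyr::group_modify(function(df, key) {
      bm <- blank_means[blank_means$temp_c == key$temp_c, ]
      idx <- vapply(
        df$time_h,
        function(t) which.min(abs(bm$time_h - t)),
        integer(1)
      )
      df$od600 <- pmax(df$od600 - bm$blank_od[idx], 0)
      df
    }) |>
    dplyr::ungroup()
  corrected[names(samples)]
}

## Heuristic single start from the data: r from the steepest log-slope,
## K from the max OD, N0 from the first positive OD.
logistic_start_heuristic <- function(time_h, od) {
  pos <- od > 0
  max_od <- max(od)
  n0 <- if (any(pos)) min(od[pos]) else max_od / 100
  r0 <- 0.2
  if (sum(pos) >= 3) {
    lt <- time_h[pos]
    ly <- log(od[pos])
    sl <- diff(ly) / diff(lt)
    sl <- sl[is.finite(sl) & sl > 0]
    if (length(sl) > 0) r0 <- max(min(stats::quantile(sl, 0.9), 3), 0.01)
  }
  c(r = unname(r0), K = max_od, N0 = n0)
}

#' Fit the logistic growth model to one OD600 time series
#'
#' Nonlinear least squares fit of [logistic_od()] to a single well's
#' blank-corrected OD600 trajectory, minimising squared OD residuals.
#' Besides a data-driven start, `n_starts` random starts are drawn
#' (uniformly: `r` in (0.01, 3) 1/h, `K` in (0.5, 2) x max OD, `N0` in
#' (1e-4, 2 x min positive OD)) and the lowest-RSS converged fit is kept.
#' Bounds enforce `r > 0` and `K > N0 > 0`.
#'
#' A fit is flagged unconverged when the well shows no usable growth
#' signal: no start converges, the observed OD range is below the
#' detection threshold `min_rise_od` (a non-growing well), or the fitted
#' total rise `K - N0` is below five times the residual standard
#' deviation (signal indistinguishable from noise). Rates below about
#' 0.01/h produce rises under typical detection thresholds within any
#' realistic incubation and are therefore reported as non-growth rather
#' than as unreliable tiny rates.
#'
#' @param time_h Time points (hours), `>= 4`.
#' @param od OD600 values, same length.
#' @param n_starts Number of random restarts (default 50).
#' @param seed Optional integer seed for the restarts.
#' @param min_rise_od Minimum observed OD range for a well to count as
#'   growing (OD600 units, default 0.05).
#' @return An object of class `"logistic_fit"`: list with `r_per_h`, `K`,
#'   `N0`, `A`, `rss`, `n_points`, `converged`.
#' @examples
#' t <- seq(0, 24, 2)
#' fit <- fit_logistic(t, logistic_od(t, r = 0.5, K = 1, N0 = 0.01))
#' fit$r_per_h
#' @export
fit_logistic <- function(time_h, od, n_starts = 50, seed = NULL,
                         min_rise_od = 0.05) {
  if (length(time_h) != length(od)) {
    stop_input("time_h and od must have equal length")
  }
  if (any(time_h < 0)) {
    stop_input("negative time values are not allowed")
  }
  if (length(time_h) < 4) {
    stop_input("fit_logistic needs >= 4 time points; got %d", length(time_h))
  }
  if (length(unique(od)) < 2) {
    stop_input("constant OD series: logistic parameters are unidentifiable")
  }
  if (length(unique(time_h)) < 3) {
    stop_input("need >= 3 distinct time points")
  }
  dat <- data.frame(time_h = time_h, od = od)
  max_od <- max(od)
  min_pos <- if (any(od > 0)) min(od[od > 0]) else max_od / 100

  ## K may exceed max(od) substantially when the well never saturates;
  ## a generous upper bound keeps r unbiased for near-exponential data
  lower <- c(r = 1e-4, K = 1e-6, N0 = 1e-8)
  upper <- c(r = 10, K = max_od * 50, N0 = max_od * 5)

  ## second heuristic start for unsaturated wells: r from a log-linear
  ## regression of the positive ODs, K well above the observed maximum
  exp_start <- {
    pos <- od > 0
    r_exp <- if (sum(pos) >= 3) {
      max(min(unname(coef(lm(log(od[pos]) ~ time_h[pos]))[2]), 5), 1e-4)
    } else {
      0.1
    }
    c(r = r_exp, K = max_od * 10, N0 = min_pos)
  }

  starts <- with_seed(seed, {
    rand <- data.frame(
      r = runif(n_starts, 0.01, 3),
      K = runif(n_starts, max_od * 0.5, max_od * 2),
      N0 = runif(n_starts, min(1e-4, min_pos / 2), max(min_pos * 2, 2e-4))
    )
    rbind(
      as.data.frame(as.list(logistic_start_heuristic(time_h, od))),
      as.data.frame(as.list(exp_start)),
      rand
    )
  })

  best <- NULL
  best_rss <- Inf
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        od ~ logistic_od(time_h, r, K, N0),
        data = dat,
        start = as.list(starts[i, ]),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(
          maxiter = 200, ftol = 1e-10, ptol = 1e-10
        )
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (rss < best_rss) {
      best_rss <- rss
      best <- coef(fit)
    }
  }

  if (is.null(best)) {
    return(structure(
      list(
        r_per_h = NA_real_, K = NA_real_, N0 = NA_real_, A = NA_real_,
        rss = NA_real_, n_points = length(time_h), converged = FALSE
      ),
      class = "logistic_fit"
    ))
  }

  resid_sd <- sqrt(best_rss / max(length(od) - 3, 1))
  signal <- (max(od) - min(od)) >= min_rise_od &&
    (best[["K"]] - best[["N0"]]) >= 5 * resid_sd
  structure(
    list(
      r_per_h = unname(best[["r"]]),
      K = unname(best[["K"]]),
      N0 = unname(best[["N0"]]),
      A = unname((best[["K"]] - best[["N0"]]) / best[["N0"]]),
      rss = best_rss,
      n_points = length(time_h),
      converged = signal
    ),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "Logistic fit: r = %.4f /h, K = %.4f, N0 = %.5f (rss %.3g, %s)\n",
    x$r_per_h, x$K, x$N0, x$rss,
    if (isTRUE(x$converged)) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' Per-taxon, per-temperature mean growth rates from a plate series
#'
#' Fits [fit_logistic()] to every (taxon, temperature, replicate) series of
#' a blank-corrected plate and averages the fitted rate `r` across technical
#' replicates within each taxon x temperature group. Replicates whose fit
#' did not converge are excluded; a group where every replicate fails is
#' emitted with a missing rate and a warning.
#'
#' @param plate Blank-corrected plate series (no blank rows).
#' @inheritParams fit_logistic
#' @return A tibble with columns `taxon`, `temp_c`, `mean_r_per_h`,
#'   `n_reps_used`.
#' @export
growth_rate_table <- function(plate, n_starts = 50, seed = NULL,
                              min_rise_od = 0.05) {
  assert_columns(
    plate, c("taxon", "temp_c", "replicate", "time_h", "od600"),
    "plate series"
  )
  if ("is_blank" %in% names(plate) && any(plate$is_blank)) {
    stop_input("plate still contains blank wells; run blank_correct() first")
  }
  groups <- plate |>
    dplyr::distinct(.data$taxon, .data$temp_c, .data$replicate)
  fits <- purrr::pmap(groups, function(taxon, temp_c, replicate) {
    sub <- plate[
      plate$taxon == taxon & plate$temp_c == temp_c &
        plate$replicate == replicate,
    ]
    sub_seed <- if (is.null(seed)) NULL else seed + nrow(sub) + replicate
    fit <- tryCatch(
      fit_logistic(sub$time_h, sub$od600,
        n_starts = n_starts, seed = sub_seed, min_rise_od = min_rise_od
      ),
      error = function(e) NULL
    )
    tibble::tibble(
      taxon = taxon, temp_c = temp_c, replicate = replicate,
      r_per_h = if (is.null(fit)) NA_real_ else fit$r_per_h,
      converged = if (is.null(fit)) FALSE else fit$converged
    )
  })
  per_rep <- dplyr::bind_rows(fits)
  out <- per_rep |>
    dplyr::group_by(.data$taxon, .data$temp_c) |>
    dplyr::summarise(
      mean_r_per_h = if (any(.data$converged)) {
        mean(.data$r_per_h[.data$converged])
      } else {
        NA_real_
      },
      n_reps_used = sum(.data$converged),
      .groups = "drop"
    )
  failed <- out[out$n_reps_used == 0, ]
  if (nrow(failed) > 0) {
    warning(sprintf(
      "all replicate fits failed for %d group(s), e.g. %s at %g C",
      nrow(failed), failed$taxon[1], failed$temp_c[1]
    ), call. = FALSE)
  }
  out
}
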