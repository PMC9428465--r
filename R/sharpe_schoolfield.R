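#' Sharpe-Schoolfield log growth rate
#'
#' Evaluates the high-temperature-deactivation Sharpe-Schoolfield model on
#' the natural-log scale:
#'
#' \deqn{\ln r(T) = E_a\left(\frac{1}{k T_c} - \frac{1}{k T}\right) +
#'   \ln r(T_c) - \ln\left(1 + e^{E_h (1/(k T_h) - 1/(k T))}\right)}
#'
#' with temperatures in Kelvin internally and the Boltzmann constant
#' \eqn{k = 8.62 \times 10^{-5}} eV/K. The deactivation term is evaluated in
#' log-sum-exp form, so large exponents do not overflow.
#'
#' @param temp_c Assay temperature(s), degrees Celsius.
#' @param ea_ev Activation energy (eV); steepness of the rising limb.
#' @param eh_ev Deactivation energy (eV); steepness of the falling limb.
#' @param th_k Half-inactivation temperature (K).
#' @param ln_r_tc Natural log of the growth rate at the reference
#'   temperature (rate in 1/h).
#' @param tc_k Reference temperature (K); default 291.15 K (18 C).
#' @return `ln r(T)` (log 1/h), vectorised over `temp_c`.
#' @examples
#' ss_ln_rate(20, ea_ev = 0.6, eh_ev = 3, th_k = 308, ln_r_tc = -1)
#' @export
ss_ln_rate <- function(temp_c, ea_ev, eh_ev, th_k, ln_r_tc,
                       tc_k = 291.15) {
  if (any(temp_c <= -C_TO_K)) {
    stop_input("temperature below absolute zero")
  }
  t_k <- temp_c + C_TO_K
  k <- BOLTZMANN_EV_K
  boltz <- ea_ev * (1 / (k * tc_k) - 1 / (k * t_k))
  x <- eh_ev * (1 / (k * th_k) - 1 / (k * t_k))
  ## log(1 + exp(x)) without overflow: for large x this is x + log1p(exp(-x))
  deact <- ifelse(x > 30, x + log1p(exp(-x)), log1p(exp(x)))
  boltz + ln_r_tc - deact
}

#' Closed-form thermal optimum of the Sharpe-Schoolfield curve
#'
#' \deqn{T_{opt} = \frac{E_h T_h}{E_h + k T_h \ln(E_h/E_a - 1)}}
#'
#' obtained by differentiating the log-rate curve and solving for its
#' maximum. Requires `eh_ev > ea_ev > 0` (otherwise the log argument is
#' non-positive and no interior optimum exists).
#'
#' @inheritParams ss_ln_rate
#' @return Optimum temperature in Kelvin (subtract 273.15 for Celsius).
#'   Vectorised.
#' @examples
#' compute_topt(0.6, 3.0, 310) - 273.15
#' compute_topt(0.5, 1.0, 305) # Eh = 2 Ea gives Topt = Th exactly
#' @export
compute_topt <- function(ea_ev, eh_ev, th_k) {
  if (any(ea_ev <= 0) || any(th_k <= 0)) {
    stop_input("compute_topt requires ea_ev > 0 and th_k > 0")
  }
  if (any(eh_ev <= ea_ev)) {
    stop_input("compute_topt requires eh_ev > ea_ev (no interior optimum)")
  }
  k <- BOLTZMANN_EV_K
  eh_ev * th_k / (eh_ev + k * th_k * log(eh_ev / ea_ev - 1))
}

#' AIC from a residual sum of squares
#'
#' Gaussian-likelihood AIC for a least-squares fit,
#' `n * log(rss / n) + 2 * (n_params + 1)`, counting the error variance as
#' an estimated parameter.
#'
#' @param rss Residual sum of squares (> 0).
#' @param n_points Number of observations.
#' @param n_params Number of fitted mean parameters.
#' @return AIC value; `-Inf` (with a warning) when `rss` is exactly zero.
#' @export
aic_from_rss <- function(rss, n_points, n_params) {
  if (n_points <= n_params) {
    stop_input("aic_from_rss requires n_points > n_params")
  }
  if (rss < 0) {
    stop_input("rss must be non-negative")
  }
  if (rss == 0) {
    warning("rss is exactly zero; AIC is -Inf", call. = FALSE)
    return(-Inf)
  }
  n_points * log(rss / n_points) + 2 * (n_params + 1)
}

#' Quasi r-squared of a nonlinear fit
#'
#' `1 - SS_res / SS_tot` computed on the scale of the fitted response
#' (here, log growth rate). Can be negative for fits worse than the mean.
#'
#' @param observed,fitted Equal-length numeric vectors, `n >= 2`.
#' @return Value in `(-Inf, 1]`; `NA` when the observed values have zero
#'   variance.
#' @export
quasi_r2 <- function(observed, fitted) {
  if (length(observed) != length(fitted)) {
    stop_input("observed and fitted must have equal length")
  }
  if (length(observed) < 2) {
    stop_input("quasi_r2 requires at least two points")
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    return(NA_real_)
  }
  1 - sum((observed - fitted)^2) / ss_tot
}
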