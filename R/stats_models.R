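#' Sequential likelihood-ratio polynomial model selection
#'
#' Fits the null (`y ~ 1`), linear (`y ~ x`), and quadratic
#' (`y ~ x + x^2`) models and selects among them by sequential
#' likelihood-ratio tests, starting from the most complex model and
#' dropping terms that fail significance at `alpha`: if the quadratic term
#' is significant the quadratic model is chosen; otherwise, if the linear
#' term is significant, the linear model; otherwise the null. The LRT
#' statistic is `n * log(RSS_reduced / RSS_full)`, referred to a chi-square
#' with df equal to the number of dropped terms. Raw (non-orthogonal)
#' polynomial terms are used, so coefficients are directly interpretable.
#'
#' @param x Predictor (needs >= 3 distinct values for the quadratic).
#' @param y Response, same length; incomplete pairs are dropped.
#' @param alpha Significance level for each sequential test; default 0.05.
#' @return An object of class `"model_choice"`: list with `chosen` (one of
#'   `"null"`, `"linear"`, `"quadratic"`), `coefficients`, `lrt` (a tibble
#'   of per-step statistic/df/p), `r2`, `f_stat` (F, df1, df2, p of the
#'   chosen model against the null), `n`, and `model` (the fitted `lm`).
#' @examples
#' x <- rep(seq(10, 35, 5), each = 5)
#' y <- -(x - 22)^2 / 40 + rnorm(length(x), 0, 0.5)
#' polynomial_lrt(x, y)$chosen
#' @export
polynomial_lrt <- function(x, y, alpha = 0.05) {
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 4) stop_input("polynomial_lrt needs >= 4 complete observations")
  if (length(unique(x)) < 2) {
    stop_input("all x values are equal: design is collinear")
  }
  quad_ok <- length(unique(x)) >= 3
  dat <- data.frame(x = x, y = y)
  m0 <- lm(y ~ 1, data = dat)
  m1 <- lm(y ~ x, data = dat)
  m2 <- if (quad_ok) lm(y ~ x + I(x^2), data = dat) else NULL

  tss <- sum((y - mean(y))^2)
  ## residual sums of squares at numerical-noise level count as exact fits
  rss_floor <- 1e-10 * max(tss, .Machine$double.eps)
  lrt_step <- function(reduced, full, label) {
    rss_r <- sum(stats::resid(reduced)^2)
    rss_f <- sum(stats::resid(full)^2)
    stat <- if (rss_r <= rss_floor) {
      0 # the reduced model already fits exactly; nothing left to explain
    } else if (rss_f <= rss_floor) {
      Inf
    } else {
      max(n * log(rss_r / rss_f), 0)
    }
    df <- length(coef(full)) - length(coef(reduced))
    tibble::tibble(
      comparison = label, statistic = stat, df = df,
      p = pchisq(stat, df, lower.tail = FALSE)
    )
  }

  steps <- list()
  chosen <- NULL
  if (quad_ok) {
    s21 <- lrt_step(m1, m2, "quadratic vs linear")
    steps <- c(steps, list(s21))
    if (s21$p < alpha) chosen <- list(name = "quadratic", model = m2)
  }
  if (is.null(chosen)) {
    s10 <- lrt_step(m0, m1, "linear vs null")
    steps <- c(steps, list(s10))
    chosen <- if (s10$p < alpha) {
      list(name = "linear", model = m1)
    } else {
      list(name = "null", model = m0)
    }
  }

  fit <- chosen$model
  rss <- sum(stats::resid(fit)^2)
  p_terms <- length(coef(fit)) - 1
  f_stat <- if (p_terms > 0 && rss > 0) {
    fval <- ((tss - rss) / p_terms) / (rss / (n - p_terms - 1))
    c(
      F = fval, df1 = p_terms, df2 = n - p_terms - 1,
      p = pf(fval, p_terms, n - p_terms - 1, lower.tail = FALSE)
    )
  } else {
    c(F = NA_real_, df1 = p_terms, df2 = n - p_terms - 1, p = NA_real_)
  }

  structure(
    list(
      chosen = chosen$name,
      coefficients = coef(fit),
      lrt = dplyr::bind_rows(steps),
      r2 = if (tss > 0) 1 - rss / tss else NA_real_,
      f_stat = f_stat,
      n = n,
      model = fit
    ),
    class = "model_choice"
  )
}

#' @export
print.model_choice <- function(x, ...) {
  cat(sprintf(
    "Model choice: %s (n = %d, r2 = %.3f)\n", x$chosen, x$n,
    ifelse(is.na(x$r2), NaN, x$r2)
  ))
  print(as.data.frame(x$lrt), row.names = FALSE)
  invisible(x)
}

#' ANCOVA of relative abundance on a thermal trait
#'
#' Fits the full-interaction linear model in which each temperature level
#' has its own intercept and its own slope of relative abundance on the
#' taxon-level trait (thermal optimum, or growth rate at the assay
#' temperature). Reports the overall F against the intercept-only null
#' (with 6 levels and n observations this is an F on (11, n - 12) df),
#' per-level slopes with standard errors, and all pairwise slope contrasts
#' as Wald tests with Holm adjustment.
#'
#' @param rel_abund Relative abundance per record (response).
#' @param trait Taxon-level trait value per record (continuous covariate).
#' @param temp_level Temperature treatment per record (coerced to factor).
#' @return An object of class `"ancova_result"`: list with `overall_f`
#'   (F, df1, df2, p), `r2`, `per_level_slopes` (tibble: level, slope, se;
#'   `NA` slope where a level has a single distinct trait value),
#'   `pairwise_contrasts` (tibble: pair, estimate, se, p_raw, p_adj), `n`,
#'   and `model`.
#' @export
ancova_trait_abundance <- function(rel_abund, trait, temp_level) {
  ok <- complete.cases(rel_abund, trait, temp_level)
  rel_abund <- rel_abund[ok]
  trait <- trait[ok]
  lev <- factor(temp_level[ok])
  n <- length(rel_abund)
  if (nlevels(lev) < 2) stop_input("need >= 2 temperature levels")

  ## cell-means coding: one intercept and one slope per level
  dat <- data.frame(y = rel_abund, trait = trait, lev = lev)
  fit <- lm(y ~ 0 + lev + lev:trait, data = dat)
  cf <- coef(fit)
  vc <- vcov(fit)

  estimable <- !is.na(cf)
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((rel_abund - mean(rel_abund))^2)
  df1 <- sum(estimable) - 1
  df2 <- n - sum(estimable)
  fval <- ((tss - rss) / df1) / (rss / df2)
  overall <- c(
    F = fval, df1 = df1, df2 = df2,
    p = pf(fval, df1, df2, lower.tail = FALSE)
  )

  slope_names <- paste0("lev", levels(lev), ":trait")
  slopes <- tibble::tibble(
    level = levels(lev),
    slope = unname(cf[slope_names]),
    se = vapply(slope_names, function(nm) {
      if (nm %in% rownames(vc) && !is.na(cf[nm])) {
        sqrt(vc[nm, nm])
      } else {
        NA_real_
      }
    }, numeric(1))
  )

  pairs <- combn(levels(lev), 2)
  contrasts <- purrr::map(seq_len(ncol(pairs)), function(j) {
    a <- paste0("lev", pairs[1, j], ":trait")
    b <- paste0("lev", pairs[2, j], ":trait")
    if (any(is.na(cf[c(a, b)]))) {
      return(tibble::tibble(
        pair = paste(pairs[1, j], pairs[2, j], sep = " - "),
        estimate = NA_real_, se = NA_real_, p_raw = NA_real_
      ))
    }
    est <- cf[a] - cf[b]
    se <- sqrt(vc[a, a] + vc[b, b] - 2 * vc[a, b])
    tval <- est / se
    tibble::tibble(
      pair = paste(pairs[1, j], pairs[2, j], sep = " - "),
      estimate = unname(est), se = se,
      p_raw = 2 * stats::pt(abs(tval), df2, lower.tail = FALSE)
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(p_adj = p.adjust(.data$p_raw, method = "holm"))

  structure(
    list(
      overall_f = overall,
      r2 = if (tss > 0) 1 - rss / tss else NA_real_,
      per_level_slopes = slopes,
      pairwise_contrasts = contrasts,
      n = n,
      model = fit
    ),
    class = "ancova_result"
  )
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf(
    "Trait-abundance ANCOVA: F(%d, %d) = %.3f, p = %.3g, r2 = %.3f\n",
    x$overall_f[["df1"]], x$overall_f[["df2"]], x$overall_f[["F"]],
    x$overall_f[["p"]], x$r2
  ))
  print(as.data.frame(x$per_level_slopes), row.names = FALSE)
  invisible(x)
}

#' Ecosystem-function regressions
#'
#' Applies the sequential-LRT polynomial ladder ([polynomial_lrt()]) to the
#' three relationships of interest: day-7 biomass (ecosystem function)
#' against temperature, evenness against temperature, and biomass against
#' evenness. Records with undefined evenness (monocultures) are excluded
#' from the evenness models; the number excluded is reported.
#'
#' @param temp_c Temperature per replicate community.
#' @param evenness Pielou J per replicate community (`NA` allowed).
#' @param biomass Day-7 OD600 per replicate community.
#' @param alpha Significance level passed to [polynomial_lrt()].
#' @return List with elements `biomass_vs_temp`, `evenness_vs_temp`,
#'   `biomass_vs_evenness` (each a `model_choice`) and
#'   `n_undefined_evenness`.
#' @export
function_regressions <- function(temp_c, evenness, biomass, alpha = 0.05) {
  if (length(temp_c) != length(evenness) ||
    length(temp_c) != length(biomass)) {
    stop_input("temp_c, evenness, biomass must have equal length")
  }
  n_undef <- sum(is.na(evenness) & !is.na(biomass))
  list(
    biomass_vs_temp = polynomial_lrt(temp_c, biomass, alpha),
    evenness_vs_temp = polynomial_lrt(temp_c, evenness, alpha),
    biomass_vs_evenness = polynomial_lrt(evenness, biomass, alpha),
    n_undefined_evenness = n_undef
  )
}
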