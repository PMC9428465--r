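## Shared fixtures built in code.

## Eight fixed ground-truth parameter sets spanning the observed trait
## ranges (thermal optima 18.7-35.3 C, activation energies 0.23-1.06 eV),
## used wherever a deterministic "paper-like" taxon pool is needed.
paper_like_taxa <- function() {
  k <- 8.62e-5
  ea <- seq(0.23, 1.06, length.out = 8)
  eh <- ea * seq(2.2, 4.5, length.out = 8)
  topt_k <- seq(18.7, 35.3, length.out = 8) + 273.15
  th_k <- topt_k * eh / (eh - k * topt_k * log(eh / ea - 1))
  tibble::tibble(
    taxon_id = sprintf("taxon_%02d", 1:8),
    ea_ev = ea, eh_ev = eh, th_k = th_k,
    ln_r_tc = seq(-1.5, -0.5, length.out = 8),
    tc_k = 291.15
  )
}

## Noiseless logistic trajectory plus optional Gaussian noise.
make_logistic_series <- function(r = 0.5, K = 1, N0 = 0.01,
                                 times = seq(0, 24, 2), sd = 0) {
  od <- thermotrait::logistic_od(times, r, K, N0)
  if (sd > 0) od <- od + rnorm(length(times), 0, sd)
  list(times = times, od = od)
}

## A small two-temperature community count table with controllable
## prevalence per taxon.
make_count_table <- function(n_reps = 20) {
  tidyr::expand_grid(
    temp_c = c(20, 35), replicate = seq_len(n_reps),
    taxon = c("A", "B", "C")
  ) |>
    dplyr::mutate(count = 5L)
}

## Independent within/among-group PERMANOVA pseudo-F, computed directly
## from sums of squared distances (the textbook two-group formula), used
## as an oracle for the trace-form implementation.
direct_pseudo_f <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- factor(groups)
  a <- nlevels(groups)
  ss_total <- sum(d[upper.tri(d)]^2) / n
  ss_within <- sum(vapply(levels(groups), function(g) {
    idx <- which(groups == g)
    dd <- d[idx, idx, drop = FALSE]
    sum(dd[upper.tri(dd)]^2) / length(idx)
  }, numeric(1)))
  ss_among <- ss_total - ss_within
  (ss_among / (a - 1)) / (ss_within / (n - a))
}
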