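# thermotrait

Thermal performance curves and trait-based microbial community assembly.

`thermotrait` is an R package for the analysis chain that links
population-level thermal traits of microbial isolates to the structure and
functioning of the communities they assemble along a temperature gradient:

1. **Growth-curve fitting** — blank-correct plate-reader OD600 time series
   and fit the logistic growth model
   *N(t) = K / (1 + A e^(−rt))*, *A = (K − N0)/N0*, by nonlinear least
   squares to obtain the exponential growth rate *r* (h⁻¹) per well, then
   average technical replicates per taxon × temperature.
2. **Thermal performance curves** — fit the Sharpe–Schoolfield model on the
   log scale,

   ln *r*(T) = *E*ₐ(1/kT_c − 1/kT) + ln *r*(T_c) − ln(1 + e^{E_h(1/kT_h − 1/kT)}),

   with Boltzmann's constant k = 8.62×10⁻⁵ eV K⁻¹ and reference
   temperature T_c = 18 °C, using many random starting-parameter sets and
   retaining the lowest-AIC fit. The optimum growth temperature follows in
   closed form: T_opt = E_h T_h / (E_h + k T_h ln(E_h/Eₐ − 1)).
3. **Community structure** — relative abundance, richness, Shannon
   diversity H′ = −Σ pᵢ ln pᵢ, Pielou evenness J = H′/ln R, rank-abundance
   curves, and a strict >25 % prevalence filter for rare taxa.
4. **Inference** — sequential likelihood-ratio selection among
   null/linear/quadratic models (richness, evenness and ecosystem function
   versus temperature; function versus evenness), ANCOVA of relative
   abundance on thermal traits with temperature as a factor, PCA of
   composition, and PERMANOVA on Bray–Curtis dissimilarities with
   Bonferroni-corrected pairwise tests.
5. **Synthetic data** — a generator that simulates logistic growth plates
   and fitness-weighted multinomial community assembly from known
   ("ground-truth") Sharpe–Schoolfield parameter sets, so every stage of
   the chain can be tested for parameter recovery.

It is aimed at microbial ecologists working with plate-reader growth
assays and colony-count community data.

## Worked example

Fit a thermal performance curve to growth rates measured at the nine assay
temperatures, with ~5 % multiplicative rate noise around a known curve:

```r
library(thermotrait)

temps <- c(0, 15, 20, 25, 30, 35, 40, 45, 50)
set.seed(1)
rates <- exp(ss_ln_rate(temps, ea_ev = 0.58, eh_ev = 2.5, th_k = 308,
  ln_r_tc = -1.2)) * exp(rnorm(9, 0, 0.05))

fit <- fit_tpc(temps, rates, n_starts = 1000, seed = 1)
fit
#> Sharpe-Schoolfield fit (9 temperatures)
#>   Ea = 0.597 eV, Eh = 2.468 eV, Th = 307.72 K, ln r(Tc) = -1.191
#>   Topt = 30.83 C, AIC = -51.61, quasi-R2 = 0.999
```

The fitted activation energy (0.597 eV, true 0.58), deactivation energy
(2.468 eV, true 2.5) and half-inactivation temperature (307.7 K, true 308)
recover the generating curve; the derived optimum of 30.83 °C is the
closed-form maximum of the fitted curve. A single well's growth curve fits
the same way:

```r
t <- seq(0, 24, 2)
od <- logistic_od(t, r = 0.62, K = 0.95, N0 = 0.01) + rnorm(13, 0, 0.005)
fit_logistic(t, pmax(od, 0), seed = 1)
#> Logistic fit: r = 0.6126 /h, K = 0.9542, N0 = 0.01030 (rss 0.000175, converged)
```

The whole chain — simulate a study (8 taxa × 9 assay temperatures × 6
replicates of growth curves; 6 community temperatures × 20 replicate
communities of colony counts under thermal selection), fit everything, and
run the statistics — is one call:

```r
res <- run_pipeline(run_config(seed = 1, simulate = list()), out_dir = "run1")
res$stats$evenness_model$chosen   # "quadratic": evenness peaks at mid temperatures
res$stats$permanova               # composition differs among temperatures
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/thermotrait.R`
(`Rscript thermotrait.R run --seed 1 --out run1`).

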