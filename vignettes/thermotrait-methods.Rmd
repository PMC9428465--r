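---
title: "Methods: thermal traits, community assembly, and the inference layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal traits, community assembly, and the inference layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermotrait)
```

`thermotrait` implements a trait-to-ecosystem analysis chain for microbial
thermal ecology: per-taxon growth rates from plate-reader time series,
thermal performance curves (TPCs) and derived thermal traits, community
diversity from colony counts along a temperature gradient, and the
statistical layer connecting traits, composition, and function. This
vignette explains the models, the tunable parameters and their defaults,
the numerical choices, and what the synthetic-data generator does and does
not emulate.

## Growth curves

Each well's blank-corrected OD600 trajectory is fitted with the logistic
model

$$N(t) = \frac{K}{1 + A e^{-rt}}, \qquad A = \frac{K - N_0}{N_0},$$

where $r$ (h$^{-1}$) is the exponential growth rate, $K$ the carrying
capacity and $N_0$ the inoculum (both OD600). Fitting minimises squared OD
residuals with Levenberg–Marquardt nonlinear least squares
(`minpack.lm::nlsLM`) under bounds $r > 0$, $K > N_0 > 0$. Because the
residual surface has local minima when curves are incomplete, each well is
fitted from a data-driven start (steepest log-slope for $r$, observed
maximum for $K$), a log-linear exponential-phase start, and 50 random
starts ($r \in (0.01, 3)$ h$^{-1}$, $K$ in (0.5, 2) × max OD, $N_0$ near
the smallest positive OD); the lowest-RSS converged fit is kept.

Two numerical choices matter for atypical wells:

* **Non-growing wells.** A well whose observed OD range is below
  `min_rise_od` (default 0.05 OD, a typical plate-reader detection scale)
  is flagged `converged = FALSE` and excluded from rate averaging. Rates
  below roughly 0.01 h$^{-1}$ cannot produce a detectable rise within a
  realistic incubation, and the logistic surface for near-flat data is a
  ridge on which any returned rate is unreliable. Declining wells are
  likewise reported unconverged rather than given negative rates. How
  such wells should enter a TPC fit is genuinely open; exclusion, rather
  than substituting zeros or pseudo-rates, keeps the log-scale TPC fit
  well defined and is logged per group.
* **Unsaturated wells.** When growth has not plateaued, $K$ is weakly
  identified and can exceed the observed maximum many-fold. The fitting
  bound allows $K$ up to 50 × max OD so that near-exponential data yield
  unbiased $r$; the random starts stay near the observed maximum because
  saturated wells are the common case.

Blank correction subtracts, per temperature, the mean blank OD at the
nearest-in-time blank read (tolerating ragged schedules), floors results
at zero, and drops the blanks. Technical-replicate rates are averaged per
taxon × temperature; groups where every replicate fails are emitted as
missing with a warning.

## Thermal performance curves

Mean rates across temperature are fitted on the natural-log scale with the
high-temperature-deactivation Sharpe–Schoolfield model

$$\ln r(T) = E_a\!\left(\frac{1}{kT_c} - \frac{1}{kT}\right) + \ln r(T_c)
  - \ln\!\left(1 + e^{E_h\left(\frac{1}{kT_h} - \frac{1}{kT}\right)}\right),$$

with $k = 8.62\times10^{-5}$ eV K$^{-1}$, reference temperature
$T_c = 18$ °C (overridable), activation energy $E_a$ (eV) governing the
rising limb, deactivation energy $E_h$ (eV) governing the collapse above
the half-inactivation temperature $T_h$ (K). The optimum is closed-form:

$$T_{opt} = \frac{E_h T_h}{E_h + k T_h \ln(E_h/E_a - 1)},$$

defined only for $E_h > E_a$. The deactivation term uses the log-sum-exp
identity $\ln(1+e^x) = x + \ln(1+e^{-x})$ for large $x$, so evaluation is
finite for arbitrarily steep curves.

Fitting runs `n_starts` (default 1000) random initial parameter sets from
uniform distributions — $E_a \in (0.05, 2)$ eV, $E_h \in (0.2, 10)$ eV,
$T_h \in$ (min assay T, max assay T + 20) K, $\ln r(T_c)$ within ±2 log
units of the observed rate range — and retains the converged fit with the
lowest AIC, computed from the residual sum of squares as
$n\ln(\mathrm{RSS}/n) + 2(p+1)$ (Gaussian likelihood, error variance
counted as a parameter; only AIC differences matter, and these equal the
full likelihood computation exactly). Starts violating $E_h > E_a$ are
projected onto $E_h = 1.05 E_a$, and fits violating it are discarded, so
the retained parameters always admit a finite $T_{opt}$. Temperatures with
non-positive rates are excluded before fitting (the response is a
logarithm) and reported; at least five usable temperatures are required
for the four-parameter model. Goodness of fit is summarised as a quasi-R²,
$1 - \mathrm{SS}_{res}/\mathrm{SS}_{tot}$ on the log-rate scale.
Convergence uses relative tolerances of $10^{-10}$ with up to 500
iterations per restart; restarts are seeded, so a fit is reproducible
bit-for-bit given its seed.

## Diversity

From colony counts per replicate community: relative abundances
$p_i = n_i/N$; richness $R$ (taxa with positive counts); Shannon
diversity $H' = -\sum p_i \ln p_i$ (nats, $0\ln 0 \equiv 0$); Pielou
evenness $J = H'/\ln R$. Natural logarithms are used in both $H'$ and $J$,
so a perfectly even community has $J = 1$ regardless of base bookkeeping.
$J$ is reported as undefined (`NA`) for monocultures — the denominator
$\ln 1$ vanishes, and substituting 0 or 1 would assert an evenness the
data cannot express. Downstream regressions drop undefined-evenness
records and report how many. Rank-abundance curves sort proportions
descending with ties broken by taxon label.

The rare-taxon rule keeps, within each temperature, taxa present in
strictly more than a fraction `min_prevalence` (default 0.25) of that
temperature's replicate communities; a taxon can be retained at one
temperature and dropped at another, and the filter is idempotent. In the
pipeline this filter applies only to the trait–abundance regressions,
where rare taxa would otherwise drive the fits; diversity indices, PCA,
and PERMANOVA use the unfiltered counts, since removing the rare tail
would itself distort evenness and composition.

## Inference layer

**Polynomial model ladder.** For a response against a predictor the
package fits intercept-only, linear, and quadratic models and selects by
sequential likelihood-ratio tests at $\alpha = 0.05$, starting from the
quadratic: the most complex model whose added term is significant is
retained. The LRT statistic is $n \ln(\mathrm{RSS}_{reduced} /
\mathrm{RSS}_{full})$ on one chi-square df per dropped term. Raw
(non-orthogonal) polynomial terms keep coefficients interpretable; the
selection itself is invariant to that choice. Residual sums of squares
below $10^{-10}$ of the response's total sum of squares are treated as
exact fits so that noiseless data do not trigger spurious "significance"
from floating-point residuals.

**Trait–abundance ANCOVA.** Relative abundance is modelled with a
separate intercept and a separate slope on the taxon-level trait (thermal
optimum, or growth rate at the assay temperature) for each temperature
level (cell-means coding). With six levels and $n$ records the overall F
against the intercept-only null is on $(11, n-12)$ df. Per-level slope
differences are tested pairwise by Wald contrasts from the coefficient
covariance with Holm adjustment — a documented replacement for single-step
Tukey machinery, which is deliberately out of scope. Levels with a single
distinct trait value have their slope flagged inestimable rather than
silently dropped.

**Composition.** PCA is computed on column-centered, unscaled relative
abundances (proportions already share a scale); each component's sign is
fixed so its largest-magnitude loading is positive. PERMANOVA uses the
McArdle–Anderson trace form: squared dissimilarities are Gower-centered
and projected onto the predictor's model matrix, and significance comes
from seeded label permutations with the add-one estimator
$p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})$, default $n_{perm} = 999$. The
predictor may be a grouping factor or a continuous covariate (a 1-df
regression on the distance matrix); both modes are exposed because either
reading is defensible for a temperature gradient. The default
dissimilarity is Bray–Curtis on relative abundances, the conventional
choice for community composition; an exhaustive-enumeration mode computes
exact p-values for small designs. Pairwise PERMANOVAs multiply each raw p
by the number of pairs (Bonferroni), capped at 1.

## The synthetic-data generator

The generator provides ground truth for parameter-recovery testing and a
stand-in for the study design it emulates: 8 taxa assayed at 0, 15, 20,
25, 30, 35, 40, 45 and 50 °C in 6 technical replicates, and 20 replicate
communities assembled at 10, 15, 20, 25, 30 and 35 °C.

**Taxon pool.** Thermal optima are drawn to span 18.7–35.3 °C and
activation energies 0.23–1.06 eV — the observed ranges for isolate pools
of this kind — by stratified uniform sampling: one value per equal-width
stratum, uniform within it, with the pairing between traits randomised.
Marginals stay uniform while every realised pool genuinely covers the
ranges, as an assembled isolate panel does; iid draws of 8 frequently
leave large gaps. $E_h$ is drawn as $E_a \times U(2, 6)$ (so $E_h > E_a$
always holds and decline limbs are realistically steep), and $T_h$ is
solved from the closed-form optimum so each taxon attains its drawn
$T_{opt}$ exactly. Reference-temperature rates span 0.3–1.0 h$^{-1}$:
a deliberately modest baseline spread, so that community structure is
shaped by temperature-driven selection rather than by
temperature-independent fitness differences — the regime the conceptual
assembly model describes (even communities at benign temperature,
dominance only under thermal stress).

**Growth plates.** Each well is the logistic curve with $r$ from the
taxon's true TPC, $K = 1.0$ and $N_0 = 0.01$ OD (typical plate-reader
magnitudes), plus a medium baseline (0.05 OD) added to every well and
additive Gaussian noise (default SD 0.005 OD) truncated so OD stays
non-negative; plate-reader noise is approximately additive at low OD.
Four blank wells per temperature read baseline plus noise on the same
2-hourly schedule. Each temperature's incubation runs until the slowest
taxon's noiseless curve reaches 99 % of $K$, at least 24 h and at most
168 h — emulating measurement until carrying capacity while acknowledging
that genuinely non-growing wells never get there.

**Communities.** At each community temperature the expected proportions
are $p_i \propto \max(r_i(T), \varepsilon)^s$ with
$\varepsilon = 10^{-6}$ and selection exponent $s$ (default 3); counts are
multinomial with 100 colonies per replicate (a typical countable plate
load). Exponent 0 gives neutral assembly; large exponents hand the
community to the fastest grower. The power-weighting is a stand-in for an
unspecified abundance–growth-rate link, not a mechanistic claim: there is
no resource competition, no species interactions, no drift beyond
multinomial sampling, and no simulation of the multi-day biomass decline.
Passing recovery tests on this generator therefore demonstrates that the
fitting and inference chain is correct and well calibrated — not that
real communities assemble by fitness-power weighting.

## Problem sizes and determinism

The test suite fits noiseless and noisy single curves exactly or to
stated tolerances, checks the closed-form optimum against grid
maximisation (0.005 K grids over 250–400 K), recovers the 8-taxon pool's
traits from rates with 5 % multiplicative noise over 20 replicate
simulations (200 restarts per fit), calibrates PERMANOVA's type-I error
on 200 null datasets of two groups of 15, measures the model ladder's
power and size on 200 datasets of n = 120, and runs the full pipeline at
the default design with reduced restart counts (300 TPC restarts, 15
logistic restarts, 199 permutations). These sizes were chosen to give
stable Monte-Carlo estimates while keeping a full run interactive.

Every stochastic stage takes a seed; the pipeline derives per-stage
substreams from one global seed, so stages are individually reproducible
and a rerun with the same configuration is bit-for-bit identical (the run
manifest records the configuration hash, seed, and package version).

## Known limitations

* The logistic model has no lag phase; wells with strong lags will bias
  $r$ downward. Gompertz/Baranyi alternatives are out of scope.
* Only the high-temperature Sharpe–Schoolfield variant is fitted; taxa
  with low-temperature inactivation within the assayed range are not
  modelled.
* The evenness of communities containing a single taxon is undefined, so
  evenness analyses use fewer records than richness analyses — by design,
  not omission.
* Confidence intervals for TPC parameters (asymptotic, Jacobian-based)
  are not exposed in the trait table; the multi-start AIC procedure
  selects a point estimate.
* PERMANOVA p-values are exchangeable-label permutation tests; they do
  not account for dispersion differences between groups.
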