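---
title: "A single-population model of family-planning indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A single-population model of family-planning indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpest)
```

# The estimation problem

National and subnational family-planning monitoring rests on scattered,
heterogeneous survey series: a DHS here, a MICS there, occasional national
surveys, each reporting the proportion of women using modern contraceptive
methods, using traditional methods, and with unmet need, with sampling
errors of varying quality. Global hierarchical models pool hundreds of
countries to estimate smooth time trends of these indicators; they are
expensive to fit and overkill when only one population is of interest.

`fpest` implements the single-population version of this estimation
strategy: all quantities that a global model would share across countries —
prior means and variances at the sub-region level, the smoothing parameters
of the distortion processes, the biases and non-sampling error variances of
each survey source type — are *fixed* inputs, supplied as a
global-parameter fixture. What remains to be estimated is population
specific: seven trend parameters and three annual distortion series.

# Model

## Latent trajectories

On an annual grid $t = t_1, \dots, t_T$ the model tracks three latent
proportions:

$$P_t = \tilde P \,\mathrm{logit}^{-1}\!\big(\rho_P (t - \Omega_P) + \varepsilon_{P,t}\big)$$

total contraceptive use: a logistic uptake curve with asymptote
$\tilde P \in (0,1)$, timing $\Omega_P$ (the calendar year at which use
reaches half its asymptote) and pace $\rho_P > 0$ (per year), distorted by a
zero-mean stationary AR(1) series $\varepsilon_P$;

$$R_t = \tilde R \,\mathrm{logit}^{-1}\!\big(\rho_R (t - \Omega_R) + \varepsilon_{R,t}\big)$$

the modern share of use, with its own logistic trend, so that modern use is
$M_t = P_t R_t$ and traditional use $T_t = P_t (1 - R_t)$ — the identity
$M_t + T_t = P_t$ holds exactly by construction;

$$Z_t = (1 - P_t)\,\mathrm{logit}^{-1}\!\big(\alpha + \beta P_t + \varepsilon_{Z,t}\big)$$

unmet need, a logit-linear fraction of non-use. Writing unmet need as a
fraction of $1 - P_t$ enforces $M_t + T_t + Z_t < 1$ for every parameter
value, so the four states (modern use, traditional use, unmet need, no
need) always form a proper composition. The slope $\beta$ couples the level
of unmet need to the level of use; it is fixed by the fixture (default 1)
rather than estimated, since a single population carries almost no
information about it.

Each distortion series is stationary AR(1): the first element is
$\mathcal N(0, \sigma^2)$ and each subsequent element
$\mathcal N(\rho\,\varepsilon_{t-1}, \sigma^2 (1-\rho^2))$, with $(\rho,
\sigma)$ per series fixed by the fixture. These distortions let the fitted
trajectory bend away from the logistic trend where the data demand it,
while reverting to the trend at the fixture's time scale
$\sim 1/(1-\rho)$ years away from data.

## Observation model

A survey row carries up to three observed proportions. The reference time is
the midpoint of the field period, mapped to the nearest grid year (exact
halves round down, for determinism; survey dating is not meaningfully
sub-annual). Component $k \in \{\text{modern}, \text{traditional},
\text{unmet}\}$ of a survey from source type $s$ contributes

$$\mathrm{logit}(y_k) \sim \mathcal N\!\Big(\mathrm{logit}(\lambda_k(t_i)) + \mathrm{bias}[s,k],\;
\mathrm{se}_{\mathrm{logit}}^2 + \tau^2[s,k] + \mathbb 1[\text{mismatch}]\,\tau^2_{\mathrm{mis}}\Big)$$

with $\lambda_{\text{modern}} = M$, $\lambda_{\text{traditional}} = T$,
$\lambda_{\text{unmet}} = Z$, and
$\mathrm{se}_{\mathrm{logit}} = \mathrm{se}/(y(1-y))$ the delta-method
transform of the proportion-scale sampling error. Missing components
contribute nothing. DHS is the reference source type with zero bias; the
other source types carry additive logit-scale biases and their own
non-sampling variances, and surveys whose sample population differs from
the target group get the extra mismatch variance. Cross-component error
covariances are set to zero (a diagonal likelihood); this is a deliberate
simplification, stated rather than hidden, and the fixture format would
accommodate a correlated extension.

Proportions are clamped to $[0.001, 0.999]$ before any logit transform;
clamping events are recorded per observation in the fit's core data.
Missing sampling errors are completed *before* fitting: per component, a
missing SE becomes the largest observed SE for that component in the
population's data (a deliberately conservative choice), or 0.025 if none is
observed; all SEs are floored at 0.005. The rule pools across source types,
since within one population there are rarely enough surveys per source to
condition on it.

## Priors and the prior level

The seven trend parameters carry independent Normal priors on the scale
where they are unbounded: $\mathrm{logit}(\tilde P)$,
$\log \rho_P$, $\Omega_P$, $\mathrm{logit}(\tilde R)$, $\log \rho_R$,
$\Omega_R$, $\alpha$. Their means and SDs come from the fixture block of the
population's *prior level*: for a national fit, the country's sub-region;
for a subnational fit, the parent country plays the sub-region's role (the
divisions table lists each subnation with its parent country's code in the
sub-region column). With zero observations the posterior is exactly the
prior, which the test suite verifies by sampling.

# Inference

The sampler is an adaptive Metropolis-within-Gibbs scheme over the seven
unconstrained trend parameters and the AR(1) *innovations* (the
non-centered parameterisation, under which the prior of each innovation is
standard normal and single-site updates mix well). Three kinds of moves run
each iteration:

1. **Component-wise random-walk updates** of every coordinate, with
   per-coordinate scales adapted towards a 0.44 acceptance rate in batches
   of 50 during warmup (diminishing adaptation), then frozen.
2. **Curve-preserving ancillary moves**: each trend parameter is also
   updated while the fitted curve is held fixed by compensating through the
   distortion series — e.g. a shift of $\Omega_P$ with
   $\rho_P(t-\Omega_P)+\varepsilon_{P,t}$ unchanged. The likelihood is
   invariant under these moves, so only the priors (and, for the asymptote
   moves, the Jacobian of holding the curve rather than the distortions
   fixed) enter the acceptance ratio. These moves break the strong
   posterior coupling between trend parameters and distortions that
   otherwise throttles mixing.
3. **A joint random-walk update** of all seven trend parameters with
   covariance learned from the warmup draws and scale adapted towards 0.25
   acceptance.

Initialisation is at the prior means with jitter of 0.1 prior SD (up to 10
re-jitters if the posterior is non-finite, which cannot occur for valid
inputs but guards degenerate fixtures). The sampler uses R's RNG, so a fit
is bit-reproducible given its seed; chains run sequentially with seeds
`seed + chain - 1`. Defaults are 4 chains × 1000 kept draws after 1000
warmup iterations.

Convergence is summarised by split-chain potential scale reduction
($\widehat R$) and an effective sample size per scalar parameter, computed
from the standard multi-chain autocovariance estimator with Geyer's
initial-positive-sequence truncation. The overall flag requires
$\widehat R < 1.1$ everywhere. Note that split $\widehat R$ has a
deterministic floor of $\sqrt{(n-1)/n}$; values marginally below 1 are
normal. Constant chains yield `NA` diagnostics rather than errors.

# Derived indicators and aggregation

All indicators are computed **per posterior draw** and only then
summarised: `total_use` $= M + T$, `non_use` $= 1 - $ `total_use`,
`total_demand` $=$ `total_use` $+ Z$, `demand_satisfied` $=$
`total_use`/`total_demand`, `demand_satisfied_modern` $= M/$`total_demand`,
`unmet_need_modern` $= Z + T$ (unmet need for modern methods: women with
unmet need plus traditional users), and user counts as proportion × number
of women in the estimate's calendar year (no interpolation of population
counts; a missing year is an error, not an extrapolation). Ratios of
quantiles are never used — quantiles of per-draw ratios propagate posterior
dependence correctly. Quantiles use linear interpolation between order
statistics (the type-7 convention), fixed for reproducibility.

All-women estimates combine the in-union and not-in-union fits per draw
(paired by chain and iteration; fits with different draw counts are
rejected rather than resampled, to avoid silently breaking posterior
dependence): each base proportion is the count-weighted mean
$(W_{\mathrm{in}} p_{\mathrm{in}} + W_{\mathrm{not}} p_{\mathrm{not}}) /
(W_{\mathrm{in}} + W_{\mathrm{not}})$, user counts sum, and ratio
indicators are recomputed from the aggregated bases. Aggregation across
divisions works identically with per-division counts as weights; it is
associative and order-invariant to floating tolerance, and the "no need"
category is available as `non_use` − `unmet_need`.

# The synthetic-data generator

`generate_global_parameters()` and `simulate_population()` stand in for the
real global-model outputs and survey databases, which are not distributed
here. The fixture defaults describe a population in which total
contraceptive use tends towards $\mathrm{logit}^{-1}(0.5) \approx 0.62$
(logit-scale prior SD 1 — weakly informative), uptake paces near 0.1/year
(total) and 0.08/year (modern share) with half-times around 1995–2000
(10-year SD), unmet-need level $\alpha \approx -1$, AR(1) autocorrelations
in $[0.8, 0.95]$ with stationary SDs in $[0.08, 0.15]$, zero DHS bias,
small random biases (SD 0.05) and non-sampling SDs ($\approx 0.02$–$0.1$)
for the other source types, and $\beta = 1$. These are package constants
chosen to resemble typical national survey series — they are documented
values, not estimates from any published model run. The default survey
design — 5 surveys of mixed source types across a 25-year grid with
proportion-scale SE 0.02 — mirrors the sparsity the tool is meant for.

Simulated observations are drawn from the exact observation model on the
logit scale; the CSV then carries the proportion-scale SE implied by the
realized value, so the delta-method transform applied at fitting time
recovers the exact logit-scale SD the data were generated with. Rows that
would violate the deterministic sum constraints (modern + traditional
$> 1$) are redrawn, so every written dataset passes input validation by
construction. Population counts grow smoothly (0.5%/year) and are treated
as known, as is conventional for these denominators.

What the generator does **not** emulate: real survey-design effects beyond
a single SE per component, age structure (a single 15–49 group), method mix
beyond modern/traditional, service-statistics inputs, and any resemblance
to a particular country's history. Passing calibration tests on this
generator therefore demonstrates internal statistical correctness — that
the posterior is computed and summarised correctly for the stated model —
not that the model is well specified for any particular real population.

# Verification

Three layers of tests back the package, at problem sizes chosen to keep the
full suite around two to three minutes:

- **Exact oracles**: the AR(1) density against a dense-covariance
  multivariate-normal evaluation (lengths ≤ 12, tolerance 1e-8); the
  observation likelihood and log-posterior against hand-summed terms
  (1e-10); indicator and aggregation identities checked exactly.
- **Sampling properties**: bit-identical draws under a repeated seed;
  prior recovery from zero-observation fits (each parameter within 3 Monte
  Carlo standard errors, using the estimated effective sample size);
  recovery of the truth from 20 precise synthetic surveys (posterior median
  of modern prevalence within ±0.02 in observed years); monotone posterior
  contraction as observations accumulate through 1, 5, 20.
- **Simulation-based calibration**: 100 populations simulated from the
  fixture prior and observation model (25-year grid, 5 surveys each), each
  fit with 2 chains × 500 kept draws; the rank of the true modern
  prevalence at a held-out year among the posterior draws is tested for
  uniformity, and the empirical coverage of the 80% and 95% bands is
  compared with the nominal levels under binomial tolerance.
  `scripts/acceptance.R` reruns this experiment from scratch.

# Known limitations

- The diagonal observation likelihood ignores the sampling covariance
  between modern and traditional use estimated from the same survey.
- $\beta$, the AR(1) parameters, biases and non-sampling SDs are taken as
  known; their uncertainty in the upstream global fit is not propagated.
- Observation times are collapsed to grid years; surveys spanning several
  years are treated as point observations at the midpoint.
- Population counts carry no uncertainty.
- With zero observations in one union stratum, all-women estimates lean
  entirely on that stratum's prior; the package does not warn beyond the
  fit's observation count.
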