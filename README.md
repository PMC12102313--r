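# fatiguecast

Survey-fatigue-adjusted contact intensity estimation for longitudinal
social contact surveys.

## The problem

Social contact surveys measure how many people each respondent met the
previous day — the contact intensities that drive epidemic models.
Longitudinal panels re-invite their members wave after wave, and repeat
respondents systematically report fewer contacts than comparable
first-time respondents. This *survey fatigue* is a reporting artefact,
not a behavioural change, and left uncorrected it biases contact
intensity estimates downward by tens of percent as the share of
long-term panellists grows.

`fatiguecast` is an R package for epidemiologists and survey
statisticians working with such panels. It provides:

* **Feature selection** (`fit_intensity_selection()`,
  `fit_fatigue_selection()`, `select_features()`, `union_selected()`):
  negative-binomial regressions with sum-to-zero and regularised
  horseshoe priors that identify which sociodemographic features drive
  contact intensity, and which subgroups fatigue, under a ±5% relevance
  rule with computed thresholds `(log 0.95, log 1.05) = (-0.0513, 0.0488)`.
* **Fatigue dynamics** (`fit_longitudinal()`, `percent_reduction_curve()`,
  `compare_forms()`): the longitudinal model
  `log λ = β₀ + xᵀβ + τ(t) + ρ(r)` with a Matérn-3/2 Gaussian-process
  calendar trend and four functional forms for the fatigue curve ρ over
  the repeat count r — the work-horse being the three-parameter Hill
  dose–response curve

      ρ(r) = −γ · e^ζ r^η / (1 + e^ζ r^η),   γ, η > 0,

  where the survey is the dose, under-reporting the response, and
  100·(e^(−γ) − 1) the maximum percent reduction.
* **Age-resolved correction** (`fit_correction()`,
  `poststrat_age_curve()`, `inclusion_experiment()`): a
  Hilbert-space-approximate-GP age effect with a separate Hill curve per
  selected fatigue feature, post-stratified intensity curves over ages
  0–84, and the incremental repeat-inclusion experiment scored by MAPE
  and 95% coverage against a first-time-only baseline.
* **Sequential multi-wave estimation** (`run_waves()`,
  `overall_intensity()`, `subgroup_intensity()`,
  `bootstrap_intensity()`): wave-by-wave refits with priors carried from
  the previous wave's posterior means, plus bootstrap and
  first-time-only comparators.
* **A synthetic panel generator** (`simulate_panel()`,
  `covimod_like_scenario()`, `wave21_like_scenario()`) with recorded
  ground truth, so the whole pipeline is testable end to end without any
  external data.

Inference runs on an in-package adaptive Metropolis-within-Gibbs sampler
(adaptive random-walk blocks, elliptical slice sampling for Gaussian
latents, slice updates for scales); every fit returns split-R̂ and
effective-sample-size diagnostics. See the vignette
(`vignettes/fatigue-modelling.Rmd`) for the full model descriptions,
priors, and design decisions.

## Worked example

Generate a ten-wave panel with known Hill-fatigue truth
(γ = 1.18, ζ = −1.90, η = 1.16), preprocess it, and fit the longitudinal
Hill model:

```r
library(fatiguecast)

sim <- simulate_panel(covimod_like_scenario(), seed = 1)
records <- preprocess_records(sim$records, seed = 2)
nrow(records)
#> [1] 12007

fit <- fit_longitudinal(records, form = "hill",
                        mcmc = mcmc_control(chains = 2, warmup = 1500,
                                            iter = 2500, thin = 1, seed = 3))
summary(fit, pars = "^(gamma|zeta|eta)$")
#>   param    median       q2.5     q97.5     rhat      ess
#> 1  zeta -2.041067 -2.5221174 -1.614216 1.016620 289.2299
#> 2 gamma  1.382479  0.9962262  2.263228 1.002133 270.8836
#> 3   eta  1.045599  0.7897935  1.340256 1.014944 282.4919

curve <- percent_reduction_curve(fit)
round(curve$pct_median, 1)
#>  [1]   0.0 -15.0 -25.7 -33.5 -39.3 -43.7 -47.3 -50.1 -52.4 -54.3 -55.9 -57.3
```

The posterior medians recover the generating values — γ = 1.38
[1.00, 2.26] against a truth of 1.18, ζ = −2.04 [−2.52, −1.61] against
−1.90, η = 1.05 [0.79, 1.34] against 1.16 — and the percent-reduction
curve shows reported contacts falling by 15% after one repeat
participation and 57% after eleven, on data whose true maximum reduction
is 100·(e^(−1.18) − 1) ≈ −69% as r → ∞.

Downstream, `fit_correction()` + `poststrat_age_curve()` turn a single
wave into fatigue-corrected age-specific intensity curves, and
`inclusion_experiment()` shows the characteristic pattern: without
adjustment the error against a first-time-only baseline grows steadily
with the number of included repeats, while the adjusted model stays flat
with near-complete interval coverage.

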