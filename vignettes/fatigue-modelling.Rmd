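---
title: "Modelling and correcting survey fatigue in longitudinal contact surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and correcting survey fatigue in longitudinal contact surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Longitudinal social contact surveys re-invite panel members across waves.
Repeat respondents progressively report fewer contacts than comparable
first-time respondents — *survey fatigue* — which biases downward every
contact-intensity summary that epidemic models consume. `fatiguecast`
implements a Bayesian modelling pipeline that measures this artefact,
identifies who it affects, gives it a parametric functional form, and
corrects population-level and age-resolved contact intensity estimates
for it.

All response models are negative-binomial: a reported count $Y$ with mean
$\lambda$ and overdispersion $\varphi$ has
$\operatorname{Var}(Y) = \lambda + \lambda^2/\varphi$, and
$1/\varphi \sim \operatorname{Exponential}(1)$ throughout.

## Stage 1 — who drives contact intensity, and who fatigues

`fit_intensity_selection()` models first-time participants' counts with

$$\log\lambda_i = \beta_0 + u_i^\top\alpha + v_i^\top\beta,$$

where $u_i$ stacks full one-hot encodings (no reference level dropped) of
the age/schooling factor (14 categories, children aged 0–5 split into
preschool attendees and children raised at home), sex (2) and household
size (5), and $v_i$ stacks employment status (9), COVID-like symptoms
(2), day type (2) and urban–rural typology (3). Identifiability of the
full one-hot blocks comes from the priors, not from dropping columns:

* control blocks get *sum-to-zero multivariate normal* priors,
  reparameterised through an orthonormal null-space basis
  (`sz_nullspace_basis()`), with variance arguments 14/13, 2 and 3/2 —
  values that give unit marginal prior variance at dimension $K$ when the
  argument is $K/(K-1)$;
* test blocks get *sum-to-zero regularised horseshoe* priors (local
  half-$t_3$ scales, global half-$t_2$ scale, slab with 4 degrees of
  freedom and scale 2), with block global scales $(8,1,1,2)/\sqrt{n}$;
  here the sum-to-zero constraint is applied by orthogonal projection,
  which preserves the coordinate-wise shrinkage structure;
* $\beta_0 \sim \operatorname{Normal}(0, 100)$.

A feature is *relevant* when its posterior-median log effect changes the
baseline intensity by more than 5%: `selection_thresholds()` computes
$(\log 0.95, \log 1.05) = (-0.0513, 0.0488)$.

`fit_fatigue_selection()` then asks which subgroups under-report when
they return: the intensity model's posterior medians enter as fixed
offsets, and one-hot fatigue blocks (age/schooling, sex, household size,
employment, urban type; 33 columns) act only on rows with at least one
prior participation, so first-time rows anchor each subgroup's baseline.
Because fatigue can only depress reporting, the concatenated fatigue
coefficients get the negative-domain half regularised horseshoe with
global scale $32/\sqrt{n_{\text{repeat}}}$; a feature is selected when
its median reduction exceeds 5%. Selections from two waves are combined
with `union_selected()`.

## Stage 2 — the functional form of fatigue

`fit_longitudinal()` models multi-wave data as

$$\log\lambda_{i,r} = \beta_0 + x_i^\top\beta + \tau(t_{i,r}) + \rho(r),$$

with dummy-encoded covariates, a zero-mean Matérn-3/2 Gaussian-process
calendar trend $\tau$ (exact, on the unique survey dates, with
$\sigma_\tau \sim \text{inv-Gamma}(3,1)$,
$\ell_\tau \sim \text{inv-Gamma}(5,1)$ on time rescaled to $[0,1]$), and
four candidate forms for the fatigue curve $\rho(r)$ over the repeat
count $r$: a single shared fixed effect, independent per-$r$ fixed
effects, a squared-exponential Gaussian process over standardised $r$
(anchored at $\rho(0)=0$ by subtracting the latent value at $r=0$), and
the three-parameter Hill dose–response curve

$$\rho^{\text{Hill}}(r) = -\gamma\,\frac{e^{\zeta} r^{\eta}}{1 + e^{\zeta} r^{\eta}},
\qquad \gamma,\eta > 0,$$

with $\gamma \sim \text{half-N}(0,1)$, $\zeta \sim \text{N}(0,1)$,
$\eta \sim \operatorname{Exponential}(1)$. The survey "dose" is the
number of participations; the response is log-scale under-reporting,
which saturates at $-\gamma$, i.e. a maximum percent reduction of
$100(e^{-\gamma}-1)$. `percent_reduction_curve()` reports the posterior
curve on that percent scale, and `compare_forms()` ranks forms by WAIC
computed from pointwise cell log-likelihood draws plus the sup-distance
between posterior-median curves. WAIC was chosen as the comparison
criterion because it is computed directly from the log-likelihood draws
the sampler already produces; the original comparison of these forms was
visual.

## Stage 3 — age-resolved correction and its accuracy

`fit_correction()` models one analysis window as

$$\log\lambda_{i,r} = \beta_0 + f_{\sigma,\ell}(a_i) + x_i^\top\beta +
w_i^\top \rho(r),$$

where $f$ is a zero-mean Hilbert-space approximate Gaussian process
(HSGP) over age with squared-exponential kernel, and every selected
fatigue feature $q$ carries its own Hill curve with priors centred on the
longitudinal estimates: $\gamma_q \sim \text{half-N}(\hat\gamma, 1)$,
$\zeta_q \sim \text{N}(\hat\zeta, 1)$,
$\eta_q \sim \operatorname{Exponential}(\hat\eta)$. Setting
`adjust = FALSE` refits the identical model without the fatigue term — a
genuine refit, not a post-hoc zeroing.

Age-specific intensities are post-stratified (`poststrat_age_curve()`):

$$\lambda^{(s)}(a) = \sum_{g,h,u,j} v_g v_h v_u v_j
\exp\!\big(\beta_0^{(s)} + f^{(s)}(a) + \beta^{(s)}_g + \beta^{(s)}_h +
\beta^{(s)}_u + \beta^{(s)}_j\big),$$

with sex, household-size and urban weights from population tables and
the employment margin from the sample (population estimates are not
available at that stratification level), each margin normalised to one.
Curves are summarised by the posterior median and 95% interval at ages
0–84.

`inclusion_experiment()` quantifies correction accuracy: a first-time-only
fit provides the fatigue-free baseline $\lambda^0_M(a)$; participants
with at most $r$ repeats are then added back step by step and each refit
is scored by

$$\operatorname{MAPE}(r) = \frac{100}{85}\sum_{a=0}^{84}
\frac{|\lambda^r_M(a)-\lambda^0_M(a)|}{|\lambda^0_M(a)|},
\qquad
\operatorname{Coverage}_{95}(r) = \frac{1}{85}\sum_{a=0}^{84}
1\{\lambda^0_M(a) \in [\lambda^r_L(a), \lambda^r_U(a)]\}.$$

The baseline uses the adjusted machinery (the fatigue term is exactly
inert at $r=0$, so this choice only affects interval widths).

## Stage 4 — sequential multi-wave estimation

`run_waves()` chains the correction model across waves. From the second
wave onward, priors are centred on the previous wave's posterior means:
$\beta_{t,p} \sim \text{N}(\hat\beta_{t-1,p}, 0.3)$,
$\gamma_{t,q} \sim \text{half-N}(\hat\gamma_{t-1,q}, 0.3)$,
$\zeta_{t,q} \sim \text{N}(\hat\zeta_{t-1,q}, 0.1)$ and
$\eta_{t,q} \sim \text{half-N}(1/\hat\eta_{t-1,q}, 0.1)$. The $\eta$
carry rule is implemented literally with the reciprocal centre as stated
by its source; because the reciprocal may be an erratum for the mean
itself, `eta_carry = "direct"` switches to centring on
$\hat\eta_{t-1,q}$. Per-wave population intensities follow the same
post-stratified sum with the age–sex margin $v_{a,g}$ (summing over the
urban margin as well, without which the weights would not normalise);
`subgroup_intensity()` renormalises $v_{a,g}$ within an age range and
fixes named covariate levels. `bootstrap_intensity()` provides the
non-model comparator: participants are resampled with replacement and
each resample summarised by its post-stratification-weighted mean count —
a nonparametric weighted interpretation of the simple bootstrap
comparator.

## Inference engine

The original analyses of this model family were run with Hamiltonian
Monte Carlo. `fatiguecast` ships its own Metropolis-within-Gibbs
sampler, built from three primitives:

* adaptive multivariate random-walk blocks (Haario-style empirical
  covariance, Robbins–Monro scaling toward 0.234/0.44 acceptance,
  adaptation frozen after warmup);
* elliptical slice sampling for whitened Gaussian latent vectors (the
  time GP, the fatigue GP, the HSGP basis weights — three passes per
  sweep for the latter, the slowest-mixing block);
* univariate stepping-out slice sampling for scalar scales and for
  robust coordinate-wise refreshes of the Hill parameters.

Three structural devices matter for mixing and are worth knowing about:

1. **Exact cell aggregation.** Rows with identical design, repeat count
   and date share one mean, so the row-level NB log-likelihood is
   computed from cell sums plus the global frequency table of counts —
   exactly, including all $\varphi$-dependent terms — at a fraction of
   the row-level cost. (A pure sufficient-statistic aggregation is *not*
   used: it is exact for the regression coefficients but distorts the
   $\varphi$ posterior.)
2. **Centred parameterisations.** The calendar GP is centred on the date
   grid, the HSGP age effect is constrained to average zero over the
   observed design ages, and the dummy design matrix is column-centred
   (a pure reparameterisation; draws are mapped back). Each removes a
   soft direction between the intercept and a flexible term.
3. **Ridge moves.** Dedicated low-dimensional updates traverse the two
   remaining soft modes: a 2-d adaptive block on
   $(\beta_0, \log\gamma)$ (baseline level versus fatigue asymptote) and
   a 1-d slice along each factor block's common-shift direction (the
   contrast between a small reference cell and the rest).

Chains are initialised from the empirical fatigue curve (group means by
repeat count, least-squares Hill fit) with per-chain jitter. Every fit
returns split-$\widehat R$ and effective sample sizes for all stored
quantities; the package flags a fit as converged when all
split-$\widehat R < 1.05$, a threshold chosen for random-walk samplers at
the default chain lengths — inspect the diagnostics directly when more
stringency is needed. There is no notion of divergent transitions for
this sampler class.

## The synthetic panel generator

`simulate_panel()` produces longitudinal panels with recorded ground
truth; `covimod_like_scenario()` is the documented default: an initial
cohort of 1,500 with 130 recruits per wave over 10 biweekly waves and
85% per-wave retention (absorbing dropout), giving roughly 2,500 unique
participants and 12–13 thousand records; the initial cohort enters with
up to two prior participations so the deepest achievable repeat count is
11. Covariate margins follow the quota-like composition of a pandemic-era
German panel wave; effects are log-linear with working/student status and
urban residence positive and stay-at-home/unemployed/long-term-sick/
retired negative; a smooth age profile peaks at school ages and declines
past 70; $\beta_0 = \log 3$, $\varphi = 2$; fatigue follows a Hill curve
with $\gamma = 1.18$, $\zeta = -1.90$, $\eta = 1.16$. The calendar-time
trend is off by default, matching the stable-restrictions window this
scenario emulates. `wave21_like_scenario()` emulates a single
late-pandemic wave (about 39% first-timers, repeat depths to 20) for the
inclusion experiment.

What the generator deliberately does not emulate: covariates are drawn
independently of each other (no age–employment coupling), dropout is
covariate-independent by default (a `retention_slope` knob links it to
contact levels for sensitivity analyses), participation gaps (skip one
wave, return later) do not occur, and fatigue in the default scenario is
homogeneous across subgroups. Passing tests on this generator therefore
demonstrates that the estimators recover the mechanisms they model; it
cannot certify behaviour under confounding structures the generator does
not contain. Minors are emitted with age bands only (0–4, 5–9, 10–14,
15–18), so the uniform age-imputation step and its noise are exercised
exactly as with real data; counts are emitted untruncated and truncated
at 50 (the conventional outlier cap) during preprocessing.

## Numerical choices and degenerate inputs

* HSGP: ages 0–84 are rescaled to $[-1,1]$; the default basis uses
  $m = 25$ functions with boundary factor $c = 1.5$ (covariance error
  under 5% of $\sigma^2$ at $m = 40$ on this domain, and $m=25$ is
  visually indistinguishable for lengthscales the data support);
  amplitude prior half-N(0,1), lengthscale inv-Gamma(3,1) — weakly
  informative on the rescaled domain, favouring age structure on the
  scale of one to a few decades.
* Kernel matrices carry a $10^{-8}$ diagonal jitter; the repeat-count GP
  is exact (the grid has at most a couple of dozen points).
* The GP fatigue form standardises $r$ by the observed row-level mean
  and standard deviation, recorded in the fit for prediction-time reuse.
* Records missing age and age band, or missing sex, are dropped with a
  logged count; ages above 84 are dropped with a warning; negative
  counts are rejected.
* A wave with no rows inside `run_waves()` passes the carry state
  through unchanged with a message.
* `fit_fatigue_selection()` requires at least one repeat row; the
  fatigue-selection null check is therefore run on panels that contain
  repeat rows whose truth has no fatigue.

## Problem sizes used in the shipped tests

The test suite exercises every stage end to end at reduced but
informative sizes chosen so that each check has adequate statistical
power: the Hill-recovery experiment runs at the full default scenario
scale (about 12,000 records) with one chain, selection-model recovery
runs at 2,000–5,000 participants, and the inclusion and multi-wave
experiments run on panels of 700–1,600 participants with shortened
chains. The acceptance script repeats the Hill-recovery experiment at
full scenario scale with two chains.

## Known limitations

* Random-walk mixing: effective sample sizes per minute are far below
  what gradient-based samplers achieve on these posteriors; the shipped
  chain lengths target stable posterior medians and 95% intervals, not
  tail functionals.
* The fatigue models assume fatigue depends only on the cumulative
  number of participations — not on calendar time, gaps between
  participations, or unmeasured individual heterogeneity.
* First-time participants are the accuracy reference; if returning and
  newly recruited participants differ in unmeasured ways, part of what
  is labelled fatigue is differential retention. The generator's
  `retention_slope` knob exists to probe exactly this.
* The employment post-stratification margin comes from the sample, so
  population summaries inherit the sample's employment composition.
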