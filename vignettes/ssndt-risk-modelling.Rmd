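---
title: "Modelling U-shaped injury risk along the SSNDT continuum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling U-shaped injury risk along the SSNDT continuum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssndtrisk)
```

## The problem and the model

The sit-to-stand navicular drop test (SSNDT) measures, in millimetres, how
far the navicular tuberosity descends between a seated subtalar-neutral
position and weight-bearing standing. Functionally it indexes medial
longitudinal arch mobility, and both extremes are plausibly harmful: a
rigid arch absorbs load poorly, a hypermobile one transfers it poorly.
`ssndtrisk` therefore treats injury risk as a smooth U-shaped function of
SSNDT rather than imposing cut-points.

Observations are feet, two per participant, and a participant's two feet
share anatomy, training exposure and injury history. The package models
this with a participant-level random intercept:

$$\operatorname{logit} P(Y_{ij}=1) = \beta_0 + \beta_1 x_{c,ij} +
\beta_2 x_{c,ij}^2 + \gamma_L \mathrm{load}_{c,i} +
\gamma_E \mathrm{exp}_{c,i} + u_i, \qquad u_i \sim N(0, \sigma_u^2),$$

with all predictors mean-centered (subscript $c$). The marginal likelihood
integrates $u_i$ out numerically; `fit_injury_model()` maximises it
directly. Weekly training load and training experience enter as
participant-level covariates because cohorts can differ in training
exposure; holding them at their sample means makes them cancel from every
odds-ratio quantity downstream.

### Estimation choices

The integral over $u_i$ is evaluated by **adaptive Gauss–Hermite
quadrature**: per cluster, the integrand's mode and curvature are found by
Newton iterations and the quadrature nodes are re-centred and re-scaled
there. One node is exactly the Laplace approximation; the default is 15
nodes, and the log-likelihood changes by less than $10^{-6}$ (relative)
between 15 and 25 nodes on calibrated data, so 15 is treated as converged.
The optimizer is BFGS on $(\beta, \log\sigma_u)$ with an analytic gradient
(obtained by differentiating through the adaptive nodes), initialised from
the ordinary logistic fit and $\sigma_u = 0.5$, and finished with Newton
polishing so that results are reproducible to ~1e-9 regardless of the
optimizer's stopping point. Standard errors come from the observed
information (numerically differentiated at the optimum). With clusters of
size two the Laplace approximation is visibly biased for $\sigma_u$ and
$\beta_2$ — the classic motivation for AGQ — which is why headline fits
default to 15 nodes while bulk refits (bootstrap, profile grids) default
to Laplace for speed, with `nagq` exposed everywhere.

Degenerate inputs fail loudly: a single outcome class is an error, fixed
effects diverging past $|\beta| > 15$ raise a separation error, and a fit
that stops without a vanishing gradient is returned with
`converged = FALSE` plus a warning, never silently.

### Model comparison

`compare_functional_forms()` fits linear, quadratic and cubic SSNDT terms
(all adjusted, all with the random intercept) and reports AIC, BIC,
Nagelkerke $R^2$ and sequential likelihood-ratio tests. The parameter
count includes the random-intercept variance. Nagelkerke $R^2$ is computed
from marginal log-likelihoods against the intercept-plus-random-intercept
null — marginal likelihoods are the only ones comparable across these
specifications. A cubic can win on AIC yet have no unique interior
minimum, which is why the threshold machinery accepts quadratic fits only.

## From curve to clinical quantities

For $\beta_2 > 0$ everything is closed-form: the minimum-risk point
$x_{\min} = \bar{x} - \beta_1 / (2\beta_2)$, the odds ratio
$OR(x) = \exp(\beta_2 (x - x_{\min})^2)$, and the two-sided thresholds
$x_{\min} \pm \sqrt{\ln(OR_t)/\beta_2}$. The closed form is the primary
path; every call cross-validates it against bracketed root-finding on each
arm of the U and errors if they disagree beyond $10^{-6}$ mm. Thresholds
are always reported on the raw mm scale.

The local risk gradient `local_or_per_mm()` is exposed in two variants,
because "the odds ratio of a 1 mm increase" is ambiguous: the exact finite
contrast $\exp(\eta(x+1) - \eta(x))$ (default) and the instantaneous
$\exp(\eta'(x))$. They differ by the factor $e^{\beta_2}$.

Zones are nested rings around the minimum: the innermost anchor band is
Safe, each further band minus its predecessor forms the next zone, and
everything outside the widest band is Extreme. Bands are closed intervals
and a value sitting exactly on a boundary goes to the *safer* zone — the
conservative screening convention; the alternative assignment was equally
defensible and this one is simply fixed and documented. Empirical per-zone
prevalence is descriptive aggregation and is *not* expected to be
monotone across zones (small inner zones can show zero events); the
model-based risk ordering is what the zones encode.

## Uncertainty: participant-level bootstrap

The resampling unit is the participant: each of the `B` replicates draws
participants with replacement (both feet travel together, each draw
becoming its own cluster), refits the quadratic model, and recomputes
$x_{\min}$ and all threshold pairs. Intervals are percentile intervals
(inverse-ECDF, quantile type 1), the simplest method consistent with a
plain "bootstrap 95% CI"; BCa was deliberately left out. Replicates whose
fit fails or whose $\hat\beta_2 \le 0$ (no U) are dropped and counted in
`n_effective`; more than half failing is an error rather than a quietly
biased interval.

Adjacent OR levels are classified *redundant* when their CIs overlap on
either side; *non-redundant* requires disjoint CIs for both the lower and
the upper threshold. At study-like sizes with 0.1-wide OR steps,
essentially every adjacent pair is redundant — the statistical expression
of a continuous risk gradient, and the reason anchor ORs are interpretive
markers rather than empirical breakpoints.

Coverage, checked by simulation at the study size (137 participants), is
close to nominal for the lower threshold (~0.95) and mildly low for the
upper one (~0.91 at $n=137$, ~0.95 by $n=400$) — ordinary small-sample
behaviour of percentile intervals on a skewed statistic, worth knowing
when reading the intervals at small $n$.

## Breakpoint analysis

`fit_segmented()` fits a broken-line (hinge) logit, continuous at each
breakpoint, within the same adjusted random-intercept framework, by
profiling the likelihood over a candidate grid (default 50 points between
the 5th and 95th SSNDT percentiles) with local refinement and a
profile-curvature standard error. A flat profile — more than half the
candidates statistically tied with the maximum — raises an `unstable`
flag; two-breakpoint fits at study-like sizes trip it routinely.

`breakpoint_test()` asks whether *any* breakpoint improves on the linear
model. The statistic is the maximal LRT over the grid; because the
maximum over candidates has no standard $\chi^2$ distribution, the null
distribution is obtained by parametric bootstrap from the fitted
no-breakpoint model (fresh random intercepts each replicate), which
accounts for the search by construction. This grid-maximal,
bootstrap-calibrated construction was chosen over the analytic
Davies bound because its small-sample calibration is exactly testable by
simulation (empirical type-I error 0.04 at nominal 0.05 in the test
suite); the analytic bound is conservative and exists in several
variants. On U-shaped data the single estimated breakpoint sits loosely
around the minimum-risk region with slopes changing sign across it — it
re-finds the turning point, not an additional risk transition.

## Reliability

`icc_consistency()` implements the single-measure consistency ICC from
the two-way ANOVA decomposition,
$ICC(3,1) = (BMS - EMS)/(BMS + (k-1)EMS)$, with the $F$ test on
$(n-1, (n-1)(k-1))$ degrees of freedom and the standard F-based interval.
The consistency form is what the (3,1) label denotes in the
Shrout–Fleiss convention and is invariant to a fixed shift between
trials; since reliability prose sometimes says "absolute agreement" while
labelling the estimator (3,1), the absolute-agreement single-measure
variant is available via `type = "agreement"` so the difference can be
inspected directly. Interpretation bands: < 0.50 poor, 0.50–0.75
moderate, 0.75–0.90 good, > 0.90 excellent.

## The synthetic-data generator

`simulate_feet()` emulates the cohort the analysis assumes: participants
with two feet; SSNDT from a Normal with mean 7.8 mm and SD 3.0 mm
truncated to the 0–25 mm plausibility window (a truncated Normal is the
simplest family matching the two reported moments); weekly load
(7.7 ± 3.1 h) and experience (4.3 ± 0.6 y) drawn at participant level and
shared by both feet; and the injury indicator from the quadratic logit
with conditional intercept −1.960, $\beta_1 = 0.238$/mm,
$\beta_2 = 0.051$/mm² (minimum-risk point ≈ 5.47 mm) and random-intercept
SD $\sigma_u = 1.0$ — a plausible degree of within-person clustering
(latent-scale ICC ≈ 0.23) for paired feet; the true value for the
original cohort is unknown, so this is an explicit free knob. Under these
defaults the marginal injury prevalence is 0.24 (Monte Carlo), inside the
~21–25% band observed for this population; reproducing the 21.2% point
estimate exactly would require $\sigma_u \approx 0.25$, i.e. almost no
clustering, because the random intercept inflates the marginal rate above
the conditional intercept's $\operatorname{logit}^{-1}(-1.96) = 0.123$.

What the generator does *not* emulate: cohort-year heterogeneity in
training exposure, left/right asymmetry, measurement error in SSNDT, and
any non-quadratic structure in the true risk curve. Passing tests on this
generator therefore demonstrate that the estimation and threshold
machinery recovers a known U-shaped truth under realistic sizes and
clustering — not that real SSNDT–injury relationships are quadratic.

`run_scenarios()` repeats the full quadratic analysis over replicate
datasets at several sample sizes (defaults 380, 288 and 274 feet — the
conservative planning size, the prevalence-based planning size, and the
achieved size) and summarises each extracted quantity by mean, SD and
2.5/97.5 percentiles, plus the fraction of replicates preserving the
threshold ordering.

## Numerical and design notes

* Seeds: every stochastic function requires or accepts an explicit seed;
  `run_full_analysis()` derives per-stage child seeds deterministically
  from one global seed, so stages rerun in isolation match the full run.
* The ratio $x_{\min} = \bar x - \beta_1/(2\beta_2)$ is heavy-tailed at
  the study size: replicates with $\hat\beta_2$ near zero throw the
  minimum far out. Means across replicates remain within Monte-Carlo
  error of truth, but the Monte-Carlo error itself is large — medians are
  the more stable summary at $n = 137$.
* Problem sizes in the test suite are chosen to make each property
  decisive at desk scale: 200 replicates for parameter recovery at the
  study size, 60 outer replicates × B = 300 for bootstrap coverage, 72
  runs × B = 99 on a 6-point grid for the breakpoint test's type-I error,
  1,000 random curves for the closed-form/root-finder agreement.
* CSV input is validated, not repaired: out-of-window SSNDT and missing
  covariates reject the row with a reason (listwise deletion keeps the
  adjusted models estimable on complete rows); non-binary outcomes,
  duplicate feet, three-footed participants and comma decimals are
  errors. The full command-line surface of the workflow is the R API plus
  `scripts/acceptance.R`; the functions themselves are the interface.

## Known limitations

Percentile intervals mildly undercover the upper threshold at small $n$
(above). The cubic specification is fitted for comparison only — no
threshold geometry is defined for it, by design. The Davies-type test's
parametric bootstrap assumes the null model's random-intercept normality.
The generator's truncated-Normal SSNDT cannot produce the skewness real
foot-posture distributions sometimes show.
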