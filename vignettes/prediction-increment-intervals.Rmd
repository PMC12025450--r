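---
title: "Estimating prediction-increment measures and their confidence intervals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating prediction-increment measures and their confidence intervals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predincr)
```

## The problem

When a risk prediction model is updated with a new marker, the question is
not whether the marker's coefficient is significant but whether the expanded
model *discriminates* better: does it separate events from nonevents more
cleanly than the standard model? `predincr` computes the measures used to
answer that question for nested model pairs and, crucially, the confidence
intervals around them — because for several of these measures the usual
normal-theory intervals are unreliable, particularly when the added marker is
weak. The package also contains the Monte-Carlo machinery to *measure* that
unreliability: empirical distributions of the estimators and coverage
probabilities of six interval constructions over configurable simulation
scenarios.

## Measures

Write $p_{old}$ and $p_{new}$ for a subject's predicted event probabilities
under the standard and expanded models.

**ΔAUC.** The AUC is estimated by the Mann–Whitney C-statistic (ties credited
0.5), and ΔAUC = C(new) − C(old) on the same subjects. Its standard error
uses the DeLong structural-component estimate of the covariance of the paired
C-statistics, $SE = \sqrt{(1,-1)\,S\,(1,-1)'}$.

**Categorical NRI.** Subjects are cross-classified by risk category under
both models (half-open bands $[low, high)$). With movement probabilities
estimated per outcome class,
$NRI = [\hat p_{up|1} - \hat p_{down|1}] + [\hat p_{down|0} - \hat p_{up|0}]
= eNRI + neNRI$. Both components are always reported alongside the sum —
a summary NRI can mask harm within one class, so the class-specific net
proportions are the interpretable quantities. The asymptotic variances are
the standard multinomial ones; $SE(NRI)^2 = SE(eNRI)^2 + SE(neNRI)^2$ holds
exactly.

**Continuous NRI (NRI > 0).** The category-free version: any strict increase
in predicted risk is upward movement, any strict decrease downward; exact
ties count as neither (the defining probability statements use strict
inequalities).

**IDI.** The change in discrimination slope:
$(\bar p_{new} - \bar p_{old})_{events} - (\bar p_{new} -
\bar p_{old})_{nonevents}$, equivalently the improvement in average
sensitivity minus the change in average one-minus-specificity integrated
over all thresholds. The SE combines the class-wise standard errors of the
per-subject paired differences.

**Survival extensions.** With right-censored data the event indicator at a
horizon $t$ is only partially observed, so:

* ΔC uses Harrell's overall C: the proportion of *usable* pairs that are
  concordant. A pair is usable when the strictly smaller observed time is an
  event time; tied observed times are not orderable and are skipped. (A
  looser reading — "at least one member had an event" — would admit pairs
  censored before the other member's event, which cannot be ordered; the
  standard earlier-time-event rule is used instead.) Prediction ties score
  0.5 by default so that constant predictions give C = 0.5; the strict 0
  convention is available via `tie_credit`.
* NRI(t) classifies subjects by movement as above and estimates
  $P(Y(t)=1\mid Z_{up})$, $P(Y(t)=1\mid Z_{down})$ and the marginal
  $p = P(Y(t)=1)$ by Kaplan–Meier within subgroups, combined through the
  Bayes decomposition; with the default weight $w = 0.5$ the reported value
  is $2\,NRI_{0.5}(t)$, which is on the binary NRI scale and reduces exactly
  to the count estimator (and to the binary NRI) when there is no censoring.
  Note that the division by $p(1-p)$ is already the doubled $w=0.5$ form; no
  further factor of two applies. A movement group with no members
  contributes zero; a subgroup curve with no events by the horizon yields a
  conditional event probability of zero, which the $P(Z)$ weighting keeps
  well defined.
* IDI(t) is the change in explained variation
  $R^2(t) = \widehat{Var}[S(t|Z)] / (\hat S(t)(1-\hat S(t)))$ with
  $\hat S(t)$ from Kaplan–Meier. $R^2(t)$ is bounded by 1 in theory; the
  sample variance here uses the $n-1$ divisor, so tiny samples can
  numerically exceed 1 — such values are reported clipped with a warning and
  the raw ratio is preserved in an attribute, never silently discarded.

## Confidence intervals

`asymptotic_ci()` gives $\hat\theta \pm z_{1-\alpha}\,\widehat{se}$; it is
only offered where an SE formula exists (the binary framework — the survival
measures have no published SE formulas, and requesting an asymptotic interval
for them is an error rather than a silent approximation).

The bootstrap engine (`bootstrap_measures()`) resamples whole subjects with
replacement and refits *both* nested models on every resample, so the interval
reflects model-fitting variability, not just variability of the measure given
fixed predictions. On top of the replicate distribution:

* `percentile_ci()` — raw empirical quantiles;
* `bc_ci()` — median-bias corrected quantile levels
  $\Phi(2z_0 + z_\alpha)$;
* `bca_ci()` — adds the jackknife acceleration;
* `bootstrap_t_ci()` — studentized pivot, using the measure's asymptotic SE
  formula evaluated on each resample as the inner SE;
* `hybrid_ci()` — percentile endpoints reflected about the point estimate.

Numerical choices that the endpoints depend on, fixed and documented:

* **Quantile rule**: linear interpolation at $h = (B+1)p$ between order
  statistics (`quantile` type 6, the classic bootstrap order-statistic
  convention). BC/BCa endpoints inherit this rule.
* **Failed replicates**: a resample can lose one outcome class, separate the
  logistic fit, or make a measure undefined (degenerate Kaplan–Meier, no
  usable pairs). Such replicates are *skipped and logged*, never redrawn —
  redrawing conditions the bootstrap distribution on success and biases it.
  If fewer than 95% of replicates survive, the distribution is flagged
  unusable and every interval constructor refuses it. Stratified resampling
  (preserving class sizes) is available for very low event counts.
* **Bootstrap-t inner SE**: the binary measures use their own asymptotic SE
  formulas per resample. This is the largest judgment call in the package:
  nothing forces that choice, but it is the natural studentization when a
  formula exists. Survival measures have none, so `bootstrap_t` is simply
  unavailable for them here rather than improvised.
* **Separation**: flagged by the definitional check
  $\min(\eta \mid y=1) \ge \max(\eta \mid y=0)$, because with saturated
  probabilities the gradient can converge numerically long before the
  coefficients diverge.
* **Fit convergence**: Newton–Raphson with step-halving; convergence at
  gradient max-norm $10^{-8}$ or a Newton increment below $10^{-10}$ (at
  mega-sample sizes the absolute gradient criterion alone sits below the
  floating-point noise of the score sum).

## The synthetic cohorts

The generator reproduces the two generative designs the coverage study runs
on, and its defaults *are* those study conditions:

* **Binary framework**: $Y \sim Bernoulli(\pi)$ with $\pi \in \{0.10,
  0.50\}$, and $X \mid Y$ multivariate normal with
  $\mu_0 = (0,0,0,0,0)$, $\mu_1 = (0.7, 0.0, 0.2, 0.5, 0.8)$,
  $\Sigma = I_5$. So `x1` is the strong standard marker (single-marker AUC
  $\Phi(0.7/\sqrt 2) \approx 0.690$) and `x2`–`x5` are null, weak, moderate
  and strong candidates. The number of events is Bernoulli-random, not a
  fixed quota, matching the class-conditional formulation. General positive
  definite $\Sigma$ is accepted for extension studies.
* **Survival framework**: proportional-hazards Weibull failure times with
  shape 2, five iid standard-normal covariates with hazard ratios
  $(2.0, 1.0, 1.2, 1.5, 2.0)$, a 10-year horizon, and either administrative
  (type I) censoring at year 10 or uniform random censoring truncated at
  year 10. Proportional hazards holds *by construction*, which is what makes
  a separate PH diagnostic step unnecessary inside the simulation. The
  baseline scale is calibrated so that the marginal incidence by year 10
  hits its target (10% or 50%). Because the linear predictor under iid
  standard-normal covariates is exactly $N(0, \sum_k (\log HR_k)^2)$, the
  marginal incidence is a one-dimensional Gaussian integral; the calibrator
  solves it by adaptive quadrature plus root finding — deterministic and
  accurate to ~1e-8 — rather than by Monte-Carlo search, and uses the closed
  form $\lambda = \tau / (-\log(1-\pi))^{1/k}$ when all hazard ratios are 1
  (e.g. $\lambda = 10/\sqrt{\ln 2} \approx 12.011$ for 50% incidence).
* The uniform censoring bound is not pinned down by the study conditions;
  the default `random_censoring_max = 2 * followup` yields light censoring
  and is an explicit, reported knob, not a hidden constant.

What the generator deliberately does **not** emulate: correlated predictors,
competing risks, time-varying covariates, informative censoring,
miscalibrated models, missing data. Passing tests therefore speak to the
estimators' behaviour under clean, correctly-specified conditions, not to
robustness on messy clinical data.

```{r example}
design <- binary_design(n = 2000, event_rate = 0.10)
cohort <- generate_binary_cohort(design, seed = 7)
standard <- fit_logistic(cohort, 1)
expanded <- fit_logistic(cohort, c(1, 5))
pairs <- build_risk_pairs(cohort, standard, expanded)
delta_auc(pairs)
idi(pairs)
dists <- bootstrap_measures(cohort, 1, c(1, 5), c("delta_auc", "idi"),
                            B = 400, seed = 11, event_rate = 0.10)
percentile_ci(dists$delta_auc)
bc_ci(dists$idi)
```

## The coverage study

`scenario_config()` describes one grid cell; `run_scenario()` draws `K`
cohorts, builds every requested interval on each, and scores them against a
reference value; `summarize_grid()` applies the acceptable-coverage band.
Decisions worth knowing:

* **Reference truth.** Coverage needs a "true" θ, and for these measures no
  closed form exists in general. `true_value()` uses the plug-in estimate on
  a single mega-cohort (default $10^6$ binary, $10^5$ survival — the overall
  C is quadratic in $n$) with a fixed internal seed, so the truth is a
  constant of the package, not of a particular run. For binary ΔAUC the
  binormal closed form
  $\Phi(\sqrt{0.7^2+\delta^2}/\sqrt 2) - \Phi(0.7/\sqrt 2)$ is computed
  alongside and a disagreement beyond 5 Monte-Carlo SEs is a hard error — it
  would mean the generator or the estimator is wrong, and the run should not
  continue. Note the truth is the *population* value; at small $n$ the
  estimators are biased away from it (most visibly for null markers), and
  that bias is part of what coverage measures.
* **Seeds.** Every repeat and every bootstrap replicate has a seed derived
  hierarchically (`derive_seed()`): scenario → repeat → replicate. Any
  single replicate is reproducible in isolation and results are invariant to
  execution order.
* **Acceptable coverage** is the closed band [94, 96] percent (boundary
  convention made explicit since "94–96%" alone does not state one), and
  every coverage estimate carries its binomial Monte-Carlo SE.
* **Scale.** Published-table scale is K = 1000 repeats with B = 2000
  replicates. The package's own checks run reduced: K = 300 / B = 400 for
  binary bootstrap cells, K = 1000 for asymptotic-only cells, K = 200 /
  B = 300 for survival cells, with n = 10,000 × 300 iterations for the
  distribution-shape diagnostics; outputs always carry (K, B) so desk-scale
  and full-scale results cannot be conflated. The same driver reproduces the
  full grid given proportionally more compute.
* Hybrid and BCa intervals run anywhere on the grid if requested (BCa needs
  the $n$ leave-one-out refits per repeat and is priced accordingly).

```{r coverage, eval = FALSE}
sc <- scenario_config("binary", event_rate = 0.10, marker = "strong",
                      n = 2000, K = 300, B = 400, master_seed = 1)
res <- run_scenario(sc, measures = c("delta_auc", "idi"),
                    methods = c("asymptotic", "percentile", "bc"))
summarize_grid(res)
```

The pattern that emerges — and that the acceptance checks in
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R` recompute — is
that asymptotic intervals for IDI sit far below nominal coverage (their SE
formula underestimates the sampling variability), that percentile intervals
are adequate-to-conservative without paying in width, and that under a null
added marker the estimator distributions are strongly right-skewed with
medians near zero, which is exactly where normal-theory intervals degrade.

## Known limitations

* The bootstrap refits assume the model-fitting step succeeds on most
  resamples; designs with a handful of events need `stratified = TRUE` and
  even then small-sample fits may be fragile.
* The survival NRI(t) subgroup Kaplan–Meier curves can be noisy when a
  movement group is small; no smoothing or shrinkage is applied.
* Inference is within-sample (apparent) discrimination improvement; no
  optimism correction or external validation is attempted.
* Weighted survival NRI$_w$ with $w \ne 0.5$ is computed on the
  class-component scale, not doubled.
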