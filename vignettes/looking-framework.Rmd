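---
title: "The looking framework: models, comparison engine, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The looking framework: models, comparison engine, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

"Vigilance" in behavioural ecology has traditionally been split into
functional categories (anti-predator scanning, social monitoring, mate
guarding) that are hard to score consistently. The looking framework
replaces them with a single observable — *looking*, any interval in which
the focal animal's line of vision extends beyond its hands and immediate
substrate — and asks which of a set of competing hypotheses best predicts
its two summaries within a 30-second focal observation:

* **frequency**: the number of looking bouts, and
* **duration**: the total time spent looking.

Each hypothesis (pre-emptive predator risk, within-group social threat,
feeding compatibility, reaction to recent events, observer effects, and so
on) is encoded as one regression model; the hypotheses are then ranked not
by null-hypothesis tests but by how well each model predicts held-out focal
observations, using leave-one-out cross-validation and Bayesian stacking.
`lookstack` implements the whole chain — synthetic data with the assumed
generative structure, derived predictors, the 21-model set, posterior
sampling, and a from-scratch model-comparison engine — so every stage is
testable without any field data.

## The two observation models

Both responses are modelled with an exposure offset, because the face of
the focal animal is only scoreable while at least half of it is in view
(`in_view_seconds`, at most 30).

**Frequency** uses a Poisson family with log link. For focal $i$ with
design row $x_i$,

$$y_i \sim \text{Poisson}(\lambda_i), \qquad
  \log \lambda_i = x_i^\top\beta + u_{d(i)} + v_{j(i)} + \log t_i,$$

where $t_i$ is the in-view time and $u_d$, $v_j$ are crossed random
intercepts for observation date and individual identity,
$u_d \sim N(0, \sigma_d^2)$, $v_j \sim N(0, \sigma_v^2)$. The unit
coefficient on $\log t_i$ makes the expected count proportional to
exposure.

**Duration** uses a Gaussian family with identity link; the offset enters
untransformed with unit coefficient. The latent duration

$$y_i^* \sim N(\mu_i, \sigma^2), \qquad \mu_i = x_i^\top\beta + u_{d(i)} +
v_{j(i)} + t_i$$

is truncated below at zero (durations cannot be negative) and right
censored at $t_i$: when the animal looks for the whole in-view time, the
recorded value equals $t_i$ and the true duration is only known to exceed
it. Uncensored records contribute
$\phi((y-\mu)/\sigma)/\sigma \,/\, [1 - \Phi(-\mu/\sigma)]$; censored
records contribute $[1 - \Phi((t-\mu)/\sigma)] / [1 - \Phi(-\mu/\sigma)]$.
The shared truncation normaliser makes density plus censor mass integrate
to one, which the test suite verifies by adaptive quadrature.

All location parameters have Student-t(3, 0, 10) priors; random-effect
standard deviations and the residual $\sigma$ have the same t restricted to
the positive half-line. Nothing is centred or scaled: several covariates
are categorical, zero is meaningful for the others (seconds of behaviour,
neighbour counts), and the spatial risk surfaces are already on $[0,1]$.

## The 21-model hypothesis set

`look_model_set(response)` returns the full framework. Model 1 is the
intercept-only null; model 2 the minimal model (age-sex class + behaviour);
models 3–15 add group geometry, feeding compatibility, specific
behaviours, nine time-since-event predictors and the within-group threat
count; models 16–20 interact one spatial risk surface at a time with
neighbour count, spatial position and behaviour; model 21 interacts
observer tolerance with observer distance and movement. Two deliberate
asymmetries:

* the behaviour covariate is time spent *engaged* (hands plus eyes busy)
  for frequency and time spent *not engaged* for duration, because bout
  initiation competes with engaged behaviours while bout length is
  constrained by everything else;
* no risk model mixes two risk variable types, so each hypothesis can be
  weighted on its own.

Time spent resting is excluded from the specific-behaviours model (it is
collinear with the remaining budget); `resting_model_spec()` provides the
companion resting-only specification. The set serialises to JSON
(`write_model_set()`) so hypotheses can be added or disabled without code
changes.

Reference levels are fixed (age-sex: adult-male; habitat: forest;
time-since: no event; position: central; familiarity: core; food item:
none) and categorical terms expand by treatment coding, so a coefficient
always reads as a contrast against the same baseline.

## Posterior computation

`fit_looking()` samples the joint posterior with a seeded, component-wise
adaptive random-walk Metropolis scheme. Each parameter carries its own
proposal scale, adapted during warmup towards the 0.44 acceptance rate that
is optimal for one-dimensional updates; scale parameters move on the log
scale with the Jacobian included; random-intercept updates touch only the
rows of their group, so a sweep costs little more than one full-likelihood
evaluation. Two extra "recentering" proposals shift an entire
random-intercept block and the fixed intercept in opposite directions —
the likelihood is invariant, so the move is cheap, and it removes the slow
mixing between an intercept and the mean of its random effects that plain
single-site samplers suffer from. All parameters initialise at zero on the
sampling scale (so sds and $\sigma$ start at 1), which keeps the first
duration-model evaluations finite even with heavy censoring.

Defaults are a desk-scale half budget (2 chains × 1000 iterations, 500
warmup). `pipeline_config(paper_settings = TRUE)` restores the full budget
of 4 chains × 2000 iterations with 1000 warmup, i.e. 4000 post-warmup
draws. Convergence is summarised by split R-hat and an
initial-positive-sequence effective sample size for every parameter.
Conditional quantities include the sampled random intercepts; marginal
quantities set them to zero — the same distinction as conditional versus
marginal $R^2$.

## The comparison engine

`psis_loo()` computes the expected log pointwise predictive density from
the $S \times n$ pointwise log-likelihood matrix. For each observation the
importance ratios $r_s \propto 1/p(y_i\mid\theta_s)$ are tail-stabilised:
the $M = \min(0.2S,\ 3\sqrt S)$ largest log ratios are replaced with
expected order statistics of a generalized Pareto distribution fitted to
their exceedances by the Zhang–Stephens profile-likelihood method, then
truncated at the largest raw ratio. The fitted shape $\hat k$ is reported
per observation; values above 0.7 flag observations whose leave-one-out
approximation should not be trusted. `exact_loo()` is the brute-force
oracle — $n$ refits, each scoring its held-out observation by the log
posterior-predictive density — and the test suite requires the two to
agree to within 0.05 elpd per observation on a 30-observation Poisson
problem.

`stacking_weights()` maximises the stacked log score
$\sum_i \log \sum_k w_k \exp(\text{elpd}_{ik})$ over the simplex by
projected gradient ascent with backtracking (tolerance $10^{-10}$). The
objective is concave, so the optimum is unique; projection lands exactly on
faces, so pointwise-dominated models get weight exactly 0 and the solver
matches a $10^{-4}$ grid search in tests. Because similar models share
weight under joint optimisation, `restack()` repeats the optimisation on
the subset of models whose first-stage weight reaches a retention threshold
(default 0.001, configurable — the natural reading of "non-zero" at
3-decimal reporting precision). Reports print weights to 3 decimals and
flag weights of at least 0.1 as accurate predictors.

`loo_r2()` reports, per draw,
$R^2 = \operatorname{Var}(\hat y)/(\operatorname{Var}(\hat y) +
\operatorname{Var}(e^{\text{loo}}))$, where $e^{\text{loo}}$ are residuals
against the PSIS-weighted leave-one-out expectation of each observation's
predicted mean. The residual definition in published LOO-$R^2$
implementations varies (some use $1 - \operatorname{Var}(e)/
\operatorname{Var}(y)$, which can go negative); this package pins the
variance-ratio form above and documents it. The marginal variant zeroes
the random intercepts; the conditional variant keeps them, so conditional
$\ge$ marginal whenever the grouping structure carries signal.

## What the synthetic generator emulates — and what it does not

The generator reproduces the statistical structure the models assume, at
the study's design sizes by default: 65 individuals observed over 78 days
with an expected 0.725 focals per individual-day (about 3,700 focals), at
most two focals per individual per day and never two in the same quarter
of a nominal 12-hour day; in-view exposure in (0, 30]; Dirichlet behaviour
budgets scaled to at most 30 s; 638 directed agonistic interactions with a
logistic rank-advantage win rule; clique-structured grooming (4 cliques by
default — a plausible community count for a group of 65, chosen once);
nine homogeneous-Poisson event processes with exponential durations
feeding the six-state time-since coding; and smooth spatial layers — a
utilisation distribution built from smoothed multinomial visit counts, a
predator risk surface from the product-integration of two selection
surfaces, an encounter intensity normalised to 240 encounters, and a
spatially coherent 8-class habitat map.

It does **not** emulate: autocorrelated movement (locations are drawn
independently per focal, weighted by the utilisation distribution),
seasonal or weather structure, observer-specific scoring error,
behavioural dependence between consecutive focals of one individual, or
the field protocol details behind visibility estimation. Passing recovery
tests therefore shows the estimation and comparison machinery is correct
under the assumed generative structure, not that the hypotheses are
identifiable in any particular field dataset.

## Numerical choices and degenerate inputs

* Linear stretch of a constant layer is defined as all zeros (the 0/0
  case); cells never used by the group are masked as no-data in the
  encounter-risk ratio rather than dividing by zero.
* Familiarity classes are terciles of cumulative utilisation *mass*
  (isopleth logic), not of raw cell values, so a location drawn in
  proportion to use falls in each class with probability 1/3.
* Time-since bins are half-open from the event's end: [0,5), [5,10),
  [10,15), [15,∞) minutes; an ongoing event dominates any completed one,
  and among completed events of a type the most recent governs.
* The social-threat count is floored at zero; the set definition cannot go
  negative, the floor just documents intent.
* I&SI ranking is exhaustive up to 8 individuals; larger groups use a
  seeded hill climb over pairwise swaps *and* single-element insertions
  with 10 random restarts — the insertion neighbourhood escapes the local
  optima that swap-only search hits on dense matrices, and the tests
  require exact agreement with the exhaustive optimum on random 6-member
  groups.
* Milliseconds are the recording resolution: generated durations are
  rounded to 3 decimals with the censoring identity
  (`censored` ⇔ `total_look_seconds == in_view_seconds`) preserved exactly,
  so written datasets round-trip byte-identically.
* Every stage derives its own RNG stream deterministically from one master
  seed; identical configuration and seed reproduce reports byte for byte.

## Problem sizes used by the test suite

The automated checks run the machinery at sizes a desk machine handles in
minutes, chosen once as the package's own study-at-reduced-scale: recovery
and coverage experiments use 15 individuals × 15 days (≈300 focals) with
2-chain samplers of 350–600 post-warmup draws, 20 seeded replicates each;
the PSIS-versus-exact oracle uses 30 observations and 2000 draws; stacking
optimality is checked against a $10^{-4}$ grid. The same experiments at
paper-scale settings only sharpen the results.

## Known limitations

* The sampler is a random-walk scheme: for very wide models (habitat ×
  behaviour interactions with many levels) it needs more iterations than a
  gradient-based sampler would, and the effective sample size per draw is
  lower. The `method` argument exists so a gradient-based backend can be
  plugged in without touching the interface.
* `loo_r2()` uses the recorded (censoring-capped) durations when forming
  residuals; for heavily censored datasets the conditional $R^2$ is
  therefore conservative.
* The observer-tolerance score is an input column (a per-individual
  conditional mode from an external flight-initiation-distance model); the
  package does not refit that model.
* Re-stacking reports both stages but, like any stacking procedure, cannot
  distinguish models whose predictive distributions are numerically
  identical — they share weight arbitrarily within the pair.
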