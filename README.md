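# lookstack

Simulation, hierarchical Bayesian modelling and stacking of **looking
behaviour** recorded during 30-second focal observations of group-living
animals.

## The problem this package addresses

Field studies of vigilance in social animals (the motivating system is a
habituated group of chacma baboons) must weigh many competing explanations
for when an animal looks up: pre-emptive predator risk that varies across
the landscape, threats from higher-ranked groupmates, reaction to recent
events (aggression, alarms, encounters with other groups or dogs),
compatibility with feeding, and the observers themselves. The looking
framework encodes each hypothesis as one regression model for a unified
observable — any interval in which the focal animal's line of vision
extends beyond its hands and substrate — and ranks the hypotheses by
out-of-sample predictive performance rather than significance tests.

`lookstack` is aimed at behavioural ecologists who want to apply (or probe)
that framework: it contains a seeded synthetic-data generator with the
exact statistical structure the analysis assumes, the derived predictors,
the full 21-model hypothesis set, a posterior sampler, and a from-scratch
model-comparison engine, so the entire chain can be validated end to end
before any field data are touched.

## The models and the comparison engine

Two responses per focal, each with exposure offset `t` (seconds the face
was in view, ≤ 30) and crossed random intercepts for date `u_d` and
individual `v_j`:

* **bout frequency** — Poisson, log link:
  `y ~ Poisson(exp(x'b + u_d + v_j + log t))`
* **total looking duration** — Gaussian, identity link, latent
  `y* ~ N(x'b + u_d + v_j + t, s^2)` truncated below at 0 and right
  censored at `t` (the recorded duration equals `t` when the animal looked
  for the whole in-view time).

Priors are Student-t(3, 0, 10) on location parameters and half-t(3, 0, 10)
on standard deviations; covariates are neither centred nor scaled.

Hypotheses are compared by PSIS-LOO (Pareto-smoothed importance-sampling
leave-one-out cross-validation, with the generalized-Pareto `k-hat`
reliability diagnostic per observation), Bayesian **stacking** of the
models' LOO predictive densities — simplex weights `w` maximising
`sum_i log sum_k w_k exp(elpd_ik)` — a second **re-stack** of the models
retaining at least 0.001 first-stage weight, and LOO-based Bayesian R²
(marginal = fixed effects only, conditional = fixed + random). All of this
is implemented in the package and cross-checked against brute-force
oracles (exact leave-one-out refits, grid search, quadrature) in the test
suite.

## Worked example

Simulate a 15-individual study (≈300 focals over 15 days), generate bout
counts from the feeding-compatibility hypothesis (model 4), refit, and
stack it against the intercept-only and minimal models:

```r
library(lookstack)

roster    <- simulate_roster(15, 3, seed = 42)
landscape <- simulate_landscape(12, seed = 42)
truth     <- default_true_config("frequency", n_individuals = 15,
                                 n_days = 15, focals_per_day = 1.4,
                                 seed = 42)
focals    <- simulate_focals(roster, landscape, truth)
agonistic <- simulate_agonistic_matrix(roster, 300, 2, seed = 42)
grooming  <- simulate_grooming(roster, seed = 42)

tab    <- derive_analysis_table(focals, roster, agonistic, grooming, landscape)
models <- look_model_set("frequency")
tab    <- generate_looking(tab, models[[4]], truth)

fit <- fit_looking(models[[4]], tab, chains = 2, iter = 2000,
                   warmup = 1000, seed = 1)
round(cbind(estimate = coef(fit), confint(fit)), 3)
#>                           estimate    low   high
#> (Intercept)                 -2.435 -2.724 -2.087
#> amount_eaten                 0.097  0.043  0.156
#> food_itemfruit               0.456  0.126  0.755
#> food_itemseeds              -0.050 -0.350  0.271
#> food_itemroots               0.391  0.097  0.679
#> food_iteminvertebrates       0.738  0.419  1.009
#> food_itemother               0.193 -0.089  0.527
#> engaged_s                   -0.031 -0.043 -0.015
#> age_sex_classadult-female   -0.375 -0.763 -0.070
#> age_sex_classsubadult        0.285  0.000  0.549
#> age_sex_classjuvenile        0.451  0.050  0.766
```

The intervals recover the generating coefficients (intercept −2.3, amount
eaten 0.12, fruit 0.4, invertebrates 0.5, engaged time −0.04, ...): each
estimate is a log-rate contrast against the reference focal (an adult male
eating nothing), and `engaged_s` shows the expected suppression of bout
initiation while hands and eyes are busy.

```r
loos <- list()
for (id in c(4, 1, 2))
  loos[[paste0("model", id)]] <- psis_loo(
    fit_looking(models[[id]], tab, chains = 2, iter = 2000,
                warmup = 1000, seed = id))
restack(stacking_weights(loos), loos)
#> <stack_result> 3 models, objective -593.5661
#>        weight restacked
#> model4  0.917     0.917
#> model1  0.000     0.000
#> model2  0.083     0.083

loo_r2(fit)
#>   marginal R2: 0.450 (0.348, 0.552)
#>   conditional R2: 0.482 (0.406, 0.548)
```

The generating hypothesis takes 0.917 of the stacking weight (weights of
at least 0.1 are flagged as accurate predictors in rendered reports), and
its fixed effects alone explain ~45% of the predicted-future variance.

`run_pipeline(pipeline_config(...))` wraps the whole chain — simulate or
ingest, derive, fit all 21 models for both responses, LOO, stack, re-stack,
R², and render CSV/markdown report tables — reproducibly from one master
seed; `pipeline_config(paper_settings = TRUE)` restores the full 4-chain,
4000-draw sampler budget.

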