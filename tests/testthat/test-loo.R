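test_that("generalized Pareto shapes are recovered from known tails", {
  set.seed(41)
  for (k in c(0.3, 0.1)) {
    x <- 1 / k * ((1 - runif(2000))^(-k) - 1)
    est <- fit_generalized_pareto(x)
    expect_lt(abs(est$k - k), 0.1)
  }
  # exponential tail is the k = 0 limit
  expect_lt(abs(fit_generalized_pareto(rexp(2000))$k), 0.1)
  # degenerate tails are flagged not-estimable
  expect_true(is.na(fit_generalized_pareto(rep(1, 50))$k))
  expect_true(is.na(fit_generalized_pareto(c(1, 2))$k))
})

test_that("PSIS reduces to the single draw when all draws coincide", {
  ll <- matrix(rep(c(-1.3, -0.2, -4.1), each = 300), 300)
  res <- psis_loo(ll)
  expect_equal(res$elpd_i, c(-1.3, -0.2, -4.1))
  expect_equal(res$elpd, sum(res$elpd_i))
})

test_that("elpd decomposes additively with the stated standard error", {
  set.seed(42)
  ll <- matrix(rnorm(500 * 20, -2, 0.3), 500)
  res <- psis_loo(ll)
  expect_equal(res$elpd, sum(res$elpd_i))
  expect_equal(res$se, sqrt(20 * var(res$elpd_i)))
  expect_length(res$pareto_k, 20)
})

test_that("smoothed weights never exceed the maximum raw weight", {
  # a few extreme draws make heavy importance-ratio tails
  set.seed(43)
  ll <- matrix(rnorm(1000 * 5, -2, 1.5), 1000)
  ll[1:3, ] <- -15   # huge raw ratios for these draws
  res <- psis_loo(ll)
  expect_true(all(is.finite(res$elpd_i)))
  # elpd_i can never exceed the best single-draw log score bound
  expect_true(all(res$elpd_i <= apply(ll, 2, max) + 1e-9))
})

test_that("non-finite likelihood rows are reported by observation", {
  ll <- matrix(-1, 50, 4)
  ll[3, 2] <- NaN
  expect_error(psis_loo(ll), "observation\\(s\\) 2")
})

test_that("exact leave-one-out treats duplicated observations symmetrically", {
  tab <- slope_table(10, seed = 44)
  tab <- rbind(tab, tab[5, ])   # duplicate one record
  spec <- look_spec(1, "frequency", "x", "slope")
  res <- exact_loo(spec, tab, chains = 2, iter = 600, warmup = 300, seed = 45,
                   random_effects = FALSE)
  expect_length(res$elpd_i, 11)
  expect_lt(abs(res$elpd_i[5] - res$elpd_i[11]), 0.1)
})

test_that("stacking solves the simplex optimisation exactly", {
  # a single model takes all the weight
  e1 <- matrix(rnorm(30), 30, 1)
  expect_equal(unname(stacking_weights(e1)$weights), 1)
  # pointwise dominance forces the vertex
  E <- cbind(a = rep(-1, 25), b = rep(-1.4, 25))
  w <- stacking_weights(E)$weights
  expect_equal(unname(w), c(1, 0))
  expect_error(stacking_weights(matrix(0, 3, 0)), "no models")
})

test_that("solver weights match a fine grid search for two models", {
  set.seed(46)
  for (r in 1:3) {
    E <- cbind(rnorm(40, -2, 0.6), rnorm(40, -2.1, 0.6))
    w <- stacking_weights(E)$weights
    grid <- seq(0, 1, by = 1e-4)
    obj <- vapply(grid, function(a)
      sum(log(a * exp(E[, 1]) + (1 - a) * exp(E[, 2]))), 0)
    expect_lt(abs(w[1] - grid[which.max(obj)]), 1e-4 + 1e-8)
  }
})

test_that("duplicated models share weight without changing the optimum", {
  set.seed(47)
  E <- cbind(m1 = rnorm(50, -2, 0.5), m2 = rnorm(50, -2.2, 0.5))
  s2 <- stacking_weights(E)
  s3 <- stacking_weights(cbind(E, m2copy = E[, 2]))
  expect_lt(abs(s2$objective - s3$objective), 1e-8)
  expect_equal(unname(s3$weights[2] + s3$weights[3]), unname(s2$weights[2]),
               tolerance = 1e-5)
})

test_that("re-stacking keeps only models above the retention threshold", {
  set.seed(48)
  E <- cbind(good = rnorm(60, -1, 0.4), ok = rnorm(60, -1.1, 0.4),
             bad = rnorm(60, -8, 0.4))
  s <- stacking_weights(E)
  s <- restack(s, E)
  expect_false(3 %in% s$retained_ids)
  expect_equal(sum(s$restacked_weights), 1, tolerance = 1e-8)
  expect_equal(s$restacked_weights[["bad"]], 0)

  # all weight on one model: restack returns that model alone
  Ed <- cbind(a = rep(-1, 20), b = rep(-3, 20))
  sd_ <- restack(stacking_weights(Ed), Ed)
  expect_equal(unname(sd_$restacked_weights), c(1, 0))
  # threshold above the maximum weight is a guard error
  expect_error(restack(stacking_weights(Ed), Ed, threshold = 1.1 * 1),
               "no model")

  # the retained-subset optimum dominates the renormalised initial weights
  keep <- s$retained_ids
  w0 <- s$weights[keep] / sum(s$weights[keep])
  obj <- function(w, M) sum(log(exp(M) %*% w))
  expect_gte(obj(s$restacked_weights[keep], E[, keep]) + 1e-10,
             obj(w0, E[, keep]))
})

test_that("LOO R-squared approaches 1 for a near-deterministic signal", {
  # huge Poisson counts: relative noise vanishes, predictor ~ response
  set.seed(49)
  n <- 40
  x <- runif(n, 0, 2)
  tab <- data.frame(individual_id = "A", date = "D1", x = x,
                    in_view_seconds = rep(1, n),
                    n_looks = rpois(n, exp(7 + 1.2 * x)))
  spec <- look_spec(1, "frequency", "x", "slope")
  f <- fit_looking(spec, tab, chains = 2, iter = 1000, warmup = 500, seed = 50,
                   random_effects = FALSE)
  r2 <- loo_r2(f, "marginal")
  expect_gt(r2$estimate, 0.95)
})

test_that("LOO R-squared sits near zero for a pure-noise intercept model", {
  set.seed(51)
  n <- 60
  tab <- data.frame(individual_id = "A", date = "D1",
                    in_view_seconds = rep(1, n), n_looks = rpois(n, 3))
  f <- fit_looking(look_spec(1, "frequency", "1", "null"), tab, chains = 2,
                   iter = 800, warmup = 400, seed = 52, random_effects = FALSE)
  r2 <- loo_r2(f)
  expect_lt(abs(r2$estimate[r2$variant == "marginal"]), 0.05)
})

test_that("LOO R-squared matches a direct recomputation from its parts", {
  set.seed(53)
  n <- 40
  x <- runif(n, 0, 2)
  tab <- data.frame(individual_id = "A", date = "D1", x = x,
                    in_view_seconds = rep(10, n),
                    n_looks = rpois(n, exp(0.2 + 0.8 * x + log(10))))
  f <- fit_looking(look_spec(1, "frequency", "x", "slope"), tab, chains = 2,
                   iter = 800, warmup = 400, seed = 54,
                   random_effects = FALSE)
  r2 <- loo_r2(f, "conditional")
  # oracle: plain importance weights (valid here: k-hat far below 0.7)
  expect_true(all(psis_loo(f)$pareto_k < 0.7, na.rm = TRUE))
  MU <- predict(f, summary = FALSE)
  W <- exp(-f$loglik)
  W <- sweep(W, 2, colSums(W), "/")
  e <- tab$n_looks - colSums(W * MU)
  r2_draws <- apply(MU, 1, var) / (apply(MU, 1, var) + var(e))
  expect_equal(r2$estimate, mean(r2_draws), tolerance = 0.02)
  expect_true(r2$low <= r2$estimate && r2$estimate <= r2$high)
})
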