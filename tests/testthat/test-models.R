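test_that("the hypothesis set matches the research framework", {
  for (resp in c("frequency", "duration")) {
    ms <- look_model_set(resp)
    expect_length(ms, 21)
    behaviour <- if (resp == "frequency") "engaged_s" else "not_engaged_s"
    # model 1 is intercept-only; all others carry age-sex class
    expect_equal(ms[[1]]$rhs, "1")
    for (i in 2:21)
      expect_true(grepl("age_sex_class", ms[[i]]$rhs))
    # behaviour covariate in all models except 1 and 5
    for (i in setdiff(2:21, 5))
      expect_true(grepl(behaviour, ms[[i]]$rhs), label = paste("model", i))
    expect_false(grepl(behaviour, ms[[5]]$rhs))
    # model 2 is the minimal model
    expect_equal(ms[[2]]$rhs, paste0("age_sex_class + ", behaviour))
    # model 5: twelve specific behaviours, resting excluded
    expect_equal(sum(gregexpr("behav_", ms[[5]]$rhs)[[1]] > 0), 12)
    expect_false(grepl("behav_rest\\b", ms[[5]]$rhs))
    # reactionary models carry no interactions
    for (i in 6:15) expect_false(grepl("\\*", ms[[i]]$rhs))
    # group-geometry and pre-emptive risk models carry the printed interactions
    expect_true(grepl("n_neighbours \\* spatial_position", ms[[3]]$rhs))
    risks <- c("leopard_rsf", "habitat", "inverted_ud", "familiarity",
               "encounter_risk")
    for (k in seq_along(risks)) {
      rhs <- ms[[15 + k]]$rhs
      expect_true(grepl(sprintf(
        "%s \\* \\(n_neighbours \\+ spatial_position \\+ %s\\)",
        risks[k], behaviour), rhs))
      expect_true(grepl("visibility \\+ rank", rhs))
      # no risk model mixes two risk variable types
      expect_false(any(vapply(setdiff(risks, risks[k]), grepl, TRUE, x = rhs)))
    }
    # observer model: tolerance interacting with distance, movement, behaviour
    expect_true(grepl(sprintf(
      "tolerance \\* \\(observer_distance_m \\+ observer_moved \\+ %s\\)",
      behaviour), ms[[21]]$rhs))
    # visibility/rank/position carried exactly where printed
    expect_true(all(grepl("visibility", vapply(ms[c(6, 9, 10, 12:20)],
                                               `[[`, "", "rhs"))))
    expect_false(any(grepl("visibility", vapply(ms[c(2, 4, 7, 8, 11, 21)],
                                                `[[`, "", "rhs"))))
    expect_equal(ms[[14]]$rhs,
      paste0("ts_group_encounter + age_sex_class + ", behaviour,
             " + visibility + spatial_position + rank + n_neighbours"))
    fams <- unique(vapply(ms, `[[`, "", "family"))
    expect_equal(fams, if (resp == "frequency") "poisson_log"
                       else "censored_truncated_normal_identity")
  }
  expect_true(grepl("behav_rest", resting_model_spec("frequency")$rhs))
  expect_error(look_model_set("speed"))
})

test_that("model sets serialise to JSON and back", {
  ms <- look_model_set("duration")
  f <- withr::local_tempfile(fileext = ".json")
  write_model_set(ms, f)
  back <- read_model_set(f)
  expect_length(back, 21)
  for (i in c(1, 5, 15, 21)) {
    expect_equal(back[[i]]$rhs, ms[[i]]$rhs)
    expect_equal(back[[i]]$family, ms[[i]]$family)
    expect_equal(back[[i]]$priors, ms[[i]]$priors)
  }
})

test_that("design matrices expand with treatment coding, uncentred", {
  tab <- data.frame(
    individual_id = c("a", "b", "c"), date = c("d1", "d1", "d2"),
    age_sex_class = factor(c("adult-male", "adult-female", "adult-male"),
                           levels = age_sex_levels()),
    engaged_s = c(1.5, 0, 20))
  X <- build_design(look_model_set("frequency")[[2]], tab)
  expect_equal(ncol(X), 3)   # intercept + 1 observed dummy + engaged time
  expect_equal(colnames(X),
               c("(Intercept)", "age_sex_classadult-female", "engaged_s"))
  expect_equal(X[, "engaged_s"], c(1.5, 0, 20), ignore_attr = TRUE)  # raw scale

  # interaction of a 3-level factor with a continuous term: 2 product columns
  tab2 <- data.frame(f = factor(c("x", "y", "z", "x")), v = 1:4)
  sp <- look_spec(1, "frequency", "f * v", "toy")
  X2 <- build_design(sp, tab2)
  expect_equal(ncol(X2), 6)
  expect_equal(sum(grepl(":", colnames(X2))), 2)
  expect_equal(X2[, "fy:v"], c(0, 2, 0, 0), ignore_attr = TRUE)

  # hand-built oracle for the within-group-threat model on a 5-row toy table
  toy <- data.frame(
    individual_id = letters[1:5], date = paste0("d", c(1, 1, 2, 2, 3)),
    n_social_threats = c(0, 1, 2, 0, 1),
    age_sex_class = factor(c("adult-male", "adult-female", "juvenile",
                             "adult-male", "subadult"),
                           levels = age_sex_levels()),
    engaged_s = c(3, 8, 0, 12, 5), visibility = c(40, 55, 70, 20, 90),
    rank = c(2, 5, 1, 3, 4), n_neighbours = c(1, 0, 4, 2, 3))
  X15 <- build_design(look_model_set("frequency")[[15]], toy)
  hand <- cbind(1, toy$n_social_threats,
                toy$age_sex_class == "adult-female",
                toy$age_sex_class == "subadult",
                toy$age_sex_class == "juvenile",
                toy$engaged_s, toy$visibility, toy$rank, toy$n_neighbours)
  expect_equal(unname(X15[, c("(Intercept)", "n_social_threats",
                              "age_sex_classadult-female",
                              "age_sex_classsubadult", "age_sex_classjuvenile",
                              "engaged_s", "visibility", "rank",
                              "n_neighbours")]),
               unname(hand * 1))

  expect_error(build_design(look_model_set("frequency")[[15]], tab),
               "missing columns")
})

test_that("the Poisson likelihood is exact and proper", {
  expect_equal(loglik_frequency(0, 0, 1), -1)
  # offset law: doubling exposure adds log 2 to the log rate
  l1 <- loglik_frequency(3, 0.7, 10)
  l2 <- dpois(3, exp(0.7 + log(10)), log = TRUE)
  expect_equal(l1, l2)
  # tail-sums to one
  for (lp in c(-1, 0, 1.5)) for (iv in c(1, 30)) {
    p <- sum(exp(loglik_frequency(0:500, lp, iv)))
    expect_equal(p, 1, tolerance = 1e-9)
  }
  expect_error(loglik_frequency(1, 0, 0), "in_view")
})

test_that("the censored truncated Gaussian likelihood is exact and proper", {
  # half-normal closed form at the origin
  expect_equal(loglik_duration(0, FALSE, 0, 1, 1e6), log(2 / sqrt(2 * pi)))
  # censored mass approaches 1 when the mean is far beyond the cap
  expect_gt(loglik_duration(30, TRUE, 1e4, 1, 30), -1e-6)
  expect_lte(loglik_duration(30, TRUE, 1e4, 1, 30), 0)
  # monotone increasing in mu for a censored record
  mus <- seq(-5, 40, length.out = 50)
  lls <- loglik_duration(rep(30, 50), TRUE, mus, 4, 30)
  expect_true(all(diff(lls) > 0))
  # density plus censor mass integrates to one
  set.seed(12)
  for (i in 1:25) {
    mu <- runif(1, -10, 40); sig <- runif(1, 0.5, 8); cap <- runif(1, 5, 35)
    dens <- integrate(function(y) exp(loglik_duration(y, FALSE, mu, sig, cap)),
                      0, cap, rel.tol = 1e-10)$value
    mass <- exp(loglik_duration(cap, TRUE, mu, sig, cap))
    expect_equal(dens + mass, 1, tolerance = 1e-7)
  }
  expect_error(loglik_duration(5, FALSE, 0, -1, 30), "sigma")
  expect_error(loglik_duration(31, FALSE, 0, 1, 30), "exceeds")
  expect_error(loglik_duration(5, TRUE, 0, 1, 30), "censored")
})

test_that("priors have the stated Student-t form", {
  # closed form of the scaled t(3, 0, 10) density at zero
  expect_equal(log_prior(0),
               log(gamma(2) / (gamma(1.5) * sqrt(3 * pi)) / 10))
  expect_equal(log_prior(numeric(0), scales = -1), -Inf)
  # prior integrates to one in 1-D
  co <- integrate(function(b) exp(vapply(b, log_prior, 0)), -Inf, Inf,
                  rel.tol = 1e-9)$value
  expect_equal(co, 1, tolerance = 1e-6)
  sc <- integrate(function(s)
    exp(vapply(s, function(x) log_prior(numeric(0), scales = x), 0)),
    0, Inf, rel.tol = 1e-9)$value
  expect_equal(sc, 1, tolerance = 1e-6)
})
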