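test_that("roster satisfies its invariants", {
  r2 <- simulate_roster(2, 1, seed = 1)
  expect_setequal(r2$latent_rank, 1:2)
  expect_equal(unique(r2$clique_label), 1L)

  r65 <- simulate_roster(65, 5, seed = 2)
  expect_equal(length(unique(r65$individual_id)), 65)
  expect_setequal(r65$latent_rank, 1:65)
  sizes <- table(r65$clique_label)
  expect_true(max(sizes) - min(sizes) <= 1)

  # tolerance scores centred at zero
  means <- vapply(1:200, function(s)
    mean(simulate_roster(10, 3, seed = s)$tolerance_score), 0)
  expect_true(all(abs(means) < 1e-5))

  expect_error(simulate_roster(1, 1), ">= 2")
  expect_error(simulate_roster(5, 9), "n_cliques")
})

test_that("landscape layers have the advertised structure", {
  land <- simulate_landscape(4, seed = 1)
  for (nm in c("ud", "leopard_rsf", "encounter_intensity", "habitat"))
    expect_equal(dim(land[[nm]]), c(4L, 4L))
  for (nm in c("ud", "leopard_rsf")) {
    v <- land[[nm]]$values
    expect_true(all(is.finite(v) & v >= 0 & v <= 1))
  }
  expect_true(all(land$habitat$values %in% 1:8))
  expect_error(simulate_landscape(3), "grid_n")

  # encounter intensity integrates to the configured total mass
  land2 <- simulate_landscape(16, seed = 3, encounter_total = 240)
  expect_equal(sum(land2$encounter_intensity$values), 240, tolerance = 1e-5)

  # smoothness: neighbouring cells are positively correlated
  big <- simulate_landscape(24, seed = 4)
  v <- big$ud$values
  expect_gt(cor(as.vector(v[-1, ]), as.vector(v[-nrow(v), ])), 0)
})

test_that("focal sampling design honours the per-day rules", {
  sm <- small_study()
  foc <- sm$focals
  per_day <- table(foc$individual_id, foc$date)
  expect_true(all(per_day <= 2))
  per_period <- aggregate(rep(1, nrow(foc)),
                          foc[c("individual_id", "date", "time_period")], sum)
  expect_true(all(per_period$x == 1))
  expect_true(all(foc$in_view_seconds > 0 & foc$in_view_seconds <= 30))
  beh <- rowSums(foc[, grep("^behav_", names(foc))])
  expect_true(all(beh <= 30 + 1e-9))
})

test_that("zero event rates give all-quiet event clocks", {
  roster <- simulate_roster(4, 2, seed = 9)
  land <- simulate_landscape(6, seed = 9)
  rates <- setNames(rep(0, 9), event_types())
  cfg <- look_true_config(n_individuals = 4, n_days = 4, focals_per_day = 2,
                          event_rates = rates, seed = 9)
  foc <- simulate_focals(roster, land, cfg)
  for (ev in event_types()) {
    expect_true(all(is.na(foc[[paste0("ev_", ev, "_elapsed")]])))
    expect_false(any(foc[[paste0("ev_", ev, "_ongoing")]]))
  }
})

test_that("ongoing-event fraction matches the busy probability of the event process", {
  # M/G/infinity: P(some event ongoing) = 1 - exp(-rate * mean duration)
  rates <- setNames(rep(0, 9), event_types())
  durs <- setNames(rep(1, 9), event_types())
  rates["male_call"] <- 6    # per hour
  durs["male_call"] <- 3     # minutes
  roster <- simulate_roster(20, 4, seed = 11)
  land <- simulate_landscape(8, seed = 11)
  cfg <- look_true_config(n_individuals = 20, n_days = 60, focals_per_day = 1.7,
                          event_rates = rates, event_durations = durs, seed = 11)
  foc <- simulate_focals(roster, land, cfg)
  expect_gt(nrow(foc), 1500)
  p_hat <- mean(foc$ev_male_call_ongoing)
  p_exp <- 1 - exp(-(6 / 60) * 3)
  se <- sqrt(p_exp * (1 - p_exp) / nrow(foc))
  expect_lt(abs(p_hat - p_exp), 4 * se)
})

test_that("agonistic matrices respect rank structure and totals", {
  roster <- simulate_roster(10, 2, seed = 13)
  M <- simulate_agonistic_matrix(roster, 638, steepness = 2, seed = 13)
  expect_equal(sum(M), 638)

  # near-infinite steepness: perfectly transitive
  Mt <- simulate_agonistic_matrix(roster, 500, steepness = 50, seed = 14)
  ord <- order(roster$latent_rank)
  upper <- Mt[ord, ord]
  expect_true(all(upper[lower.tri(upper)] == 0))

  # zero steepness: wins split evenly regardless of rank
  M0 <- simulate_agonistic_matrix(roster, 10000, steepness = 0, seed = 15)
  up <- sum(M0[ord, ord][upper.tri(M0)])
  expect_lt(abs(up / 10000 - 0.5), 3 * sqrt(0.25 / 10000))

  # win fraction of i over j non-decreasing in rank advantage
  Ms <- simulate_agonistic_matrix(simulate_roster(6, 2, seed = 16), 20000,
                                  steepness = 0.5, seed = 16)
  ros <- simulate_roster(6, 2, seed = 16)
  adv <- outer(ros$latent_rank, ros$latent_rank, function(a, b) b - a)
  tot <- Ms + t(Ms)
  frac <- ifelse(tot > 0, Ms / tot, NA)
  o <- order(adv[upper.tri(adv) | lower.tri(adv)])
  f <- frac[upper.tri(frac) | lower.tri(frac)][o]
  a <- adv[upper.tri(adv) | lower.tri(adv)][o]
  grp <- tapply(f, a, mean, na.rm = TRUE)
  expect_true(all(diff(grp[!is.na(grp)]) > -0.12))
})

test_that("grooming is clique-structured", {
  roster <- simulate_roster(18, 3, seed = 17)
  G <- simulate_grooming(roster, within_rate = 5, between_rate = 0.3, seed = 17)
  expect_true(isSymmetric(G))
  same <- outer(roster$clique_label, roster$clique_label, "==")
  expect_gt(mean(G[same & upper.tri(G)]), mean(G[!same & upper.tri(G)]))

  G0 <- simulate_grooming(roster, within_rate = 5, between_rate = 0, seed = 18)
  lab <- detect_cliques(G0)
  expect_equal(adjusted_rand(lab, roster$clique_label), 1)
})

test_that("generators are deterministic under a fixed seed", {
  a <- simulate_roster(8, 2, seed = 21)
  b <- simulate_roster(8, 2, seed = 21)
  expect_identical(a, b)
  la <- simulate_landscape(8, seed = 21)
  lb <- simulate_landscape(8, seed = 21)
  expect_identical(la, lb)
  cfg <- look_true_config(n_individuals = 8, n_days = 3, seed = 21)
  expect_identical(simulate_focals(a, la, cfg), simulate_focals(b, lb, cfg))
})

test_that("looking responses follow the generative families", {
  # zero effects, no random noise, fixed exposure: mean count = exposure
  n <- 100000
  tab <- data.frame(individual_id = "A", date = "D1",
                    in_view_seconds = rep(30, n))
  spec <- look_spec(1, "frequency", "1", "null")
  cfg <- look_true_config("frequency", model_id = 1,
                          coefficients = c("(Intercept)" = 0),
                          re_sd_date = 0, re_sd_individual = 0, seed = 23)
  out <- generate_looking(tab, spec, cfg)
  se <- sqrt(30 / n)
  expect_lt(abs(mean(out$n_looks) - 30), 3 * se)

  # doubling the exposure doubles the mean count
  tab2 <- tab; tab2$in_view_seconds <- 15
  cfg2 <- cfg; class(cfg2) <- class(cfg)
  out2 <- generate_looking(tab2, spec, cfg2)
  expect_lt(abs(mean(out$n_looks) / mean(out2$n_looks) - 2), 0.05)

  # duration far above the cap: everything censored at the in-view time
  dspec <- look_spec(1, "duration", "1", "null")
  dcfg <- look_true_config("duration", model_id = 1,
                           coefficients = c("(Intercept)" = 100),
                           re_sd_date = 0, re_sd_individual = 0, sigma = 1,
                           seed = 24)
  dtab <- data.frame(individual_id = "A", date = "D1",
                     in_view_seconds = runif(200, 20, 30))
  dout <- generate_looking(dtab, dspec, dcfg)
  expect_true(all(dout$censored))
  expect_equal(dout$total_look_seconds, dout$in_view_seconds)

  # censoring invariant on a mixed configuration
  mcfg <- look_true_config("duration", model_id = 1,
                           coefficients = c("(Intercept)" = -5), sigma = 8,
                           seed = 25)
  mout <- generate_looking(dtab, dspec, mcfg)
  expect_true(all(mout$total_look_seconds <= mout$in_view_seconds))
  expect_equal(mout$censored,
               mout$total_look_seconds == mout$in_view_seconds)
  expect_true(all(mout$total_look_seconds >= 0))

  expect_error(generate_looking(tab, spec,
    look_true_config("frequency", model_id = 1,
                     coefficients = c(wrong_name = 1), seed = 1)),
    "no coefficient")
})
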