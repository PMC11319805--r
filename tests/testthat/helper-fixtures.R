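# Shared fixtures, built once per test run.

# small simulated study: 12 individuals, 10 days, ~170 focals
small_study <- local({
  cache <- NULL
  function(seed = 5) {
    if (!is.null(cache)) return(cache)
    roster <- simulate_roster(12, 3, seed = seed)
    land <- simulate_landscape(12, seed = seed)
    cfg <- look_true_config(n_individuals = 12, n_days = 10,
                            focals_per_day = 1.4, seed = seed)
    foc <- simulate_focals(roster, land, cfg)
    agon <- simulate_agonistic_matrix(roster, 300, 2, seed = seed)
    groom <- simulate_grooming(roster, seed = seed)
    tab <- derive_analysis_table(foc, roster, agon, groom, land)
    cache <<- list(roster = roster, land = land, cfg = cfg, focals = foc,
                   agonistic = agon, grooming = groom, table = tab)
    cache
  }
})

# medium study used by the recovery experiments (~300 focals)
make_study <- function(seed, n_ind = 15, n_days = 15, fpd = 1.4, grid_n = 12) {
  roster <- simulate_roster(n_ind, 3, seed = seed)
  land <- simulate_landscape(grid_n, seed = seed)
  cfg <- look_true_config(n_individuals = n_ind, n_days = n_days,
                          focals_per_day = fpd, seed = seed)
  foc <- simulate_focals(roster, land, cfg)
  agon <- simulate_agonistic_matrix(roster, 300, 2, seed = seed)
  groom <- simulate_grooming(roster, seed = seed)
  tab <- derive_analysis_table(foc, roster, agon, groom, land)
  list(roster = roster, land = land, table = tab)
}

# intercept+slope Poisson table with no grouping structure
slope_table <- function(n, b0 = 0.4, b1 = 0.6, seed = 7) {
  set.seed(seed)
  x <- stats::runif(n, 0, 2)
  data.frame(individual_id = "A", date = "D1", x = x,
             in_view_seconds = rep(1, n),
             n_looks = stats::rpois(n, exp(b0 + b1 * x)))
}

# adjusted Rand index between two labellings (contingency-table form)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
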