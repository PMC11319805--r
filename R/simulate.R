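#' Controlled behaviour vocabulary
#'
#' Behaviours scored during a 30-s focal, split by whether they demand visual
#' attention and use of the hands ("engaged") or leave the eyes free
#' ("not engaged"). Engaged time constrains concurrent looking and enters the
#' bout-frequency models; not-engaged time enters the duration models.
#'
#' @return named list with character vectors `engaged` and `not_engaged`.
#' @export
behaviour_vocabulary <- function() {
  list(
    engaged = c("give_groom", "self_groom", "digging", "search_substrate",
                "pick", "aggression_play"),
    not_engaged = c("rest", "chewing", "mating", "self_scratch",
                    "receive_groom", "drink", "movement", "communication",
                    "biting", "handling", "posture")
  )
}

#' Event types tracked for the time-since-event predictors
#' @return character vector of the nine event types.
#' @export
event_types <- function() {
  c("aggression", "mating", "female_call", "male_call", "hetero_active",
    "hetero_passive", "dog", "alarm", "group_encounter")
}

#' Age-sex class levels (reference level first)
#' @return character vector of length 4.
#' @export
age_sex_levels <- function() {
  c("adult-male", "adult-female", "subadult", "juvenile")
}

#' Food item categories
#' @return character vector.
#' @export
food_item_levels <- function() {
  c("none", "fruit", "seeds", "roots", "invertebrates", "other")
}

#' Time-since-event category levels
#' @return character vector of the six ordered states.
#' @export
time_since_levels <- function() {
  c("no_event", "ongoing", "post_0_5", "post_5_10", "post_10_15", "post_gt15")
}

# deterministic sub-seed derivation; kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 9973) %% 2147483399 + 1)
}

#' Simulate a group roster
#'
#' Draws a study group with unique ids, age-sex classes, a latent dominance
#' order (a permutation of 1..N, 1 = top), balanced grooming-clique labels
#' (sizes differing by at most one) and individual observer-tolerance scores
#' centred at zero (emulating conditional modes from an external
#' flight-initiation-distance model).
#'
#' @param n_individuals group size (>= 2). Default 65, a typical non-infant
#'   head count for a large habituated baboon group.
#' @param n_cliques number of grooming cliques (1..n_individuals). Default 4.
#' @param seed integer seed.
#' @param tolerance_sd spread of the tolerance scores.
#' @return data.frame of class `look_roster`.
#' @export
simulate_roster <- function(n_individuals = 65, n_cliques = 4, seed = 1,
                            tolerance_sd = 1) {
  if (n_individuals < 2) stop("simulate_roster: n_individuals must be >= 2")
  if (n_cliques < 1 || n_cliques > n_individuals)
    stop("simulate_roster: n_cliques must be in 1..n_individuals")
  set.seed(derive_seed(seed, 1L))
  n <- n_individuals
  ids <- sprintf("ID%02d", seq_len(n))
  cls <- sample(age_sex_levels(), n, replace = TRUE,
                prob = c(0.15, 0.35, 0.2, 0.3))
  rank <- sample.int(n)
  clique <- sample(rep_len(seq_len(n_cliques), n))
  tol <- stats::rnorm(n, 0, tolerance_sd)
  tol <- round(tol - mean(tol), 6)   # centred, as conditional modes are
  out <- data.frame(individual_id = ids,
                    age_sex_class = factor(cls, levels = age_sex_levels()),
                    latent_rank = rank,
                    clique_label = clique,
                    tolerance_score = tol,
                    stringsAsFactors = FALSE)
  class(out) <- c("look_roster", "data.frame")
  out
}

#' Simulate the spatial layers
#'
#' Builds the gridded surfaces the pre-emptive-risk models consume. The
#' utilisation distribution (UD) comes from smoothed multinomial visit counts
#' on the grid (a stand-in for a home-range estimator: only the downstream
#' [0,1] surface matters), the predator risk layer from the scale integration
#' of two smooth selection surfaces, the encounter-intensity layer from a
#' smooth field normalised to a configured total encounter mass, and the
#' habitat layer from quantile bands of a further smooth field so classes are
#' spatially coherent.
#'
#' @param grid_n grid edge length in cells (>= 4).
#' @param seed integer seed.
#' @param n_visits number of ranging fixes to allocate across cells.
#' @param encounter_total total encounter mass to spread over the grid
#'   (default 240 recorded inter-group encounters).
#' @return named list of [spatial_layer()]s: `ud`, `leopard_rsf`,
#'   `encounter_intensity`, `habitat` (plus the raw `rsf2`, `rsf3`
#'   components).
#' @export
simulate_landscape <- function(grid_n = 24, seed = 1, n_visits = 11936,
                               encounter_total = 240) {
  if (grid_n < 4) stop("simulate_landscape: grid_n must be >= 4")
  set.seed(derive_seed(seed, 2L))
  field <- function(passes = 3L)
    smooth_matrix(matrix(stats::rnorm(grid_n^2), grid_n), passes)

  intensity <- exp(2 * field())
  p <- as.vector(intensity) / sum(intensity)
  visits <- matrix(as.numeric(stats::rmultinom(1, n_visits, p)), grid_n)
  ud <- spatial_layer(round(linear_stretch(smooth_matrix(visits, 2L)), 8),
                      kind = "ud")

  rsf2 <- spatial_layer(round(linear_stretch(field()), 8), kind = "leopard_rsf")
  rsf3 <- spatial_layer(round(linear_stretch(field()), 8), kind = "leopard_rsf")
  leopard <- integrate_rsf(rsf2, rsf3)
  leopard$values <- round(leopard$values, 8)

  enc <- exp(1.5 * field())
  enc <- enc / sum(enc) * encounter_total
  encounter <- spatial_layer(round(enc, 8), kind = "encounter_risk")

  hab_field <- field()
  br <- stats::quantile(hab_field, probs = seq(0, 1, length.out = 9))
  hab <- matrix(as.integer(cut(hab_field, breaks = br, include.lowest = TRUE)),
                grid_n)
  habitat <- spatial_layer(hab * 1.0, kind = "habitat")

  list(ud = ud, leopard_rsf = leopard, encounter_intensity = encounter,
       habitat = habitat, rsf2 = rsf2, rsf3 = rsf3)
}

#' Generative configuration for a synthetic looking dataset
#'
#' Bundles the true-model settings used by [generate_looking()] and the
#' sampling-design sizes used by [simulate_focals()]. Defaults mirror the
#' study design: 65 individuals over 78 observation days with an expected
#' 0.725 focals per individual-day (~3676 focals in total), nine ad-libitum
#' event processes, and crossed date-by-individual random intercepts.
#'
#' @param response `"frequency"` or `"duration"`.
#' @param model_id which hypothesis model (1..21) generates the response.
#' @param coefficients named numeric vector matching the design columns of
#'   the chosen model (see [build_design()]).
#' @param re_sd_date,re_sd_individual random-intercept standard deviations.
#' @param sigma residual sd (duration response only).
#' @param n_individuals,n_days,focals_per_day sampling-design sizes;
#'   `focals_per_day` is the expected number of focals per individual per day
#'   (at most 2 are ever scheduled, never 2 in one time period).
#' @param event_rates named per-hour rates for the nine [event_types()].
#' @param event_durations named mean event durations in minutes.
#' @param seed integer master seed.
#' @return list of class `look_true_config`.
#' @export
look_true_config <- function(response = c("frequency", "duration"),
                             model_id = 2L,
                             coefficients = NULL,
                             re_sd_date = 0.1,
                             re_sd_individual = 0.1,
                             sigma = 2,
                             n_individuals = 65L,
                             n_days = 78L,
                             focals_per_day = 0.725,
                             event_rates = NULL,
                             event_durations = NULL,
                             seed = 1L) {
  response <- match.arg(response)
  default_rates <- c(aggression = 1.5, mating = 0.3, female_call = 0.8,
                     male_call = 0.5, hetero_active = 0.15,
                     hetero_passive = 0.3, dog = 0.05, alarm = 0.2,
                     group_encounter = 0.1)
  default_dur <- c(aggression = 1, mating = 0.5, female_call = 0.5,
                   male_call = 0.5, hetero_active = 5, hetero_passive = 5,
                   dog = 5, alarm = 2, group_encounter = 15)
  if (is.null(event_rates)) event_rates <- default_rates
  if (is.null(event_durations)) event_durations <- default_dur
  stopifnot(all(event_types() %in% names(event_rates)),
            all(event_types() %in% names(event_durations)))
  if (any(event_rates < 0)) stop("look_true_config: event rates must be >= 0")
  if (re_sd_date < 0 || re_sd_individual < 0 || sigma <= 0)
    stop("look_true_config: invalid variance components")
  structure(list(response = response, model_id = as.integer(model_id),
                 coefficients = coefficients, re_sd_date = re_sd_date,
                 re_sd_individual = re_sd_individual, sigma = sigma,
                 n_individuals = as.integer(n_individuals),
                 n_days = as.integer(n_days),
                 focals_per_day = focals_per_day,
                 event_rates = event_rates[event_types()],
                 event_durations = event_durations[event_types()],
                 seed = as.integer(seed)),
            class = "look_true_config")
}

# Simulate one day's event log for every event type: homogeneous Poisson
# starts over a 12-h day with exponential durations (minutes).
simulate_day_events <- function(config) {
  day_min <- 720
  out <- list()
  for (ev in event_types()) {
    rate_per_min <- config$event_rates[[ev]] / 60
    n <- stats::rpois(1, rate_per_min * day_min)
    if (n == 0) { out[[ev]] <- data.frame(start = numeric(0), end = numeric(0)); next }
    start <- sort(stats::runif(n, 0, day_min))
    dur <- stats::rexp(n, 1 / config$event_durations[[ev]])
    out[[ev]] <- data.frame(start = start, end = start + dur)
  }
  out
}

# State of one event type at time t (minutes since dawn): list(elapsed, ongoing)
event_state_at <- function(log_df, t) {
  if (nrow(log_df) == 0 || all(log_df$start > t))
    return(list(elapsed = NA_real_, ongoing = FALSE))
  started <- log_df[log_df$start <= t, , drop = FALSE]
  if (any(started$end > t)) return(list(elapsed = NA_real_, ongoing = TRUE))
  list(elapsed = t - max(started$end), ongoing = FALSE)
}

#' Simulate focal observations (responses unfilled)
#'
#' Lays out the sampling design — per individual per day at most two 30-s
#' focals, never two in the same day-quarter time period — and draws all
#' contextual fields: in-view exposure, behaviour time budgets (Dirichlet over
#' the behaviour vocabulary, scaled to at most 30 s), neighbour sets,
#' visibility, observer distance and movement, spatial position, grid
#' location with habitat, feeding records, and the per-event-type clock state
#' (elapsed minutes since the last event that day, or an ongoing flag) from
#' Poisson event processes. The looking responses themselves are added by
#' [generate_looking()].
#'
#' @param roster a [simulate_roster()] result.
#' @param landscape a [simulate_landscape()] result.
#' @param config a [look_true_config()].
#' @return data.frame of class `look_focals`, one row per focal observation.
#' @export
simulate_focals <- function(roster, landscape, config) {
  stopifnot(inherits(roster, "look_roster"),
            inherits(config, "look_true_config"))
  set.seed(derive_seed(config$seed, 3L))
  n_ind <- nrow(roster)
  grid_n <- nrow(landscape$ud$values)
  ud_w <- as.vector(landscape$ud$values) + 1e-9
  vocab <- unlist(behaviour_vocabulary(), use.names = FALSE)
  evs <- event_types()

  rows <- vector("list", config$n_days)
  for (d in seq_len(config$n_days)) {
    events <- simulate_day_events(config)
    n_foc <- stats::rbinom(n_ind, 2L, config$focals_per_day / 2)
    day_rows <- list()
    for (i in seq_len(n_ind)) {
      if (n_foc[i] == 0) next
      periods <- sort(sample.int(4L, n_foc[i]))
      for (tp in periods) {
        t_start <- (tp - 1) * 180 + stats::runif(1, 0, 179.5)
        cell <- sample.int(grid_n^2, 1, prob = ud_w)
        r <- (cell - 1L) %% grid_n + 1L
        cc <- (cell - 1L) %/% grid_n + 1L
        neigh <- roster$individual_id[-i][stats::runif(n_ind - 1) < 0.08]
        n_neigh <- length(neigh)
        peripheral <- stats::runif(1) < stats::plogis(0.8 - 0.6 * n_neigh)
        in_view <- round(30 * stats::rbeta(1, 20, 1.5), 3)
        props <- stats::rgamma(length(vocab), 0.35)
        props <- props / sum(props)
        behav <- round(props * 30 * stats::runif(1, 0.85, 1), 3)
        feeding <- stats::runif(1) < 0.55
        food <- if (feeding) sample(food_item_levels()[-1], 1) else "none"
        amount <- if (feeding) stats::rpois(1, 3) else 0L
        st <- lapply(events, event_state_at, t = t_start)
        rec <- data.frame(
          individual_id = roster$individual_id[i],
          date = sprintf("D%03d", d),
          time_period = tp,
          focal_start_min = round(t_start, 3),
          in_view_seconds = in_view,
          visibility_pct = round(stats::runif(1, 15, 100), 1),
          spatial_position = if (peripheral) "peripheral" else "central",
          n_neighbours = n_neigh,
          neighbour_ids = paste(neigh, collapse = ";"),
          food_item = food,
          amount_eaten = amount,
          observer_distance_m = round(stats::runif(1, 2, 15), 2),
          observer_moved = stats::runif(1) < 0.3,
          grid_row = r, grid_col = cc,
          habitat = habitat_levels()[landscape$habitat$values[r, cc]],
          stringsAsFactors = FALSE)
        for (b in vocab) rec[[paste0("behav_", b)]] <- behav[match(b, vocab)]
        for (ev in evs) {
          rec[[paste0("ev_", ev, "_elapsed")]] <- round(st[[ev]]$elapsed, 3)
          rec[[paste0("ev_", ev, "_ongoing")]] <- st[[ev]]$ongoing
        }
        day_rows[[length(day_rows) + 1L]] <- rec
      }
    }
    rows[[d]] <- if (length(day_rows)) do.call(rbind, day_rows) else NULL
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  class(out) <- c("look_focals", "data.frame")
  out
}

#' Simulate a directed agonistic interaction matrix
#'
#' Allocates `n_interactions` decided dyadic contests among all pairs; the
#' probability that the higher-ranked contestant wins increases with the rank
#' advantage through a logistic in `steepness`. `steepness = 0` gives
#' coin-flip outcomes; large values give a perfectly transitive matrix.
#'
#' @param roster a [simulate_roster()] result (uses `latent_rank`).
#' @param n_interactions total number of interactions (default 638, one
#'   study-year's worth).
#' @param steepness >= 0, hierarchy steepness.
#' @param seed integer seed.
#' @return square integer matrix, entry (i, j) = wins of i over j.
#' @export
simulate_agonistic_matrix <- function(roster, n_interactions = 638,
                                      steepness = 2, seed = 1) {
  if (n_interactions < 1) stop("n_interactions must be >= 1")
  if (steepness < 0) stop("steepness must be >= 0")
  set.seed(derive_seed(seed, 4L))
  n <- nrow(roster)
  ids <- roster$individual_id
  rank <- roster$latent_rank
  M <- matrix(0L, n, n, dimnames = list(ids, ids))
  pair <- t(utils::combn(n, 2L))
  pick <- sample.int(nrow(pair), n_interactions, replace = TRUE)
  for (k in pick) {
    i <- pair[k, 1]; j <- pair[k, 2]
    # rank 1 = top; advantage of i over j is rank_j - rank_i
    p_i <- stats::plogis(steepness * (rank[j] - rank[i]))
    if (stats::runif(1) < p_i) M[i, j] <- M[i, j] + 1L else M[j, i] <- M[j, i] + 1L
  }
  M
}

#' Simulate a symmetric grooming weight matrix
#'
#' Dyadic grooming effort with higher expected weight within cliques than
#' between them (Poisson counts with rates `within_rate` / `between_rate`).
#'
#' @param roster a [simulate_roster()] result (uses `clique_label`).
#' @param within_rate,between_rate expected dyadic weights;
#'   `within_rate > between_rate >= 0` for recoverable cliques.
#' @param seed integer seed.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
simulate_grooming <- function(roster, within_rate = 5, between_rate = 0.3,
                              seed = 1) {
  if (between_rate < 0 || within_rate < 0)
    stop("simulate_grooming: rates must be >= 0")
  set.seed(derive_seed(seed, 5L))
  n <- nrow(roster)
  ids <- roster$individual_id
  G <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    rate <- if (roster$clique_label[i] == roster$clique_label[j])
      within_rate else between_rate
    w <- stats::rpois(1, rate)
    G[i, j] <- G[j, i] <- w
  }
  G
}
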