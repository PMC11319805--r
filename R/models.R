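#' Prior specification for the looking models
#'
#' All location parameters (intercept and regression coefficients) take
#' Student-t priors with 3 degrees of freedom, location 0 and scale 10;
#' standard deviations of the crossed random intercepts and the residual sd
#' of the duration family take the same Student-t restricted to the positive
#' half-line.
#'
#' @param df,location,scale Student-t hyperparameters.
#' @return list of class `look_priors`.
#' @export
look_priors <- function(df = 3, location = 0, scale = 10) {
  structure(list(df = df, location = location, scale = scale),
            class = "look_priors")
}

# log density of the scaled Student-t coefficient prior
dt_scaled <- function(x, prior) {
  stats::dt((x - prior$location) / prior$scale, df = prior$df, log = TRUE) -
    log(prior$scale)
}

# log density of the half Student-t prior for scales (x > 0)
dhalf_t <- function(x, prior) {
  ifelse(x > 0, dt_scaled(x, prior) + log(2), -Inf)
}

#' Log prior density of a parameter set
#'
#' Sums Student-t(3, 0, 10) log densities over coefficients and
#' half-Student-t(3, 0, 10) log densities over scale parameters. Any
#' non-positive scale yields `-Inf` (a rejected state).
#'
#' @param coefficients numeric vector of location parameters.
#' @param scales numeric vector of sd / sigma parameters (must be positive).
#' @param prior a [look_priors()].
#' @return scalar log density.
#' @export
log_prior <- function(coefficients, scales = numeric(0), prior = look_priors()) {
  lp <- sum(dt_scaled(coefficients, prior))
  if (length(scales)) {
    if (any(scales <= 0)) return(-Inf)
    lp <- lp + sum(dhalf_t(scales, prior))
  }
  lp
}

# term strings shared by the pre-emptive risk interaction block
risk_block <- function(risk, behaviour) {
  sprintf("%s * (n_neighbours + spatial_position + %s) + visibility + rank + age_sex_class",
          risk, behaviour)
}

#' Build the 21-model hypothesis set
#'
#' Returns the full research framework for one response: 21 model
#' specifications from the intercept-only null through compatibility,
#' reactionary, within-group-threat, pre-emptive spatial-risk and
#' observer-risk hypotheses. The behaviour covariate is time spent engaged
#' for the frequency response and time spent not engaged for the duration
#' response. Model 5 (specific behaviours) omits resting, which is
#' collinear with the remaining budget; [resting_model_spec()] provides the
#' separate resting-only specification.
#'
#' @param response `"frequency"` or `"duration"`.
#' @return list of 21 `look_spec` objects (class `look_model_set`).
#' @export
look_model_set <- function(response = c("frequency", "duration")) {
  response <- match.arg(response)
  behaviour <- if (response == "frequency") "engaged_s" else "not_engaged_s"
  specific <- c("behav_biting", "behav_digging", "behav_handling", "behav_pick",
                "behav_search_substrate", "behav_give_groom", "behav_self_groom",
                "behav_receive_groom", "behav_chewing", "behav_self_scratch",
                "behav_movement", "behav_posture")
  base2 <- sprintf("age_sex_class + %s", behaviour)
  forms <- c(
    "1",
    base2,
    sprintf("n_neighbours * spatial_position + %s", base2),
    sprintf("amount_eaten + food_item + %s + age_sex_class", behaviour),
    paste(c(specific, "age_sex_class"), collapse = " + "),
    sprintf("ts_aggression + %s + visibility + rank", base2),
    sprintf("ts_mating + %s", base2),
    sprintf("ts_female_call + %s", base2),
    sprintf("ts_male_call + %s + visibility + rank", base2),
    sprintf("ts_hetero_active + %s + visibility + rank", base2),
    sprintf("ts_hetero_passive + %s", base2),
    sprintf("ts_dog + %s + visibility + spatial_position + n_neighbours", base2),
    sprintf("ts_alarm + %s + visibility + spatial_position + n_neighbours", base2),
    sprintf("ts_group_encounter + %s + visibility + spatial_position + rank + n_neighbours", base2),
    sprintf("n_social_threats + %s + visibility + rank + n_neighbours", base2),
    risk_block("leopard_rsf", behaviour),
    risk_block("habitat", behaviour),
    risk_block("inverted_ud", behaviour),
    risk_block("familiarity", behaviour),
    risk_block("encounter_risk", behaviour),
    sprintf("tolerance * (observer_distance_m + observer_moved + %s) + age_sex_class",
            behaviour)
  )
  labels <- c(
    "Intercept-only", "Minimal (age-sex class + behaviour)",
    "Group geometry and cohesion", "Feeding rate and food items",
    "Specific behaviours", "Time since within-group aggression",
    "Time since mating", "Time since adult female calls",
    "Time since male calls", "Time since active heterospecific encounter",
    "Time since passive heterospecific encounter", "Time since dog encounter",
    "Time since alarm", "Time since extra-group encounter",
    "Within-group threats", "Leopard encounter risk", "Habitat type",
    "Continuous landscape familiarity", "Categorical landscape familiarity",
    "Inter-group encounter risk", "Observer tolerance")
  out <- lapply(seq_along(forms), function(i)
    look_spec(model_id = i, response = response, rhs = forms[i],
              label = labels[i]))
  class(out) <- "look_model_set"
  out
}

#' Single model specification
#'
#' @param model_id integer identifier.
#' @param response `"frequency"` or `"duration"`.
#' @param rhs right-hand-side formula string for the fixed effects.
#' @param label human-readable hypothesis label.
#' @param priors a [look_priors()].
#' @return object of class `look_spec`. The family is
#'   `poisson_log` with a log in-view offset for frequency, and
#'   `censored_truncated_normal_identity` with an additive unit-coefficient
#'   in-view offset for duration.
#' @export
look_spec <- function(model_id, response = c("frequency", "duration"), rhs,
                      label = "", priors = look_priors()) {
  response <- match.arg(response)
  structure(list(
    model_id = model_id,
    response = response,
    rhs = rhs,
    formula = stats::as.formula(paste("~", rhs)),
    label = label,
    family = if (response == "frequency") "poisson_log"
             else "censored_truncated_normal_identity",
    offset_name = "in_view_seconds",
    priors = priors), class = "look_spec")
}

#' Resting-only specification
#'
#' Companion to model 5: time spent resting as the single behavioural
#' covariate (resting is excluded from the specific-behaviours model because
#' it is collinear with the remaining budget).
#' @inheritParams look_spec
#' @export
resting_model_spec <- function(response = c("frequency", "duration")) {
  look_spec(model_id = 22L, response = match.arg(response),
            rhs = "behav_rest + age_sex_class", label = "Resting only")
}

#' @export
print.look_spec <- function(x, ...) {
  cat(sprintf("<look_spec %s> model %s: %s\n  ~ %s\n  family: %s, offset: %s\n",
              x$response, x$model_id, x$label, x$rhs, x$family, x$offset_name))
  invisible(x)
}

#' @export
print.look_model_set <- function(x, ...) {
  cat(sprintf("<look_model_set> %d models, response '%s'\n",
              length(x), x[[1]]$response))
  for (m in x) cat(sprintf("  %2d  %s\n", m$model_id, m$label))
  invisible(x)
}

#' Build the fixed-effects design matrix for a specification
#'
#' Expands the specification's formula against an analysis table with
#' treatment (reference-level) coding and no centring or scaling; interaction
#' columns are products of the expanded columns. Unused factor levels are
#' dropped. Grouping indices for the crossed date and individual random
#' intercepts are attached as attributes.
#'
#' @param spec a [look_spec()].
#' @param table analysis table (see [derive_analysis_table()]).
#' @return numeric matrix with attributes `date_index`, `individual_index`
#'   (integer codes) and their level sets.
#' @export
build_design <- function(spec, table) {
  vars <- all.vars(spec$formula)
  missing <- setdiff(vars, names(table))
  if (length(missing))
    stop(sprintf("build_design: missing columns in analysis table: %s",
                 paste(missing, collapse = ", ")))
  tab <- droplevels(as.data.frame(table)[, vars, drop = FALSE])
  X <- stats::model.matrix(spec$formula, data = tab)
  attr(X, "assign") <- NULL
  attr(X, "contrasts") <- NULL
  if ("date" %in% names(table)) {
    d <- factor(table$date)
    attr(X, "date_index") <- as.integer(d)
    attr(X, "date_levels") <- levels(d)
  }
  if ("individual_id" %in% names(table)) {
    i <- factor(table$individual_id)
    attr(X, "individual_index") <- as.integer(i)
    attr(X, "individual_levels") <- levels(i)
  }
  X
}

#' Poisson log-link log likelihood with exposure offset
#'
#' `log P(y | lambda)` with `lambda = exp(linear_predictor + log(in_view))`:
#' the expected bout count scales linearly with the in-view exposure.
#'
#' @param y non-negative integer counts.
#' @param linear_predictor linear predictor excluding the offset.
#' @param in_view in-view exposure in seconds (> 0).
#' @return vector of pointwise log densities.
#' @export
loglik_frequency <- function(y, linear_predictor, in_view) {
  if (any(in_view <= 0)) stop("loglik_frequency: in_view must be > 0")
  stats::dpois(y, exp(linear_predictor + log(in_view)), log = TRUE)
}

#' Censored, zero-truncated Gaussian log likelihood
#'
#' Total looking duration is modelled as a latent Gaussian with identity
#' link, truncated below at 0 (durations cannot be negative) and right
#' censored at the in-view time `cap`. Uncensored records contribute the
#' truncated density; censored records contribute the truncated upper tail
#' mass beyond `cap`. The truncation normaliser `P(latent > 0)` is shared by
#' both branches, so density plus censor mass integrates to one.
#'
#' @param y recorded duration in `[0, cap]`.
#' @param censored logical; `TRUE` when `y == cap`.
#' @param mu latent mean (includes the additive in-view offset).
#' @param sigma residual sd (> 0).
#' @param cap in-view time (censoring point).
#' @return vector of pointwise log densities.
#' @export
loglik_duration <- function(y, censored, mu, sigma, cap) {
  if (any(sigma <= 0)) stop("loglik_duration: sigma must be > 0")
  if (any(y > cap + 1e-9)) stop("loglik_duration: y exceeds the censoring cap")
  if (any(censored & abs(y - cap) > 1e-9))
    stop("loglik_duration: censored records must have y == cap")
  n <- max(length(y), length(mu), length(cap))
  y <- rep_len(y, n); censored <- rep_len(censored, n)
  mu <- rep_len(mu, n); sigma <- rep_len(sigma, n); cap <- rep_len(cap, n)
  lnorm <- stats::pnorm(0, mu, sigma, lower.tail = FALSE, log.p = TRUE)
  out <- numeric(n)
  unc <- !censored
  out[unc] <- stats::dnorm(y[unc], mu[unc], sigma[unc], log = TRUE) - lnorm[unc]
  out[!unc] <- stats::pnorm(cap[!unc], mu[!unc], sigma[!unc],
                            lower.tail = FALSE, log.p = TRUE) - lnorm[!unc]
  out
}

#' Serialise a model set to JSON
#'
#' Writes the model identifiers, labels, formulas and prior hyperparameters
#' so a hypothesis set can be audited or extended without code changes.
#'
#' @param models a [look_model_set()] (or any list of `look_spec`s).
#' @param path output path; if `NULL`, returns the JSON string.
#' @export
write_model_set <- function(models, path = NULL) {
  rows <- lapply(models, function(m)
    list(model_id = m$model_id, response = m$response, label = m$label,
         formula = m$rhs, family = m$family, offset = m$offset_name,
         prior = unclass(m$priors)))
  js <- jsonlite::toJSON(rows, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a model set from JSON
#' @param path file written by [write_model_set()].
#' @return list of `look_spec` objects.
#' @export
read_model_set <- function(path) {
  rows <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- lapply(rows, function(r)
    look_spec(model_id = r$model_id, response = r$response, rhs = r$formula,
              label = r$label,
              priors = look_priors(r$prior$df, r$prior$location, r$prior$scale)))
  class(out) <- "look_model_set"
  out
}
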