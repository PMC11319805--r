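#' Fill in the looking responses
#'
#' Simulates the looking responses of each focal from the generative twin of
#' a fitted model. For the frequency response the bout count is Poisson with
#' log link and the log in-view exposure as offset:
#' `n_looks ~ Poisson(exp(x'b + u_date + u_id + log(in_view)))`. For the
#' duration response a latent Gaussian
#' `Normal(x'b + u_date + u_id + in_view, sigma)` (identity link, additive
#' unit-coefficient offset) is truncated below at zero; the recorded value is
#' the latent capped at the in-view time, with the censored flag set when the
#' cap binds.
#'
#' @param observations a [simulate_focals()] table already joined into an
#'   analysis table by [derive_analysis_table()] (the design columns of the
#'   generating model must be present).
#' @param spec the generating [look_spec()]; must match `config$response`
#'   and `config$model_id`.
#' @param config a [look_true_config()] supplying coefficients, random-effect
#'   sds and (for duration) sigma.
#' @return the table with `n_looks` or `total_look_seconds` + `censored`
#'   filled, plus the true random-intercept draws as attributes.
#' @export
generate_looking <- function(observations, spec, config) {
  stopifnot(inherits(spec, "look_spec"), inherits(config, "look_true_config"))
  if (spec$response != config$response || spec$model_id != config$model_id)
    stop("generate_looking: spec does not match config response/model_id")
  X <- build_design(spec, observations)
  beta <- config$coefficients
  if (is.null(beta)) stop("generate_looking: config$coefficients is NULL")
  # extras are tolerated (factor levels unrealised in a small table);
  # a design column without a coefficient is a specification error
  if (!all(colnames(X) %in% names(beta)))
    stop(sprintf(
      "generate_looking: no coefficient for design column(s): %s",
      paste(setdiff(colnames(X), names(beta)), collapse = ", ")))
  beta <- beta[colnames(X)]

  set.seed(derive_seed(config$seed, 8L))
  di <- attr(X, "date_index"); ii <- attr(X, "individual_index")
  u_d <- stats::rnorm(length(attr(X, "date_levels")), 0, config$re_sd_date)
  u_i <- stats::rnorm(length(attr(X, "individual_levels")), 0,
                      config$re_sd_individual)
  eta <- as.vector(X %*% beta) + u_d[di] + u_i[ii]
  iv <- observations$in_view_seconds

  out <- observations
  if (spec$response == "frequency") {
    out$n_looks <- stats::rpois(nrow(out), exp(eta + log(iv)))
  } else {
    mu <- eta + iv
    p0 <- stats::pnorm(0, mu, config$sigma)
    latent <- stats::qnorm(stats::runif(nrow(out), p0, 1), mu, config$sigma)
    cens <- latent >= iv
    rec <- round(pmin(latent, iv), 3)
    # keep the censoring invariant exact after rounding to milliseconds
    rec[cens] <- iv[cens]
    clash <- !cens & rec >= iv
    rec[clash] <- iv[clash] - 0.001
    out$total_look_seconds <- rec
    out$censored <- cens
  }
  attr(out, "true_u_date") <- u_d
  attr(out, "true_u_individual") <- u_i
  out
}

#' Default strong-effect generative configurations
#'
#' Ready-made true-model configurations used in recovery experiments: the
#' feeding-rate hypothesis (model 4) for the frequency response and the
#' within-group-threat hypothesis (model 15) for the duration response, with
#' clearly non-zero coefficients.
#'
#' @param response `"frequency"` or `"duration"`.
#' @param ... overrides passed to [look_true_config()].
#' @return a [look_true_config()].
#' @export
default_true_config <- function(response = c("frequency", "duration"), ...) {
  response <- match.arg(response)
  if (response == "frequency") {
    coefs <- c("(Intercept)" = -2.3,
               amount_eaten = 0.12,
               food_itemfruit = 0.4, food_itemseeds = -0.3,
               food_itemroots = 0.25, food_iteminvertebrates = 0.5,
               food_itemother = 0.1,
               engaged_s = -0.04,
               "age_sex_classadult-female" = -0.3,
               age_sex_classsubadult = 0.25, age_sex_classjuvenile = 0.45)
    look_true_config(response = "frequency", model_id = 4L,
                     coefficients = coefs, ...)
  } else {
    coefs <- c("(Intercept)" = -16,
               n_social_threats = 2.5,
               "age_sex_classadult-female" = -1.5,
               age_sex_classsubadult = 1, age_sex_classjuvenile = 2,
               not_engaged_s = 0.15,
               visibility = 0.02, rank = -0.02, n_neighbours = 0.4)
    look_true_config(response = "duration", model_id = 15L,
                     coefficients = coefs, sigma = 3, ...)
  }
}
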