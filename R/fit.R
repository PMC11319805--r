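#' Fit a looking model
#'
#' Samples the posterior of one hypothesis model: fixed effects with
#' Student-t(3, 0, 10) priors, crossed date and individual random intercepts
#' with half-Student-t(3, 0, 10) sd priors, and (duration family) a residual
#' sd with the same half-t prior. The likelihoods are exactly those of
#' [loglik_frequency()] and [loglik_duration()]. Sampling uses a seeded
#' component-wise adaptive random-walk Metropolis scheme: each parameter has
#' its own proposal scale tuned during warmup towards a 0.44 acceptance
#' rate; scale parameters are updated on the log scale with the Jacobian
#' included. All parameters are initialised at zero on the sampling scale
#' (so sds and sigma start at 1).
#'
#' @param spec a [look_spec()].
#' @param table analysis table containing the response (`n_looks` or
#'   `total_look_seconds` + `censored`), the offset column and all design
#'   columns.
#' @param chains number of chains (paper settings: 4).
#' @param iter iterations per chain including warmup (paper: 2000).
#' @param warmup warmup iterations discarded and used for adaptation
#'   (paper: 1000).
#' @param seed integer seed; chains use derived sub-seeds.
#' @param random_effects include the crossed random intercepts (default
#'   TRUE; FALSE fits a fixed-effects-only model).
#' @param subset optional integer vector of rows to condition on (the design
#'   is always built from the full table so factor codings are stable);
#'   used by [exact_loo()].
#' @param method sampling method; `"rwm"` (adaptive random-walk Metropolis)
#'   is the built-in vehicle.
#' @return object of class `look_fit` with posterior `draws` (S x P, S =
#'   chains x (iter - warmup)), the pointwise log-likelihood matrix, split
#'   R-hat and effective sample size per parameter, and fitting metadata.
#' @export
fit_looking <- function(spec, table, chains = 2, iter = 1000,
                        warmup = floor(iter / 2), seed = 1L,
                        random_effects = TRUE, subset = NULL,
                        method = "rwm") {
  stopifnot(inherits(spec, "look_spec"), iter > warmup, chains >= 1)
  if (!identical(method, "rwm"))
    stop("fit_looking: only the 'rwm' sampler is built in")
  X <- build_design(spec, table)
  n_all <- nrow(X)
  rows <- if (is.null(subset)) seq_len(n_all) else subset
  dat <- extract_response(spec, table)
  di <- attr(X, "date_index"); ii <- attr(X, "individual_index")
  use_re <- isTRUE(random_effects) && !is.null(di) && !is.null(ii)
  if (isTRUE(random_effects) && !use_re)
    warning("fit_looking: date/individual columns absent; fitting without random effects")
  if (use_re && (length(unique(di[rows])) < 2 || length(unique(ii[rows])) < 2))
    warning("fit_looking: a grouping factor has a single level; its sd is prior-dominated")

  chain_out <- vector("list", chains)
  for (ch in seq_len(chains)) {
    chain_out[[ch]] <- run_look_chain(
      spec, X, dat, rows, di, ii, use_re, iter = iter, warmup = warmup,
      seed = derive_seed(seed, 100L + ch))
  }
  draws <- do.call(rbind, lapply(chain_out, `[[`, "draws"))
  chain_id <- rep(seq_len(chains), each = iter - warmup)

  fit <- structure(list(
    spec = spec, draws = draws, chain_id = chain_id,
    design = X, data = dat, rows = rows,
    use_re = use_re,
    settings = list(chains = chains, iter = iter, warmup = warmup,
                    seed = seed, method = method,
                    random_effects = random_effects)),
    class = "look_fit")
  fit$loglik <- pointwise_loglik(fit)
  diag <- fit_diagnostics(draws, chain_id)
  fit$rhat <- diag$rhat
  fit$ess <- diag$ess
  fit
}

extract_response <- function(spec, table) {
  iv <- table[[spec$offset_name]]
  if (any(iv <= 0)) stop("fit_looking: offset (in-view seconds) must be > 0")
  if (spec$response == "frequency") {
    y <- table$n_looks
    if (is.null(y)) stop("fit_looking: column 'n_looks' is missing")
    list(y = y, iv = iv, cens = NULL)
  } else {
    y <- table$total_look_seconds
    cens <- table$censored
    if (is.null(y) || is.null(cens))
      stop("fit_looking: columns 'total_look_seconds'/'censored' are missing")
    if (any(y > iv + 1e-9) || any(cens & abs(y - iv) > 1e-9))
      stop("fit_looking: censoring invariant violated in the data")
    list(y = y, iv = iv, cens = cens)
  }
}

# pointwise log-lik closure over a row subset; eta excludes the offset
make_ll_fun <- function(spec, dat) {
  if (spec$response == "frequency") {
    liv <- log(dat$iv); y <- dat$y
    function(eta, sigma, idx)
      stats::dpois(y[idx], exp(eta + liv[idx]), log = TRUE)
  } else {
    y <- dat$y; iv <- dat$iv; cens <- dat$cens
    function(eta, sigma, idx) {
      mu <- eta + iv[idx]
      lno <- stats::pnorm(0, mu, sigma, lower.tail = FALSE, log.p = TRUE)
      ci <- cens[idx]
      r <- numeric(length(mu))
      if (any(!ci))
        r[!ci] <- stats::dnorm(y[idx][!ci], mu[!ci], sigma, log = TRUE) - lno[!ci]
      if (any(ci))
        r[ci] <- stats::pnorm(iv[idx][ci], mu[ci], sigma,
                              lower.tail = FALSE, log.p = TRUE) - lno[ci]
      r
    }
  }
}

run_look_chain <- function(spec, X, dat, rows, di, ii, use_re, iter, warmup,
                           seed) {
  set.seed(seed)
  prior <- spec$priors
  dur <- spec$response == "duration"
  p <- ncol(X)
  Xcols <- lapply(seq_len(p), function(k) X[rows, k])
  dat_sub <- list(y = dat$y[rows], iv = dat$iv[rows],
                  cens = if (!is.null(dat$cens)) dat$cens[rows])
  ll_fun <- make_ll_fun(spec, dat_sub)
  n <- length(rows)

  if (use_re) {
    D <- length(attr(X, "date_levels")); I <- length(attr(X, "individual_levels"))
    d_rows <- split(seq_len(n), factor(di[rows], levels = seq_len(D)))
    i_rows <- split(seq_len(n), factor(ii[rows], levels = seq_len(I)))
  } else {
    D <- I <- 0L
  }

  beta <- numeric(p)
  u_d <- numeric(D); u_i <- numeric(I)
  lsd_d <- 0; lsd_i <- 0; lsig <- 0
  sigma <- if (dur) exp(lsig) else NULL
  # two extra recentering moves (random-effect block mean vs intercept)
  has_int <- "(Intercept)" %in% colnames(X)
  n_recenter <- if (use_re && has_int) 2L else 0L
  n_theta <- p + (if (use_re) D + I + 2L else 0L) + (if (dur) 1L else 0L)
  n_par <- n_theta + n_recenter
  ls <- rep(log(0.5), n_par)   # per-parameter log proposal scales
  acc <- integer(n_par); batch <- 0L

  eta <- as.vector(X[rows, , drop = FALSE] %*% beta)
  if (use_re) eta <- eta + u_d[di[rows]] + u_i[ii[rows]]
  ll <- ll_fun(eta, sigma, seq_len(n))

  kept <- iter - warmup
  out <- matrix(NA_real_, kept, n_theta)
  accept <- function(lr) is.finite(lr) && log(stats::runif(1)) < lr

  for (t in seq_len(iter)) {
    j <- 0L
    for (k in seq_len(p)) {
      j <- j + 1L
      d <- stats::rnorm(1, 0, exp(ls[j]))
      eta_new <- eta + d * Xcols[[k]]
      ll_new <- ll_fun(eta_new, sigma, seq_len(n))
      lr <- sum(ll_new) - sum(ll) +
        dt_scaled(beta[k] + d, prior) - dt_scaled(beta[k], prior)
      if (accept(lr)) {
        beta[k] <- beta[k] + d; eta <- eta_new; ll <- ll_new
        acc[j] <- acc[j] + 1L
      }
    }
    if (use_re) {
      sd_d <- exp(lsd_d); sd_i <- exp(lsd_i)
      for (g in seq_len(D)) {
        j <- j + 1L
        d <- stats::rnorm(1, 0, exp(ls[j]))
        idx <- d_rows[[g]]
        lr <- stats::dnorm(u_d[g] + d, 0, sd_d, log = TRUE) -
              stats::dnorm(u_d[g], 0, sd_d, log = TRUE)
        if (length(idx)) {
          ll_new <- ll_fun(eta[idx] + d, sigma, idx)
          lr <- lr + sum(ll_new) - sum(ll[idx])
        }
        if (accept(lr)) {
          u_d[g] <- u_d[g] + d
          if (length(idx)) { eta[idx] <- eta[idx] + d; ll[idx] <- ll_new }
          acc[j] <- acc[j] + 1L
        }
      }
      for (g in seq_len(I)) {
        j <- j + 1L
        d <- stats::rnorm(1, 0, exp(ls[j]))
        idx <- i_rows[[g]]
        lr <- stats::dnorm(u_i[g] + d, 0, sd_i, log = TRUE) -
              stats::dnorm(u_i[g], 0, sd_i, log = TRUE)
        if (length(idx)) {
          ll_new <- ll_fun(eta[idx] + d, sigma, idx)
          lr <- lr + sum(ll_new) - sum(ll[idx])
        }
        if (accept(lr)) {
          u_i[g] <- u_i[g] + d
          if (length(idx)) { eta[idx] <- eta[idx] + d; ll[idx] <- ll_new }
          acc[j] <- acc[j] + 1L
        }
      }
      # log-sd updates: normal likelihood of the intercepts + half-t prior
      for (which_sd in 1:2) {
        j <- j + 1L
        d <- stats::rnorm(1, 0, exp(ls[j]))
        if (which_sd == 1L) {
          new <- lsd_d + d
          lr <- sum(stats::dnorm(u_d, 0, exp(new), log = TRUE)) -
                sum(stats::dnorm(u_d, 0, exp(lsd_d), log = TRUE)) +
                dhalf_t(exp(new), prior) - dhalf_t(exp(lsd_d), prior) + d
          if (accept(lr)) { lsd_d <- new; acc[j] <- acc[j] + 1L }
        } else {
          new <- lsd_i + d
          lr <- sum(stats::dnorm(u_i, 0, exp(new), log = TRUE)) -
                sum(stats::dnorm(u_i, 0, exp(lsd_i), log = TRUE)) +
                dhalf_t(exp(new), prior) - dhalf_t(exp(lsd_i), prior) + d
          if (accept(lr)) { lsd_i <- new; acc[j] <- acc[j] + 1L }
        }
      }
    }
    if (n_recenter) {
      # shift a random-intercept block by d and the intercept by -d: the
      # linear predictor is unchanged, so only the priors enter the ratio
      k0 <- match("(Intercept)", colnames(X))
      for (block in 1:2) {
        j <- j + 1L
        d <- stats::rnorm(1, 0, exp(ls[j]))
        if (block == 1L) {
          lr <- sum(stats::dnorm(u_d + d, 0, exp(lsd_d), log = TRUE)) -
                sum(stats::dnorm(u_d, 0, exp(lsd_d), log = TRUE)) +
                dt_scaled(beta[k0] - d, prior) - dt_scaled(beta[k0], prior)
          if (accept(lr)) {
            u_d <- u_d + d; beta[k0] <- beta[k0] - d; acc[j] <- acc[j] + 1L
          }
        } else {
          lr <- sum(stats::dnorm(u_i + d, 0, exp(lsd_i), log = TRUE)) -
                sum(stats::dnorm(u_i, 0, exp(lsd_i), log = TRUE)) +
                dt_scaled(beta[k0] - d, prior) - dt_scaled(beta[k0], prior)
          if (accept(lr)) {
            u_i <- u_i + d; beta[k0] <- beta[k0] - d; acc[j] <- acc[j] + 1L
          }
        }
      }
    }
    if (dur) {
      j <- j + 1L
      d <- stats::rnorm(1, 0, exp(ls[j]))
      new_sig <- exp(lsig + d)
      ll_new <- ll_fun(eta, new_sig, seq_len(n))
      lr <- sum(ll_new) - sum(ll) +
        dhalf_t(new_sig, prior) - dhalf_t(sigma, prior) + d
      if (accept(lr)) {
        lsig <- lsig + d; sigma <- new_sig; ll <- ll_new
        acc[j] <- acc[j] + 1L
      }
    }
    # Robbins-Monro scale adaptation during warmup
    if (t <= warmup && t %% 25L == 0L) {
      batch <- batch + 1L
      delta <- min(0.25, 1 / sqrt(batch))
      ls <- ls + ifelse(acc / 25 > 0.44, delta, -delta)
      acc[] <- 0L
    }
    if (t > warmup) {
      theta <- c(beta,
                 if (use_re) c(u_d, u_i, exp(lsd_d), exp(lsd_i)),
                 if (dur) sigma)
      out[t - warmup, ] <- theta
    }
  }

  cn <- colnames(X)
  if (use_re)
    cn <- c(cn, paste0("u_date[", attr(X, "date_levels"), "]"),
            paste0("u_id[", attr(X, "individual_levels"), "]"),
            "sd_date", "sd_individual")
  if (dur) cn <- c(cn, "sigma")
  colnames(out) <- cn
  list(draws = out)
}

#' Pointwise log-likelihood matrix of a fit
#'
#' Entry (s, i) is the conditional log likelihood (random intercepts
#' included) of observation i of the fitted rows under draw s; rows of the
#' returned matrix are draws. Summing over i gives the total data log
#' likelihood per draw.
#'
#' @param fit a [fit_looking()] result.
#' @param rows observation rows to evaluate (defaults to the fitted rows).
#' @param conditional include the random intercepts (TRUE) or set them to
#'   zero (FALSE).
#' @return S x length(rows) matrix.
#' @export
pointwise_loglik <- function(fit, rows = fit$rows, conditional = TRUE) {
  ETA <- linpred_draws(fit, rows, conditional)
  S <- nrow(ETA)
  dat <- fit$data
  if (fit$spec$response == "frequency") {
    lam_t <- exp(t(ETA) + log(dat$iv[rows]))          # n x S, y recycles
    LL <- t(stats::dpois(dat$y[rows], lam_t, log = TRUE))
  } else {
    sig <- fit$draws[, "sigma"]
    mu_t <- t(ETA) + dat$iv[rows]
    sig_m <- matrix(rep(sig, each = length(rows)), nrow = length(rows))
    lno <- stats::pnorm(0, mu_t, sig_m, lower.tail = FALSE, log.p = TRUE)
    ci <- dat$cens[rows]
    out_t <- matrix(0, length(rows), S)
    if (any(!ci))
      out_t[!ci, ] <- stats::dnorm(dat$y[rows][!ci], mu_t[!ci, , drop = FALSE],
                                   sig_m[!ci, , drop = FALSE], log = TRUE) -
                      lno[!ci, , drop = FALSE]
    if (any(ci))
      out_t[ci, ] <- stats::pnorm(dat$iv[rows][ci], mu_t[ci, , drop = FALSE],
                                  sig_m[ci, , drop = FALSE],
                                  lower.tail = FALSE, log.p = TRUE) -
                     lno[ci, , drop = FALSE]
    LL <- t(out_t)
  }
  dimnames(LL) <- NULL
  LL
}

# S x n matrix of linear predictors (offset excluded)
linpred_draws <- function(fit, rows = fit$rows, conditional = TRUE) {
  X <- fit$design
  p <- ncol(X)
  B <- fit$draws[, seq_len(p), drop = FALSE]
  ETA <- B %*% t(X[rows, , drop = FALSE])
  if (conditional && fit$use_re) {
    di <- attr(X, "date_index")[rows]; ii <- attr(X, "individual_index")[rows]
    D <- length(attr(X, "date_levels")); I <- length(attr(X, "individual_levels"))
    U_d <- fit$draws[, p + seq_len(D), drop = FALSE]
    U_i <- fit$draws[, p + D + seq_len(I), drop = FALSE]
    ETA <- ETA + U_d[, di, drop = FALSE] + U_i[, ii, drop = FALSE]
  }
  ETA
}

#' Credible interval for a parameter
#'
#' Empirical central quantile interval of the posterior draws (2.5% and
#' 97.5% quantiles at the default level).
#'
#' @param fit a [fit_looking()] result.
#' @param parameter parameter name (a column of `fit$draws`).
#' @param level interval mass (default 0.95).
#' @return named numeric vector `c(low, high)`.
#' @export
credible_interval <- function(fit, parameter, level = 0.95) {
  if (!parameter %in% colnames(fit$draws))
    stop(sprintf("credible_interval: unknown parameter '%s'", parameter))
  a <- (1 - level) / 2
  q <- stats::quantile(fit$draws[, parameter], c(a, 1 - a), names = FALSE)
  stats::setNames(q, c("low", "high"))
}

fit_diagnostics <- function(draws, chain_id) {
  P <- ncol(draws)
  rhat <- ess <- stats::setNames(numeric(P), colnames(draws))
  for (k in seq_len(P)) {
    rhat[k] <- split_rhat(draws[, k], chain_id)
    ess[k] <- ess_basic(draws[, k], chain_id)
  }
  list(rhat = rhat, ess = ess)
}

# split R-hat: each chain halved, between/within variance ratio
split_rhat <- function(x, chain_id) {
  halves <- lapply(split(x, chain_id), function(v) {
    h <- floor(length(v) / 2)
    list(v[seq_len(h)], v[h + seq_len(h)])
  })
  chains <- unlist(halves, recursive = FALSE)
  m <- length(chains); n <- length(chains[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(chains, mean, 0)
  vars <- vapply(chains, stats::var, 0)
  W <- mean(vars); B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# initial-positive-sequence ESS summed over chains
ess_basic <- function(x, chain_id) {
  per_chain <- vapply(split(x, chain_id), function(v) {
    n <- length(v)
    if (stats::var(v) == 0) return(n)
    ac <- stats::acf(v, lag.max = min(100L, n - 2L), plot = FALSE)$acf[-1]
    s <- 0
    for (r in ac) { if (r < 0.05) break; s <- s + r }
    n / (1 + 2 * s)
  }, 0)
  sum(per_chain)
}

#' @export
print.look_fit <- function(x, ...) {
  cat(sprintf("<look_fit> %s model %s (%s)\n", x$spec$response,
              x$spec$model_id, x$spec$label))
  cat(sprintf("  %d obs, %d draws (%d chains x %d post-warmup), max R-hat %.3f\n",
              length(x$rows), nrow(x$draws), x$settings$chains,
              x$settings$iter - x$settings$warmup,
              max(x$rhat, na.rm = TRUE)))
  invisible(x)
}

#' @export
coef.look_fit <- function(object, ...) {
  p <- ncol(object$design)
  colMeans(object$draws[, seq_len(p), drop = FALSE])
}

#' @export
summary.look_fit <- function(object, level = 0.95, ...) {
  a <- (1 - level) / 2
  qs <- t(apply(object$draws, 2, stats::quantile, probs = c(a, 1 - a),
                names = FALSE))
  out <- data.frame(parameter = colnames(object$draws),
                    mean = colMeans(object$draws),
                    low = qs[, 1], high = qs[, 2],
                    rhat = object$rhat, ess = round(object$ess),
                    row.names = NULL)
  names(out)[3:4] <- sprintf("q%.1f", 100 * c(a, 1 - a))
  class(out) <- c("summary.look_fit", "data.frame")
  out
}

#' @export
confint.look_fit <- function(object, parm, level = 0.95, ...) {
  if (missing(parm)) parm <- colnames(object$design)
  t(vapply(parm, function(p) credible_interval(object, p, level), numeric(2)))
}

#' Posterior predictions from a looking fit
#'
#' @param object a [fit_looking()] result.
#' @param rows observation rows (defaults to the fitted rows).
#' @param type `"mean"` for the expected response (Poisson rate x exposure,
#'   or latent Gaussian mean) or `"link"` for the linear predictor.
#' @param re `"conditional"` includes the random intercepts, `"marginal"`
#'   sets them to zero.
#' @param summary return the posterior mean per observation (TRUE) or the
#'   full S x n draw matrix (FALSE).
#' @param ... unused.
#' @export
predict.look_fit <- function(object, rows = object$rows, type = c("mean", "link"),
                             re = c("conditional", "marginal"),
                             summary = TRUE, ...) {
  type <- match.arg(type); re <- match.arg(re)
  ETA <- linpred_draws(object, rows, conditional = re == "conditional")
  out <- if (type == "link") ETA else predicted_mean(object, ETA, rows)
  if (summary) colMeans(out) else out
}

# expected-response matrix from a linear-predictor matrix
predicted_mean <- function(fit, ETA, rows) {
  iv <- fit$data$iv[rows]
  if (fit$spec$response == "frequency")
    t(exp(t(ETA) + log(iv)))
  else
    t(t(ETA) + iv)
}

#' @export
residuals.look_fit <- function(object, re = "conditional", ...) {
  object$data$y[object$rows] -
    predict(object, re = re, summary = TRUE)
}

#' @export
plot.look_fit <- function(x, parameter = colnames(x$draws)[1], ...) {
  d <- split(x$draws[, parameter], x$chain_id)
  graphics::matplot(do.call(cbind, d), type = "l", lty = 1,
                    xlab = "post-warmup iteration", ylab = parameter,
                    main = sprintf("model %s (%s)", x$spec$model_id,
                                   x$spec$response), ...)
  invisible(x)
}
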