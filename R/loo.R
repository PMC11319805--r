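#' Fit a generalized Pareto distribution to tail exceedances
#'
#' Profile-likelihood estimator (Zhang-Stephens style) of the shape k and
#' scale of a generalized Pareto distribution fitted to positive exceedances
#' over a threshold: a grid of candidate inverse-scale values is weighted by
#' profile likelihood and averaged, after which the shape follows in closed
#' form. The shape receives the usual weak prior regularisation towards 0.5.
#' Deterministic given its input.
#'
#' @param tail_sample numeric vector of exceedances (values above the
#'   threshold, shifted to be positive).
#' @param min_tail minimum usable tail size (default 5).
#' @return list with `k` (shape; `NA` when not estimable) and `sigma`
#'   (scale).
#' @export
fit_generalized_pareto <- function(tail_sample, min_tail = 5L) {
  x <- sort(tail_sample[is.finite(tail_sample)])
  n <- length(x)
  if (n < min_tail || x[n] <= 0 || x[1] == x[n])
    return(list(k = NA_real_, sigma = NA_real_))
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  quart <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * quart)
  # profile likelihood in the Hosking convention (k_old = -shape), then
  # convert: modern shape k > 0 = heavy tail
  k_old <- function(b) -mean(log1p(-b * x))
  ks <- vapply(theta, k_old, 0)
  l_prof <- n * (log(theta / ks) + ks - 1)
  w <- 1 / vapply(l_prof, function(l) sum(exp(l_prof - l)), 0)
  b_hat <- sum(theta * w)
  k_hat <- -k_old(b_hat)
  sigma <- -k_hat / b_hat
  k_reg <- (n * k_hat + 10 * 0.5) / (n + 10)
  list(k = k_reg, sigma = sigma)
}

# GPD quantile function (location 0)
qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma / k * ((1 - p)^(-k) - 1)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' PSIS leave-one-out cross-validation
#'
#' Computes the expected log pointwise predictive density (elpd) of each
#' observation by importance sampling from the full posterior, with the
#' importance-ratio tails regularised by Pareto smoothing: for each
#' observation the raw log ratios are `-loglik`; the `M = min(0.2 S,
#' 3 sqrt(S))` largest ratios are replaced by expected order statistics of a
#' generalized Pareto distribution fitted to their exceedances, truncated at
#' the maximum raw ratio; the fitted shape `k` is reported per observation
#' as the reliability diagnostic (values above ~0.7 flag an unreliable
#' approximation).
#'
#' @param x an S x n pointwise log-likelihood matrix, or a `look_fit` (its
#'   stored matrix is used).
#' @param ... unused.
#' @return object of class `loo_result`: `elpd_i`, `elpd = sum(elpd_i)`,
#'   `se = sqrt(n var(elpd_i))`, `pareto_k`.
#' @export
psis_loo <- function(x, ...) {
  ll <- if (inherits(x, "look_fit")) x$loglik else as.matrix(x)
  if (any(!is.finite(ll))) {
    bad <- unique(which(!is.finite(ll), arr.ind = TRUE)[, 2])
    stop(sprintf("psis_loo: non-finite log-likelihoods for observation(s) %s",
                 paste(utils::head(bad, 10), collapse = ", ")))
  }
  S <- nrow(ll); n <- ncol(ll)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  elpd_i <- numeric(n); k_i <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lw <- -ll[, i]
    lw <- lw - max(lw)
    if (M >= 5 && S - M >= 1) {
      ord <- order(lw)
      tail_idx <- ord[(S - M + 1):S]
      cut <- lw[ord[S - M]]
      exceed <- exp(lw[tail_idx]) - exp(cut)
      gpd <- fit_generalized_pareto(exceed)
      k_i[i] <- gpd$k
      if (!is.na(gpd$k)) {
        probs <- (seq_len(M) - 0.5) / M
        smoothed <- log(exp(cut) + vapply(probs, qgpd, 0, k = gpd$k,
                                          sigma = gpd$sigma))
        smoothed <- pmin(smoothed, 0)   # truncate at the max raw weight
        lw[tail_idx[order(lw[tail_idx])]] <- smoothed
      }
    }
    elpd_i[i] <- log_sum_exp(lw + ll[, i]) - log_sum_exp(lw)
  }
  structure(list(elpd_i = elpd_i, elpd = sum(elpd_i),
                 se = sqrt(n * stats::var(elpd_i)), pareto_k = k_i,
                 n = n, S = S),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("<loo_result> elpd %.2f (se %.2f), n = %d, S = %d\n",
              x$elpd, x$se, x$n, x$S))
  if (any(!is.na(x$pareto_k)))
    cat(sprintf("  Pareto k: max %.3f, %d/%d above 0.7\n",
                max(x$pareto_k, na.rm = TRUE),
                sum(x$pareto_k > 0.7, na.rm = TRUE), x$n))
  invisible(x)
}

#' Exact leave-one-out cross-validation by refitting
#'
#' The brute-force oracle for [psis_loo()]: refits the model n times, each
#' time leaving one observation out, and scores the held-out observation by
#' its log posterior-predictive density under the reduced fit. Only feasible
#' for small n.
#'
#' @param spec a [look_spec()].
#' @param table analysis table.
#' @param ... fitting settings passed to [fit_looking()].
#' @return a `loo_result` (with `pareto_k` all `NA`).
#' @export
exact_loo <- function(spec, table, ...) {
  n <- nrow(table)
  elpd_i <- numeric(n)
  for (i in seq_len(n)) {
    f <- tryCatch(fit_looking(spec, table, subset = setdiff(seq_len(n), i), ...),
                  error = function(e)
                    stop(sprintf("exact_loo: refit without observation %d failed: %s",
                                 i, conditionMessage(e))))
    ll_i <- pointwise_loglik(f, rows = i)
    elpd_i[i] <- log_sum_exp(ll_i[, 1]) - log(nrow(ll_i))
  }
  structure(list(elpd_i = elpd_i, elpd = sum(elpd_i),
                 se = sqrt(n * stats::var(elpd_i)),
                 pareto_k = rep(NA_real_, n), n = n, S = NA_integer_),
            class = "loo_result")
}

# elpd matrix (n x K) from a list of loo_results or matrices
elpd_matrix <- function(loos) {
  if (is.matrix(loos)) return(loos)
  cols <- lapply(loos, function(l) if (inherits(l, "loo_result")) l$elpd_i else l)
  n <- unique(vapply(cols, length, 0L))
  if (length(n) != 1) stop("stacking_weights: models disagree on n")
  do.call(cbind, cols)
}

# Euclidean projection onto the probability simplex (Duchi et al.)
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  tau <- (1 - css[rho]) / rho
  pmax(v + tau, 0)
}

#' Bayesian stacking weights from LOO predictive densities
#'
#' Finds the simplex weights maximising the stacked log score
#' `sum_i log sum_k w_k exp(elpd_ik)`: the log predictive density of the
#' weighted mixture of the models' LOO predictive distributions. The
#' objective is concave; it is maximised by projected gradient ascent with
#' backtracking from the uniform start to tolerance 1e-10, so similar models
#' share weight and pointwise-dominated models land exactly on the zero
#' vertex.
#'
#' @param loos list of [psis_loo()] results (or an n x K elpd matrix).
#' @param threshold retention threshold stored for [restack()] (default
#'   0.001).
#' @param max_iter iteration cap.
#' @return object of class `stack_result` with `weights` (simplex over the
#'   K models), the optimum `objective`, and bookkeeping fields.
#' @export
stacking_weights <- function(loos, threshold = 0.001, max_iter = 50000L) {
  E <- elpd_matrix(loos)
  K <- ncol(E)
  if (K == 0) stop("stacking_weights: no models supplied")
  nm <- colnames(E)
  if (is.null(nm)) nm <- paste0("model", seq_len(K))
  # per-row shift for numerical stability; changes the objective by a constant
  shift <- apply(E, 1, max)
  A <- exp(E - shift)
  obj <- function(w) sum(log(A %*% w))
  grad <- function(w) as.vector(t(A) %*% (1 / (A %*% w)))
  w <- rep(1 / K, K)
  f <- obj(w)
  step <- 1 / nrow(A)
  for (it in seq_len(max_iter)) {
    g <- grad(w)
    w_new <- project_simplex(w + step * g)
    f_new <- obj(w_new)
    while (f_new < f && step > 1e-18) {   # backtrack
      step <- step / 2
      w_new <- project_simplex(w + step * g)
      f_new <- obj(w_new)
    }
    if (f_new - f < 1e-10 && sqrt(sum((w_new - w)^2)) < 1e-10) {
      w <- w_new; f <- f_new
      break
    }
    w <- w_new; f <- f_new
    step <- step * 1.5
  }
  structure(list(weights = stats::setNames(w, nm),
                 objective = f + sum(shift),
                 threshold = threshold,
                 retained_ids = which(w >= threshold),
                 restacked_weights = NULL),
            class = "stack_result")
}

#' Re-stack the retained models
#'
#' Second-stage stacking: models whose first-stage weight reaches the
#' retention threshold (default 0.001) are stacked again on their own. The
#' comparison of first-stage and re-stacked weights shows which weight was
#' shared among similar models during the joint optimisation.
#'
#' @param stack a [stacking_weights()] result.
#' @param loos the same list/matrix of LOO results used for the first stage.
#' @param threshold retention threshold.
#' @return the `stack_result` with `restacked_weights` and `retained_ids`
#'   filled.
#' @export
restack <- function(stack, loos, threshold = stack$threshold) {
  E <- elpd_matrix(loos)
  keep <- which(stack$weights >= threshold)
  if (!length(keep))
    stop("restack: no model reaches the retention threshold")
  sub <- stacking_weights(E[, keep, drop = FALSE])
  stack$threshold <- threshold
  stack$retained_ids <- keep
  w2 <- stats::setNames(numeric(length(stack$weights)), names(stack$weights))
  w2[keep] <- sub$weights
  stack$restacked_weights <- w2
  stack
}

#' @export
print.stack_result <- function(x, ...) {
  cat(sprintf("<stack_result> %d models, objective %.4f\n",
              length(x$weights), x$objective))
  tab <- data.frame(weight = round(x$weights, 3))
  if (!is.null(x$restacked_weights))
    tab$restacked <- round(x$restacked_weights, 3)
  print(tab)
  invisible(x)
}

#' LOO-based Bayesian R-squared
#'
#' For each posterior draw, the proportion of variance a model is expected
#' to explain in future observations:
#' `R2 = Var(predicted mean) / (Var(predicted mean) + Var(LOO residual))`,
#' where the LOO residuals use the PSIS-weighted leave-one-out expectation
#' of each observation's predicted mean. The marginal variant sets the
#' random intercepts to zero in the predictor (fixed effects only); the
#' conditional variant includes them. Point estimate is the posterior mean;
#' the interval the 2.5/97.5% quantiles.
#'
#' @param fit a [fit_looking()] result.
#' @param variant `"conditional"`, `"marginal"`, or both.
#' @return object of class `r2_result`: one row per variant with estimate
#'   and 95% interval.
#' @export
loo_r2 <- function(fit, variant = c("marginal", "conditional")) {
  variant <- match.arg(variant, several.ok = TRUE)
  rows <- fit$rows
  y <- fit$data$y[rows]
  # PSIS smoothing of the importance ratios, shared across variants
  ll <- fit$loglik
  S <- nrow(ll)
  LW <- apply(ll, 2, function(l) {
    lw <- -l; lw - max(lw)
  })
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  for (i in seq_len(ncol(LW))) {
    lw <- LW[, i]
    if (M >= 5 && S - M >= 1) {
      ord <- order(lw)
      tail_idx <- ord[(S - M + 1):S]
      cut <- lw[ord[S - M]]
      gpd <- fit_generalized_pareto(exp(lw[tail_idx]) - exp(cut))
      if (!is.na(gpd$k)) {
        probs <- (seq_len(M) - 0.5) / M
        sm <- log(exp(cut) + vapply(probs, qgpd, 0, k = gpd$k, sigma = gpd$sigma))
        lw[tail_idx[order(lw[tail_idx])]] <- pmin(sm, 0)
      }
    }
    LW[, i] <- lw
  }
  W <- exp(LW)
  W <- sweep(W, 2, colSums(W), "/")

  out <- lapply(variant, function(v) {
    MU <- predicted_mean(fit,
                         linpred_draws(fit, rows, conditional = v == "conditional"),
                         rows)
    mu_loo <- colSums(W * MU)
    e <- y - mu_loo
    var_e <- stats::var(e)
    var_mu <- apply(MU, 1, stats::var)
    if (all(var_mu + var_e == 0)) stop("loo_r2: zero total variance")
    r2 <- var_mu / (var_mu + var_e)
    c(estimate = mean(r2),
      stats::setNames(stats::quantile(r2, c(0.025, 0.975), names = FALSE),
                      c("low", "high")))
  })
  res <- as.data.frame(do.call(rbind, out))
  res <- cbind(variant = variant, res)
  class(res) <- c("r2_result", "data.frame")
  res
}

#' @export
print.r2_result <- function(x, ...) {
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %s R2: %.3f (%.3f, %.3f)\n", x$variant[i], x$estimate[i],
                x$low[i], x$high[i]))
  invisible(x)
}
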