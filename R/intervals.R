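# Interval construction from posterior draws: quantile credible intervals
# for latent concentrations and Wald-type or posterior-predictive quantile
# prediction intervals for unobserved concentrations.

#' Bundle lower/upper interval bounds
#'
#' @param lower,upper Matrices (or vectors) of bounds, `lower <= upper`
#'   elementwise where both are non-missing.
#' @param level Coverage level `1 - alpha`.
#' @param target `"mu_credible"` or `"V_prediction"`.
#' @param method `"quantile"` or `"wald"`.
#' @return A list of class `interval_set`.
#' @export
interval_set <- function(lower, upper,
                         level = 0.95,
                         target = c("mu_credible", "V_prediction"),
                         method = c("quantile", "wald")) {
  target <- match.arg(target)
  method <- match.arg(method)
  ok <- !is.na(lower) & !is.na(upper)
  if (any(lower[ok] > upper[ok])) {
    stop("lower bound exceeds upper bound", call. = FALSE)
  }
  structure(list(lower = lower, upper = upper, level = level,
                 target = target, method = method),
            class = "interval_set")
}

#' Quantile credible interval from posterior draws
#'
#' The `(alpha/2, 1 - alpha/2)` empirical quantiles of the draws, with
#' linear interpolation of order statistics. Unlike the delta-method
#' intervals of the scaling-factor estimator, these exist for every sample
#' and taxon, including pairs with zero reads.
#'
#' @param mu_draws Numeric vector of at least 100 posterior draws.
#' @param alpha Interval level is `1 - alpha`.
#' @return Named vector `c(lower, upper)`.
#' @export
credible_interval <- function(mu_draws, alpha = 0.05) {
  stopifnot(length(mu_draws) >= 100)
  q <- stats::quantile(mu_draws, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                       type = 7)
  c(lower = q[1], upper = q[2])
}

#' Wald-type prediction interval for an unobserved concentration
#'
#' Combines Poisson sampling variability with posterior uncertainty via the
#' law of total variance: with `m = mean(draws)` and `v = var(draws)`, the
#' interval is `max(0, m +/- z * sqrt(m + v))`, truncated at zero because
#' concentrations are nonnegative.
#'
#' @inheritParams credible_interval
#' @return Named vector `c(lower, upper)` with `lower >= 0`.
#' @export
wald_prediction_interval <- function(mu_draws, alpha = 0.05) {
  stopifnot(length(mu_draws) >= 100)
  m <- mean(mu_draws)
  v <- stats::var(mu_draws)
  z <- stats::qnorm(1 - alpha / 2)
  half <- z * sqrt(m + v)
  c(lower = max(0, m - half), upper = m + half)
}

#' Posterior-predictive quantile prediction interval
#'
#' Draws one Poisson variate per posterior draw of the concentration and
#' takes the `(alpha/2, 1 - alpha/2)` empirical quantiles of those counts —
#' the generative reading of the Poisson observation model.
#'
#' @inheritParams credible_interval
#' @param seed Optional seed for the predictive resampling.
#' @return Named vector `c(lower, upper)`.
#' @export
quantile_prediction_interval <- function(mu_draws, alpha = 0.05,
                                         seed = NULL) {
  stopifnot(length(mu_draws) >= 100)
  if (!is.null(seed)) set.seed(seed)
  v <- rpois_large(length(mu_draws), mu_draws)
  q <- stats::quantile(v, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                       type = 7)
  c(lower = q[1], upper = q[2])
}

# Poisson sampler falling back to a normal approximation for means too
# large for rpois (negligible skew there).
rpois_large <- function(n, lambda) {
  lambda <- rep_len(lambda, n)
  out <- numeric(n)
  big <- lambda > 1e9
  if (any(!big)) out[!big] <- stats::rpois(sum(!big), lambda[!big])
  if (any(big)) {
    out[big] <- round(stats::rnorm(sum(big), lambda[big], sqrt(lambda[big])))
  }
  out
}

#' Credible intervals for every sample and taxon
#'
#' @param fit An `abundance_fit`.
#' @param alpha Interval level is `1 - alpha`.
#' @return An [interval_set()] with `n x q` bound matrices.
#' @export
credible_intervals <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "abundance_fit"))
  lo <- apply(fit$draws$mu, c(2, 3), function(d) {
    stats::quantile(d, alpha / 2, names = FALSE, type = 7)
  })
  up <- apply(fit$draws$mu, c(2, 3), function(d) {
    stats::quantile(d, 1 - alpha / 2, names = FALSE, type = 7)
  })
  interval_set(lo, up, 1 - alpha, "mu_credible", "quantile")
}

#' Predict unobserved concentrations
#'
#' Point predictions and prediction intervals for the realized
#' concentrations `V_ij` of the taxa without concentration data
#' (`j > qobs`). The point prediction is the posterior mean (or median) of
#' `mu_ij`.
#'
#' @param fit An `abundance_fit`.
#' @param alpha Interval level is `1 - alpha`.
#' @param method `"wald"` (default) or `"quantile"`.
#' @param point `"mean"` (default) or `"median"`.
#' @param seed Seed for the quantile method's predictive resampling.
#' @return A list with `V_hat` (`n x (q - qobs)` matrix) and `intervals`
#'   (an [interval_set()]); both empty with a message when `qobs = q`.
#' @export
predict_unobserved <- function(fit, alpha = 0.05,
                               method = c("wald", "quantile"),
                               point = c("mean", "median"), seed = NULL) {
  stopifnot(inherits(fit, "abundance_fit"))
  method <- match.arg(method)
  point <- match.arg(point)
  qobs <- fit$data$qobs
  q <- dim(fit$draws$mu)[3]
  n <- dim(fit$draws$mu)[2]
  if (qobs >= q) {
    message("all taxa have observed concentrations; nothing to predict")
    empty <- matrix(numeric(0), n, 0)
    return(list(V_hat = empty,
                intervals = interval_set(empty, empty, 1 - alpha,
                                         "V_prediction", method)))
  }
  unobs <- (qobs + 1):q
  mu_unobs <- fit$draws$mu[, , unobs, drop = FALSE]
  stat <- if (point == "mean") mean else stats::median
  V_hat <- apply(mu_unobs, c(2, 3), stat)
  if (!is.null(seed)) set.seed(seed)
  bounds <- apply(mu_unobs, c(2, 3), function(d) {
    if (method == "wald") wald_prediction_interval(d, alpha)
    else quantile_prediction_interval(d, alpha)
  })
  lo <- bounds[1, , ]; up <- bounds[2, , ]
  dn <- list(fit$data$counts$sample_ids, fit$data$counts$taxon_ids[unobs])
  dimnames(V_hat) <- dn
  lo <- matrix(lo, n, length(unobs), dimnames = dn)
  up <- matrix(up, n, length(unobs), dimnames = dn)
  list(V_hat = V_hat,
       intervals = interval_set(lo, up, 1 - alpha, "V_prediction", method))
}
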