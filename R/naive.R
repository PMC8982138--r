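# The scaling-factor ("naive") estimator of concentrations and its
# delta-method confidence and prediction intervals.

#' Per-sample scaling factor
#'
#' The implied scaling between concentration units and read counts for one
#' sample, aggregated over the taxa with observed concentrations:
#' `s_i = sum(V_i) / sum(W_obs_i)`.
#'
#' @param V_row Observed concentrations for one sample (length `qobs`).
#' @param W_obs_row Read counts for the same sample restricted to the
#'   observed taxa (length `qobs`).
#' @param sample_id Optional identifier used in error messages.
#' @return A positive scalar.
#' @examples
#' scaling_factor(c(10, 20), c(5, 10))  # 2
#' @export
scaling_factor <- function(V_row, W_obs_row, sample_id = NULL) {
  stopifnot(length(V_row) == length(W_obs_row))
  tw <- sum(W_obs_row)
  if (tw <= 0) {
    stop("scaling factor undefined: no reads on observed taxa",
         if (!is.null(sample_id)) paste0(" in sample ", sample_id),
         call. = FALSE)
  }
  sum(V_row) / tw
}

#' Naive point estimate of concentrations for one sample
#'
#' Scales the read counts by the per-sample factor: `mu_hat_ij = s_i * W_ij`.
#' Zeros in `W` are preserved as zero estimates.
#'
#' @param s_i Positive scaling factor from [scaling_factor()].
#' @param W_row Read counts for one sample (length `q`).
#' @return Nonnegative estimates of length `q`.
#' @export
naive_point <- function(s_i, W_row) {
  stopifnot(is.numeric(s_i), length(s_i) == 1, s_i > 0)
  s_i * W_row
}

#' Delta-method variance of the log naive estimate
#'
#' Plug-in variance of `log(mu_hat_ij)` treating the total observed
#' concentration as Poisson and the reads as multinomial, with `T_V` and
#' `T_W` the totals of `V` and `W` over the observed taxa:
#' `1/T_V + 1/W_ij - 1/T_W` for an observed taxon (`j <= qobs`, where
#' `W_ij` is a component of `T_W` and the positive covariance reduces the
#' variance of the log ratio), and `1/T_V + 1/W_ij + 1/T_W` for an
#' unobserved taxon (`j > qobs`, where `W_ij` and `T_W` are almost
#' uncorrelated and the two log terms add). Both forms are validated
#' against a parametric bootstrap in the test suite. Returns `NA` when
#' `W_ij = 0` (no estimate). A negative computed value (possible for an
#' observed taxon carrying nearly all reads) is clamped to zero with a
#' warning.
#'
#' @param V_row Observed concentrations (length `qobs`).
#' @param W_row Read counts for all `q` taxa, observed taxa first.
#' @param j Taxon index into `W_row`.
#' @return A nonnegative scalar, or `NA` if `W_row[j] == 0`.
#' @export
naive_log_variance <- function(V_row, W_row, j) {
  qobs <- length(V_row)
  stopifnot(length(W_row) >= qobs, j >= 1, j <= length(W_row))
  w <- W_row[j]
  if (w == 0) return(NA_real_)
  tv <- sum(V_row)
  tw <- sum(W_row[seq_len(qobs)])
  if (tv <= 0 || tw <= 0) {
    stop("log-variance undefined: zero observed totals", call. = FALSE)
  }
  v <- 1 / tv + 1 / w + if (j <= qobs) -1 / tw else 1 / tw
  if (v < 0) {
    warning("negative delta-method variance clamped to 0")
    v <- 0
  }
  v
}

lognormal_interval <- function(mu_hat, sd_log, alpha) {
  z <- stats::qnorm(1 - alpha / 2)
  c(lower = mu_hat * exp(-z * sd_log), upper = mu_hat * exp(z * sd_log))
}

#' Delta-method confidence interval for a concentration
#'
#' `exp(log(mu_hat) +/- z_{1-alpha/2} * sqrt(var_log))`. Only defined for a
#' positive point estimate; returns a pair of `NA`s when `mu_hat = 0`.
#'
#' @param mu_hat Naive point estimate.
#' @param var_log Variance of the log estimate from [naive_log_variance()].
#' @param alpha Interval level is `1 - alpha`; default 0.05.
#' @return Named vector `c(lower, upper)`.
#' @export
naive_confidence_interval <- function(mu_hat, var_log, alpha = 0.05) {
  if (is.na(mu_hat) || mu_hat <= 0 || is.na(var_log)) {
    return(c(lower = NA_real_, upper = NA_real_))
  }
  lognormal_interval(mu_hat, sqrt(var_log), alpha)
}

#' Delta-method prediction interval for an unobserved concentration
#'
#' As [naive_confidence_interval()] but with standard error
#' `sqrt(1/mu_hat + var_log)`, adding the Poisson variability of the
#' realized concentration around its mean.
#'
#' @inheritParams naive_confidence_interval
#' @return Named vector `c(lower, upper)`.
#' @export
naive_prediction_interval <- function(mu_hat, var_log, alpha = 0.05) {
  if (is.na(mu_hat) || mu_hat <= 0 || is.na(var_log)) {
    return(c(lower = NA_real_, upper = NA_real_))
  }
  lognormal_interval(mu_hat, sqrt(1 / mu_hat + var_log), alpha)
}

#' Naive estimation over a full paired dataset
#'
#' Applies the scaling-factor estimator to every sample and taxon of an
#' aligned paired dataset, with delta-method confidence intervals for the
#' latent concentrations and prediction intervals for the unobserved
#' concentrations. Pairs with zero reads have a zero point estimate and
#' missing intervals.
#'
#' @param paired A `paired_abundance` from [align_tables()] or
#'   [simulate_dataset()].
#' @param alpha Interval level is `1 - alpha`.
#' @return A list of class `naive_estimate`: `s_hat` (length `n`), `mu_hat`
#'   and `var_log_mu_hat` (`n x q`), `ci` and `pi` (interval sets; the
#'   prediction set covers only the unobserved columns).
#' @export
naive_estimate <- function(paired, alpha = 0.05) {
  stopifnot(inherits(paired, "paired_abundance"))
  W <- paired$counts$W
  V <- paired$conc$V
  qobs <- paired$qobs
  n <- nrow(W); q <- ncol(W)
  s_hat <- vapply(seq_len(n), function(i) {
    scaling_factor(V[i, ], W[i, seq_len(qobs)],
                   sample_id = paired$counts$sample_ids[i])
  }, numeric(1))
  mu_hat <- s_hat * W
  var_log <- matrix(NA_real_, n, q, dimnames = dimnames(W))
  for (i in seq_len(n)) {
    for (j in seq_len(q)) {
      if (W[i, j] > 0) var_log[i, j] <- naive_log_variance(V[i, ], W[i, ], j)
    }
  }
  lo_ci <- up_ci <- matrix(NA_real_, n, q, dimnames = dimnames(W))
  lo_pi <- up_pi <- matrix(NA_real_, n, q - qobs)
  dimnames(lo_pi) <- dimnames(up_pi) <-
    list(rownames(W), colnames(W)[(qobs + 1):q])
  for (i in seq_len(n)) {
    for (j in seq_len(q)) {
      ci <- naive_confidence_interval(mu_hat[i, j], var_log[i, j], alpha)
      lo_ci[i, j] <- ci[1]; up_ci[i, j] <- ci[2]
      if (j > qobs) {
        pi_ <- naive_prediction_interval(mu_hat[i, j], var_log[i, j], alpha)
        lo_pi[i, j - qobs] <- pi_[1]; up_pi[i, j - qobs] <- pi_[2]
      }
    }
  }
  structure(
    list(s_hat = s_hat, mu_hat = mu_hat, var_log_mu_hat = var_log,
         ci = interval_set(lo_ci, up_ci, 1 - alpha, "mu_credible", "wald"),
         pi = interval_set(lo_pi, up_pi, 1 - alpha, "V_prediction", "wald"),
         alpha = alpha),
    class = "naive_estimate"
  )
}
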