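# Performance metrics and the replicated simulation study / jackknife
# validation surfaces.

#' Root mean squared error
#'
#' @param est,truth Numeric matrices (or vectors) of matching shape.
#' @param subset Optional logical mask or index vector restricting the
#'   cells that enter the mean.
#' @return `sqrt(mean((est - truth)^2))` over the subset.
#' @export
rmse <- function(est, truth, subset = NULL) {
  stopifnot(length(est) == length(truth))
  d <- est - truth
  if (!is.null(subset)) d <- d[subset]
  if (length(d) == 0) stop("empty subset in rmse", call. = FALSE)
  sqrt(mean(d^2))
}

#' Root mean squared prediction error
#'
#' RMSE of predicted against realized concentrations over the unobserved
#' block; identical arithmetic to [rmse()].
#'
#' @param pred Predicted concentrations for the unobserved taxa.
#' @param realized Realized concentrations for the same cells.
#' @param subset Optional restriction as in [rmse()].
#' @return A nonnegative scalar.
#' @export
rmspe <- function(pred, realized, subset = NULL) {
  rmse(pred, realized, subset)
}

#' Empirical interval coverage
#'
#' Fraction of non-excluded cells whose truth lies inside the closed
#' interval `[lower, upper]`. The exclusion mask implements the convention
#' that pairs without a defined interval (zero scaling-factor estimates)
#' do not enter coverage averages.
#'
#' @param intervals An [interval_set()].
#' @param truth Matrix of true values, same shape as the bounds.
#' @param exclude Optional logical matrix marking cells to drop.
#' @return A fraction in `[0, 1]`.
#' @export
empirical_coverage <- function(intervals, truth, exclude = NULL) {
  stopifnot(inherits(intervals, "interval_set"))
  lo <- intervals$lower; up <- intervals$upper
  stopifnot(length(lo) == length(truth))
  keep <- if (is.null(exclude)) rep(TRUE, length(truth)) else !exclude
  keep <- keep & !is.na(lo) & !is.na(up)
  if (!any(keep)) stop("all cells excluded from coverage", call. = FALSE)
  mean(lo[keep] <= truth[keep] & truth[keep] <= up[keep])
}

#' Fraction of zero read counts
#'
#' Share of sample-taxon pairs in the analyzed (retained) table whose read
#' count — and hence whose scaling-factor estimate — is zero.
#'
#' @param W Read-count matrix.
#' @return A fraction in `[0, 1]`.
#' @export
zero_fraction <- function(W) {
  mean(W == 0)
}

#' Conditional mean relative abundance of one taxon
#'
#' Mean of `W_ij / M_i` over the samples where the taxon is present
#' (`W_ij > 0`); the statistic used to rank observed taxa by how abundant
#' they are when present.
#'
#' @param W_col Read counts of one taxon across samples.
#' @param M Read depths of the same samples.
#' @return A fraction, or `NA` (with a warning) if the taxon is absent
#'   everywhere.
#' @export
conditional_mean_relative_abundance <- function(W_col, M) {
  stopifnot(length(W_col) == length(M))
  pos <- W_col > 0
  if (!any(pos)) {
    warning("taxon absent in every sample: statistic undefined")
    return(NA_real_)
  }
  mean(W_col[pos] / M[pos])
}

#' Replicated zero-count fraction under the equal-efficiency process
#'
#' Simulates `B` independent datasets (equal efficiencies, default
#' generator conditions) and returns the average percentage of retained
#' sample-taxon pairs with a zero read count — the pairs for which the
#' scaling-factor estimator produces no interval. `beta` is redrawn every
#' replicate.
#'
#' @param q Number of simulated taxa.
#' @param qobs Observed taxa requested (capped by the retained count; the
#'   statistic does not depend on the observed-taxon selection).
#' @param B Number of replicates.
#' @param n Samples per replicate.
#' @param seed Master seed.
#' @return Mean percentage (0-100) across replicates, with the
#'   per-replicate percentages as attribute `"replicates"`.
#' @export
zero_fraction_study <- function(q, qobs = 7, B = 50, n = 100, seed = 1) {
  set.seed(seed)
  rep_seeds <- sample.int(2^31 - 2, B)
  zf <- vapply(seq_len(B), function(b) {
    cfg <- simulation_config(q = q, qobs = min(qobs, q - 1), n = n,
                             sigma_e = 0, seed = rep_seeds[b])
    sim <- suppressWarnings(simulate_dataset(cfg))
    100 * zero_fraction(sim$paired$counts$W)
  }, numeric(1))
  structure(mean(zf), replicates = zf)
}

metrics_row <- function(sim, estimator, alpha, mu_hat, ci, pred = NULL,
                        pi_ = NULL, exclude_mu = NULL, exclude_V = NULL,
                        rhat_median = NA_real_, note = "") {
  truth_mu <- aligned_truth(sim, "mu")
  truth_V <- aligned_truth(sim, "V_full")
  qobs <- sim$paired$qobs
  q <- ncol(truth_mu)
  unobs <- if (qobs < q) (qobs + 1):q else integer(0)
  data.frame(
    estimator = estimator,
    q_retained = q,
    qobs = qobs,
    rmse_mu = rmse(mu_hat, truth_mu),
    coverage_mu = empirical_coverage(ci, truth_mu, exclude_mu),
    rmspe_V = if (length(unobs) && !is.null(pred)) {
      rmspe(pred, truth_V[, unobs, drop = FALSE])
    } else NA_real_,
    coverage_V = if (length(unobs) && !is.null(pi_)) {
      empirical_coverage(pi_, truth_V[, unobs, drop = FALSE], exclude_V)
    } else NA_real_,
    zero_fraction = zero_fraction(sim$paired$counts$W),
    n_excluded_naive = sum(sim$paired$counts$W == 0),
    rhat_mu_median = rhat_median,
    note = note,
    stringsAsFactors = FALSE
  )
}

#' Replicated simulation study
#'
#' Generates `B` independent datasets from a [simulation_config()] (with
#' per-replicate sub-seeds derived from its master seed; `beta` is redrawn
#' each replicate unless fixed in the config), applies the requested
#' estimators, and reports replicate-level error, coverage, and sparsity
#' metrics. Sampler failures are recorded in the `note` column and the
#' study continues.
#'
#' @param cfg A [simulation_config()].
#' @param B Number of Monte Carlo replicates.
#' @param estimators Subset of `"naive"`, `"efficiency_naive"`,
#'   `"varying_efficiency"`.
#' @param mcmc An [mcmc_config()] used for the Bayesian estimators (its
#'   seed is replaced by a per-replicate seed).
#' @param hyper A [hyperparameters()] object.
#' @param alpha Interval level is `1 - alpha`.
#' @return A data frame with one row per (replicate, estimator).
#' @export
run_simulation_study <- function(cfg, B = 10,
                                 estimators = c("naive", "efficiency_naive",
                                                "varying_efficiency"),
                                 mcmc = mcmc_config(),
                                 hyper = hyperparameters(), alpha = 0.05) {
  stopifnot(inherits(cfg, "simulation_config"), B >= 1)
  estimators <- match.arg(estimators, several.ok = TRUE)
  set.seed(cfg$seed)
  rep_seeds <- sample.int(2^31 - 2, B)
  rows <- list()
  for (b in seq_len(B)) {
    cfg_b <- cfg
    cfg_b$seed <- rep_seeds[b]
    sim <- simulate_dataset(cfg_b)
    paired <- sim$paired
    for (est in estimators) {
      row <- tryCatch({
        if (est == "naive") {
          ne <- naive_estimate(paired, alpha)
          W <- paired$counts$W
          qobs <- paired$qobs
          unobs_zero <- W[, -seq_len(qobs), drop = FALSE] == 0
          metrics_row(sim, est, alpha, ne$mu_hat, ne$ci,
                      pred = ne$mu_hat[, -seq_len(qobs), drop = FALSE],
                      pi_ = ne$pi, exclude_mu = W == 0,
                      exclude_V = unobs_zero)
        } else {
          spec <- model_spec(variant = est, hyper = hyper)
          mc <- mcmc
          mc$seed <- (rep_seeds[b] + match(est, estimators)) %% (2^31 - 2)
          fit <- fit_abundance(paired, spec, mc)
          mu_hat <- apply(fit$draws$mu, c(2, 3), mean)
          ci <- credible_intervals(fit, alpha)
          pred <- predict_unobserved(fit, alpha)
          metrics_row(sim, est, alpha, mu_hat, ci,
                      pred = pred$V_hat, pi_ = pred$intervals,
                      rhat_median = fit$diagnostics$rhat_mu_median)
        }
      }, error = function(err) {
        truth_mu <- aligned_truth(sim, "mu")
        data.frame(estimator = est, q_retained = ncol(truth_mu),
                   qobs = paired$qobs, rmse_mu = NA_real_,
                   coverage_mu = NA_real_, rmspe_V = NA_real_,
                   coverage_V = NA_real_,
                   zero_fraction = zero_fraction(paired$counts$W),
                   n_excluded_naive = sum(paired$counts$W == 0),
                   rhat_mu_median = NA_real_,
                   note = paste("failed:", conditionMessage(err)),
                   stringsAsFactors = FALSE)
      })
      row$replicate <- b
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out[, c("replicate", setdiff(names(out), "replicate"))]
}

#' Leave-one-taxon-out jackknife validation
#'
#' Restricts the data to the taxa with observed concentrations, removes
#' each in turn from the concentration table, refits, and predicts the
#' withheld concentrations — measuring how well each estimator recovers
#' concentration data it has not seen. Reports per-fold prediction-interval
#' coverage and mean squared prediction error against the withheld column.
#' Fold seeds derive from the MCMC master seed plus the taxon index, so
#' folds are reproducible independently of execution order.
#'
#' @param paired A `paired_abundance` with `qobs >= 2` observed taxa.
#' @param estimators Subset of `"naive"`, `"efficiency_naive"`,
#'   `"varying_efficiency"`.
#' @param mcmc An [mcmc_config()].
#' @param hyper A [hyperparameters()] object.
#' @param alpha Interval level is `1 - alpha`.
#' @return A data frame with one row per (fold, estimator): withheld taxon,
#'   coverage, and MSPE. Failed folds carry a `note`.
#' @export
jackknife_loo <- function(paired,
                          estimators = c("naive", "efficiency_naive",
                                         "varying_efficiency"),
                          mcmc = mcmc_config(),
                          hyper = hyperparameters(), alpha = 0.05) {
  stopifnot(inherits(paired, "paired_abundance"), paired$qobs >= 2)
  estimators <- match.arg(estimators, several.ok = TRUE)
  qobs <- paired$qobs
  # restrict to the observed taxa only
  counts_obs <- count_table(paired$counts$W[, seq_len(qobs), drop = FALSE])
  V <- paired$conc$V
  rows <- list()
  for (k in seq_len(qobs)) {
    conc_k <- concentration_table(V[, -k, drop = FALSE])
    pair_k <- align_tables(counts_obs, conc_k)
    held_out <- V[, k]
    for (est in estimators) {
      row <- tryCatch({
        if (est == "naive") {
          ne <- naive_estimate(pair_k, alpha)
          pred <- ne$mu_hat[, qobs]     # withheld taxon sits last
          covered <- !is.na(ne$pi$lower[, 1]) &
            ne$pi$lower[, 1] <= held_out & held_out <= ne$pi$upper[, 1]
          usable <- !is.na(ne$pi$lower[, 1])
          data.frame(taxon = paired$conc$taxon_ids[k], estimator = est,
                     coverage = if (any(usable)) mean(covered[usable])
                                else NA_real_,
                     mspe = mean((pred - held_out)^2), note = "",
                     stringsAsFactors = FALSE)
        } else {
          spec <- model_spec(variant = est, hyper = hyper)
          mc <- mcmc
          mc$seed <- (mcmc$seed + 131L * k) %% (2^31 - 2)
          fit <- fit_abundance(pair_k, spec, mc)
          pred <- predict_unobserved(fit, alpha)
          lo <- pred$intervals$lower[, 1]; up <- pred$intervals$upper[, 1]
          data.frame(taxon = paired$conc$taxon_ids[k], estimator = est,
                     coverage = mean(lo <= held_out & held_out <= up),
                     mspe = mean((pred$V_hat[, 1] - held_out)^2), note = "",
                     stringsAsFactors = FALSE)
        }
      }, error = function(err) {
        data.frame(taxon = paired$conc$taxon_ids[k], estimator = est,
                   coverage = NA_real_, mspe = NA_real_,
                   note = paste("failed:", conditionMessage(err)),
                   stringsAsFactors = FALSE)
      })
      row$fold <- k
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out[, c("fold", setdiff(names(out), "fold"))]
}
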