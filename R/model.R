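# The hierarchical multinomial-Poisson model: prior hyperparameters, model
# variants, efficiency centering, and the joint log density.

#' Prior hyperparameters for the hierarchical model
#'
#' Defaults follow the scale of log concentrations typical of qPCR data
#' (log-variances near 50): a diffuse normal prior on the mean log
#' concentrations `beta` and a diffuse lognormal prior on the diagonal of
#' the log-concentration covariance. The efficiency spread variance
#' `sigma_e^2` carries an inverse-gamma prior with shape `alpha_sigma` and
#' scale `kappa_sigma` (density proportional to
#' `x^(-alpha-1) exp(-kappa/x)`).
#'
#' @param sigma_beta_sq Prior variance of each `beta_j` (default 50).
#' @param sigma_Sigma_sq Prior log-variance of each `Sigma_jj` (default 50).
#' @param alpha_sigma,kappa_sigma Inverse-gamma shape and scale for
#'   `sigma_e^2` (defaults 2 and 1).
#' @param sigma_beta0_sq,sigma_beta1_sq Prior variances for the intercept
#'   and covariate-effect coefficients of the covariate-adjusted mean model
#'   (defaults `1.62^2` and `1`).
#' @param alpha_level Default interval level is `1 - alpha_level`.
#' @return A list of class `hyperparameters`.
#' @export
hyperparameters <- function(sigma_beta_sq = 50, sigma_Sigma_sq = 50,
                            alpha_sigma = 2, kappa_sigma = 1,
                            sigma_beta0_sq = 1.62^2, sigma_beta1_sq = 1,
                            alpha_level = 0.05) {
  vals <- c(sigma_beta_sq = sigma_beta_sq, sigma_Sigma_sq = sigma_Sigma_sq,
            alpha_sigma = alpha_sigma, kappa_sigma = kappa_sigma,
            sigma_beta0_sq = sigma_beta0_sq, sigma_beta1_sq = sigma_beta1_sq)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all hyperparameters must be strictly positive", call. = FALSE)
  }
  if (alpha_level <= 0 || alpha_level >= 1) {
    stop("alpha_level must lie in (0, 1)", call. = FALSE)
  }
  structure(c(as.list(vals), list(alpha_level = alpha_level)),
            class = "hyperparameters")
}

#' Specify a model variant
#'
#' The `varying_efficiency` variant is the full model with taxon-specific
#' efficiencies `e_j ~ Lognormal(0, sigma_e^2)` (soft centering through the
#' zero-mean prior); `efficiency_naive` fixes `e_j = 1` for all taxa. Hard
#' centering divides the efficiencies by their geometric mean over the
#' observed taxa (`hard_observed`) or all taxa (`hard_all`) as a
#' deterministic transform.
#'
#' @param variant `"varying_efficiency"` (default) or `"efficiency_naive"`.
#' @param covariate_adjusted If `TRUE`, the mean log concentration for
#'   sample `i` is `beta0 + beta1 * X_i` for a per-sample covariate `X`.
#' @param hyper A [hyperparameters()] object.
#' @param centering `"soft"` (default), `"hard_observed"`, or `"hard_all"`.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(variant = c("varying_efficiency", "efficiency_naive"),
                       covariate_adjusted = FALSE,
                       hyper = hyperparameters(),
                       centering = c("soft", "hard_observed", "hard_all")) {
  structure(
    list(variant = match.arg(variant),
         covariate_adjusted = isTRUE(covariate_adjusted),
         hyper = hyper,
         centering = match.arg(centering)),
    class = "model_spec"
  )
}

#' Multinomial read probabilities under taxon-specific efficiencies
#'
#' `p_ij = mu_ij e_j / sum_l mu_il e_l`. With all efficiencies equal this
#' reduces to the plain compositional probabilities `mu_ij / sum_l mu_il`.
#' Scaling `e` by a positive constant leaves `p` unchanged, which is why
#' the efficiencies are identified only up to scale and must be centered.
#'
#' @param mu_row Positive concentrations for one sample (length `q`).
#' @param e Positive efficiencies (length `q`).
#' @return Probabilities summing to one.
#' @export
relative_abundance_probs <- function(mu_row, e) {
  stopifnot(length(mu_row) == length(e))
  if (any(mu_row <= 0) || any(e <= 0)) {
    stop("concentrations and efficiencies must be strictly positive",
         call. = FALSE)
  }
  # normalize on the log scale to dodge overflow for widely spread mu
  lw <- log(mu_row) + log(e)
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Hard-center efficiencies to unit geometric mean
#'
#' Divides each efficiency by the geometric mean of the efficiencies over
#' `index_set`, so the output has geometric mean exactly one over that set.
#' Idempotent.
#'
#' @param e_raw Positive efficiencies.
#' @param index_set Indices of the taxa defining the geometric mean
#'   (default: all).
#' @return Centered efficiencies.
#' @export
hard_center <- function(e_raw, index_set = seq_along(e_raw)) {
  stopifnot(length(index_set) >= 1, all(e_raw > 0))
  e_raw / exp(mean(log(e_raw[index_set])))
}

#' Covariate-adjusted mean log concentration
#'
#' Linear predictor `beta0 + beta1 * X_i` for a scalar per-sample covariate
#' (e.g., case/control status).
#'
#' @param beta0,beta1 Length-`q` coefficient vectors.
#' @param X_i Scalar covariate value for one sample.
#' @return Length-`q` mean vector.
#' @export
covariate_mean <- function(beta0, beta1, X_i) {
  stopifnot(length(beta0) == length(beta1), length(X_i) == 1)
  beta0 + beta1 * X_i
}

#' Construct a latent state of the hierarchical model
#'
#' @param mu `n x q` matrix of strictly positive true concentrations.
#' @param e Length-`q` strictly positive efficiencies.
#' @param beta Length-`q` mean log concentrations (unadjusted model).
#' @param Sigma_diag Length-`q` strictly positive variances of the log
#'   concentrations.
#' @param sigma_e_sq Positive variance of the log efficiencies.
#' @param beta0,beta1 Coefficients for the covariate-adjusted mean model
#'   (used instead of `beta` when both are supplied).
#' @return A list of class `latent_state`.
#' @export
latent_state <- function(mu, e, beta = NULL, Sigma_diag, sigma_e_sq,
                         beta0 = NULL, beta1 = NULL) {
  mu <- as.matrix(mu)
  q <- ncol(mu)
  stopifnot(length(e) == q, length(Sigma_diag) == q)
  if (any(mu <= 0) || any(e <= 0) || any(Sigma_diag <= 0) || sigma_e_sq <= 0) {
    stop("mu, e, Sigma_diag and sigma_e_sq must be strictly positive",
         call. = FALSE)
  }
  if (is.null(beta) && (is.null(beta0) || is.null(beta1))) {
    stop("supply either beta or both beta0 and beta1", call. = FALSE)
  }
  structure(
    list(mu = mu, e = e, beta = beta, Sigma_diag = Sigma_diag,
         sigma_e_sq = sigma_e_sq, beta0 = beta0, beta1 = beta1),
    class = "latent_state"
  )
}

log_invgamma_density <- function(x, shape, scale) {
  shape * log(scale) - lgamma(shape) - (shape + 1) * log(x) - scale / x
}

#' Joint log density of data and latent state
#'
#' Sums the log densities of every model component: Poisson observed
#' concentrations, multinomial reads with efficiency-weighted
#' probabilities, the lognormal concentration hierarchy (normal on
#' `log mu`), the `beta` prior, the lognormal `Sigma_jj` prior, and (for
#' the varying-efficiency variant) the lognormal efficiency prior with its
#' inverse-gamma hyperprior. The per-component terms are attached as
#' attribute `"terms"`.
#'
#' @param state A [latent_state()].
#' @param data A `paired_abundance`.
#' @param spec A [model_spec()].
#' @param X Optional per-sample covariate vector for the covariate-adjusted
#'   mean model.
#' @return The joint log density (a finite scalar for valid states), with a
#'   named numeric attribute `"terms"`.
#' @export
log_joint_density <- function(state, data, spec, X = NULL) {
  stopifnot(inherits(state, "latent_state"),
            inherits(data, "paired_abundance"),
            inherits(spec, "model_spec"))
  W <- data$counts$W
  V <- data$conc$V
  M <- data$counts$M
  qobs <- data$qobs
  n <- nrow(W); q <- ncol(W)
  if (!all(dim(state$mu) == c(n, q))) {
    stop("mu has dimensions ", paste(dim(state$mu), collapse = "x"),
         " but the data have ", n, "x", q, call. = FALSE)
  }
  hy <- spec$hyper
  e_used <- if (spec$variant == "efficiency_naive") rep(1, q) else state$e

  term_V <- sum(stats::dpois(V, state$mu[, seq_len(qobs), drop = FALSE],
                             log = TRUE))
  term_W <- sum(vapply(seq_len(n), function(i) {
    stats::dmultinom(W[i, ], size = M[i],
                     prob = relative_abundance_probs(state$mu[i, ], e_used),
                     log = TRUE)
  }, numeric(1)))

  if (spec$covariate_adjusted) {
    if (is.null(X)) stop("covariate-adjusted model requires X", call. = FALSE)
    stopifnot(length(X) == n)
    mean_mat <- t(vapply(X, function(x) covariate_mean(state$beta0,
                                                       state$beta1, x),
                         numeric(q)))
    term_beta <- sum(stats::dnorm(state$beta0, 0, sqrt(hy$sigma_beta0_sq),
                                  log = TRUE)) +
      sum(stats::dnorm(state$beta1, 0, sqrt(hy$sigma_beta1_sq), log = TRUE))
  } else {
    mean_mat <- matrix(state$beta, n, q, byrow = TRUE)
    term_beta <- sum(stats::dnorm(state$beta, 0, sqrt(hy$sigma_beta_sq),
                                  log = TRUE))
  }
  term_mu <- sum(stats::dnorm(log(state$mu), mean_mat,
                              matrix(sqrt(state$Sigma_diag), n, q,
                                     byrow = TRUE), log = TRUE))
  term_Sigma <- sum(stats::dlnorm(state$Sigma_diag, 0,
                                  sqrt(hy$sigma_Sigma_sq), log = TRUE))

  terms <- c(V = term_V, W = term_W, mu = term_mu, beta = term_beta,
             Sigma = term_Sigma)
  if (spec$variant == "varying_efficiency") {
    terms["e"] <- sum(stats::dlnorm(state$e, 0, sqrt(state$sigma_e_sq),
                                    log = TRUE))
    terms["sigma_e_sq"] <- log_invgamma_density(state$sigma_e_sq,
                                                hy$alpha_sigma,
                                                hy$kappa_sigma)
  }
  structure(sum(terms), terms = terms)
}
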