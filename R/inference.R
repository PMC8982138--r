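# Posterior sampling for the hierarchical model via Gibbs/slice MCMC
# (JAGS), with deterministic initialization and convergence diagnostics.

#' MCMC settings
#'
#' Desk-scale defaults (4 chains, 1000 warmup, 500 retained draws per
#' chain) keep routine fits to seconds; set `warmup_iters = 10000`,
#' `total_iters = 10500` for full-scale runs.
#'
#' @param chains Number of chains (at least 2 so that R-hat is defined).
#' @param warmup_iters Adaptation plus burn-in iterations per chain.
#' @param total_iters Total iterations per chain; `total_iters -
#'   warmup_iters` draws are retained.
#' @param seed Integer master seed; per-chain RNG seeds derive from it.
#' @param init_strategy `"naive_anchor"` (deterministic initialization at
#'   the scaling-factor estimate) or `"random"` (jittered around it).
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 4, warmup_iters = 1000, total_iters = 1500,
                        seed = 1,
                        init_strategy = c("naive_anchor", "random")) {
  stopifnot(chains >= 2, warmup_iters >= 1, total_iters > warmup_iters)
  structure(
    list(chains = as.integer(chains),
         warmup_iters = as.integer(warmup_iters),
         total_iters = as.integer(total_iters),
         seed = as.integer(seed),
         init_strategy = match.arg(init_strategy)),
    class = "mcmc_config"
  )
}

# Model code for the sampler, assembled per variant/centering/covariate.
#
# The chain runs on lambda_ij = mu_ij * e_j, the quantity the multinomial
# reads identify directly, with mu recovered as lambda / e. For unobserved
# taxa under soft centering the intercept and log efficiency enter the
# likelihood only through their sum, so the sampler draws that sum
# (`blam`) against the data and then the log efficiency from its exact
# normal conditional given the sum — an analytic reparameterization of the
# same joint model that removes the ridge a one-scalar-at-a-time sampler
# would otherwise have to random-walk along.
jags_model_string <- function(spec, n, q, qobs) {
  hy <- spec$hyper
  varying <- spec$variant == "varying_efficiency"
  covadj <- spec$covariate_adjusted
  sb_sq <- if (covadj) hy$sigma_beta0_sq else hy$sigma_beta_sq
  b0 <- if (covadj) "beta0" else "beta"
  mean_term <- paste0(b0, "[j]",
                      if (covadj) " + beta1[j] * X[i]",
                      if (varying) " + log_e[j]")
  marginalize <- varying && spec$centering == "soft" && qobs < q

  lines <- c(
    "model {",
    "  for (i in 1:n) {",
    "    for (j in 1:qobs) { V[i,j] ~ dpois(mu[i,j]) }",
    "    W[i,1:q] ~ dmulti(lambda[i,1:q], M[i])",
    "    for (j in 1:q) {",
    sprintf("      log_lambda[i,j] ~ dnorm(%s, tau_mu[j])", mean_term),
    "      lambda[i,j] <- exp(log_lambda[i,j])",
    if (varying) "      mu[i,j] <- lambda[i,j] / e[j]"
    else         "      mu[i,j] <- lambda[i,j]",
    "    }",
    "  }",
    "  for (j in 1:q) {",
    sprintf("    log_Sigma[j] ~ dnorm(0, %.17g)", 1 / hy$sigma_Sigma_sq),
    "    Sigma_diag[j] <- exp(log_Sigma[j])",
    "    tau_mu[j] <- exp(-log_Sigma[j])",
    if (covadj) sprintf("    beta1[j] ~ dnorm(0, %.17g)",
                        1 / hy$sigma_beta1_sq),
    if (varying) "    e[j] <- exp(log_e[j])",
    "  }"
  )
  if (varying) {
    lines <- c(lines, sprintf(
      "  tau_e ~ dgamma(%.17g, %.17g)\n  sigma_e_sq <- 1 / tau_e",
      hy$alpha_sigma, hy$kappa_sigma))
  }
  if (!varying) {
    lines <- c(lines, sprintf(
      "  for (j in 1:q) { %s[j] ~ dnorm(0, %.17g) }", b0, 1 / sb_sq))
  } else if (spec$centering != "soft") {
    # hard centering: raw efficiencies centered by a deterministic
    # geometric-mean transform
    upper <- if (spec$centering == "hard_observed") "qobs" else "q"
    lines <- c(lines,
      "  for (j in 1:q) {",
      sprintf("    %s[j] ~ dnorm(0, %.17g)", b0, 1 / sb_sq),
      "    log_e_raw[j] ~ dnorm(0, tau_e)",
      sprintf("    log_e[j] <- log_e_raw[j] - mean(log_e_raw[1:%s])", upper),
      "  }")
  } else {
    lines <- c(lines,
      sprintf("  for (j in 1:%d) {", qobs),
      sprintf("    %s[j] ~ dnorm(0, %.17g)", b0, 1 / sb_sq),
      "    log_e[j] ~ dnorm(0, tau_e)",
      "  }")
    if (marginalize) {
      lines <- c(lines,
        sprintf("  v_blam <- %.17g + sigma_e_sq", sb_sq),
        "  w_e <- sigma_e_sq / v_blam",
        sprintf("  prec_e_cond <- v_blam / (%.17g * sigma_e_sq)", sb_sq),
        sprintf("  for (j in %d:%d) {", qobs + 1, q),
        "    blam[j] ~ dnorm(0, 1 / v_blam)",
        "    log_e[j] ~ dnorm(blam[j] * w_e, prec_e_cond)",
        sprintf("    %s[j] <- blam[j] - log_e[j]", b0),
        "  }")
    }
  }
  paste(c(lines, "}", ""), collapse = "\n")
}

#' Initial latent states for the chains
#'
#' The `naive_anchor` strategy starts the latent log concentrations (via
#' the sampler's `log lambda` scale, with efficiencies started at one) at
#' the log scaling-factor estimate with a 0.5 pseudo-count
#' (`log(s_i W_ij + 0.5)`), the mean coefficients at the column means of
#' that anchor, `Sigma_jj` at one, and `sigma_e^2` at its prior mode
#' `kappa / (alpha + 1)`. The `random` strategy jitters the anchor with a
#' per-chain seed. Samples whose observed subcomposition has no reads fall
#' back to the global (all-sample) scaling factor. Entries of partially
#' deterministic coefficient vectors are `NA` where the model computes
#' them.
#'
#' @param data A `paired_abundance`.
#' @param spec A [model_spec()].
#' @param mcmc An [mcmc_config()].
#' @return A list of per-chain named lists of initial values.
#' @export
initialize_chains <- function(data, spec, mcmc = mcmc_config()) {
  W <- data$counts$W
  V <- data$conc$V
  qobs <- data$qobs
  n <- nrow(W); q <- ncol(W)
  tw <- rowSums(W[, seq_len(qobs), drop = FALSE])
  s_global <- sum(V) / max(sum(W[, seq_len(qobs), drop = FALSE]), 1)
  s_hat <- ifelse(tw > 0, rowSums(V) / pmax(tw, 1), s_global)
  log_lambda0 <- log(s_hat * W + 0.5)
  beta_anchor <- colMeans(log_lambda0)
  hy <- spec$hyper
  varying <- spec$variant == "varying_efficiency"
  marginalize <- varying && spec$centering == "soft" && qobs < q
  b0_name <- if (spec$covariate_adjusted) "beta0" else "beta"
  anchor <- list(log_lambda = log_lambda0, log_Sigma = rep(0, q))
  anchor[[b0_name]] <- beta_anchor
  if (spec$covariate_adjusted) anchor$beta1 <- rep(0, q)
  if (varying) {
    anchor$tau_e <- (hy$alpha_sigma + 1) / hy$kappa_sigma
    if (spec$centering == "soft") {
      anchor$log_e <- rep(0, q)
    } else {
      anchor$log_e_raw <- rep(0, q)
    }
    if (marginalize) {
      unobs <- (qobs + 1):q
      blam <- rep(NA_real_, q)
      blam[unobs] <- beta_anchor[unobs]
      anchor$blam <- blam
      anchor[[b0_name]][unobs] <- NA_real_  # computed as blam - log_e
    }
  }
  lapply(seq_len(mcmc$chains), function(ch) {
    init <- anchor
    if (mcmc$init_strategy == "random") {
      rng <- local({
        set.seed(chain_seed(mcmc$seed, ch))
        list(mu = matrix(stats::rnorm(n * q, 0, 1), n, q),
             beta = stats::rnorm(q, 0, 1))
      })
      init$log_lambda <- init$log_lambda + rng$mu
      keep <- !is.na(init[[b0_name]])
      init[[b0_name]][keep] <- init[[b0_name]][keep] + rng$beta[keep]
      if (!is.null(init$blam)) {
        miss <- !is.na(init$blam)
        init$blam[miss] <- init$blam[miss] + rng$beta[miss]
      }
    }
    init$.RNG.name <- "base::Mersenne-Twister"
    init$.RNG.seed <- chain_seed(mcmc$seed, ch)
    init
  })
}

# Distinct positive 32-bit seeds per chain, safe for large master seeds.
chain_seed <- function(seed, chain) {
  as.integer((as.numeric(seed) * 1009 + chain * 7919) %% 2147483629) + 1L
}

#' Fit the hierarchical model by MCMC
#'
#' Samples the joint posterior of the latent concentrations `mu`,
#' efficiencies `e`, mean parameters, `Sigma` diagonal, and `sigma_e^2`
#' under the chosen [model_spec()]. Draws from all chains are pooled with
#' chain labels retained; rerunning with identical data, spec, and
#' configuration (including seed) reproduces the draws exactly.
#'
#' @param data A `paired_abundance` from [align_tables()] or
#'   [simulate_dataset()].
#' @param spec A [model_spec()].
#' @param mcmc An [mcmc_config()].
#' @param X Optional per-sample covariate vector (required when
#'   `spec$covariate_adjusted`).
#' @param quiet Suppress sampler progress output (default `TRUE`).
#' @return An object of class `abundance_fit`: `draws` (list with `mu`
#'   `[S, n, q]`, `e` `[S, q]`, mean coefficients, `Sigma_diag` `[S, q]`,
#'   `sigma_e_sq` `[S]`), `chain` (chain label per draw), `diagnostics`
#'   (per-parameter R-hat and effective sample size plus the median/IQR
#'   summary over `mu`), and the inputs.
#' @export
fit_abundance <- function(data, spec = model_spec(), mcmc = mcmc_config(),
                          X = NULL, quiet = TRUE) {
  stopifnot(inherits(data, "paired_abundance"))
  W <- data$counts$W
  V <- data$conc$V
  n <- nrow(W); q <- ncol(W); qobs <- data$qobs
  stopifnot(q >= qobs, qobs >= 1)
  if (spec$covariate_adjusted) {
    if (is.null(X)) stop("covariate-adjusted model requires X", call. = FALSE)
    stopifnot(length(X) == n, !anyNA(X))
  }
  jdata <- list(n = n, q = q, qobs = qobs, V = V, W = W,
                M = as.numeric(data$counts$M))
  if (spec$covariate_adjusted) jdata$X <- as.numeric(X)
  inits <- initialize_chains(data, spec, mcmc)
  model_str <- jags_model_string(spec, n, q, qobs)
  n_adapt <- max(100L, min(500L, mcmc$warmup_iters %/% 2L))
  jm <- rjags::jags.model(textConnection(model_str), data = jdata,
                          inits = inits, n.chains = mcmc$chains,
                          n.adapt = n_adapt, quiet = quiet)
  burn <- mcmc$warmup_iters - n_adapt
  if (burn > 0) {
    stats::update(jm, n.iter = burn,
                  progress.bar = if (quiet) "none" else "text")
  }
  monitors <- c("mu", "Sigma_diag",
                if (spec$covariate_adjusted) c("beta0", "beta1") else "beta",
                if (spec$variant == "varying_efficiency")
                  c("e", "sigma_e_sq"))
  n_keep <- mcmc$total_iters - mcmc$warmup_iters
  samples <- rjags::coda.samples(jm, monitors, n.iter = n_keep,
                                 progress.bar = if (quiet) "none" else "text")
  build_abundance_fit(samples, data, spec, mcmc, X)
}

# Reshape coda output into pooled draw arrays and compute diagnostics.
build_abundance_fit <- function(samples, data, spec, mcmc, X) {
  n <- nrow(data$counts$W); q <- ncol(data$counts$W)
  mats <- lapply(samples, as.matrix)
  pooled <- do.call(rbind, mats)
  S_chain <- nrow(mats[[1]])
  chain <- rep(seq_along(mats), each = S_chain)
  cn <- colnames(pooled)

  pick <- function(prefix) {
    idx <- grep(paste0("^", prefix, "(\\[|$)"), cn)
    pooled[, idx, drop = FALSE]
  }
  mu_flat <- pick("mu")
  # JAGS names are mu[i,j]; map columns into an [S, n, q] array
  ij <- do.call(rbind, lapply(colnames(mu_flat), function(nm) {
    as.integer(strsplit(gsub("mu\\[|\\]", "", nm), ",")[[1]])
  }))
  mu_arr <- array(NA_real_, c(nrow(pooled), n, q))
  for (k in seq_len(ncol(mu_flat))) {
    mu_arr[, ij[k, 1], ij[k, 2]] <- mu_flat[, k]
  }
  dimnames(mu_arr) <- list(NULL, data$counts$sample_ids,
                           data$counts$taxon_ids)
  order_taxa <- function(m, prefix) {
    idx <- order(as.integer(gsub(paste0(prefix, "\\[|\\]"), "", colnames(m))))
    m <- m[, idx, drop = FALSE]
    colnames(m) <- data$counts$taxon_ids
    m
  }
  draws <- list(
    mu = mu_arr,
    e = if (spec$variant == "varying_efficiency") {
      order_taxa(pick("e"), "e")
    } else {
      matrix(1, nrow(pooled), q,
             dimnames = list(NULL, data$counts$taxon_ids))
    },
    Sigma_diag = order_taxa(pick("Sigma_diag"), "Sigma_diag"))
  if (spec$covariate_adjusted) {
    draws$beta0 <- order_taxa(pick("beta0"), "beta0")
    draws$beta1 <- order_taxa(pick("beta1"), "beta1")
  } else {
    draws$beta <- order_taxa(pick("beta"), "beta")
  }
  if (spec$variant == "varying_efficiency") {
    draws$sigma_e_sq <- as.numeric(pick("sigma_e_sq"))
  }

  rhat <- vapply(cn, function(j) {
    chains <- lapply(mats, function(m) m[, j])
    if (mean(vapply(chains, stats::var, numeric(1))) <= 0) {
      return(NA_real_)  # constant node; R-hat undefined
    }
    gelman_rubin(chains)
  }, numeric(1))
  ess <- tryCatch(coda::effectiveSize(samples), error = function(e) NULL)
  mu_rhat <- rhat[grep("^mu\\[", cn)]
  diagnostics <- list(
    rhat = rhat, ess = ess,
    rhat_mu_median = stats::median(mu_rhat, na.rm = TRUE),
    rhat_mu_iqr = stats::quantile(mu_rhat, c(0.25, 0.75), na.rm = TRUE,
                                  names = FALSE)
  )
  structure(
    list(draws = draws, chain = chain, diagnostics = diagnostics,
         data = data, spec = spec, mcmc = mcmc, X = X),
    class = "abundance_fit"
  )
}

#' @export
print.abundance_fit <- function(x, ...) {
  d <- dim(x$draws$mu)
  cat("abundance_fit (", x$spec$variant, "): ", d[1], " pooled draws over ",
      max(x$chain), " chains; ", d[2], " samples x ", d[3], " taxa\n",
      "median R-hat over mu: ", round(x$diagnostics$rhat_mu_median, 3),
      " (IQR ", round(x$diagnostics$rhat_mu_iqr[1], 3), "-",
      round(x$diagnostics$rhat_mu_iqr[2], 3), ")\n", sep = "")
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic R-hat from between- and within-chain variances:
#' `sqrt((W (S - 1) / S + B / S) / W)` with `B = S * var(chain means)` and
#' `W` the mean within-chain variance. Values slightly below one are
#' possible. Returns `NA` (flagged with a warning) when the within-chain
#' variance is zero.
#'
#' @param chain_draws List of equal-length numeric vectors, one per chain
#'   (at least 2 chains of at least 4 draws).
#' @return The potential scale reduction factor, or `NA` if undefined.
#' @export
gelman_rubin <- function(chain_draws) {
  stopifnot(is.list(chain_draws), length(chain_draws) >= 2)
  S <- unique(lengths(chain_draws))
  stopifnot(length(S) == 1, S >= 4)
  within <- mean(vapply(chain_draws, stats::var, numeric(1)))
  if (!is.finite(within) || within == 0) {
    warning("zero within-chain variance: R-hat undefined")
    return(NA_real_)
  }
  between <- S * stats::var(vapply(chain_draws, mean, numeric(1)))
  sqrt((within * (S - 1) / S + between / S) / within)
}
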