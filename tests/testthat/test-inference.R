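test_that("gelman_rubin matches its defining variance decomposition", {
  set.seed(1)
  # chains from a common distribution sit at 1
  chains <- list(rnorm(1e4), rnorm(1e4))
  expect_gt(gelman_rubin(chains), 0.99)
  expect_lt(gelman_rubin(chains), 1.01)
  # separated chains inflate the between-chain variance
  expect_gt(gelman_rubin(list(rnorm(500, 0), rnorm(500, 10))), 1.5)
  # degenerate chains are flagged, not silently 1
  expect_warning(r <- gelman_rubin(list(rep(2, 10), rep(2, 10))),
                 "undefined")
  expect_true(is.na(r))
})

test_that("chain initialization anchors at the scaling-factor estimate", {
  pair <- tiny_paired()
  mc <- mcmc_config(chains = 2, warmup_iters = 10, total_iters = 20, seed = 3)
  inits <- initialize_chains(pair, model_spec(), mc)
  ne <- naive_estimate(pair)
  anchor <- log(ne$mu_hat + 0.5)
  expect_equal(inits[[1]]$log_lambda, anchor, ignore_attr = TRUE)
  # observed-taxon intercepts at the anchor column means; the unobserved
  # taxon's intercept is derived from its sampled sum with log e
  expect_equal(inits[[1]]$beta[1:2], colMeans(anchor)[1:2],
               ignore_attr = TRUE)
  expect_true(is.na(inits[[1]]$beta[3]))
  expect_equal(inits[[1]]$blam[3], colMeans(anchor)[3], ignore_attr = TRUE)
  expect_equal(inits[[1]]$tau_e, 3)  # prior-mode start: (alpha+1)/kappa
  # zero counts anchor at the pseudo-count
  W <- matrix(c(5, 4, 6, 3, 0, 0), 2, 3,
              dimnames = list(c("s1", "s2"), c("A", "B", "C")))
  V <- matrix(c(10, 8, 12, 6), 2, 2,
              dimnames = list(c("s1", "s2"), c("A", "B")))
  pz <- align_tables(count_table(W), concentration_table(V))
  iz <- initialize_chains(pz, model_spec(), mc)
  s <- naive_estimate(pz)$s_hat
  expect_equal(iz[[1]]$log_lambda[, 3], log(s * 0 + 0.5),
               ignore_attr = TRUE)
  # random strategy jitters differently per chain
  mcr <- mcmc_config(chains = 2, warmup_iters = 10, total_iters = 20,
                     seed = 3, init_strategy = "random")
  ir <- initialize_chains(pair, model_spec(), mcr)
  expect_false(identical(ir[[1]]$log_lambda, ir[[2]]$log_lambda))
  expect_false(identical(ir[[1]]$.RNG.seed, ir[[2]]$.RNG.seed))
})

test_that("identical seeds reproduce identical draws", {
  sim <- suppressWarnings(simulate_dataset(
    simulation_config(q = 8, qobs = 3, n = 10, sigma_e = 0.5, seed = 21)))
  mc <- quick_mcmc(seed = 9)
  f1 <- fit_abundance(sim$paired, model_spec(), mc)
  f2 <- fit_abundance(sim$paired, model_spec(), mc)
  expect_identical(f1$draws$mu, f2$draws$mu)
  expect_identical(f1$draws$e, f2$draws$e)
  f3 <- fit_abundance(sim$paired, model_spec(), quick_mcmc(seed = 10))
  expect_false(identical(f1$draws$mu, f3$draws$mu))
})

test_that("posterior recovers concentrations in a fully observed community", {
  # degenerate but legal qobs = q: every taxon has concentration data
  set.seed(14)
  n <- 5; q <- 3
  mu <- exp(matrix(rnorm(n * q, rep(c(4, 5, 6), each = n), 0.5), n, q))
  M <- sample(2e4:5e4, n, TRUE)
  W <- t(sapply(1:n, function(i) rmultinom(1, M[i], mu[i, ] / sum(mu[i, ]))))
  V <- matrix(rpois(n * q, mu), n, q)
  pair <- manual_paired(W, V)
  fit <- fit_abundance(pair, model_spec("efficiency_naive"),
                       quick_mcmc(seed = 2))
  post_mean <- apply(fit$draws$mu, c(2, 3), mean)
  post_sd <- apply(fit$draws$mu, c(2, 3), sd)
  frac_close <- mean(abs(post_mean - mu) <= 3 * post_sd)
  expect_gte(frac_close, 0.9)
})

test_that("posterior means track observed concentrations with unit slope", {
  sim <- suppressWarnings(simulate_dataset(
    simulation_config(q = 10, qobs = 4, n = 25, sigma_e = 0, seed = 4,
                      beta_var = 4)))
  fit <- fit_abundance(sim$paired, model_spec("efficiency_naive"),
                       quick_mcmc(seed = 5))
  post_mean <- apply(fit$draws$mu, c(2, 3), mean)
  qobs <- sim$paired$qobs
  V <- sim$paired$conc$V
  big <- V > 50
  slope <- coef(lm(c(post_mean[, seq_len(qobs)])[big] ~ 0 + c(V)[big]))
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
  expect_lt(fit$diagnostics$rhat_mu_median, 1.1)
})

test_that("soft centering keeps the mean log efficiency near zero", {
  sim <- suppressWarnings(simulate_dataset(
    simulation_config(q = 12, qobs = 5, n = 20, sigma_e = 0.8, seed = 3)))
  fit <- fit_abundance(sim$paired, model_spec("varying_efficiency"),
                       quick_mcmc(seed = 6))
  mean_log_e <- mean(rowMeans(log(fit$draws$e)))
  expect_lt(abs(mean_log_e), 0.5)
})

test_that("modeling efficiency lowers estimation error when it varies", {
  sim <- suppressWarnings(simulate_dataset(
    simulation_config(q = 12, qobs = 5, n = 20, sigma_e = 0.8, seed = 3)))
  truth_mu <- aligned_truth(sim, "mu")
  fit_v <- fit_abundance(sim$paired, model_spec("varying_efficiency"),
                         quick_mcmc(seed = 8))
  fit_n <- fit_abundance(sim$paired, model_spec("efficiency_naive"),
                         quick_mcmc(seed = 8))
  rmse_v <- rmse(apply(fit_v$draws$mu, c(2, 3), mean), truth_mu)
  rmse_n <- rmse(apply(fit_n$draws$mu, c(2, 3), mean), truth_mu)
  expect_lt(rmse_v, rmse_n)
})

test_that("hard centering fixes the observed-taxa geometric mean at one", {
  sim <- suppressWarnings(simulate_dataset(
    simulation_config(q = 8, qobs = 3, n = 12, sigma_e = 0.6, seed = 12)))
  fit <- fit_abundance(sim$paired,
                       model_spec("varying_efficiency",
                                  centering = "hard_observed"),
                       quick_mcmc(seed = 4))
  gm <- exp(rowMeans(log(fit$draws$e[, seq_len(sim$paired$qobs),
                                     drop = FALSE])))
  expect_equal(gm, rep(1, length(gm)), tolerance = 1e-10)
})

test_that("covariate-adjusted fit recovers the direction of a group effect", {
  set.seed(20)
  n <- 24; q <- 5; qobs <- 2
  X <- rep(c(0, 1), each = n / 2)
  b0 <- c(5, 5, 4, 4, 3)
  b1 <- c(2, 0, 0, -2, 0)   # strong up- and down-effects on two taxa
  mu <- exp(sapply(1:q, function(j) rnorm(n, b0[j] + b1[j] * X, 0.5)))
  M <- sample(2e4:5e4, n, TRUE)
  W <- t(sapply(1:n, function(i) rmultinom(1, M[i], mu[i, ] / sum(mu[i, ]))))
  V <- matrix(rpois(n * qobs, mu[, 1:qobs]), n, qobs)
  pair <- manual_paired(W, V)
  spec <- model_spec("varying_efficiency", covariate_adjusted = TRUE)
  fit <- fit_abundance(pair, spec, quick_mcmc(seed = 30), X = X)
  b1_mean <- colMeans(fit$draws$beta1)
  expect_gt(b1_mean[1], 0.5)
  expect_lt(b1_mean[4], -0.5)
  expect_identical(dim(fit$draws$beta0), dim(fit$draws$beta1))
})
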