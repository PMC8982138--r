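test_that("read probabilities are efficiency-weighted compositions", {
  expect_equal(relative_abundance_probs(c(2, 3, 5), c(1, 1, 1)),
               c(0.2, 0.3, 0.5))
  expect_equal(relative_abundance_probs(c(1, 1), c(1, 3)), c(0.25, 0.75))
  # scale invariance of e (the identifiability problem centering solves)
  p1 <- relative_abundance_probs(c(2, 7, 1), c(0.5, 1, 2))
  p2 <- relative_abundance_probs(c(2, 7, 1), 10 * c(0.5, 1, 2))
  expect_equal(p1, p2)
  # sums to one even for widely spread concentrations
  set.seed(2)
  for (r in 1:20) {
    p <- relative_abundance_probs(exp(rnorm(30, 0, 7)), exp(rnorm(30, 0, 1)))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
  expect_error(relative_abundance_probs(c(1, -1), c(1, 1)), "positive")
})

test_that("hard centering removes the geometric mean and is a projection", {
  expect_equal(hard_center(c(2, 8)), c(0.5, 2))
  expect_equal(hard_center(c(3, 3, 3)), c(1, 1, 1))
  e <- exp(rnorm(6))
  once <- hard_center(e, 1:4)
  expect_equal(exp(mean(log(once[1:4]))), 1)
  expect_equal(hard_center(once, 1:4), once)
})

test_that("covariate mean is linear in the covariate", {
  expect_equal(covariate_mean(c(0, 1), c(2, -1), 0), c(0, 1))
  expect_equal(covariate_mean(c(0, 1), c(2, -1), 1), c(2, 0))
  b0 <- rnorm(4); b1 <- rnorm(4)
  expect_equal(covariate_mean(b0, b1, 2),
               2 * covariate_mean(b0, b1, 1) - covariate_mean(b0, b1, 0))
})

test_that("joint density reduces to Poisson in the single-taxon community", {
  pair <- manual_paired(matrix(3, 1, 1), matrix(3, 1, 1))
  st <- latent_state(mu = matrix(2.5, 1, 1), e = 1, beta = 0,
                     Sigma_diag = 1, sigma_e_sq = 0.5)
  ld <- log_joint_density(st, pair, model_spec("varying_efficiency"))
  terms <- attr(ld, "terms")
  expect_equal(unname(terms["W"]), 0)  # one category: log(1)
  expect_equal(unname(terms["V"]), dpois(3, 2.5, log = TRUE))
})

test_that("joint density equals an independently coded component sum", {
  pair <- tiny_paired()
  q <- 3
  set.seed(5)
  st <- latent_state(mu = matrix(exp(rnorm(6, 2, 1)), 2, 3),
                     e = exp(rnorm(3, 0, 0.3)),
                     beta = rnorm(3), Sigma_diag = exp(rnorm(3, 0, 0.2)),
                     sigma_e_sq = 0.7)
  spec <- model_spec("varying_efficiency")
  ld <- log_joint_density(st, pair, spec)

  # oracle: scalar densities composed term by term, written independently
  hy <- spec$hyper
  W <- pair$counts$W; V <- pair$conc$V; M <- pair$counts$M
  oracle <- 0
  for (i in 1:2) for (j in 1:2) {
    oracle <- oracle - st$mu[i, j] + V[i, j] * log(st$mu[i, j]) -
      lfactorial(V[i, j])
  }
  for (i in 1:2) {
    num <- st$mu[i, ] * st$e
    p <- num / sum(num)
    oracle <- oracle + lfactorial(M[i]) - sum(lfactorial(W[i, ])) +
      sum(W[i, ] * log(p))
  }
  for (i in 1:2) for (j in 1:3) {
    z <- (log(st$mu[i, j]) - st$beta[j]) / sqrt(st$Sigma_diag[j])
    oracle <- oracle - 0.5 * z^2 - 0.5 * log(2 * pi * st$Sigma_diag[j])
  }
  for (j in 1:3) {
    oracle <- oracle - 0.5 * st$beta[j]^2 / hy$sigma_beta_sq -
      0.5 * log(2 * pi * hy$sigma_beta_sq)
    ls <- log(st$Sigma_diag[j])
    oracle <- oracle - 0.5 * ls^2 / hy$sigma_Sigma_sq -
      0.5 * log(2 * pi * hy$sigma_Sigma_sq) - ls
    le <- log(st$e[j])
    oracle <- oracle - 0.5 * le^2 / st$sigma_e_sq -
      0.5 * log(2 * pi * st$sigma_e_sq) - le
  }
  oracle <- oracle + hy$alpha_sigma * log(hy$kappa_sigma) -
    lgamma(hy$alpha_sigma) -
    (hy$alpha_sigma + 1) * log(st$sigma_e_sq) -
    hy$kappa_sigma / st$sigma_e_sq
  expect_equal(as.numeric(ld), as.numeric(oracle), tolerance = 1e-10)
})

test_that("scaling the efficiencies only moves the efficiency prior term", {
  pair <- tiny_paired()
  set.seed(6)
  mu <- matrix(exp(rnorm(6, 2, 1)), 2, 3)
  st1 <- latent_state(mu = mu, e = c(1, 2, 0.5), beta = rep(0, 3),
                      Sigma_diag = rep(1, 3), sigma_e_sq = 1)
  st2 <- latent_state(mu = mu, e = 3 * c(1, 2, 0.5), beta = rep(0, 3),
                      Sigma_diag = rep(1, 3), sigma_e_sq = 1)
  spec <- model_spec("varying_efficiency")
  t1 <- attr(log_joint_density(st1, pair, spec), "terms")
  t2 <- attr(log_joint_density(st2, pair, spec), "terms")
  expect_equal(t1["W"], t2["W"])
  expect_equal(t1["V"], t2["V"])
  expect_false(isTRUE(all.equal(t1["e"], t2["e"])))
})

test_that("density decreases when a concentration outruns its observation", {
  pair <- tiny_paired()
  vals <- sapply(c(5, 50, 500, 5000), function(m) {
    mu <- matrix(c(m, 2, 3, 2, 5, 4), 2, 3, byrow = TRUE)
    st <- latent_state(mu = mu, e = rep(1, 3), beta = rep(1, 3),
                       Sigma_diag = rep(1, 3), sigma_e_sq = 1)
    as.numeric(log_joint_density(st, pair, model_spec()))
  })
  expect_true(all(diff(vals[2:4]) < 0))
})

test_that("covariate-adjusted density shifts the concentration means", {
  pair <- tiny_paired()
  X <- c(0, 1)
  set.seed(9)
  mu <- matrix(exp(rnorm(6, 2, 1)), 2, 3)
  b0 <- rnorm(3); b1 <- rnorm(3)
  st <- latent_state(mu = mu, e = rep(1, 3), Sigma_diag = rep(1, 3),
                     sigma_e_sq = 1, beta0 = b0, beta1 = b1)
  spec <- model_spec("varying_efficiency", covariate_adjusted = TRUE)
  ld <- log_joint_density(st, pair, spec, X = X)
  # mu term: sample 1 centered at beta0, sample 2 at beta0 + beta1
  mu_term <- sum(dnorm(log(mu[1, ]), b0, 1, log = TRUE)) +
    sum(dnorm(log(mu[2, ]), b0 + b1, 1, log = TRUE))
  expect_equal(unname(attr(ld, "terms")["mu"]), mu_term, tolerance = 1e-12)
  expect_error(log_joint_density(st, pair, spec), "requires X")
})
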