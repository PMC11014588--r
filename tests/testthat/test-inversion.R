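test_that("linear-Gaussian evidence: limits and Monte-Carlo oracle", {
  # maximum-likelihood limit under a nearly flat prior
  set.seed(51)
  y <- rnorm(4)
  flat <- gaussian_density(rep(0, 4), rep(1e6, 4))
  res <- linear_gaussian_evidence(diag(4), y, flat, diag(4))
  expect_equal(res$posterior$mean, y, tolerance = 1e-3)
  # dogmatic prior pins the posterior at the prior mean
  dog <- gaussian_density(c(0.3, -0.2), diag(c(0, 0)))
  res2 <- linear_gaussian_evidence(matrix(rnorm(8), 4, 2), y, dog,
                                   diag(4))
  expect_equal(res2$posterior$mean, c(0.3, -0.2))
  # Monte-Carlo integration oracle on a 2-parameter model
  set.seed(52)
  X <- matrix(rnorm(12), 6, 2)
  th <- c(0.5, -1)
  yy <- as.numeric(X %*% th) + rnorm(6, sd = 0.7)
  prior <- gaussian_density(c(0, 0), diag(2))
  res3 <- linear_gaussian_evidence(X, yy, prior, 0.49 * diag(6))
  mc <- oracle_mc_log_evidence(X, yy, prior, 0.49, 200000, seed = 53)
  expect_equal(res3$log_evidence, mc, tolerance = 0.05)
})

test_that("free energy reduces to the exact log evidence for linear models", {
  # a 1-parameter linear-Gaussian model y = theta + e: the Laplace free
  # energy at the analytic posterior equals the log marginal likelihood
  y <- c(0.8)
  prior <- gaussian_density(0.2, matrix(0.5))
  noise_var <- 0.3
  ex <- linear_gaussian_evidence(matrix(1), y, prior, matrix(noise_var))
  f <- free_energy(ex$posterior, prior, y,
                   predictor = function(th) th,
                   noise_precision = 1 / noise_var)
  expect_equal(f, ex$log_evidence, tolerance = 1e-8)
  # multivariate version
  set.seed(54)
  X <- matrix(rnorm(15), 5, 3)
  yy <- rnorm(5)
  prior3 <- gaussian_density(rep(0, 3), rep(0.4, 3))
  ex3 <- linear_gaussian_evidence(X, yy, prior3, diag(5))
  f3 <- free_energy(ex3$posterior, prior3, yy,
                    predictor = function(th) as.numeric(X %*% th),
                    noise_precision = 1)
  expect_equal(f3, ex3$log_evidence, tolerance = 1e-6)
})

test_that("free energy: KL identities", {
  prior <- fixture_gaussian(3, seed = 55)
  pred <- function(th) th
  y <- c(0.1, -0.2, 0.3)
  # q = prior: KL is exactly zero, F equals the expected log-likelihood
  f <- free_energy(prior, prior, y, pred, noise_precision = 2)
  g <- prior$mean
  # with q = prior the KL term vanishes exactly, leaving the expected
  # log-likelihood of the identity predictor
  expect_equal(f, -sum((y - g)^2) * 2 / 2 - 2 / 2 * sum(diag(prior$cov)) +
                 3 / 2 * log(2) - 3 / 2 * log(2 * pi))
  # inflating prior variance decreases the KL penalty for a distant q
  q <- gaussian_density(prior$mean + 3, prior$cov)
  kl_tight <- hebdcm:::gd_kl(q, prior)
  wide <- gaussian_density(prior$mean, 100 * prior$cov)
  kl_wide <- hebdcm:::gd_kl(q, wide)
  expect_lt(kl_wide, kl_tight)
  # degenerate q covariance errors
  bad <- prior
  bad$cov[1, 1] <- -1
  expect_error(free_energy(bad, prior, y, pred, 1), "degenerate")
})

test_that("inversion is self-consistent at the prior mean and deterministic", {
  lay <- dcm_layout(3)
  priors <- dcm_priors(3)
  grid <- fixture_grid()
  cs <- fixture_csd_from_theta(priors$prior$mean, lay, grid)
  fit <- invert_dcm(cs, priors, config = list(max_iter = 16))
  expect_lt(max(abs(fit$posterior$mean - priors$prior$mean)), 1e-3)
  # determinism: bit-identical free energy on a nontrivial problem
  th <- priors$prior$mean
  th[lay$idx_A_offdiag] <- c(0.2, -0.1, 0.15, 0.05, -0.2, 0.1)
  cs2 <- fixture_csd_from_theta(th, lay, grid)
  f1 <- suppressWarnings(invert_dcm(cs2, priors,
                                    config = list(max_iter = 24)))
  f2 <- suppressWarnings(invert_dcm(cs2, priors,
                                    config = list(max_iter = 24)))
  expect_identical(f1$free_energy, f2$free_energy)
  expect_identical(f1$posterior$mean, f2$posterior$mean)
})

test_that("accepted Gauss-Newton steps never decrease the free energy", {
  lay <- dcm_layout(3)
  priors <- dcm_priors(3)
  grid <- fixture_grid()
  th <- priors$prior$mean
  set.seed(56)
  th[lay$idx_A_offdiag] <- rnorm(6, sd = 0.2)
  cs <- fixture_csd_from_theta(th, lay, grid)
  fit <- suppressWarnings(invert_dcm(cs, priors,
                                     config = list(max_iter = 48)))
  expect_true(all(diff(fit$trace) >= 0))
})

test_that("inversion recovers a simulated 3-region subject", {
  cfg <- sim_config(n = 3, subjects = 1, snr = 2, seed = 57)
  C <- sample_structural(3, density = 1, seed = 58)
  A2 <- ensure_stable(sample_group_ec(normalize_structural(C), 0.02,
                                      0.25, -0.5, seed = 59))
  ts <- simulate_bold(A2, config = cfg, seed = 60)
  feats <- csd_features(ts, fixture_grid(), cfg$sampling_interval)
  fit <- suppressWarnings(invert_dcm(feats, dcm_priors(3)))
  lay <- dcm_layout(3)
  est <- fit$posterior$mean[lay$idx_A_offdiag]
  tru <- A2[!diag(3) == 1]
  expect_gt(cor(est, tru), 0.7)
})

test_that("variational free energy at convergence matches the conjugate solution", {
  # Laplace is exact for linear-Gaussian models: run the Gauss-Newton
  # machinery on a linear predictor and compare with the closed form
  set.seed(61)
  d <- 4
  X <- matrix(rnorm(4 * d * d), 4 * d, d)
  th_true <- rnorm(d, sd = 0.5)
  noise_var <- 0.25
  y <- as.numeric(X %*% th_true) + rnorm(4 * d, sd = sqrt(noise_var))
  prior <- gaussian_density(rep(0, d), rep(0.3, d))
  ex <- linear_gaussian_evidence(X, y, prior, noise_var * diag(4 * d))
  f <- free_energy(ex$posterior, prior, y,
                   predictor = function(th) as.numeric(X %*% th),
                   noise_precision = 1 / noise_var)
  expect_equal(f, ex$log_evidence, tolerance = 1e-6)
  # and F lower-bounds a Monte-Carlo estimate of ln p(y) for a
  # 2-parameter nonlinear model
  g <- function(th) c(th[1] + 0.3 * th[2]^2, th[1] * th[2], th[1],
                      th[2])
  ynl <- c(0.5, -0.2, 0.4, -0.3)
  prior2 <- gaussian_density(c(0, 0), c(0.5, 0.5))
  set.seed(62)
  L <- chol(prior2$cov)
  ll <- vapply(seq_len(400000), function(i) {
    th <- prior2$mean + as.numeric(t(L) %*% rnorm(2))
    -sum((ynl - g(th))^2) / 2 - 4 / 2 * log(2 * pi)
  }, numeric(1))
  m <- max(ll)
  lnz <- m + log(mean(exp(ll - m)))
  # mode finding + Laplace q; the local-linearization expectation
  # carries a small O(curvature) error, so the bound is asserted with
  # matching slack
  opt <- optim(c(0.1, 0.1), function(th) {
    sum((ynl - g(th))^2) / 2 + sum(th^2) / (2 * 0.5)
  })
  J <- numDeriv_jac(g, opt$par)
  Sq <- solve(crossprod(J) + diag(2) / 0.5)
  q <- gaussian_density(opt$par, Sq)
  f2 <- free_energy(q, prior2, ynl, g, noise_precision = 1)
  expect_lt(f2, lnz + 0.05)
  expect_equal(f2, lnz, tolerance = 0.15)
})

test_that("conditioning on data never inflates posterior spread", {
  # linear-Gaussian case: posterior covariance eigenvalues are bounded
  # by the prior's (information is never lost)
  for (seed in 1:5) {
    set.seed(6000 + seed)
    d <- sample(2:5, 1)
    X <- matrix(rnorm(3 * d * d), 3 * d, d)
    y <- rnorm(3 * d)
    prior <- fixture_gaussian(d, seed = 7000 + seed)
    res <- linear_gaussian_evidence(X, y, prior, diag(3 * d))
    ev_post <- eigen(res$posterior$cov, symmetric = TRUE,
                     only.values = TRUE)$values
    ev_prior <- eigen(prior$cov, symmetric = TRUE,
                      only.values = TRUE)$values
    expect_lte(max(ev_post), max(ev_prior) + 1e-10)
    expect_true(all(sort(ev_post) <= sort(ev_prior) + 1e-10))
  }
})
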