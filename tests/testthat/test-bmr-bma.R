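test_that("BMR identity reduction returns the full posterior with zero change", {
  prior <- fixture_gaussian(5, seed = 81)
  post <- fixture_gaussian(5, seed = 82)
  res <- bmr_gaussian(prior, post, prior, full_free_energy = 12.5)
  expect_identical(res$reduced_posterior$mean, post$mean)
  expect_identical(res$delta_free_energy, 0)
  expect_identical(res$reduced_free_energy, 12.5)
})

test_that("BMR equals the conjugate evidence difference on random linear models", {
  # 25 random linear-Gaussian models of dimension <= 6: the analytic
  # reduction must agree with direct re-inversion under the reduced
  # prior, in both posterior and evidence change
  for (rep in 1:25) {
    set.seed(900 + rep)
    d <- sample(2:6, 1)
    nobs <- d + sample(2:6, 1)
    X <- matrix(rnorm(nobs * d), nobs, d)
    y <- rnorm(nobs)
    noise <- diag(runif(nobs, 0.3, 1.2))
    prior <- fixture_gaussian(d, seed = 1900 + rep)
    red_prior <- fixture_gaussian(d, seed = 2900 + rep, scale = 0.6)
    full <- linear_gaussian_evidence(X, y, prior, noise)
    red <- linear_gaussian_evidence(X, y, red_prior, noise)
    bmr <- bmr_gaussian(prior, full$posterior, red_prior,
                        full_free_energy = full$log_evidence)
    expect_equal(bmr$delta_free_energy,
                 red$log_evidence - full$log_evidence,
                 tolerance = 1e-6)
    expect_equal(bmr$reduced_posterior$mean, red$posterior$mean,
                 tolerance = 1e-6)
    expect_equal(bmr$reduced_posterior$cov, red$posterior$cov,
                 tolerance = 1e-6)
  }
})

test_that("BMR prunes a parameter when its reduced prior variance vanishes", {
  set.seed(83)
  d <- 4
  X <- matrix(rnorm(12 * d), 12, d)
  y <- rnorm(12)
  prior <- gaussian_density(rep(0, d), rep(1, d))
  full <- linear_gaussian_evidence(X, y, prior, diag(12))
  red_prior <- gaussian_density(c(0.7, 0, 0, 0),
                                c(1e-8, 1, 1, 1))
  res <- bmr_gaussian(prior, full$posterior, red_prior)
  expect_equal(res$reduced_posterior$mean[1], 0.7, tolerance = 1e-3)
  expect_lt(res$reduced_posterior$cov[1, 1], 1e-7)
})

test_that("regime enumeration matches its brute-force construction", {
  # degenerate grid: exactly the uninformed regime
  g1 <- enumerate_regimes(grid_spec(alpha_points = 1, beta_points = 30,
                                    alpha_range = c(1 / 2, 1 / 2)))
  expect_equal(nrow(g1), 1L)
  expect_equal(g1$alpha, 0.5)
  expect_equal(g1$beta, 0)
  # constraint filters hold everywhere
  g2 <- enumerate_regimes(grid_spec())
  expect_true(all(g2$alpha >= 0))
  expect_true(all(g2$alpha + g2$beta >= 1e-5))
  # 5x5 grid equals an exhaustive double loop with the same filters
  g3 <- enumerate_regimes(grid_spec(alpha_points = 5, beta_points = 5))
  brute <- list()
  for (a in seq(-0.5, 0.5, length.out = 5)) {
    if (0.5 - a < 0) next
    betas <- unique(seq(0, 0.5 - a, length.out = 5))
    for (b in betas) {
      if (a >= 0 && a + b >= 1e-5) {
        brute[[length(brute) + 1]] <- c(a, b)
      }
    }
  }
  brute <- do.call(rbind, brute)
  expect_equal(nrow(g3), nrow(brute))
  expect_equal(g3$alpha, brute[, 1])
  expect_equal(g3$beta, brute[, 2])
  expect_error(
    enumerate_regimes(grid_spec(alpha_points = 2, beta_points = 1,
                                alpha_range = c(-0.5, -0.2))),
    "empty grid")
})

test_that("softmax model averaging is stable, normalized and shift-invariant", {
  regimes <- enumerate_regimes(grid_spec(alpha_points = 3,
                                         beta_points = 4))
  K <- nrow(regimes)
  # equal evidence: arithmetic mean of regimes
  b1 <- bma_average(rep(0, K), regimes)
  expect_equal(b1$alpha_bar, mean(regimes$alpha))
  expect_equal(b1$beta_bar, mean(regimes$beta))
  expect_equal(sum(b1$regimes$weight), 1, tolerance = 1e-12)
  # winner-take-all at 50 nats
  fk <- rep(0, K)
  fk[3] <- 50
  b2 <- bma_average(fk, regimes)
  expect_equal(b2$alpha_bar, regimes$alpha[3], tolerance = 1e-8)
  expect_equal(b2$beta_bar, regimes$beta[3], tolerance = 1e-8)
  # shift invariance, including shifts that would overflow naively
  set.seed(84)
  fk3 <- rnorm(K, sd = 5)
  w1 <- bma_average(fk3, regimes)$regimes$weight
  w2 <- bma_average(fk3 + 900, regimes)$regimes$weight
  expect_lt(max(abs(w1 - w2)), 1e-12)
  # high-precision oracle: weights equal normalized exponentials
  # computed with exact rational-style bookkeeping at moderate values
  set.seed(85)
  fk4 <- runif(10, -3, 3)
  reg10 <- tibble::tibble(alpha = runif(10), beta = runif(10) * 0.2,
                          delta = 1 / 64)
  w <- bma_average(fk4, reg10)$regimes$weight
  brute <- exp(fk4) / sum(exp(fk4))
  expect_equal(w, brute, tolerance = 1e-14)
  # convex-hull property of the average
  expect_true(b1$alpha_bar >= min(regimes$alpha) &&
                b1$alpha_bar <= max(regimes$alpha))
})

test_that("log-Bayes factors behave as evidence differences", {
  expect_equal(log_bayes_factor(10, 10), 0)
  expect_equal(log_bayes_factor(13, 10), 3)
  expect_equal(exp(log_bayes_factor(13, 10)), 20, tolerance = 0.01)
  expect_equal(log_bayes_factor(1, 2), -log_bayes_factor(2, 1))
  expect_identical(STRONG_EVIDENCE_LNBF, 3)
  expect_error(log_bayes_factor(Inf, 1), "is.finite")
})

test_that("grid scoring is stateless and zero at the identity regime", {
  set.seed(86)
  C <- matrix(runif(9), 3, 3)
  C <- (C + t(C)) / 2
  diag(C) <- 0
  Ct <- normalize_structural(C)
  lay <- dcm_layout(3)
  prior0 <- build_prior_covariance(Ct, uninformed_transform())
  means <- matrix(rnorm(9 * 5, sd = 0.3), 9, 5)
  gm <- structure(list(A1 = as.numeric(means), means = means,
                       covs = replicate(5, diag(0.02, 9),
                                        simplify = FALSE),
                       S = 5L, n = 3L, a_names = lay$names[lay$idx_A]),
                  class = "group_model")
  peb <- invert_group(gm, prior0)
  regimes <- enumerate_regimes(grid_spec(alpha_points = 6,
                                         beta_points = 4))
  scored <- score_grid(peb, Ct, regimes)
  # the uninformed regime itself scores exactly zero
  idx <- which(scored$alpha == 0.5 & scored$beta == 0)
  expect_equal(scored$delta_f[idx], 0)
  # permutation equivariance
  perm <- sample(nrow(regimes))
  scored2 <- score_grid(peb, Ct, regimes[perm, ])
  expect_equal(scored2$delta_f, scored$delta_f[perm])
})

test_that("downward updates: identity and dominant empirical priors", {
  lay <- dcm_layout(2)
  priors <- dcm_priors(2)
  set.seed(87)
  post <- gaussian_density(rnorm(lay$d, sd = 0.1),
                           diag(0.01, lay$d), names = lay$names)
  # empirical prior equal to the subject prior on the A block: no change
  a_idx <- lay$idx_A
  gp_same <- hebdcm:::gd_subset(priors$prior, a_idx)
  res <- update_subjects(priors, list(post), gp_same)
  expect_equal(res[[1]]$reduced_posterior$mean, post$mean,
               tolerance = 1e-9)
  expect_equal(res[[1]]$delta_free_energy, 0, tolerance = 1e-9)
  # near-dogmatic empirical prior pins the A block at the group mean
  gvals <- c(0.3, -0.2, 0.1, 0.05)
  gp_tight <- gaussian_density(gvals, rep(1e-8, 4),
                               names = lay$names[a_idx])
  res2 <- update_subjects(priors, list(post), gp_tight)
  expect_equal(unname(res2[[1]]$reduced_posterior$mean[a_idx]), gvals,
               tolerance = 1e-3)
  # non-A parameters pass through essentially unchanged
  rest <- setdiff(seq_len(lay$d), a_idx)
  expect_equal(res2[[1]]$reduced_posterior$mean[rest],
               post$mean[rest], tolerance = 0.05)
  # name misalignment errors
  bad <- gaussian_density(gvals, rep(1, 4),
                          names = paste0("B[", 1:4, "]"))
  expect_error(update_subjects(priors, list(post), bad), "misaligned")
})

test_that("downward updates match direct re-inversion on a linear toy", {
  # two-subject linear-Gaussian system: BMR under the group posterior as
  # empirical prior equals exact re-inversion under that prior
  set.seed(88)
  d <- 3
  X <- matrix(rnorm(9 * d), 9, d)
  prior <- gaussian_density(rep(0, d), rep(0.8, d),
                            names = paste0("A[", 1:3, ",1]"))
  group_post <- gaussian_density(c(0.4, -0.1, 0.2),
                                 diag(c(0.05, 0.08, 0.02)),
                                 names = prior$mean |> names())
  for (s in 1:2) {
    y <- rnorm(9)
    full <- linear_gaussian_evidence(X, y, prior, diag(9))
    upd <- update_subjects(list(prior), list(full$posterior),
                           group_post)[[1]]
    direct <- linear_gaussian_evidence(X, y, group_post, diag(9))
    expect_equal(upd$reduced_posterior$mean, direct$posterior$mean,
                 tolerance = 1e-6)
    expect_equal(upd$reduced_posterior$cov, direct$posterior$cov,
                 tolerance = 1e-6)
    expect_equal(upd$delta_free_energy,
                 direct$log_evidence - full$log_evidence,
                 tolerance = 1e-6)
  }
})

test_that("the BMR code path is level-agnostic", {
  # the same routine serves group-level regime scoring and
  # subject-level empirical-prior updates: verify one call of each kind
  # reduces to identical arithmetic on identical inputs
  nm <- paste0("A[", 1:4, ",1]")
  prior0 <- fixture_gaussian(4, seed = 89)
  post0 <- fixture_gaussian(4, seed = 90)
  red0 <- fixture_gaussian(4, seed = 91, scale = 0.5)
  prior <- gaussian_density(prior0$mean, prior0$cov, names = nm)
  post <- gaussian_density(post0$mean, post0$cov, names = nm)
  red <- gaussian_density(red0$mean, red0$cov, names = nm)
  direct <- bmr_gaussian(prior, post, red, full_free_energy = 3)
  via_update <- update_subjects(list(prior), list(post), red)
  # update_subjects with a full-dimension group posterior is exactly
  # bmr_gaussian
  expect_equal(via_update[[1]]$reduced_posterior$mean,
               direct$reduced_posterior$mean)
  expect_equal(via_update[[1]]$delta_free_energy,
               direct$delta_free_energy)
})

test_that("the transform envelope brackets the averaged transform", {
  regimes <- enumerate_regimes(grid_spec(alpha_points = 8,
                                         beta_points = 8))
  set.seed(92)
  bma <- bma_average(rnorm(nrow(regimes)), regimes)
  env <- transform_envelope(bma, ctilde = c(0, 0.5, 1))
  expect_true(all(env$lower <= env$upper))
  # weighted quantiles bracket the bulk of regime values
  for (k in seq_len(nrow(env))) {
    vals <- bma$regimes$beta * env$ctilde[k] + bma$regimes$alpha
    w <- bma$regimes$weight
    inside <- vals >= env$lower[k] & vals <= env$upper[k]
    expect_gte(sum(w[inside]), 0.9)
  }
})
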