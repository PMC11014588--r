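test_that("hemodynamic transfer is region-symmetric and vanishes at high frequency", {
  grid <- fixture_grid()
  hp <- hemodynamic_params(decay = rep(0.1, 4), transit = rep(-0.2, 4))
  H <- hemodynamic_transfer(hp, grid)
  for (r in 2:4) expect_equal(H[, r], H[, 1])
  # |H| -> 0 as omega grows
  wide <- frequency_grid(c(0.01, 0.1, 1, 10, 100))
  Hw <- hemodynamic_transfer(hemodynamic_params(0, 0), wide)
  expect_true(all(diff(Mod(Hw[3:5, 1])) < 0))
  expect_lt(Mod(Hw[5, 1]), 1e-3 * max(Mod(Hw[, 1])))
  expect_error(hemodynamic_params(decay = NA), "non-finite")
})

test_that("transfer matches the DFT of the numerically integrated impulse response", {
  # time-domain oracle: Euler-integrate the same linearized ODE at a
  # fine step, sample the impulse response, then DFT
  dt <- 0.05
  nt <- 2^14
  sub <- 10
  ss <- hebdcm:::hemo_state_space(0.1, -0.1)
  z <- ss$B
  ir <- numeric(nt)
  ir[1] <- sum(ss$C * z)
  dti <- dt / sub
  for (k in 2:nt) {
    for (j in seq_len(sub)) z <- z + dti * (ss$A %*% z)
    ir[k] <- sum(ss$C * z)
  }
  spec_td <- fft(ir) * dt
  freqs <- (seq_len(nt) - 1) / (nt * dt)
  pick <- c(6, 12, 25, 50) # interior bins well below Nyquist
  grid <- frequency_grid(freqs[pick])
  H <- hemodynamic_transfer(hemodynamic_params(0.1, -0.1), grid)
  rel <- Mod(H[, 1] - spec_td[pick]) / Mod(spec_td[pick])
  expect_lt(max(rel), 0.01)
})

test_that("doubling the transit-time scaling lowers the peak frequency of |H|", {
  grid <- frequency_grid(exp(seq(log(0.005), log(1), length.out = 256)))
  peak_at <- function(transit) {
    H <- hemodynamic_transfer(hemodynamic_params(0, transit), grid)
    grid$freq_hz[which.max(Mod(H[, 1]))]
  }
  # argmax over the grid is monotone non-increasing in the transit
  # scaling (the peak can sit on the grid edge), strictly so across a
  # four-fold change
  expect_lte(peak_at(log(2)), peak_at(0))
  expect_lte(peak_at(0), peak_at(-log(2)))
  expect_lt(peak_at(log(2)), peak_at(-log(2)))
})

test_that("power-law spectrum follows its closed form", {
  grid <- fixture_grid()
  # flat-spectrum convention at log_exp = -Inf
  expect_equal(powerlaw_spectrum(0.3, -Inf, grid),
               rep(exp(0.3), 32))
  # exponent 1: halving under frequency doubling
  g2 <- frequency_grid(c(0.01, 0.02))
  s <- powerlaw_spectrum(0, 0, g2)
  expect_equal(s[2] / s[1], 1 / 2)
  # brute-force evaluation a * w^-b at all 32 points
  s3 <- powerlaw_spectrum(0.7, log(1.4), grid)
  expect_equal(s3, exp(0.7) * grid$omega^(-1.4))
  expect_true(all(diff(s3) < 0))
  expect_error(powerlaw_spectrum(0, Inf, grid), "invalid")
  expect_error(frequency_grid(c(-0.1, 0.2)), "> 0")
})

test_that("decoupled regions give exactly zero cross-spectra", {
  grid <- fixture_grid()
  A <- diag(c(-0.4, -0.6, -0.5))
  cs <- predicted_csd(A, hemodynamic_params(rep(0, 3), rep(0, 3)),
                      noise_spectra_params(v_amp = rep(0, 3),
                                           e_amp = rep(-2, 3)),
                      grid)
  off <- abs(row(diag(3)) - col(diag(3))) > 0
  for (k in c(1, 16, 32)) {
    expect_equal(max(Mod(cs$csd[, , k][off])), 0)
  }
})

test_that("predicted CSD is linear in the neuronal noise amplitude", {
  grid <- fixture_grid()
  A <- oracle_random_stable_A(3, seed = 7)
  hp <- hemodynamic_params(rep(0, 3), rep(0, 3))
  np1 <- noise_spectra_params(v_amp = rep(0, 3), e_amp = rep(-1, 3))
  np2 <- noise_spectra_params(v_amp = rep(log(2), 3),
                              e_amp = rep(-1, 3))
  g1 <- predicted_csd(A, hp, np1, grid)
  g2 <- predicted_csd(A, hp, np2, grid)
  ge <- hebdcm:::noise_spectra_eval(np1, grid, "e")
  for (k in c(2, 20)) {
    e1 <- g1$csd[, , k]
    diag(e1) <- diag(e1) - ge[k, ]
    e2 <- g2$csd[, , k]
    diag(e2) <- diag(e2) - ge[k, ]
    expect_equal(e2, 2 * e1, tolerance = 1e-12)
  }
})

test_that("predicted CSD is Hermitian PSD and matches the explicit latent factorization", {
  grid <- fixture_grid()
  for (seed in 1:5) {
    A <- oracle_random_stable_A(4, seed = 100 + seed)
    hp <- hemodynamic_params(rnorm(4, sd = 0.1), rnorm(4, sd = 0.1))
    np <- noise_spectra_params(v_amp = rnorm(4, sd = 0.2), v_exp = 0,
                               e_amp = rnorm(4, sd = 0.2) - 2,
                               e_exp = -1)
    cs <- predicted_csd(A, hp, np, grid)
    H <- hemodynamic_transfer(hp, grid)
    Gv <- hebdcm:::noise_spectra_eval(np, grid, "v")
    Ge <- hebdcm:::noise_spectra_eval(np, grid, "e")
    for (k in c(1, 15, 32)) {
      m <- cs$csd[, , k]
      expect_lt(max(Mod(m - Conj(t(m)))), 1e-12 * max(1, max(Mod(m))))
      ev <- eigen((m + Conj(t(m))) / 2, symmetric = TRUE,
                  only.values = TRUE)$values
      expect_gt(min(ev), -1e-8 * max(abs(ev)))
      # explicit X(w) X(w)^H sandwich equals the fused formula
      Mi <- solve(1i * grid$omega[k] * diag(4) - A)
      XX <- Mi %*% diag(Gv[k, ]) %*% Conj(t(Mi))
      ref <- diag(H[k, ] + 0i) %*% XX %*% diag(Conj(H[k, ]))
      diag(ref) <- diag(ref) + Ge[k, ]
      expect_equal(m, ref, tolerance = 1e-12)
    }
  }
})

test_that("predicted CSD agrees with a long Euler-Maruyama simulation", {
  # white neuronal noise (flat-spectrum convention) through the same
  # hemodynamics; Welch-estimated spectrum of the simulation should
  # match the analytic prediction on the diagonal at interior
  # frequencies within 10%
  dt <- 0.05
  nsteps <- 2^19
  ok <- 0
  for (seed in 1:3) {
    A <- oracle_random_stable_A(3, seed = 200 + seed)
    y <- oracle_simulate_linear(A, dt, nsteps, seed = 300 + seed)
    w <- oracle_welch_csd(y, dt, nseg = 2048)
    # interior band: away from the window resolution limit below and
    # from the steep hemodynamic roll-off (leakage floor) above
    pick <- which(w$freq > 0.015 & w$freq < 0.05)
    grid <- frequency_grid(w$freq[pick])
    cs <- predicted_csd(A, hemodynamic_params(rep(0, 3), rep(0, 3)),
                        noise_spectra_params(v_amp = rep(0, 3),
                                             v_exp = -Inf,
                                             e_amp = rep(-30, 3),
                                             e_exp = -Inf),
                        grid)
    rel <- vapply(seq_along(pick), function(j) {
      pred <- Re(diag(cs$csd[, , j]))
      est <- Re(diag(w$csd[, , pick[j]]))
      mean(abs(est - pred) / pred)
    }, numeric(1))
    if (mean(rel) < 0.10) ok <- ok + 1
  }
  expect_gte(ok, 2)
})

test_that("CSD serialization round-trips", {
  grid <- fixture_grid(8)
  A <- oracle_random_stable_A(3, seed = 17)
  cs <- predicted_csd(A, hemodynamic_params(rep(0, 3), rep(0, 3)),
                      noise_spectra_params(v_amp = rep(0, 3),
                                           e_amp = rep(-2, 3)),
                      grid)
  path <- tempfile(fileext = ".txt")
  write_csd(cs, path)
  back <- read_csd(path)
  expect_equal(back$grid$freq_hz, cs$grid$freq_hz)
  expect_equal(back$csd, cs$csd, tolerance = 1e-14)
  expect_equal(back$labels, cs$labels)
})
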