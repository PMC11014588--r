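# Independent oracles used across the test files.  These deliberately
# avoid the package's own fast paths: brute-force evaluation, direct
# time-domain integration, segment-averaged periodograms and Monte-Carlo
# integration.

# Welch-type cross-spectral estimate via Hann-windowed half-overlapping
# segment FFTs; returns the two-sided density on the segment frequency
# grid (per Hz, scaled by the sampling interval).
oracle_welch_csd <- function(Y, dt, nseg = 512) {
  Tn <- nrow(Y)
  n <- ncol(Y)
  Y <- scale(Y, scale = FALSE)
  nwin <- floor(Tn / (nseg / 2)) - 1
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  U <- sum(win^2)
  acc <- array(0i, c(n, n, nseg))
  for (s in seq_len(nwin)) {
    i0 <- (s - 1) * nseg / 2
    seg <- Y[i0 + seq_len(nseg), , drop = FALSE] * win
    Fs <- stats::mvfft(seg)
    for (k in seq_len(nseg)) {
      acc[, , k] <- acc[, , k] + outer(Fs[k, ], Conj(Fs[k, ]))
    }
  }
  list(freq = (seq_len(nseg) - 1) / (nseg * dt),
       csd = acc * dt / (U * nwin))
}

# Direct Euler integration of the linear state equation driven by white
# noise, observed through the package's linearized hemodynamics; used as
# the Monte-Carlo oracle for the predicted CSD.
oracle_simulate_linear <- function(A, dt, nsteps, seed) {
  n <- nrow(A)
  set.seed(seed)
  ss <- hebdcm:::hemo_state_space(0, 0)
  x <- numeric(n)
  h <- matrix(0, 4, n)
  y <- matrix(0, nsteps, n)
  sd_in <- 1 / sqrt(dt) # unit spectral density white input
  for (t in seq_len(nsteps)) {
    v <- rnorm(n, sd = sd_in)
    x <- as.numeric(x + dt * (A %*% x + v))
    h <- h + dt * (ss$A %*% h + outer(ss$B, x))
    y[t, ] <- as.numeric(ss$C %*% h)
  }
  y
}

# Simulate a stable VAR(1) series.
oracle_var1 <- function(Phi, Tn, seed, sd = 1) {
  n <- nrow(Phi)
  set.seed(seed)
  Y <- matrix(0, Tn, n)
  x <- numeric(n)
  for (t in seq_len(Tn)) {
    x <- as.numeric(Phi %*% x) + rnorm(n, sd = sd)
    Y[t, ] <- x
  }
  Y
}

# Random stable transition matrix with negative-real-part eigenvalues.
oracle_random_stable_A <- function(n, seed, self = -0.5, sd = 0.15) {
  set.seed(seed)
  A <- matrix(rnorm(n * n, sd = sd), n, n)
  diag(A) <- self
  ensure_stable(A, margin = 0.1)
}

# Monte-Carlo estimate of the log evidence of a linear-Gaussian model by
# averaging likelihoods over prior draws.
oracle_mc_log_evidence <- function(X, y, prior, noise_var, ndraw,
                                   seed) {
  set.seed(seed)
  d <- length(prior$mean)
  L <- chol(prior$cov)
  ll <- vapply(seq_len(ndraw), function(i) {
    th <- prior$mean + as.numeric(t(L) %*% rnorm(d))
    r <- y - X %*% th
    sum(stats::dnorm(r, sd = sqrt(noise_var), log = TRUE))
  }, numeric(1))
  m <- max(ll)
  m + log(mean(exp(ll - m)))
}

# Forward-difference Jacobian for oracle use in tests.
numDeriv_jac <- function(f, x, step = 1e-6) {
  g0 <- f(x)
  J <- matrix(0, length(g0), length(x))
  for (i in seq_along(x)) {
    xi <- x
    xi[i] <- xi[i] + step
    J[, i] <- (f(xi) - g0) / step
  }
  J
}
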