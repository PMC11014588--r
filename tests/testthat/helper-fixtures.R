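# Small shared fixtures, built in code at load time.

fixture_grid <- function(n = 32) default_frequency_grid(n)

fixture_csd_from_theta <- function(theta, layout, grid) {
  y <- csd_predictor(layout, grid)(theta)
  n <- layout$n
  nf <- length(grid$omega)
  arr <- array(0i, c(n, n, nf))
  blk <- 2 * n^2
  for (k in seq_len(nf)) {
    o <- (k - 1) * blk
    arr[, , k] <- matrix(y[o + seq_len(n^2)], n, n) +
      1i * matrix(y[o + n^2 + seq_len(n^2)], n, n)
  }
  cross_spectra(grid, arr, check = FALSE)
}

# A tiny random Gaussian density with positive-definite covariance.
fixture_gaussian <- function(d, seed, scale = 1) {
  set.seed(seed)
  M <- matrix(rnorm(d * d), d, d)
  gaussian_density(rnorm(d), scale * (crossprod(M) / d + diag(d)))
}
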