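#' Parameter layout of a subject-level spectral DCM
#'
#' Fixes the (column-major) vectorization of the parameter vector once,
#' for the whole package: the n^2 connectivity block first (`A[i,j]`,
#' row index fastest; diagonal entries hold the log self-connection
#' scaling, with `A_ii = -1/2 * exp(a_ii)` Hz), then per-region
#' hemodynamic log-scalings (`decay[r]`, `transit[r]`), then noise
#' log-amplitudes and shared log-exponents (`v_amp[r]`, `v_exp`,
#' `e_amp[r]`, `e_exp`).
#'
#' @param n Number of regions.
#' @param labels Optional region labels.
#' @return Object of class `dcm_layout` with the name vector and index
#'   blocks.
#' @export
dcm_layout <- function(n, labels = paste0("R", seq_len(n))) {
  stopifnot(n >= 1, length(labels) == n)
  ij <- expand.grid(i = seq_len(n), j = seq_len(n)) # column-major
  a_names <- sprintf("A[%d,%d]", ij$i, ij$j)
  h_names <- c(sprintf("decay[%d]", seq_len(n)),
               sprintf("transit[%d]", seq_len(n)))
  n_names <- c(sprintf("v_amp[%d]", seq_len(n)), "v_exp",
               sprintf("e_amp[%d]", seq_len(n)), "e_exp")
  nm <- c(a_names, h_names, n_names)
  idx_A <- seq_len(n^2)
  diag_pos <- which(ij$i == ij$j)
  structure(list(
    n = n, labels = labels, names = nm, d = length(nm),
    idx_A = idx_A,
    idx_A_diag = diag_pos,
    idx_A_offdiag = setdiff(idx_A, diag_pos),
    idx_hemo = n^2 + seq_len(2 * n),
    idx_noise = n^2 + 2 * n + seq_len(2 * n + 2)
  ), class = "dcm_layout")
}

#' Map between matrix indices and vectorized positions of the A block
#'
#' @param layout A [dcm_layout()].
#' @param i,j Row (target) and column (source) region indices.
#' @return Position of `A[i,j]` in the vectorized parameter block.
#' @export
a_index <- function(layout, i, j) (j - 1) * layout$n + i

# Unpack a named parameter vector into model components.
theta_to_model <- function(theta, layout) {
  n <- layout$n
  A <- matrix(theta[layout$idx_A], n, n)
  diag(A) <- -0.5 * exp(diag(A))
  h <- theta[layout$idx_hemo]
  hp <- hemodynamic_params(decay = h[seq_len(n)],
                           transit = h[n + seq_len(n)])
  nn <- theta[layout$idx_noise]
  np <- noise_spectra_params(v_amp = nn[seq_len(n)], v_exp = nn[n + 1],
                             e_amp = nn[n + 1 + seq_len(n)],
                             e_exp = nn[2 * n + 2])
  list(A = A, hparams = hp, nparams = np)
}

#' Default subject-level priors for a spectral DCM
#'
#' Off-diagonal connections are shrunk around zero with variance 1/64;
#' self-connections are parameterized as `-1/2 * exp(a_ii)` Hz with
#' `a_ii ~ N(0, 1/64)` (guaranteeing a negative diagonal); hemodynamic
#' and noise log-parameters have variance 1/16.  The observation-noise
#' log-precision hyperparameter carries a weakly informative Gaussian
#' hyperprior so the feature-noise level can adapt to the scale of the
#' cross-spectral features.
#'
#' @param n Number of regions.
#' @param labels Optional region labels.
#' @param var_a Prior variance of connectivity parameters (default 1/64).
#' @param var_hemo,var_noise Prior variances of hemodynamic and noise
#'   log-parameters (default 1/16).
#' @param lambda_mean,lambda_var Hyperprior on the log-precision of
#'   observation noise in the feature space.
#' @return Object of class `dcm_priors`: `prior` (a [gaussian_density()]),
#'   `layout`, `lambda_prior`.
#' @export
dcm_priors <- function(n, labels = paste0("R", seq_len(n)),
                       var_a = 1 / 64, var_hemo = 1 / 16,
                       var_noise = 1 / 16,
                       lambda_mean = 0, lambda_var = 9) {
  layout <- dcm_layout(n, labels)
  v <- numeric(layout$d)
  v[layout$idx_A] <- var_a
  v[layout$idx_hemo] <- var_hemo
  v[layout$idx_noise] <- var_noise
  prior <- gaussian_density(rep(0, layout$d), v, names = layout$names)
  structure(list(prior = prior, layout = layout,
                 lambda_prior = list(mean = lambda_mean,
                                     var = lambda_var)),
            class = "dcm_priors")
}
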