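#' Configuration of the in-silico study design
#'
#' Defaults emulate the validation design: a 6-region network, BOLD-like
#' series of 1200 samples at a 0.72 s sampling interval, signal-to-noise
#' ratio 1, group effective connectivity drawn as a standard Gaussian
#' scaled by the square root of the linear structure-to-variance
#' transform, and Gaussian subject-level deviations.
#'
#' @param n Number of regions.
#' @param subjects Subjects per instantiation.
#' @param instantiations Number of instantiations of the full design.
#' @param snr Signal-to-noise ratio: per-region temporal standard
#'   deviation of the noiseless BOLD signal divided by the observation
#'   noise standard deviation (`Inf` disables observation noise).
#' @param alpha_true,beta_true Ground-truth transform generating group
#'   effective connectivity variance `beta_true * ctilde + alpha_true`.
#' @param rfx_sd Standard deviation of subject-level random deviations
#'   (Hz).
#' @param self_value Ground-truth self-connection (Hz, negative).
#' @param n_times Series length in samples.
#' @param sampling_interval Sampling interval (s).
#' @param integration_step Requested integration step (s); the effective
#'   step divides the sampling interval exactly.
#' @param density Fraction of possible undirected edges present in the
#'   structural connectome.
#' @param weight_range Range of uniform structural edge weights before
#'   normalization.
#' @param stability_margin All simulated systems are deepened until the
#'   largest real eigenvalue part is at most `-stability_margin` Hz.
#' @param fluct_tau Time constant (s) of the one-pole low-pass filter
#'   shaping the endogenous fluctuations.
#' @param seed Master seed; all other randomness derives from it.
#' @export
sim_config <- function(n = 6, subjects = 10, instantiations = 50,
                       snr = 1, alpha_true = 0.02, beta_true = 0.25,
                       rfx_sd = 0.1, self_value = -0.5, n_times = 1200,
                       sampling_interval = 0.72, integration_step = 0.05,
                       density = 0.5, weight_range = c(0.1, 1),
                       stability_margin = 0.05, fluct_tau = 2,
                       seed = 1) {
  stopifnot(snr > 0, n >= 2, subjects >= 1, n_times >= 2,
            sampling_interval > 0, integration_step > 0,
            self_value < 0, rfx_sd > 0)
  if (n_times * sampling_interval < 128) {
    stop("series too short for the lowest analysis frequency ",
         "(need n_times * sampling_interval >= 128 s)", call. = FALSE)
  }
  structure(list(n = n, subjects = subjects,
                 instantiations = instantiations, snr = snr,
                 alpha_true = alpha_true, beta_true = beta_true,
                 rfx_sd = rfx_sd, self_value = self_value,
                 n_times = n_times, sampling_interval = sampling_interval,
                 integration_step = integration_step, density = density,
                 weight_range = weight_range,
                 stability_margin = stability_margin,
                 fluct_tau = fluct_tau, seed = seed),
            class = "sim_config")
}

# Derived sub-seed: deterministic, well below 2^31.
sub_seed <- function(seed, ...) {
  ix <- c(...)
  s <- seed
  for (v in ix) s <- (s * 69069 + v) %% 2147483629
  as.integer(s)
}

#' Sample a sparse symmetric structural connectome
#'
#' Edges are drawn without replacement from the undirected pairs until a
#' connected support is obtained (deterministically per seed); weights
#' are uniform on `weight_range`.
#'
#' @param n Regions.
#' @param density Fraction of the `n(n-1)/2` undirected edges present.
#' @param weight_range Length-2 interval of positive weights.
#' @param seed Integer seed.
#' @export
sample_structural <- function(n, density = 0.5,
                              weight_range = c(0.1, 1), seed = 1) {
  stopifnot(density > 0, density <= 1)
  n_pairs <- n * (n - 1) / 2
  m <- round(density * n_pairs)
  if (m < n - 1) {
    stop("infeasible density: ", m, " edges cannot connect ", n,
         " regions", call. = FALSE)
  }
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  for (try in seq_len(1000)) {
    C <- local_rng(sub_seed(seed, 11, try), {
      idx <- sample.int(n_pairs, m)
      w <- stats::runif(m, weight_range[1], weight_range[2])
      C <- matrix(0, n, n)
      for (k in seq_len(m)) {
        C[pairs[idx[k], 1], pairs[idx[k], 2]] <- w[k]
        C[pairs[idx[k], 2], pairs[idx[k], 1]] <- w[k]
      }
      C
    })
    if (is_connected(C > 0)) {
      dimnames(C) <- list(paste0("R", seq_len(n)), paste0("R", seq_len(n)))
      return(C)
    }
  }
  stop("infeasible density: could not obtain a connected support",
       call. = FALSE)
}

# Evaluate `expr` under a local, restored RNG state.
local_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

is_connected <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  seen[1] <- TRUE
  frontier <- 1
  while (length(frontier) > 0) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Sample group-level effective connectivity from the structural prior
#'
#' Off-diagonal entries are independent draws
#' `sqrt(beta_true * ctilde_ij + alpha_true) * z_ij` with standard
#' Gaussian `z` (independent per directed edge even though the
#' structural matrix is symmetric); the diagonal is set to `self_value`.
#'
#' @param Ctilde Normalized structural connectivity.
#' @param alpha_true,beta_true Ground-truth transform.
#' @param self_value Self-connection value (Hz).
#' @param seed Integer seed.
#' @export
sample_group_ec <- function(Ctilde, alpha_true, beta_true,
                            self_value = -0.5, seed = 1) {
  n <- nrow(Ctilde)
  v <- beta_true * Ctilde + alpha_true
  diag(v) <- 0
  if (any(v < 0)) {
    stop("invalid transform: negative variance at some edge",
         call. = FALSE)
  }
  z <- local_rng(seed, matrix(stats::rnorm(n * n), n, n))
  A <- sqrt(v) * z
  diag(A) <- self_value
  dimnames(A) <- dimnames(Ctilde)
  A
}

#' Sample subject-level effective connectivity
#'
#' Adds iid Gaussian deviations `N(0, rfx_sd^2)` to the off-diagonal of
#' the group matrix; the diagonal passes through unperturbed (stability
#' is enforced separately by [ensure_stable()]).
#'
#' @param A2 Group effective connectivity.
#' @param rfx_sd Deviation standard deviation (Hz, > 0).
#' @param seed Integer seed.
#' @export
sample_subject_ec <- function(A2, rfx_sd, seed = 1) {
  stopifnot(rfx_sd > 0)
  n <- nrow(A2)
  eps <- local_rng(seed, matrix(stats::rnorm(n * n, sd = rfx_sd), n, n))
  diag(eps) <- 0
  A2 + eps
}

#' Enforce stability of an effective connectivity matrix
#'
#' If the largest real eigenvalue part exceeds `-margin`, the diagonal
#' is uniformly deepened (a scalar shift) until it equals `-margin`;
#' off-diagonal entries are untouched.  Idempotent.
#'
#' @param A Square matrix (Hz).
#' @param margin Positive stability margin (Hz).
#' @export
ensure_stable <- function(A, margin = 0.05) {
  stopifnot(margin > 0)
  mre <- max(Re(eigen(A, only.values = TRUE)$values))
  if (mre > -margin * (1 - 1e-9)) {
    A <- A - (mre + margin) * diag(nrow(A))
  }
  A
}

#' Simulate BOLD-like time series from an effective connectivity network
#'
#' Euler-Maruyama integration of the linear neuronal state equation
#' driven by low-pass-filtered Gaussian fluctuations, passed region-wise
#' through the linearized hemodynamic model, decimated to the sampling
#' interval, and corrupted with white observation noise calibrated to
#' the configured signal-to-noise ratio.  Deterministic per seed.
#'
#' @param A Stable effective connectivity matrix (Hz).
#' @param hparams [hemodynamic_params()] (defaults to canonical values).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Numeric matrix `n_times x n` with region labels.
#' @export
simulate_bold <- function(A, hparams = NULL, config = sim_config(),
                          seed = 1) {
  n <- nrow(A)
  if (is.null(hparams)) hparams <- hemodynamic_params(rep(0, n),
                                                      rep(0, n))
  dt_out <- config$sampling_interval
  k <- max(1L, round(dt_out / config$integration_step))
  dt <- dt_out / k
  burn_samples <- 64L
  n_tot <- (config$n_times + burn_samples) * k
  rho <- exp(-dt / config$fluct_tau)
  # per-region hemodynamic blocks, assembled block-diagonally so the
  # whole latent system advances with two matrix products per step
  hss <- lapply(seq_len(n), function(r)
    hemo_state_space(hparams$decay[r], hparams$transit[r]))
  Ah <- matrix(0, 4 * n, 4 * n)
  Ch <- matrix(0, n, 4 * n)
  for (r in seq_len(n)) {
    ix <- (r - 1) * 4 + 1:4
    Ah[ix, ix] <- hss[[r]]$A
    Ch[r, ix] <- hss[[r]]$C
  }
  noise <- local_rng(sub_seed(seed, 23),
                     matrix(stats::rnorm(n_tot * n), n_tot, n))
  x <- numeric(n)
  v <- numeric(n)
  h <- numeric(4 * n)
  b_ix <- (seq_len(n) - 1) * 4 + 1 # input enters the first state
  y <- matrix(0, config$n_times + burn_samples, n)
  # scale the innovations so the filtered fluctuation has roughly unit
  # variance regardless of dt (AR(1) stationary variance correction)
  innov_sd <- sqrt(1 - rho^2)
  row <- 0L
  for (t in seq_len(n_tot)) {
    v <- rho * v + innov_sd * noise[t, ]
    x <- as.numeric(x + dt * (A %*% x + v))
    dh <- Ah %*% h
    dh[b_ix] <- dh[b_ix] + x
    h <- as.numeric(h + dt * dh)
    if (t %% k == 0L) {
      row <- row + 1L
      y[row, ] <- Ch %*% h
    }
  }
  if (any(!is.finite(y))) {
    stop("instability: non-finite state during integration at step ",
         which(!is.finite(rowSums(y)))[1], call. = FALSE)
  }
  y <- y[(burn_samples + 1):nrow(y), , drop = FALSE]
  if (is.finite(config$snr)) {
    sds <- apply(y, 2, stats::sd)
    obs <- local_rng(sub_seed(seed, 29),
                     matrix(stats::rnorm(length(y)), nrow(y), n))
    y <- y + obs * rep(sds / config$snr, each = nrow(y))
  }
  colnames(y) <- if (!is.null(rownames(A))) rownames(A) else
    paste0("R", seq_len(n))
  y
}

#' Generate one instantiation of the in-silico design
#'
#' Samples (or reuses) a structural connectome, draws group effective
#' connectivity from the structure-scaled Gaussian, adds subject-level
#' deviations, enforces stability and simulates a BOLD-like series per
#' subject.  Fully reproducible from the config's master seed; all
#' derived seeds are recorded.
#'
#' @param config A [sim_config()].
#' @param C Optional pre-supplied structural connectome (fixed across
#'   instantiations by the study protocol).
#' @param instantiation Index used to derive seeds.
#' @return List with `truth` (C, Ctilde, A2, A_subjects, seeds) and
#'   `series` (list of subject time-series matrices).
#' @export
generate_dataset <- function(config, C = NULL, instantiation = 1) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- list(
    structural = sub_seed(config$seed, 1),
    group = sub_seed(config$seed, 2, instantiation),
    subjects = vapply(seq_len(config$subjects), function(s)
      sub_seed(config$seed, 3, instantiation, s), integer(1)),
    series = vapply(seq_len(config$subjects), function(s)
      sub_seed(config$seed, 4, instantiation, s), integer(1))
  )
  if (is.null(C)) {
    C <- sample_structural(config$n, config$density,
                           config$weight_range, seed = seeds$structural)
  }
  Ctilde <- normalize_structural(C)
  A2 <- sample_group_ec(Ctilde, config$alpha_true, config$beta_true,
                        config$self_value, seed = seeds$group)
  A2 <- ensure_stable(A2, config$stability_margin)
  A_subj <- vector("list", config$subjects)
  series <- vector("list", config$subjects)
  for (s in seq_len(config$subjects)) {
    As <- sample_subject_ec(A2, config$rfx_sd, seed = seeds$subjects[s])
    As <- ensure_stable(As, config$stability_margin)
    A_subj[[s]] <- As
    series[[s]] <- simulate_bold(As, config = config,
                                 seed = seeds$series[s])
  }
  list(truth = list(C = C, Ctilde = Ctilde, A2 = A2,
                    A_subjects = A_subj, seeds = seeds),
       series = series)
}
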