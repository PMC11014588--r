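#' Canonical hemodynamic constants
#'
#' Fixed constants of the linearized balloon model used throughout the
#' package: `kappa` (signal decay rate, 1/s), `gamma` (autoregulatory
#' feedback rate, 1/s), `tau` (mean transit time, s), `alpha` (Grubb's
#' vessel stiffness exponent), `E0` (resting oxygen extraction fraction)
#' and `V0` (resting venous blood volume fraction), together with the
#' classic BOLD signal coefficients `k1`, `k2`, `k3`.  Subject-level free
#' parameters are unitless log-scaling factors applied to `kappa` (signal
#' decay) and `tau` (transit time) around these values.
#'
#' @format Named numeric vector.
#' @export
hemo_constants <- c(
  kappa = 0.64, gamma = 0.32, tau = 2.00, alpha = 0.32,
  E0 = 0.40, V0 = 0.04,
  k1 = 7 * 0.40, k2 = 2.0, k3 = 2 * 0.40 - 0.2
)

#' Hemodynamic free parameters
#'
#' Per-region unitless log-scaling factors for the signal-decay rate and
#' the mean transit time of the linearized balloon model.  `decay = 0`
#' and `transit = 0` give the canonical constants.
#'
#' @param decay Numeric vector, one log-scaling per region.
#' @param transit Numeric vector, one log-scaling per region (same length).
#' @return Object of class `hemodynamic_params`.
#' @export
hemodynamic_params <- function(decay = 0, transit = 0) {
  n <- max(length(decay), length(transit))
  decay <- rep_len(as.numeric(decay), n)
  transit <- rep_len(as.numeric(transit), n)
  if (!all(is.finite(decay)) || !all(is.finite(transit))) {
    stop("non-finite hemodynamic parameters", call. = FALSE)
  }
  structure(list(decay = decay, transit = transit, n = n),
            class = "hemodynamic_params")
}

# State-space matrices of the balloon model linearized about rest, for one
# region.  States are (vasodilatory signal, normalized inflow deviation,
# normalized volume deviation, normalized deoxyhemoglobin deviation); the
# input is neuronal activity and the output the BOLD signal change.
hemo_state_space <- function(decay = 0, transit = 0, const = hemo_constants) {
  kappa <- const[["kappa"]] * exp(decay)
  tau <- const[["tau"]] * exp(transit)
  gam <- const[["gamma"]]
  alpha <- const[["alpha"]]
  E0 <- const[["E0"]]
  if (!is.finite(kappa) || !is.finite(tau) || tau <= 0 || kappa <= 0) {
    stop("implied hemodynamic time constants must be positive",
         call. = FALSE)
  }
  # d/df [ f * (1 - (1-E0)^(1/f)) / E0 ] at f = 1
  cf <- 1 + (1 - E0) * log(1 - E0) / E0
  A <- matrix(c(
    -kappa, -gam,              0,                    0,
    1,      0,                 0,                    0,
    0,      1 / tau,           -1 / (tau * alpha),   0,
    0,      cf / tau,          -(1 / alpha - 1) / tau, -1 / tau
  ), nrow = 4, byrow = TRUE)
  B <- c(1, 0, 0, 0)
  V0 <- const[["V0"]]
  C <- -V0 * c(0, 0, const[["k3"]] - const[["k2"]],
               const[["k1"]] + const[["k2"]])
  list(A = A, B = B, C = C)
}

#' Hemodynamic transfer function
#'
#' Fourier transform of the linearized balloon model's impulse response,
#' evaluated on a frequency grid: `H(w) = C (iwI - A)^-1 B` for the
#' region-specific linearization.
#'
#' @param hparams A [hemodynamic_params()] object.
#' @param grid A [frequency_grid()].
#' @return Complex matrix, frequencies in rows and regions in columns.
#' @export
hemodynamic_transfer <- function(hparams, grid) {
  stopifnot(inherits(hparams, "hemodynamic_params"),
            inherits(grid, "frequency_grid"))
  omega <- grid$omega
  H <- matrix(0i, nrow = length(omega), ncol = hparams$n)
  for (r in seq_len(hparams$n)) {
    ss <- hemo_state_space(hparams$decay[r], hparams$transit[r])
    for (k in seq_along(omega)) {
      H[k, r] <- sum(ss$C * solve(1i * omega[k] * diag(4) - ss$A, ss$B))
    }
  }
  H
}

# Impulse response of the linearized hemodynamic model sampled at `dt`
# for `nt` steps (matrix exponential free: forward integration would drift,
# so use eigendecomposition of the 4x4 state matrix).
hemo_impulse_response <- function(decay = 0, transit = 0, dt, nt) {
  ss <- hemo_state_space(decay, transit)
  e <- eigen(ss$A)
  w <- solve(e$vectors, ss$B)
  tt <- (seq_len(nt) - 1) * dt
  # y(t) = C expm(A t) B
  Re(vapply(tt, function(t) {
    sum((ss$C %*% e$vectors) * (exp(e$values * t) * w))
  }, numeric(1)))
}
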