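#' Fit a multivariate autoregressive model by ordinary least squares
#'
#' The empirical cross-spectral data features are parametric: an MVAR
#' model is fitted to the (detrended) time series and its spectrum
#' evaluated analytically by [mvar_csd()].
#'
#' @param timeseries Numeric matrix, rows = time points, columns =
#'   regions (optionally with column names as region labels).
#' @param order Model order `p >= 1` (default 8, the conventional default
#'   for cross-spectral features of resting-state BOLD).
#' @param detrend Remove per-column mean and linear trend before fitting
#'   (default TRUE; set FALSE for mean-centering only).
#' @param cov_denominator Convention for the innovation-covariance
#'   denominator: `"adjusted"` uses `T - p - n*p` (degrees-of-freedom
#'   corrected for the `n*p` regressors per equation), `"naive"` uses
#'   `T - p`.
#' @return Object of class `mvar_model`: `order`, `coef` (list of p
#'   n-by-n matrices; `coef[[k]][i, j]` is the effect of region j at lag k
#'   on region i), `innovation_cov`, `n_obs`, `labels`.
#' @export
fit_mvar <- function(timeseries, order = 8,
                     detrend = TRUE,
                     cov_denominator = c("adjusted", "naive")) {
  cov_denominator <- match.arg(cov_denominator)
  Y0 <- as.matrix(timeseries)
  Tn <- nrow(Y0)
  n <- ncol(Y0)
  p <- as.integer(order)
  stopifnot(p >= 1)
  if (Tn <= n * p + 1) {
    stop("too few time points for the requested order", call. = FALSE)
  }
  labels <- colnames(Y0)
  if (is.null(labels)) labels <- paste0("R", seq_len(n))
  sds <- apply(Y0, 2, stats::sd)
  if (any(sds == 0)) {
    stop("ill-conditioned data: zero-variance column(s) ",
         paste(labels[sds == 0], collapse = ", "), call. = FALSE)
  }
  Y0 <- detrend_series(Y0, linear = detrend)
  # lagged design
  Y <- Y0[(p + 1):Tn, , drop = FALSE]
  X <- do.call(cbind, lapply(seq_len(p), function(k) {
    Y0[(p + 1 - k):(Tn - k), , drop = FALSE]
  }))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("ill-conditioned data: rank-deficient regressor matrix",
         call. = FALSE)
  }
  B <- qr.coef(qrX, Y)              # (n*p) x n, columns = target regions
  resid <- Y - X %*% B
  denom <- switch(cov_denominator,
                  adjusted = Tn - p - n * p,
                  naive = Tn - p)
  if (denom <= 0) stop("nonpositive covariance denominator", call. = FALSE)
  Sigma <- crossprod(resid) / denom
  coef <- lapply(seq_len(p), function(k) {
    t(B[((k - 1) * n + 1):(k * n), , drop = FALSE])
  })
  structure(list(order = p, coef = coef,
                 innovation_cov = (Sigma + t(Sigma)) / 2,
                 n_obs = Tn, labels = labels),
            class = "mvar_model")
}

detrend_series <- function(Y, linear = TRUE) {
  Tn <- nrow(Y)
  if (linear) {
    X <- cbind(1, seq_len(Tn))
    Y - X %*% qr.coef(qr(X), Y)
  } else {
    sweep(Y, 2, colMeans(Y))
  }
}

#' Parametric cross-spectral density of a fitted MVAR model
#'
#' `S(w) = A(w)^-1 Sigma A(w)^-H * dt` with
#' `A(w) = I - sum_k A_k exp(-i w k dt)`, evaluated on a frequency grid.
#'
#' @param model An [fit_mvar()] result.
#' @param grid A [frequency_grid()]; all frequencies must lie below the
#'   Nyquist frequency for the sampling interval.
#' @param sampling_interval Sampling interval in seconds.
#' @return A [cross_spectra()] object.
#' @export
mvar_csd <- function(model, grid, sampling_interval) {
  stopifnot(inherits(model, "mvar_model"),
            inherits(grid, "frequency_grid"))
  dt <- sampling_interval
  if (any(grid$freq_hz >= 1 / (2 * dt))) {
    stop("grid contains frequencies at or above Nyquist (",
         format(1 / (2 * dt)), " Hz)", call. = FALSE)
  }
  n <- nrow(model$coef[[1]])
  I <- diag(n)
  mats <- vector("list", length(grid$omega))
  for (k in seq_along(grid$omega)) {
    w <- grid$omega[k]
    Aw <- I + 0i
    for (j in seq_len(model$order)) {
      Aw <- Aw - model$coef[[j]] * exp(-1i * w * j * dt)
    }
    Ai <- tryCatch(solve(Aw, I), error = function(e) NULL)
    if (is.null(Ai)) {
      stop("MVAR transfer matrix singular at ",
           format(grid$freq_hz[k]), " Hz", call. = FALSE)
    }
    S <- Ai %*% model$innovation_cov %*% Conj(t(Ai)) * dt
    mats[[k]] <- (S + Conj(t(S))) / 2
  }
  cross_spectra(grid, mats, labels = model$labels, check = FALSE)
}

#' Cross-spectral features of an observed time series
#'
#' Convenience wrapper: detrend, fit an MVAR model and evaluate its
#' parametric spectrum on the analysis grid.
#'
#' @inheritParams fit_mvar
#' @inheritParams mvar_csd
#' @export
csd_features <- function(timeseries, grid = default_frequency_grid(),
                         sampling_interval = 0.72, order = 8,
                         detrend = TRUE) {
  model <- fit_mvar(timeseries, order = order, detrend = detrend)
  mvar_csd(model, grid, sampling_interval)
}
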