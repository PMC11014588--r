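#' Structurally masked multivariate autoregressive baseline
#'
#' The comparison model of directed functional connectivity: structural
#' connectivity serves as a template for possible interactions, so the
#' autoregressive coefficient from region j to region i is estimated
#' only where a direct structural connection exists (self-lags are
#' always included).  Estimation is per-target least squares restricted
#' to the masked predictors across all lags; the reported weight is the
#' sum over lags.
#'
#' @param timeseries Numeric matrix, rows = time points, columns =
#'   regions.
#' @param C Structural connectivity matrix (only the off-diagonal
#'   support is used).
#' @param order AR order (default 1).
#' @param detrend Remove mean and linear trend first (default TRUE).
#' @return Object of class `directed_fc`: `weights` (n x n;
#'   `weights[i, j]` is the lag-summed influence of region j on region
#'   i, exactly 0 outside the mask), `mask`, `order`.
#' @export
fit_masked_mvar <- function(timeseries, C, order = 1, detrend = TRUE) {
  Y0 <- as.matrix(timeseries)
  Tn <- nrow(Y0)
  n <- ncol(Y0)
  p <- as.integer(order)
  stopifnot(p >= 1, nrow(C) == n)
  if (Tn <= n * p + 1) {
    stop("too few time points for the requested order", call. = FALSE)
  }
  mask <- C > 0
  diag(mask) <- TRUE
  Y0 <- detrend_series(Y0, linear = detrend)
  Y <- Y0[(p + 1):Tn, , drop = FALSE]
  lags <- lapply(seq_len(p), function(k)
    Y0[(p + 1 - k):(Tn - k), , drop = FALSE])
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    preds <- which(mask[i, ])
    if (length(preds) == 1 && preds == i && sum(mask[i, ]) == 1) {
      warning("region ", i, " has no allowed predictors; fitting ",
              "self-lags only", call. = FALSE)
    }
    X <- do.call(cbind, lapply(lags, function(L)
      L[, preds, drop = FALSE]))
    b <- qr.coef(qr(X), Y[, i])
    b[is.na(b)] <- 0
    bmat <- matrix(b, nrow = length(preds)) # predictors x lags
    W[i, preds] <- W[i, preds] + rowSums(bmat)
  }
  labels <- colnames(Y0)
  if (!is.null(labels)) dimnames(W) <- list(labels, labels)
  structure(list(weights = W, mask = mask, order = p),
            class = "directed_fc")
}

#' Group-average directed functional connectivity
#'
#' Element-wise arithmetic mean of subject-level masked estimates;
#' masked zeros are preserved exactly.
#'
#' @param estimates List of [fit_masked_mvar()] results.
#' @return Numeric n x n matrix.
#' @export
group_directed_fc <- function(estimates) {
  stopifnot(length(estimates) >= 1)
  m0 <- estimates[[1]]$mask
  for (e in estimates) {
    if (!identical(dim(e$weights), dim(estimates[[1]]$weights)) ||
        !identical(e$mask, m0)) {
      stop("mask mismatch across subject estimates", call. = FALSE)
    }
  }
  Reduce(`+`, lapply(estimates, `[[`, "weights")) / length(estimates)
}
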