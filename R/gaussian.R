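#' Multivariate Gaussian density
#'
#' The common currency of the package: priors, posteriors and empirical
#' priors are all carried around as a mean vector plus covariance matrix,
#' with parameter names mapping positions to model parameters.
#'
#' @param mean Numeric vector (optionally named).
#' @param cov Covariance matrix, or a numeric vector of variances which is
#'   taken as a diagonal covariance.
#' @param names Optional character vector of parameter names; defaults to
#'   `names(mean)`.
#' @return An object of class `gaussian_density` with elements `mean`
#'   (named numeric) and `cov` (matrix).
#' @export
gaussian_density <- function(mean, cov, names = NULL) {
  mean <- as.numeric(mean)
  d <- length(mean)
  if (is.null(dim(cov))) {
    cov <- diag(as.numeric(cov), nrow = d)
  }
  cov <- as.matrix(cov)
  if (!all(dim(cov) == c(d, d))) {
    stop("dimension mismatch between mean and covariance", call. = FALSE)
  }
  if (!all(is.finite(mean)) || !all(is.finite(cov))) {
    stop("non-finite values in Gaussian density", call. = FALSE)
  }
  asym <- max(abs(cov - t(cov)))
  if (asym > 1e-8 * max(1, max(abs(cov)))) {
    stop("covariance is not symmetric", call. = FALSE)
  }
  cov <- (cov + t(cov)) / 2
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(1, max(abs(ev)))) {
    stop("covariance has a negative eigenvalue: ", format(min(ev)),
         call. = FALSE)
  }
  if (is.null(names)) names <- base::names(mean)
  if (!is.null(names)) {
    stopifnot(length(names) == d)
    base::names(mean) <- names
    dimnames(cov) <- list(names, names)
  }
  structure(list(mean = mean, cov = cov), class = "gaussian_density")
}

#' @export
print.gaussian_density <- function(x, ...) {
  cat("<gaussian_density> dim", length(x$mean), "\n")
  invisible(x)
}

#' @export
length.gaussian_density <- function(x) length(x$mean)

# Symmetric pseudo-inverse with rank bookkeeping.  Eigenvalues below
# tol * max(|eigenvalue|) are treated as exact zeros (clamped directions);
# the log-pseudo-determinant is restricted to the retained support.
sym_pinv <- function(m, tol = 1e-12) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  scale <- max(abs(e$values), 1e-300)
  keep <- abs(e$values) > tol * scale
  inv_vals <- ifelse(keep, 1 / e$values, 0)
  inv <- e$vectors %*% (inv_vals * t(e$vectors))
  structure(
    (inv + t(inv)) / 2,
    rank = sum(keep),
    logdet = sum(log(abs(e$values[keep])))
  )
}

# Log pseudo-determinant of a symmetric matrix (support only).
sym_logdet <- function(m, tol = 1e-12) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(e), 1e-300)
  sum(log(abs(e[abs(e) > tol * scale])))
}

#' Precision (inverse covariance) of a Gaussian density
#'
#' Computed by symmetric pseudo-inverse so that exact-zero prior variances
#' (connections clamped to the prior mean) are handled gracefully: the
#' clamped directions carry zero precision and are excluded from
#' log-determinants.
#'
#' @param x A [gaussian_density()].
#' @return Precision matrix with attributes `rank` and `logdet` (the log
#'   pseudo-determinant of the covariance on its support).
#' @export
gd_precision <- function(x) {
  p <- sym_pinv(x$cov)
  attr(p, "logdet") <- -attr(p, "logdet") # logdet of precision
  p
}

# KL(q || p) between two Gaussians of equal dimension.
gd_kl <- function(q, p) {
  d <- length(q$mean)
  stopifnot(length(p$mean) == d)
  pp <- sym_pinv(p$cov)
  dm <- q$mean - p$mean
  0.5 * (sum(pp * q$cov) + sum(dm * (pp %*% dm)) - d +
           attr(pp, "logdet") - sym_logdet(q$cov))
}

# Extract a named sub-density (marginal over the retained coordinates).
gd_subset <- function(x, idx) {
  gaussian_density(x$mean[idx], x$cov[idx, idx, drop = FALSE])
}
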