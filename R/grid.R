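#' Hyperparameter grid over prior-variance transformations
#'
#' Describes the triangular sampling space of the linear transformation
#' `sigma2 = beta * ctilde + alpha`: `alpha` equidistant over its range;
#' for each `alpha`, `beta` equidistant over `[0, 1/2 - alpha]`;
#' combinations violating `alpha >= 0` or `alpha + beta >= 1e-5` are
#' filtered out after construction.
#'
#' @param alpha_points,beta_points Number of equidistant samples
#'   (default 30 each).
#' @param alpha_range Range of `alpha` (default `[-1/2, 1/2]`; the
#'   negative half is removed by the filter, mirroring the declared
#'   sampling-then-filtering construction).
#' @param delta Fixed intraregional variance.
#' @export
grid_spec <- function(alpha_points = 30, beta_points = 30,
                      alpha_range = c(-1 / 2, 1 / 2), delta = 1 / 64) {
  stopifnot(alpha_points >= 1, beta_points >= 1,
            length(alpha_range) == 2, delta > 0)
  structure(list(alpha_points = alpha_points, beta_points = beta_points,
                 alpha_range = alpha_range, delta = delta),
            class = "grid_spec")
}

#' Enumerate prior-variance regimes from a grid specification
#'
#' @param spec A [grid_spec()].
#' @return Tibble with columns `alpha`, `beta`, `delta`, in stable
#'   alpha-major order, containing only regimes satisfying
#'   `alpha >= 0` and `alpha + beta >= 1e-5`.
#' @export
enumerate_regimes <- function(spec = grid_spec()) {
  stopifnot(inherits(spec, "grid_spec"))
  alphas <- if (spec$alpha_points == 1) mean(spec$alpha_range) else
    seq(spec$alpha_range[1], spec$alpha_range[2],
        length.out = spec$alpha_points)
  rows <- lapply(alphas, function(a) {
    upper <- 1 / 2 - a
    if (upper < 0) return(NULL)
    betas <- if (spec$beta_points == 1 || upper == 0) 0 else
      seq(0, upper, length.out = spec$beta_points)
    tibble::tibble(alpha = a, beta = unique(betas))
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::filter(out, .data$alpha >= 0,
                       .data$alpha + .data$beta >= 1e-5)
  if (nrow(out) == 0) {
    stop("empty grid: no regime satisfies the constraints",
         call. = FALSE)
  }
  out$delta <- spec$delta
  out
}

#' Score prior-variance regimes by Bayesian model reduction
#'
#' The group model is inverted once under the uninformed prior; every
#' structurally informed regime is then scored analytically, without
#' re-optimization, by reducing the third-level prior.
#'
#' @param group_full A [invert_group()] fit obtained under the
#'   uninformed third-level prior.
#' @param Ctilde Normalized structural connectivity.
#' @param regimes Tibble from [enumerate_regimes()].
#' @return The `regimes` tibble with columns `delta_f` (free-energy
#'   change versus the uninformed model) and `free_energy`.
#' @export
score_grid <- function(group_full, Ctilde, regimes) {
  stopifnot(inherits(group_full, "peb_fit"))
  full_prior <- group_full$third_prior
  out <- regimes
  out$delta_f <- NA_real_
  for (k in seq_len(nrow(regimes))) {
    tr <- prior_variance_transform(regimes$alpha[k], regimes$beta[k],
                                   regimes$delta[k])
    red <- build_prior_covariance(Ctilde, tr, mean = full_prior$mean)
    res <- tryCatch(
      bmr_gaussian(full_prior, group_full$posterior, red,
                   full_free_energy = group_full$free_energy),
      error = function(e) {
        stop("regime ", k, " (alpha=", format(regimes$alpha[k]),
             ", beta=", format(regimes$beta[k]), "): ",
             conditionMessage(e), call. = FALSE)
      })
    out$delta_f[k] <- res$delta_free_energy
  }
  out$free_energy <- group_full$free_energy + out$delta_f
  out
}

#' Bayesian model averaging over prior-variance regimes
#'
#' Softmax weighting of the regimes by their free energies (computed
#' after subtracting the maximum, so hundreds-of-nats spreads cannot
#' overflow), and the evidence-weighted average transformation
#' `lambda_bar = sum_k p_k lambda_k`.
#'
#' @param scored Tibble from [score_grid()] (columns `alpha`, `beta`,
#'   `delta`, `free_energy`), or a numeric free-energy vector together
#'   with `regimes`.
#' @param regimes Optional regimes tibble when `scored` is a numeric
#'   vector.
#' @return Object of class `bma_result`: `regimes` (with `weight`
#'   column), `alpha_bar`, `beta_bar`, `delta`, `transform` (the
#'   averaged [prior_variance_transform()]).
#' @export
bma_average <- function(scored, regimes = NULL) {
  if (is.numeric(scored)) {
    stopifnot(!is.null(regimes), length(scored) == nrow(regimes))
    tab <- regimes
    tab$free_energy <- as.numeric(scored)
  } else {
    tab <- scored
  }
  fk <- tab$free_energy
  if (any(!is.finite(fk))) stop("non-finite free energies", call. = FALSE)
  w <- exp(fk - max(fk))
  w <- w / sum(w)
  stopifnot(all(is.finite(w))) # guaranteed by max-subtraction
  tab$weight <- w
  alpha_bar <- sum(w * tab$alpha)
  beta_bar <- sum(w * tab$beta)
  delta <- tab$delta[1]
  structure(list(regimes = tab, alpha_bar = alpha_bar,
                 beta_bar = beta_bar, delta = delta,
                 transform = prior_variance_transform(
                   max(alpha_bar, 0), beta_bar, delta)),
            class = "bma_result")
}

#' @export
print.bma_result <- function(x, ...) {
  cat("<bma_result>", nrow(x$regimes), "regimes; alpha_bar =",
      format(x$alpha_bar, digits = 4), "beta_bar =",
      format(x$beta_bar, digits = 4), "\n")
  invisible(x)
}

#' Evidence-weighted envelope of the prior-variance transformation
#'
#' Weighted pointwise percentiles of `sigma2(ctilde) = beta * ctilde +
#' alpha` over the scored regimes, evaluated on an equidistant grid of
#' normalized structural connectivity values.
#'
#' @param bma A [bma_average()] result.
#' @param ctilde Evaluation points in `[0, 1]` (default 101 equidistant).
#' @param probs Lower/upper percentile (default 2.5 and 97.5).
#' @return Tibble with columns `ctilde`, `mean` (the averaged
#'   transformation), `lower`, `upper`.
#' @export
transform_envelope <- function(bma, ctilde = seq(0, 1, length.out = 101),
                               probs = c(0.025, 0.975)) {
  stopifnot(inherits(bma, "bma_result"))
  w <- bma$regimes$weight
  res <- lapply(ctilde, function(ct) {
    vals <- bma$regimes$beta * ct + bma$regimes$alpha
    q <- weighted_quantile(vals, w, probs)
    tibble::tibble(ctilde = ct,
                   mean = bma$beta_bar * ct + bma$alpha_bar,
                   lower = q[1], upper = q[2])
  })
  dplyr::bind_rows(res)
}

# Step-function weighted quantile (type-1 analogue).
weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]
  cw <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1]], numeric(1))
}
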