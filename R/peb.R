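#' Normalize a structural connectome
#'
#' Zeroes the diagonal (intraregional weights are not modeled by the
#' structural prior) and divides by the maximum off-diagonal weight, so
#' the result lies in `[0, 1]` with its strongest edge exactly 1.
#'
#' @param C Nonnegative symmetric matrix of structural connection
#'   weights.
#' @param tol Symmetry tolerance.
#' @return Normalized matrix with zero diagonal and max off-diagonal 1.
#' @export
normalize_structural <- function(C, tol = 1e-10) {
  C <- as.matrix(C)
  n <- nrow(C)
  stopifnot(ncol(C) == n)
  if (any(!is.finite(C))) stop("non-finite structural weights",
                               call. = FALSE)
  if (any(C < 0)) stop("structural weights must be nonnegative",
                       call. = FALSE)
  if (max(abs(C - t(C))) > tol * max(1, max(abs(C)))) {
    stop("structural connectivity must be symmetric", call. = FALSE)
  }
  off <- C * (1 - diag(n))
  m <- max(off)
  if (m <= 0) {
    stop("degenerate connectome: all off-diagonal weights are zero",
         call. = FALSE)
  }
  out <- off / m
  dimnames(out) <- dimnames(C)
  out
}

#' Prior-variance transformation hyperparameters
#'
#' The linear map from normalized structural connectivity to third-level
#' prior variance: `sigma2_ij = beta * ctilde_ij + alpha` for
#' interregional connections and `sigma2_ii = delta` for self
#' connections.
#'
#' @param alpha Baseline variance (must be >= 0).
#' @param beta Scaling of variance with structural connectivity
#'   (`alpha + beta >= 1e-5`).
#' @param delta Intraregional (self-connection) variance (> 0).
#' @export
prior_variance_transform <- function(alpha, beta, delta = 1 / 64) {
  if (!is.finite(alpha) || !is.finite(beta) || !is.finite(delta) ||
      alpha < 0 || alpha + beta < 1e-5 || delta <= 0) {
    stop("invalid transform: require alpha >= 0, alpha + beta >= 1e-5, ",
         "delta > 0", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, delta = delta),
            class = "prior_variance_transform")
}

#' Uninformed third-level transform
#'
#' The reference regime with no structural information:
#' `beta = 0, alpha = 1/2, delta = 1/64`.
#' @export
uninformed_transform <- function() {
  prior_variance_transform(alpha = 1 / 2, beta = 0, delta = 1 / 64)
}

#' Third-level prior over group effective connectivity
#'
#' Builds the diagonal covariance `Sigma3` over the vectorized
#' connectivity block from normalized structural connectivity and a
#' prior-variance transformation.  Variances of exactly zero are
#' permitted (`alpha = 0` with an absent edge): the connection is then
#' clamped to the prior mean and handled downstream through the
#' pseudo-inverse contract of Bayesian model reduction.
#'
#' @param Ctilde Normalized structural connectivity
#'   (see [normalize_structural()]).
#' @param transform A [prior_variance_transform()].
#' @param mean Prior mean over the block (default 0; self connections
#'   are parameterized on the log scale, so 0 maps to -1/2 Hz).
#' @return A [gaussian_density()] over the n^2 block in column-major
#'   order with names `A[i,j]`.
#' @export
build_prior_covariance <- function(Ctilde, transform, mean = 0) {
  stopifnot(inherits(transform, "prior_variance_transform"))
  n <- nrow(Ctilde)
  v <- transform$beta * Ctilde + transform$alpha
  diag(v) <- transform$delta
  if (any(v < 0)) {
    stop("invalid transform: negative prior variance implied",
         call. = FALSE)
  }
  layout <- dcm_layout(n)
  gaussian_density(rep_len(mean, n^2), as.numeric(v),
                   names = layout$names[layout$idx_A])
}

#' Stack subject posterior means into the group-level data vector
#'
#' Extracts the connectivity block of each subject posterior, vectorizes
#' column-major and stacks subject-major; the subject posterior
#' covariances over the block are retained for the later subject-level
#' Bayesian model reduction but are not part of the second-level
#' likelihood (the random-effects model treats the MAP means as data).
#'
#' @param posteriors List of [invert_dcm()] fits (or of
#'   [gaussian_density()] objects whose names contain the `A[i,j]`
#'   block).
#' @return Object of class `group_model`: `A1` (stacked vector), `means`
#'   (n^2 x S matrix), `covs` (list of block covariances), `S`, `n`,
#'   `a_names`.
#' @export
stack_subject_means <- function(posteriors) {
  qs <- lapply(posteriors, function(p) {
    if (inherits(p, "dcm_fit")) p$posterior else p
  })
  a_names <- grep("^A\\[", names(qs[[1]]$mean), value = TRUE)
  if (length(a_names) == 0) stop("no connectivity block found",
                                 call. = FALSE)
  for (q in qs) {
    if (!identical(grep("^A\\[", names(q$mean), value = TRUE), a_names)) {
      stop("misaligned subjects: connectivity blocks differ",
           call. = FALSE)
    }
  }
  means <- vapply(qs, function(q) q$mean[a_names],
                  numeric(length(a_names)))
  covs <- lapply(qs, function(q) q$cov[a_names, a_names, drop = FALSE])
  n <- as.integer(sqrt(length(a_names)))
  structure(list(A1 = as.numeric(means), means = means, covs = covs,
                 S = length(qs), n = n, a_names = a_names),
            class = "group_model")
}

#' Invert the group-level random-effects model
#'
#' Second/third level of the hierarchy: `A1 = (1 (x) I) A2 + e2` with
#' `e2 ~ N(0, exp(-gamma) * Q)`, `Q = I`, and third-level prior
#' `A2 ~ N(mu3, Sigma3)`.  Conditional on the random-effects
#' log-precision `gamma` the posterior over `A2` is conjugate and
#' closed-form; `gamma` itself is optimized by variational Laplace with
#' a Gaussian hyperprior.  Deterministic.
#'
#' @param model A [stack_subject_means()] result (requires `S >= 2`).
#' @param third_prior [gaussian_density()] over the n^2 block with
#'   diagonal covariance (from [build_prior_covariance()]).
#' @param gamma_prior Hyperprior on the log random-effects precision
#'   (list with `mean`, `var`).
#' @param fix_gamma Optional fixed value clamping the hyperparameter, in
#'   which case the returned free energy is the exact conditional log
#'   evidence.
#' @return Object of class `peb_fit`: `posterior` over A2,
#'   `gamma` (posterior mean and variance), `free_energy`,
#'   `log_marginal`, `third_prior`, `model`.
#' @export
invert_group <- function(model, third_prior = NULL,
                         gamma_prior = list(mean = 0, var = 9),
                         fix_gamma = NULL) {
  stopifnot(inherits(model, "group_model"))
  if (model$S < 2) {
    stop("insufficient replication: at least 2 subjects required",
         call. = FALSE)
  }
  if (is.null(third_prior)) {
    warning("no third-level prior supplied; this is unusual")
  }
  d <- nrow(model$means)
  stopifnot(length(third_prior$mean) == d)
  offdiag_cov <- third_prior$cov
  diag(offdiag_cov) <- 0
  if (max(abs(offdiag_cov)) > 0) {
    stop("third-level prior covariance must be diagonal", call. = FALSE)
  }
  w <- diag(third_prior$cov)
  mu3 <- third_prior$mean
  S <- model$S
  ybar <- rowMeans(model$means)
  ss <- rowSums((model$means - ybar)^2) # within-coordinate scatter

  log_marg <- function(gamma) {
    v <- exp(-gamma)
    # per coordinate: y_s = a2 + e, marginal N(mu3 * 1, v I + w 11')
    quad <- (ss + S * (ybar - mu3)^2 * v / (v + S * w)) / v
    -0.5 * sum(S * log(2 * pi) + (S - 1) * log(v) + log(v + S * w) +
                 quad)
  }
  if (is.null(fix_gamma)) {
    obj <- function(g) {
      log_marg(g) + stats::dnorm(g, gamma_prior$mean,
                                 sqrt(gamma_prior$var), log = TRUE)
    }
    opt <- stats::optimize(obj, interval = c(-12, 12), maximum = TRUE,
                           tol = 1e-8)
    g_star <- opt$maximum
    h <- 1e-4
    curv <- (obj(g_star + h) - 2 * opt$objective + obj(g_star - h)) / h^2
    vq <- if (is.finite(curv) && curv < 0) -1 / curv else gamma_prior$var
    lm_star <- log_marg(g_star)
    f2 <- obj(g_star) + 0.5 * log(2 * pi * vq)
  } else {
    g_star <- fix_gamma
    vq <- 0
    lm_star <- log_marg(g_star)
    f2 <- lm_star
  }
  v <- exp(-g_star)
  prec <- S / v + ifelse(w > 0, 1 / w, Inf)
  post_var <- 1 / prec
  post_mean <- ifelse(w > 0,
                      (S * ybar / v + mu3 / w) * post_var,
                      mu3)
  posterior <- gaussian_density(post_mean, post_var,
                                names = model$a_names)
  structure(list(posterior = posterior,
                 gamma = list(mean = g_star, var = vq),
                 free_energy = f2, log_marginal = lm_star,
                 third_prior = third_prior, model = model),
            class = "peb_fit")
}

#' @export
print.peb_fit <- function(x, ...) {
  cat("<peb_fit>", x$model$S, "subjects,", x$model$n,
      "regions; F(2) =", format(x$free_energy), "\n")
  invisible(x)
}
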