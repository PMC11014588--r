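#' Analytic Bayesian model reduction of a Gaussian posterior
#'
#' Given a model inverted under a full prior, computes the posterior and
#' free-energy change that would have been obtained under an alternative
#' (reduced) prior with the same likelihood, in closed form:
#' reduced posterior precision `P_q + P0_red - P0_full`, the
#' corresponding precision-weighted mean, and the log-evidence change
#' from the determinant and quadratic terms of the Gaussian integrals.
#' Precisions are computed by symmetric pseudo-inverse with rank
#' bookkeeping, so exact-zero prior variances (clamped parameters) are
#' supported; log-determinants are restricted to the common support.
#' The routine is level-agnostic: the identical code path serves
#' group-level regime scoring and subject-level empirical-prior updates.
#'
#' @param full_prior,full_posterior,reduced_prior [gaussian_density()]
#'   objects of the same dimension (and naming, if named).
#' @param full_free_energy Free energy of the full model (default 0, in
#'   which case `reduced_free_energy` is the change alone).
#' @return Object of class `bmr_result`: `reduced_posterior`,
#'   `delta_free_energy` (reduced minus full, nats),
#'   `reduced_free_energy`.
#' @export
bmr_gaussian <- function(full_prior, full_posterior, reduced_prior,
                         full_free_energy = 0) {
  d <- length(full_prior$mean)
  if (length(full_posterior$mean) != d || length(reduced_prior$mean) != d) {
    stop("density dimensions differ", call. = FALSE)
  }
  nm <- names(full_prior$mean)
  if (!is.null(nm) && !is.null(names(reduced_prior$mean)) &&
      !identical(nm, names(reduced_prior$mean))) {
    stop("misaligned parameters: prior names differ", call. = FALSE)
  }
  if (identical(full_prior$mean, reduced_prior$mean) &&
      identical(full_prior$cov, reduced_prior$cov)) {
    # identity reduction: nothing changes, exactly
    return(structure(list(reduced_posterior = full_posterior,
                          delta_free_energy = 0,
                          reduced_free_energy = full_free_energy),
                     class = "bmr_result"))
  }
  P0 <- sym_pinv(full_prior$cov)
  Pq <- sym_pinv(full_posterior$cov)
  # exact-zero reduced prior variances clamp a parameter to its reduced
  # prior mean; realize the clamp as a near-dogmatic precision so the
  # closed-form limit is taken numerically (the log-determinant terms
  # cancel in the limit)
  rc <- reduced_prior$cov
  clamp <- diag(rc) <= 0
  if (any(clamp)) diag(rc)[clamp] <- 1e-10
  Pr <- sym_pinv(rc)
  Ps <- Pq + Pr - P0
  ev <- eigen((Ps + t(Ps)) / 2, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-10 * max(abs(ev), 1)
  if (min(ev) < -tol) {
    stop("improper reduction: reduced posterior precision has negative ",
         "eigenvalue ", format(min(ev)), call. = FALSE)
  }
  Ss <- sym_pinv(Ps)
  mu_s <- Ss %*% (Pq %*% full_posterior$mean + Pr %*% reduced_prior$mean -
                    P0 %*% full_prior$mean)
  mu_s <- as.numeric(mu_s)
  ld <- function(p) -attr(p, "logdet") # logdet of the precision
  ld_Ps <- attr(Ss, "logdet")          # logdet(Ps) on its support
  dF <- 0.5 * (ld(Pr) + ld(Pq) - ld(P0) - ld_Ps) -
    0.5 * (sum(reduced_prior$mean * (Pr %*% reduced_prior$mean)) -
             sum(full_prior$mean * (P0 %*% full_prior$mean)) +
             sum(full_posterior$mean * (Pq %*% full_posterior$mean)) -
             sum(mu_s * (Ps %*% mu_s)))
  structure(list(
    reduced_posterior = gaussian_density(mu_s, unclass(Ss), names = nm),
    delta_free_energy = as.numeric(dF),
    reduced_free_energy = as.numeric(full_free_energy + dF)
  ), class = "bmr_result")
}

#' Log-Bayes factor between two models
#'
#' The difference of (free-energy approximated) log evidences,
#' `ln BF = F1 - F2`.  By convention a value of
#' [STRONG_EVIDENCE_LNBF] (= 3 nats, about a 20-fold evidence ratio) or
#' more is considered strong evidence for the first model; the threshold
#' is documentation, not enforcement.
#'
#' @param F1,F2 Finite free energies (nats).
#' @export
log_bayes_factor <- function(F1, F2) {
  stopifnot(is.finite(F1), is.finite(F2))
  F1 - F2
}

#' @rdname log_bayes_factor
#' @export
STRONG_EVIDENCE_LNBF <- 3

#' Propagate a group posterior downward to the subjects
#'
#' For each subject, the group-level posterior over the connectivity
#' block acts as an empirical (reduced) prior replacing the subject's
#' original prior on that block; non-connectivity parameters keep their
#' original prior.  The update is a single Bayesian model reduction per
#' subject, returning the re-evaluated posterior and free energy.
#'
#' @param subject_priors List of [gaussian_density()] priors (or a
#'   single [dcm_priors()] applied to every subject).
#' @param subject_posteriors List of [invert_dcm()] fits or
#'   [gaussian_density()] posteriors.
#' @param group_posterior [gaussian_density()] over the `A[i,j]` block.
#' @return List (one element per subject) of `bmr_result` objects.
#' @export
update_subjects <- function(subject_priors, subject_posteriors,
                            group_posterior) {
  if (inherits(subject_priors, "dcm_priors")) {
    subject_priors <- rep(list(subject_priors$prior),
                          length(subject_posteriors))
  }
  g_names <- names(group_posterior$mean)
  lapply(seq_along(subject_posteriors), function(s) {
    post <- subject_posteriors[[s]]
    f0 <- 0
    if (inherits(post, "dcm_fit")) {
      f0 <- post$free_energy
      post <- post$posterior
    }
    prior <- subject_priors[[s]]
    nm <- names(prior$mean)
    idx <- match(g_names, nm)
    if (anyNA(idx)) {
      stop("misaligned parameters: group posterior block not found in ",
           "subject ", s, call. = FALSE)
    }
    red <- prior
    red$mean[idx] <- group_posterior$mean
    red$cov[idx, ] <- 0
    red$cov[, idx] <- 0
    red$cov[idx, idx] <- group_posterior$cov
    red <- gaussian_density(red$mean, red$cov, names = nm)
    bmr_gaussian(prior, post, red, full_free_energy = f0)
  })
}
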