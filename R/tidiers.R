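#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a subject-level DCM fit
#'
#' One row per parameter: posterior mean, posterior standard deviation
#' and block label.
#'
#' @param x A [invert_dcm()] result.
#' @param ... Unused.
#' @export
tidy.dcm_fit <- function(x, ...) {
  nm <- names(x$posterior$mean)
  block <- dplyr::case_when(
    grepl("^A\\[(\\d+),\\1\\]$", nm) ~ "self",
    grepl("^A\\[", nm) ~ "connection",
    grepl("^(decay|transit)", nm) ~ "hemodynamic",
    .default = "noise"
  )
  tibble::tibble(term = nm, estimate = unname(x$posterior$mean),
                 std_error = sqrt(diag(x$posterior$cov)),
                 block = block)
}

#' @rdname tidy.dcm_fit
#' @export
glance.dcm_fit <- function(x, ...) {
  tibble::tibble(free_energy = x$free_energy,
                 iterations = x$iterations, converged = x$converged,
                 log_precision = x$lambda$mean)
}

#' Tidy a group-level random-effects fit
#'
#' @param x A [invert_group()] result.
#' @param ... Unused.
#' @export
tidy.peb_fit <- function(x, ...) {
  nm <- names(x$posterior$mean)
  tibble::tibble(term = nm, estimate = unname(x$posterior$mean),
                 std_error = sqrt(diag(x$posterior$cov)))
}

#' @rdname tidy.peb_fit
#' @export
glance.peb_fit <- function(x, ...) {
  tibble::tibble(free_energy = x$free_energy,
                 log_marginal = x$log_marginal,
                 gamma = x$gamma$mean, subjects = x$model$S)
}

#' Tidy a Bayesian model-averaging result
#'
#' One row per regime with its free energy and softmax weight.
#'
#' @param x A [bma_average()] result.
#' @param ... Unused.
#' @export
tidy.bma_result <- function(x, ...) x$regimes

#' @rdname tidy.bma_result
#' @export
glance.bma_result <- function(x, ...) {
  tibble::tibble(alpha_bar = x$alpha_bar, beta_bar = x$beta_bar,
                 delta = x$delta, n_regimes = nrow(x$regimes))
}

#' Tidy an in-silico experiment report
#'
#' @param x A [run_insilico()] result.
#' @param ... Unused.
#' @export
tidy.heb_insilico <- function(x, ...) x$per_instantiation

#' @rdname tidy.heb_insilico
#' @export
glance.heb_insilico <- function(x, ...) {
  h <- x$pooled[x$pooled$method == "heb", ]
  m <- x$pooled[x$pooled$method == "mvar", ]
  tibble::tibble(
    pooled_r = h$pearson_r, pooled_rmse = h$rmse,
    pooled_r_mvar = m$pearson_r, pooled_rmse_mvar = m$rmse,
    prop_lnbf_strong = mean(x$per_instantiation$log_bf >
                              STRONG_EVIDENCE_LNBF),
    prop_envelope_covers = mean(x$per_instantiation$
                                  envelope_covers_truth),
    median_beta_bar = stats::median(x$per_instantiation$beta_bar),
    instantiations = nrow(x$per_instantiation)
  )
}
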