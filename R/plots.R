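#' Parity plot of group-level recovery
#'
#' Scatter of pooled MAP group effective connectivity estimates against
#' ground truth, for the hierarchical model and the masked MVAR
#' baseline, with the identity line.
#'
#' @param object A [run_insilico()] result.
#' @param ... Unused.
#' @export
autoplot.heb_insilico <- function(object, ...) {
  pts <- object$pooled_points
  df <- dplyr::bind_rows(
    tibble::tibble(truth = pts$truth, estimate = pts$heb,
                   method = "hierarchical empirical Bayes"),
    tibble::tibble(truth = pts$truth, estimate = pts$mvar,
                   method = "masked MVAR")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$truth,
                                   y = .data$estimate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = "true group effective connectivity (Hz)",
                  y = "estimated") +
    ggplot2::theme_minimal()
}

#' Evidence-weighted prior-variance transformation with envelope
#'
#' @param object A [bma_average()] result.
#' @param truth Optional true transform (list with `alpha`, `beta`) to
#'   overlay as a dashed line.
#' @param ... Unused.
#' @export
autoplot.bma_result <- function(object, truth = NULL, ...) {
  env <- transform_envelope(object)
  p <- ggplot2::ggplot(env, ggplot2::aes(x = .data$ctilde)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         fill = "seagreen", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean),
                       colour = "seagreen4") +
    ggplot2::labs(x = "normalized structural connectivity",
                  y = "prior variance of group effective connectivity") +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_abline(slope = truth$beta,
                                  intercept = truth$alpha,
                                  linetype = 2)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
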