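#' Parity metrics between estimated and true connectivity
#'
#' Pearson product-moment correlation and root mean squared error over
#' the scoped entries.  Self-connections use a different
#' parameterization and prior, so the default scope is the off-diagonal
#' entries only.
#'
#' @param estimate,truth Numeric matrices of equal dimension (or equal
#'   length vectors).
#' @param scope `"offdiag"` (default) or `"all"`.
#' @return One-row tibble: `pearson_r`, `rmse`, `n_points`, `scope`.
#' @export
parity_metrics <- function(estimate, truth,
                           scope = c("offdiag", "all")) {
  scope <- match.arg(scope)
  estimate <- as.matrix(estimate)
  truth <- as.matrix(truth)
  stopifnot(all(dim(estimate) == dim(truth)))
  if (scope == "offdiag" && nrow(estimate) == ncol(estimate)) {
    keep <- !diag(nrow = nrow(estimate))
    e <- estimate[keep]
    t_ <- truth[keep]
  } else {
    e <- as.numeric(estimate)
    t_ <- as.numeric(truth)
  }
  if (stats::sd(e) == 0 || stats::sd(t_) == 0) {
    stop("undefined correlation: zero-variance input", call. = FALSE)
  }
  tibble::tibble(pearson_r = stats::cor(e, t_),
                 rmse = sqrt(mean((e - t_)^2)),
                 n_points = length(e), scope = scope)
}

#' Macro F1 for sign classification of connections
#'
#' Entries are classified as positive, negative, or absent: the
#' estimate uses `|x| < zero_threshold` for absence, the truth uses
#' exact zeros.  The macro F1 is the unweighted mean of the three
#' per-class F1 scores, with an empty or never-predicted class scoring
#' zero.
#'
#' @param estimate,truth Numeric matrices (off-diagonal entries scored).
#' @param zero_threshold Absolute magnitude (Hz) below which an
#'   estimated connection is called absent (default 0.05).
#' @return List with `macro_f1`, `per_class` (tibble of precision,
#'   recall, f1 per class), `threshold`.
#' @export
sign_macro_f1 <- function(estimate, truth, zero_threshold = 0.05) {
  stopifnot(zero_threshold >= 0)
  estimate <- as.matrix(estimate)
  truth <- as.matrix(truth)
  stopifnot(all(dim(estimate) == dim(truth)))
  keep <- if (nrow(estimate) == ncol(estimate))
    !diag(nrow = nrow(estimate)) else
      matrix(TRUE, nrow(estimate), ncol(estimate))
  classify <- function(x, thr) {
    ifelse(abs(x) < thr | x == 0, "absent",
           ifelse(x > 0, "positive", "negative"))
  }
  pred <- classify(estimate[keep], zero_threshold)
  tru <- classify(truth[keep], 0)
  classes <- c("positive", "negative", "absent")
  per <- lapply(classes, function(cl) {
    tp <- sum(pred == cl & tru == cl)
    fp <- sum(pred == cl & tru != cl)
    fn <- sum(pred != cl & tru == cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    tibble::tibble(class = cl, precision = prec, recall = rec, f1 = f1)
  })
  per <- dplyr::bind_rows(per)
  list(macro_f1 = mean(per$f1), per_class = per,
       threshold = zero_threshold)
}
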