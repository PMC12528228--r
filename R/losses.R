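#' Binary cross-entropy over a multi-label batch
#'
#' Mean over all `n x C` entries of `-(y log p + (1-y) log(1-p))`, with
#' probabilities clipped to `[eps, 1-eps]` before the logs.
#'
#' @param y Binary matrix `(n, C)` of targets.
#' @param yhat Probability matrix `(n, C)`.
#' @param eps Clipping constant.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(y, yhat, eps = 1e-7) {
  check_pair(y, yhat)
  p <- pmin(pmax(yhat, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Double soft F1-loss
#'
#' A differentiable macro-F1 surrogate built from soft counts per class j
#' over the batch: `tp = sum p y`, `fp = sum p (1-y)` and a false-negative
#' term that exists in two forms.  The `"corrected"` default uses the
#' standard soft false-negative count `fn = sum (1-p) y`, under which a
#' perfect prediction drives the loss to zero.  The `"verbatim"` variant
#' uses `fn = sum (1-p)(1-y)` (a soft true-negative count) and is retained
#' for fidelity comparisons.  Each class contributes
#' `1 - 2 tp / (2 tp + fp + fn + 1e-16)`; classes are averaged unweighted.
#'
#' @param y Binary matrix `(n, C)`.
#' @param yhat Probability matrix `(n, C)` with entries in `[0, 1]`.
#' @param variant `"corrected"` or `"verbatim"`.
#' @return Scalar in `[0, 1]`.
#' @export
double_soft_f1_loss <- function(y, yhat,
                                variant = c("corrected", "verbatim")) {
  variant <- match.arg(variant)
  check_pair(y, yhat)
  if (any(yhat < 0 | yhat > 1)) stop("yhat entries must lie in [0, 1]")
  tp <- colSums(yhat * y)
  fp <- colSums(yhat * (1 - y))
  fn <- if (variant == "corrected") colSums((1 - yhat) * y)
        else colSums((1 - yhat) * (1 - y))
  mean(1 - 2 * tp / (2 * tp + fp + fn + 1e-16))
}

# Analytic gradients of the two losses with respect to yhat, on the
# internal (C, batch) orientation used by the training loop.
bce_grad <- function(Y, P, eps = 1e-7) {
  Pc <- pmin(pmax(P, eps), 1 - eps)
  ((1 - Y) / (1 - Pc) - Y / Pc) / length(Y)
}

dsf1_grad <- function(Y, P, variant = "corrected") {
  C <- nrow(Y)
  tp <- rowSums(P * Y)
  if (variant == "corrected") {
    D <- rowSums(P) + rowSums(Y) + 1e-16
    (2 * tp - 2 * Y * D) / D^2 / C
  } else {
    D <- 2 * tp + rowSums(P * (1 - Y)) + rowSums((1 - P) * (1 - Y)) + 1e-16
    -2 * Y * (D - 2 * tp) / D^2 / C
  }
}

#' Class-averaged multi-label accuracy
#'
#' For each class, the fraction of records whose thresholded prediction
#' matches the label; the per-class accuracies are then averaged
#' unweighted.
#'
#' @param y Binary matrix `(n_s, n_c)`.
#' @param yhat_bin Binary matrix of thresholded predictions, same shape.
#' @return Scalar in `[0, 1]`.
#' @export
average_accuracy <- function(y, yhat_bin) {
  check_pair(y, yhat_bin)
  mean(colMeans(y == yhat_bin))
}

#' Macro F1-score
#'
#' Per-class F1 `2tp / (2tp + fp + fn)` averaged unweighted over classes.
#' Classes with no positives in either labels or predictions have an
#' undefined F1 and are excluded from the average (`micro = TRUE` instead
#' pools counts over all classes first).
#'
#' @param y Binary matrix `(n, C)`.
#' @param yhat_bin Binary prediction matrix, same shape.
#' @param micro Pool counts across classes instead of macro-averaging.
#' @return Scalar in `[0, 1]`.
#' @export
f1_macro <- function(y, yhat_bin, micro = FALSE) {
  check_pair(y, yhat_bin)
  tp <- colSums(y * yhat_bin)
  fp <- colSums((1 - y) * yhat_bin)
  fn <- colSums(y * (1 - yhat_bin))
  if (micro) return(2 * sum(tp) / (2 * sum(tp) + sum(fp) + sum(fn)))
  denom <- 2 * tp + fp + fn
  ok <- denom > 0
  if (!any(ok)) return(NA_real_)
  mean(2 * tp[ok] / denom[ok])
}

# Rank-based (Mann-Whitney) AUROC for one class, with midranks for ties.
auroc_one <- function(y, score) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro AUROC
#'
#' Unweighted mean of per-class ROC areas computed by the rank statistic.
#' Classes without both a positive and a negative example are skipped; if
#' every class is degenerate an error is raised.
#'
#' @param y Binary matrix `(n, C)`.
#' @param yhat Probability (or score) matrix, same shape.
#' @return Scalar in `[0, 1]`.
#' @export
auroc_macro <- function(y, yhat) {
  check_pair(y, yhat)
  per <- vapply(seq_len(ncol(y)),
                function(j) auroc_one(y[, j], yhat[, j]), numeric(1))
  if (all(is.na(per)))
    stop("AUROC undefined: every class lacks a positive or a negative")
  mean(per, na.rm = TRUE)
}

#' Full metrics report for a set of predictions
#'
#' @param y Binary label matrix `(n, C)`.
#' @param probs Probability matrix `(n, C)`.
#' @param threshold Binarization threshold for accuracy and F1.
#' @return List of class `"metrics_report"` with `accuracy`, `f1_macro`,
#'   `auroc_macro` and a `per_class` data frame.
#' @export
evaluate_predictions <- function(y, probs, threshold = 0.5) {
  check_pair(y, probs)
  bin <- (probs >= threshold) * 1
  per_acc <- colMeans(y == bin)
  tp <- colSums(y * bin); fp <- colSums((1 - y) * bin)
  fn <- colSums(y * (1 - bin))
  denom <- 2 * tp + fp + fn
  per_f1 <- ifelse(denom > 0, 2 * tp / denom, NA_real_)
  per_auc <- vapply(seq_len(ncol(y)),
                    function(j) auroc_one(y[, j], probs[, j]), numeric(1))
  rep <- list(accuracy = mean(per_acc),
              f1_macro = mean(per_f1, na.rm = TRUE),
              f1_micro = f1_macro(y, bin, micro = TRUE),
              auroc_macro = if (all(is.na(per_auc))) NA_real_
                            else mean(per_auc, na.rm = TRUE),
              per_class = data.frame(class = seq_len(ncol(y)),
                                     accuracy = per_acc, f1 = per_f1,
                                     auroc = per_auc),
              threshold = threshold, n = nrow(y))
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "metrics (n=%d): accuracy %.4f | macro F1 %.4f | macro AUROC %.4f\n",
    x$n, x$accuracy, x$f1_macro, x$auroc_macro))
  invisible(x)
}

check_pair <- function(y, yhat) {
  if (!is.matrix(y)) y <- as.matrix(y)
  if (!is.matrix(yhat)) yhat <- as.matrix(yhat)
  if (!all(dim(y) == dim(yhat)))
    stop("y and yhat must have identical dimensions (",
         paste(dim(y), collapse = "x"), " vs ",
         paste(dim(yhat), collapse = "x"), ")")
  invisible(TRUE)
}
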