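# LIME-style surrogate explanations for the ECG classifier.
#
# Interpretable features are contiguous time segments per lead.  A
# perturbation masks a random subset of segments (replacing them with a
# reference mean), the model's probability for the class of interest is
# collected over all perturbations, and a distance-weighted ridge
# regression on the mask indicators yields one coefficient per segment.
# Broadcasting coefficients back over samples gives a saliency map shaped
# like the input.

#' Partition each lead's time axis into near-equal segments
#'
#' @param length Number of samples per lead.
#' @param n_segments_per_lead Number of contiguous segments (>= 1,
#'   <= length).
#' @return List with `seg_of` (integer vector mapping sample -> segment),
#'   `starts`, `ends`, and `n_segments`.
#' @export
segment_ecg <- function(length, n_segments_per_lead) {
  stopifnot(n_segments_per_lead >= 1, n_segments_per_lead <= length)
  bounds <- floor(seq(0, length, length.out = n_segments_per_lead + 1))
  starts <- bounds[-(n_segments_per_lead + 1)] + 1L
  ends <- bounds[-1]
  seg_of <- rep.int(seq_len(n_segments_per_lead), ends - starts + 1L)
  list(seg_of = as.integer(seg_of), starts = as.integer(starts),
       ends = as.integer(ends),
       n_segments = as.integer(n_segments_per_lead))
}

#' Fit a per-class LIME context from the training folds
#'
#' Samples, with replacement, `n_pos` records annotated with the class of
#' interest and `n_neg` records annotated otherwise, and estimates the
#' perturbation statistics reused by every explanation of that class: the
#' per-(lead, segment) reference means that masked segments are replaced
#' with, and the distance-kernel width.
#'
#' @param model The trained `"ecg_model"`.
#' @param x Training-fold signal array `(n, l, 12)`.
#' @param y Training-fold label matrix.
#' @param class_idx Class to explain (1-based column of `y`).
#' @param n_pos,n_neg Number of draws with replacement from the positive /
#'   non-positive pools.
#' @param n_segments Segments per lead.
#' @param kernel_width Width of the exponential distance kernel; default
#'   `0.75 * sqrt(n_features)`.
#' @param seed Integer seed.
#' @return List of class `"lime_context"`, or `NULL` (with a warning) if
#'   the class has no positive example.
#' @export
fit_class_lime <- function(model, x, y, class_idx, n_pos = 1000L,
                           n_neg = 1000L, n_segments = 20L,
                           kernel_width = NULL, seed = 1L) {
  pos <- which(y[, class_idx] == 1)
  neg <- which(y[, class_idx] == 0)
  if (!length(pos)) {
    warning("class ", class_idx, " has no positive example; skipped")
    return(NULL)
  }
  l <- dim(x)[2]
  seg <- segment_ecg(l, n_segments)
  n_features <- 12L * seg$n_segments
  if (is.null(kernel_width)) kernel_width <- 0.75 * sqrt(n_features)
  idx <- with_seed(seed, c(pos[sample.int(length(pos), n_pos,
                                          replace = TRUE)],
                           if (length(neg))
                             neg[sample.int(length(neg), n_neg,
                                            replace = TRUE)]))
  # reference value per (segment, lead): mean over sampled records and
  # over the samples inside the segment
  ref <- matrix(NA_real_, seg$n_segments, 12L)
  for (lead in seq_len(12L)) {
    cm <- colMeans(x[idx, , lead, drop = FALSE][, , 1])
    for (s in seq_len(seg$n_segments))
      ref[s, lead] <- mean(cm[seg$starts[s]:seg$ends[s]])
  }
  structure(list(class_idx = as.integer(class_idx), segmentation = seg,
                 ref_means = ref, kernel_width = kernel_width,
                 n_sampled = length(idx), sampled_idx = idx),
            class = "lime_context")
}

#' Explain one ECG for one class
#'
#' Draws `n_perturb` random segment-masking patterns (each segment kept
#' independently with probability 1/2), replaces masked segments with the
#' reference mean (from `context`, or the instance's own segment means when
#' no context is given), queries the model's probability for `class_idx`,
#' and fits a distance-weighted ridge regression of those probabilities on
#' the mask indicators.  Each segment's coefficient is broadcast over its
#' samples.
#'
#' @param model The trained `"ecg_model"`, or any function mapping an
#'   array `(n, l, 12)` to a probability matrix `(n, C)`.
#' @param ecg Matrix `(l, 12)`, one record in dataset orientation.
#' @param class_idx Class to explain.
#' @param n_perturb Number of masking patterns.
#' @param seed Integer seed; same seed, same map.
#' @param context Optional `"lime_context"` from [fit_class_lime()].
#' @param n_segments Segments per lead when no context is supplied.
#' @param ridge Ridge penalty of the surrogate fit.
#' @return Matrix `(l, 12)` of attribution scores, with attributes `"r2"`
#'   (weighted surrogate fit quality, flagged by a warning when < 0.1) and
#'   `"coefficients"` (`n_segments x 12`).
#' @export
explain_instance <- function(model, ecg, class_idx, n_perturb = 1000L,
                             seed = 1L, context = NULL, n_segments = 20L,
                             ridge = 1e-3) {
  pf <- if (is.function(model)) model
        else function(xx) predict_proba(model, xx)
  if (inherits(model, "ecg_model"))
    stopifnot(class_idx >= 1, class_idx <= model$cfg$n_classes)
  l <- nrow(ecg)
  if (!is.null(context)) {
    seg <- context$segmentation
    ref <- context$ref_means
    kw <- context$kernel_width
  } else {
    seg <- segment_ecg(l, n_segments)
    ref <- matrix(NA_real_, seg$n_segments, 12L)
    for (s in seq_len(seg$n_segments))
      ref[s, ] <- colMeans(ecg[seg$starts[s]:seg$ends[s], , drop = FALSE])
    kw <- 0.75 * sqrt(12 * seg$n_segments)
  }
  nf <- 12L * seg$n_segments
  masks <- with_seed(seed,
    matrix(stats::rbinom(n_perturb * nf, 1L, 0.5), n_perturb, nf))
  masks <- rbind(rep(1L, nf), masks)       # the unperturbed instance
  # feature f = (lead - 1) * n_segments + segment
  xs <- array(rep(ecg, n_perturb + 1L), c(l, 12L, n_perturb + 1L))
  for (p in seq_len(n_perturb) + 1L) {
    off <- which(masks[p, ] == 0L)
    for (f in off) {
      lead <- (f - 1L) %/% seg$n_segments + 1L
      s <- (f - 1L) %% seg$n_segments + 1L
      xs[seg$starts[s]:seg$ends[s], lead, p] <- ref[s, lead]
    }
  }
  probs <- pf(aperm(xs, c(3, 1, 2)))[, class_idx]
  if (stats::sd(probs) < 1e-12) {
    warning("model output is constant over all perturbations; ",
            "returning a zero saliency map")
    out <- matrix(0, l, 12L)
    attr(out, "r2") <- 0
    attr(out, "coefficients") <- matrix(0, seg$n_segments, 12L)
    return(out)
  }
  d2 <- rowSums(masks == 0L)               # squared distance to instance
  w <- exp(-d2 / kw^2)
  Z <- cbind(1, masks)
  A <- crossprod(Z * w, Z) + diag(c(0, rep(ridge, nf)))
  beta <- solve(A, crossprod(Z * w, probs))
  fit <- as.numeric(Z %*% beta)
  r2 <- 1 - sum(w * (probs - fit)^2) /
            sum(w * (probs - stats::weighted.mean(probs, w))^2)
  if (is.finite(r2) && r2 < 0.1)
    warning(sprintf("surrogate fit is poor (weighted R^2 = %.3f)", r2))
  coefs <- matrix(beta[-1], seg$n_segments, 12L)
  out <- coefs[seg$seg_of, , drop = FALSE]
  attr(out, "r2") <- r2
  attr(out, "coefficients") <- coefs
  out
}

#' Aggregate per-record explanations into a class-by-lead importance matrix
#'
#' For each class with a fitted context, every validation record annotated
#' with that class is explained; a record's per-lead total activation is
#' the sum over samples of the absolute attribution, and the matrix entry
#' (class, lead) is the mean (or `statistic`) of those totals over
#' records.  Classes without a context or without validation positives get
#' a row of `NA` and are flagged.
#'
#' @param model The trained `"ecg_model"`.
#' @param x_val,y_val Validation-fold signals and labels.
#' @param contexts List of `"lime_context"` (or `NULL`) per class, as from
#'   [fit_class_lime()].
#' @param n_perturb Perturbations per explained record.
#' @param max_records Cap on explained records per class (sampled,
#'   seeded); `Inf` explains all annotated records.
#' @param statistic Reducer across records: `"mean"`, `"sum"` or
#'   `"median"`.
#' @param signed Use signed attributions instead of absolute values.
#' @param normalize Divide each row by its maximum (display aid; leaves
#'   the per-row argmax unchanged).
#' @param seed Integer seed.
#' @return List of class `"lead_importance"`: `importance`
#'   (`n_classes x 12`), `n_explained` per class, `flagged` classes.
#' @export
aggregate_lead_importance <- function(model, x_val, y_val, contexts,
                                      n_perturb = 1000L,
                                      max_records = Inf,
                                      statistic = c("mean", "sum",
                                                    "median"),
                                      signed = FALSE, normalize = FALSE,
                                      seed = 1L) {
  statistic <- match.arg(statistic)
  reducer <- switch(statistic, mean = colMeans,
                    sum = colSums,
                    median = function(m) apply(m, 2, stats::median))
  C <- length(contexts)
  imp <- matrix(NA_real_, C, 12L,
                dimnames = list(NULL, LEAD_NAMES))
  n_explained <- integer(C)
  for (cl in seq_len(C)) {
    ctx <- contexts[[cl]]
    if (is.null(ctx)) next
    idx <- which(y_val[, cl] == 1)
    if (!length(idx)) next
    if (length(idx) > max_records)
      idx <- with_seed(seed + cl,
                       sort(sample(idx, max_records)))
    totals <- matrix(NA_real_, length(idx), 12L)
    for (j in seq_along(idx)) {
      # one mask set per class, shared by all its records: the aggregate
      # is then exactly invariant to record ordering
      map <- explain_instance(model, x_val[idx[j], , ], cl,
                              n_perturb = n_perturb,
                              seed = seed + 1000L * cl,
                              context = ctx)
      a <- if (signed) map else abs(map)
      totals[j, ] <- colSums(a)
    }
    imp[cl, ] <- reducer(totals)
    n_explained[cl] <- length(idx)
  }
  flagged <- which(n_explained == 0)
  if (normalize) {
    mx <- apply(imp, 1, max)
    imp <- imp / ifelse(is.na(mx) | mx == 0, 1, mx)
  }
  structure(list(importance = imp, n_explained = n_explained,
                 flagged = flagged, statistic = statistic,
                 normalized = normalize),
            class = "lead_importance")
}

#' Heatmap of the class-by-lead importance matrix
#'
#' @param li A `"lead_importance"`.
#' @param class_names Optional row labels (e.g. catalog condition names).
#' @return A ggplot object.
#' @export
plot_lead_importance <- function(li, class_names = NULL) {
  imp <- li$importance
  C <- nrow(imp)
  if (is.null(class_names)) class_names <- paste("class", seq_len(C))
  df <- data.frame(
    condition = factor(rep(class_names, 12L),
                       levels = rev(class_names)),
    lead = factor(rep(LEAD_NAMES, each = C), levels = LEAD_NAMES),
    importance = as.vector(imp))
  ggplot2::ggplot(df, ggplot2::aes(x = lead, y = condition,
                                   fill = importance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::labs(x = "ECG lead", y = NULL,
                  fill = if (li$normalized) "importance\n(row-max = 1)"
                         else "importance") +
    ggplot2::theme_minimal()
}
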