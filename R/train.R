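#' Training configuration
#'
#' The fixed recipe: 15 epochs, batch size 30, Adam with learning rate
#' 0.001.  No early stopping, no schedule, no checkpoint selection.
#'
#' @param epochs,batch_size,lr Positive recipe constants.
#' @param loss `"double_soft_f1"` or `"bce"`.
#' @param loss_variant Variant of the soft F1-loss (see
#'   [double_soft_f1_loss()]).
#' @param target_fs Sampling frequency the dataset was built at (metadata).
#' @param seed Seed governing weight initialisation and batch shuffling.
#' @param augment An [augment_config()]; augmentation defaults off.
#' @param verbose Print per-epoch loss.
#' @return List of class `"train_config"`.
#' @export
train_config <- function(epochs = 15L, batch_size = 30L, lr = 0.001,
                         loss = c("double_soft_f1", "bce"),
                         loss_variant = "corrected",
                         target_fs = NA_real_, seed = 1L,
                         augment = augment_config(), verbose = FALSE) {
  loss <- match.arg(loss)
  stopifnot(epochs > 0, batch_size > 0, lr > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 loss = loss, loss_variant = loss_variant,
                 target_fs = target_fs, seed = as.integer(seed),
                 augment = augment, verbose = verbose),
            class = "train_config")
}

#' Iterative multi-label stratified k-fold assignment
#'
#' Greedy iterative stratification: labels are processed from rarest to
#' most frequent; each record carrying the current label goes to the fold
#' with the greatest remaining demand for that label, ties broken by
#' remaining fold capacity and then at random (seeded).  Records with no
#' positive labels are spread by capacity.  Deterministic given `seed`.
#'
#' @param labels Binary matrix `(n, C)`.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return List of class `"fold_assignment"` with `fold_of` (integer in
#'   `1..k` per record), `k`, and `class_counts` (`C x k` positives table).
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L) {
  labels <- as.matrix(labels)
  n <- nrow(labels)
  if (n < k) stop("need at least k records")
  C <- ncol(labels)
  rare <- colSums(labels)
  if (any(rare > 0 & rare < k))
    warning("class(es) ", paste(which(rare > 0 & rare < k), collapse = ","),
            " have fewer than ", k, " positives; balance is best-effort")
  fold_of <- with_seed(seed, {
    fold_of <- integer(n)
    capacity <- rep(n / k, k)
    demand <- outer(colSums(labels), rep(1 / k, k))   # (C, k)
    unassigned <- rep(TRUE, n)
    repeat {
      remaining <- colSums(labels[unassigned, , drop = FALSE])
      if (all(remaining == 0)) break
      lbl <- which.min(ifelse(remaining == 0, Inf, remaining))
      idx <- which(unassigned & labels[, lbl] == 1)
      idx <- idx[sample.int(length(idx))]
      for (i in idx) {
        d <- demand[lbl, ]
        best <- which(d == max(d))
        if (length(best) > 1) {
          cap <- capacity[best]
          best <- best[cap == max(cap)]
          if (length(best) > 1) best <- best[sample.int(length(best), 1)]
        }
        fold_of[i] <- best
        unassigned[i] <- FALSE
        capacity[best] <- capacity[best] - 1
        on_i <- which(labels[i, ] == 1)
        demand[on_i, best] <- demand[on_i, best] - 1
      }
    }
    idx <- which(unassigned)
    idx <- idx[sample.int(length(idx))]
    for (i in idx) {
      best <- which(capacity == max(capacity))
      if (length(best) > 1) best <- best[sample.int(length(best), 1)]
      fold_of[i] <- best
      capacity[best] <- capacity[best] - 1
    }
    fold_of
  })
  counts <- vapply(seq_len(k),
                   function(f) colSums(labels[fold_of == f, , drop = FALSE]),
                   numeric(C))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = C)
  structure(list(fold_of = fold_of, k = as.integer(k),
                 class_counts = counts), class = "fold_assignment")
}

# Internal loss dispatch on the (C, batch) orientation.
loss_value <- function(Y, P, cfg) {
  if (cfg$loss == "bce") bce_loss(t(Y), t(P))
  else double_soft_f1_loss(t(Y), t(P), variant = cfg$loss_variant)
}
loss_grad <- function(Y, P, cfg) {
  if (cfg$loss == "bce") bce_grad(Y, P)
  else dsf1_grad(Y, P, variant = cfg$loss_variant)
}

#' Train a model on one dataset split
#'
#' Mini-batch gradient descent with Adam under the fixed recipe in `cfg`.
#' Batch order is reshuffled every epoch from the run seed.  A non-finite
#' loss aborts with a diagnostic.
#'
#' @param model An `"ecg_model"` from [build_model()].
#' @param x Signal array `(n, l, 12)`.
#' @param y Binary label matrix `(n, C)`.
#' @param cfg A [train_config()].
#' @return The trained model.
#' @export
train_model <- function(model, x, y, cfg = train_config()) {
  n <- dim(x)[1]
  stopifnot(nrow(y) == n, ncol(y) == model$cfg$n_classes)
  opt <- adam_init(model$params)
  params <- model$params
  with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      n_batch <- 0L
      for (at in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[at:min(at + cfg$batch_size - 1L, n)]
        Xb <- aperm(x[idx, , , drop = FALSE], c(2, 3, 1))
        if (cfg$augment$noise_enabled || cfg$augment$wander_enabled) {
          for (j in seq_along(idx))
            Xb[, , j] <- t(apply_augmentation(
              t(Xb[, , j]), cfg$augment,
              offset = (epoch - 1L) * n + idx[j]))
        }
        Yb <- t(y[idx, , drop = FALSE])
        fwd <- nn_fwd(model$node, Xb, params, model$state, training = TRUE)
        P <- fwd$out
        lv <- loss_value(Yb, P, cfg)
        if (!is.finite(lv))
          stop("training diverged: non-finite loss at epoch ", epoch)
        ep_loss <- ep_loss + lv
        n_batch <- n_batch + 1L
        grads <- new.env(parent = emptyenv())
        nn_bwd(model$node, loss_grad(Yb, P, cfg), fwd$cache, params, grads)
        params <- adam_step(params, grads, opt, cfg$lr)
      }
      if (cfg$verbose)
        message(sprintf("epoch %2d/%d  %s loss %.5f", epoch, cfg$epochs,
                        cfg$loss, ep_loss / n_batch))
    }
  })
  model$params <- params
  model
}

#' k-fold cross-validation of the full pipeline
#'
#' For each validation fold: a fresh model (initialisation reseeded per
#' fold from the run seed), training on the remaining folds under the
#' recipe, evaluation of accuracy, macro F1 and macro AUROC on the held-out
#' fold.
#'
#' @param dataset List with `x` `(n, l, 12)` and `y` `(n, C)` (as from
#'   [build_dataset()] or [synth_dataset()]).
#' @param cfg A [train_config()].
#' @param k Number of folds.
#' @param folds_to_run Optional subset of fold ids in `1..k` to execute
#'   (defaults to all); metric summaries then cover the executed folds.
#' @param model_cfg Optional [model_config()]; derived from the dataset
#'   dimensions when omitted.
#' @return List of class `"cv_result"` with `reports` (one
#'   `"metrics_report"` per executed fold), `summary` (mean and sd per
#'   metric), `folds` (the assignment) and `models`.
#' @export
run_cv <- function(dataset, cfg = train_config(), k = 10L,
                   folds_to_run = NULL, model_cfg = NULL,
                   keep_models = FALSE) {
  x <- dataset$x; y <- dataset$y
  if (is.null(model_cfg))
    model_cfg <- model_config(input_length = dim(x)[2],
                              n_channels = dim(x)[3],
                              n_classes = ncol(y))
  folds <- stratified_kfold(y, k = k, seed = cfg$seed)
  if (is.null(folds_to_run)) folds_to_run <- seq_len(k)
  reports <- list()
  models <- list()
  for (f in folds_to_run) {
    val <- folds$fold_of == f
    model <- build_model(model_cfg, seed = cfg$seed + f)
    model <- train_model(model, x[!val, , , drop = FALSE],
                         y[!val, , drop = FALSE], cfg)
    probs <- predict_proba(model, x[val, , , drop = FALSE])
    reports[[as.character(f)]] <-
      evaluate_predictions(y[val, , drop = FALSE], probs)
    if (keep_models) models[[as.character(f)]] <- model
  }
  metrics <- c("accuracy", "f1_macro", "auroc_macro")
  vals <- sapply(reports, function(r) unlist(r[metrics]))
  summary <- data.frame(metric = metrics,
                        mean = rowMeans(vals),
                        sd = apply(vals, 1, stats::sd))
  structure(list(reports = reports, summary = summary, folds = folds,
                 folds_run = folds_to_run, cfg = cfg, models = models),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cross-validation over folds",
      paste(x$folds_run, collapse = ","), "\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %.4f +/- %.4f\n", s$metric[i], s$mean[i],
                ifelse(is.na(s$sd[i]), 0, s$sd[i])))
  invisible(x)
}

#' Sampling-frequency sweep
#'
#' Rebuilds the dataset at each frequency and repeats the cross-validation,
#' producing a long-format results table (one row per frequency, fold and
#' metric) ready for box-plot summaries.  A failure at one frequency is
#' recorded and does not abort the others.
#'
#' @param record_dir Directory of WFDB-dialect records (see
#'   [build_dataset()]), or a function `(fs) -> dataset` for in-memory
#'   corpora.
#' @param freqs Sampling frequencies in Hz.
#' @param cfg A [train_config()].
#' @param ... Passed to [run_cv()] (e.g. `folds_to_run`).
#' @return Data frame with columns `frequency`, `fold`, `metric`, `value`,
#'   plus an attribute `"errors"` naming failed frequencies.
#' @export
sweep_frequencies <- function(record_dir, freqs, cfg = train_config(),
                              ...) {
  stopifnot(length(freqs) >= 1)
  rows <- list()
  errors <- character(0)
  for (fs in freqs) {
    res <- tryCatch({
      dataset <- if (is.function(record_dir)) record_dir(fs)
                 else build_dataset(record_dir, target_fs = fs)
      cv <- run_cv(dataset, cfg, ...)
      do.call(rbind, lapply(names(cv$reports), function(f) {
        r <- cv$reports[[f]]
        data.frame(frequency = fs, fold = as.integer(f),
                   metric = c("accuracy", "f1_macro", "auroc_macro"),
                   value = c(r$accuracy, r$f1_macro, r$auroc_macro))
      }))
    }, error = function(e) {
      errors <<- c(errors, sprintf("%g Hz: %s", fs, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[as.character(fs)]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "errors") <- errors
  out
}

#' Paired comparison of the two loss functions
#'
#' Runs the cross-validation twice, identical in every respect (seed, fold
#' assignment, initial weights) except the training loss, and reports
#' per-fold paired metric differences (double soft F1 minus BCE).
#'
#' @param dataset As in [run_cv()].
#' @param cfg_base A [train_config()]; its `loss` field is overridden.
#' @param ... Passed to [run_cv()].
#' @return List with the two `"cv_result"`s and a `paired` data frame of
#'   per-fold differences.
#' @export
compare_losses <- function(dataset, cfg_base = train_config(), ...) {
  cfg_f1 <- cfg_base; cfg_f1$loss <- "double_soft_f1"
  cfg_bce <- cfg_base; cfg_bce$loss <- "bce"
  cv_f1 <- run_cv(dataset, cfg_f1, ...)
  cv_bce <- run_cv(dataset, cfg_bce, ...)
  metrics <- c("accuracy", "f1_macro", "auroc_macro")
  paired <- do.call(rbind, lapply(names(cv_f1$reports), function(f) {
    a <- cv_f1$reports[[f]]; b <- cv_bce$reports[[f]]
    data.frame(fold = as.integer(f), metric = metrics,
               double_soft_f1 = unlist(a[metrics]),
               bce = unlist(b[metrics]),
               difference = unlist(a[metrics]) - unlist(b[metrics]))
  }))
  rownames(paired) <- NULL
  list(double_soft_f1 = cv_f1, bce = cv_bce, paired = paired)
}
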