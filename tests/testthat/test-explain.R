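# A deterministic stand-in "model": a function reading the signal power in
# one planted region of the input, which lets the surrogate's attributions
# be checked against a known dependence.  (Power, not the mean: masking
# replaces a segment by its mean, so a mean-reading function would be
# blind to the perturbation.)
region_model <- function(lead, start, end, n_classes = 3, class_idx = 1) {
  function(x) {
    v <- apply(x[, start:end, lead, drop = FALSE]^2, 1, mean)
    p <- matrix(0.5, dim(x)[1], n_classes)
    p[, class_idx] <- 1 / (1 + exp(-3 * (v - 1)))
    p
  }
}

test_that("segmentation partitions every sample exactly once", {
  seg <- segment_ecg(750, 10)
  expect_equal(unique(seg$ends - seg$starts + 1L), 75L)
  expect_length(seg$seg_of, 750)

  seg2 <- segment_ecg(751, 10)
  sizes <- seg2$ends - seg2$starts + 1L
  expect_lte(diff(range(sizes)), 1L)
  expect_equal(sum(sizes), 751L)
  # contiguous cover, no overlap
  expect_equal(seg2$starts[-1], seg2$ends[-10] + 1L)
  expect_equal(seg2$starts[1], 1L)
  expect_equal(seg2$ends[10], 751L)
  expect_equal(tabulate(seg2$seg_of, 10), sizes)

  expect_error(segment_ecg(10, 11))
})

test_that("a constant model yields a zero map with a warning", {
  const_model <- function(x) matrix(0.5, dim(x)[1], 3)
  set.seed(1)
  ecg <- matrix(rnorm(300 * 12), 300, 12)
  expect_warning(map <- explain_instance(const_model, ecg, 1,
                                         n_perturb = 50, seed = 1),
                 "constant")
  expect_true(all(map == 0))
  expect_equal(dim(map), c(300, 12))
})

test_that("explanations are deterministic given the seed", {
  mod <- region_model(lead = 2, start = 101, end = 150)
  set.seed(2)
  ecg <- matrix(rnorm(300 * 12), 300, 12)
  m1 <- explain_instance(mod, ecg, 1, n_perturb = 80, seed = 5,
                         n_segments = 6)
  m2 <- explain_instance(mod, ecg, 1, n_perturb = 80, seed = 5,
                         n_segments = 6)
  expect_identical(m1, m2)
})

test_that("the surrogate pins a planted single-segment dependence", {
  # model reads only lead 2, segment 3 (samples 101-150 of 300 with 6
  # segments of 50)
  mod <- region_model(lead = 2, start = 101, end = 150)
  set.seed(3)
  ecg <- matrix(rnorm(300 * 12), 300, 12)
  map <- explain_instance(mod, ecg, 1, n_perturb = 400, seed = 7,
                          n_segments = 6)
  coefs <- attr(map, "coefficients")
  target <- abs(coefs[3, 2])
  others <- abs(coefs); others[3, 2] <- NA
  expect_gt(target, 5 * max(others, na.rm = TRUE))
  expect_gt(attr(map, "r2"), 0.5)
  expect_equal(dim(map), c(300, 12))
})

test_that("class contexts sample with replacement and differ by class", {
  set.seed(4)
  n <- 40
  x <- array(rnorm(n * 100 * 12), c(n, 100, 12))
  x[, , 3] <- x[, , 3] + 5        # make reference means distinguishable
  y <- cbind(c(rep(1, 5), rep(0, 35)), c(rep(0, 35), rep(1, 5)))
  mod <- build_model(model_config(input_length = 100, n_classes = 2),
                     seed = 1)
  c1 <- fit_class_lime(mod, x, y, 1, n_pos = 1000, n_neg = 1000,
                       n_segments = 5, seed = 11)
  c2 <- fit_class_lime(mod, x, y, 2, n_pos = 1000, n_neg = 1000,
                       n_segments = 5, seed = 11)
  expect_equal(c1$n_sampled, 2000)
  expect_false(identical(c1$ref_means, c2$ref_means))
  expect_gt(mean(c1$ref_means[, 3]), mean(c1$ref_means[, 1]))

  y0 <- cbind(rep(0, n), y[, 2])
  expect_warning(c0 <- fit_class_lime(mod, x, y0, 1), "no positive")
  expect_null(c0)
})

test_that("aggregation recovers planted leads and respects options", {
  # three classes, each read from a different lead by a function model
  mods <- list(region_model(4, 51, 150, 3, 1),
               region_model(7, 101, 200, 3, 2),
               region_model(11, 1, 100, 3, 3))
  combined <- function(x) {
    p <- matrix(0.5, dim(x)[1], 3)
    for (k in 1:3) p[, k] <- mods[[k]](x)[, k]
    p
  }
  set.seed(5)
  n <- 12
  x <- array(rnorm(n * 300 * 12), c(n, 300, 12))
  y <- matrix(1L, n, 3)
  ctxs <- lapply(1:3, function(cl)
    fit_class_lime(combined, x, y, cl, n_pos = 50, n_neg = 50,
                   n_segments = 6, seed = cl))
  li <- aggregate_lead_importance(combined, x, y, ctxs, n_perturb = 150,
                                  max_records = 4, seed = 9)
  expect_equal(dim(li$importance), c(3, 12))
  expect_equal(unname(apply(li$importance, 1, which.max)), c(4, 7, 11))
  expect_equal(li$n_explained, rep(4L, 3))

  # row normalization leaves the argmax unchanged
  lin <- aggregate_lead_importance(combined, x, y, ctxs, n_perturb = 150,
                                   max_records = 4, seed = 9,
                                   normalize = TRUE)
  expect_equal(apply(lin$importance, 1, which.max),
               apply(li$importance, 1, which.max))
  expect_equal(unname(apply(lin$importance, 1, max)), rep(1, 3))

  # classes without validation positives are flagged
  y2 <- y; y2[, 2] <- 0L
  li2 <- aggregate_lead_importance(combined, x, y2, ctxs,
                                   n_perturb = 80, max_records = 2,
                                   seed = 9)
  expect_true(all(is.na(li2$importance[2, ])))
  expect_equal(li2$flagged, 2L)
})

test_that("aggregation is invariant to record order within a class", {
  mod <- region_model(6, 101, 200, 2, 1)
  set.seed(6)
  x <- array(rnorm(6 * 300 * 12), c(6, 300, 12))
  y <- matrix(1L, 6, 2)
  ctx <- fit_class_lime(mod, x, y, 1, n_pos = 30, n_neg = 30,
                        n_segments = 6, seed = 2)
  li_a <- aggregate_lead_importance(mod, x, y, list(ctx, NULL),
                                    n_perturb = 100, seed = 4)
  perm <- c(4, 2, 6, 1, 5, 3)
  li_b <- aggregate_lead_importance(mod, x[perm, , ],
                                    y[perm, , drop = FALSE],
                                    list(ctx, NULL),
                                    n_perturb = 100, seed = 4)
  expect_equal(li_a$importance, li_b$importance)
})

test_that("the importance heatmap builds", {
  li <- structure(list(importance = matrix(runif(36), 3, 12,
                         dimnames = list(NULL, LEAD_NAMES)),
                       n_explained = rep(2L, 3), flagged = integer(0),
                       statistic = "mean", normalized = FALSE),
                  class = "lead_importance")
  p <- plot_lead_importance(li, class_names = c("A", "B", "C"))
  expect_s3_class(p, "ggplot")
})
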