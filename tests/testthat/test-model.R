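# Observed temporal length after each sequential stage of the live
# network, for comparison with the closed-form trace.
observed_lengths <- function(model, l) {
  X <- array(0, c(l, model$cfg$n_channels, 2L))
  node <- model$node
  st <- ecgception:::nn_init_state(node)
  lens <- c(input = l)
  labels <- c("zeropad", "stem1", "stem1_bn", "stem1_relu", "stem_pool",
              "stem2", "stem2_bn", "stem2_relu", "incep1", "incep2",
              "post_pool")
  for (i in seq_along(labels)) {
    X <- ecgception:::nn_fwd(node$children[[i]], X, model$params, st)$out
    lens[labels[i]] <- dim(X)[1]
  }
  lens
}

test_that("forward pass maps (b, l, 12) to (b, 30) probabilities", {
  for (l in c(250, 750, 5000)) {
    cfg <- model_config(input_length = l)
    m <- build_model(cfg, seed = 1)
    b <- if (l == 5000) 2 else 4
    set.seed(1)
    x <- array(rnorm(b * l * 12), c(b, l, 12))
    p <- predict_proba(m, x)
    expect_equal(dim(p), c(b, 30))
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("the pre-head feature vector has width 64", {
  m <- build_model(model_config(input_length = 750), seed = 1)
  expect_equal(dim(m$params$head$W), c(30, 64))
  expect_equal(sum(m$cfg$inception_path_filters), 64)
  # run the graph up to global average pooling and look at the features
  X <- array(rnorm(750 * 12 * 3), c(750, 12, 3))
  st <- ecgception:::nn_init_state(m$node)
  for (i in 1:12)                      # ... through gap (child 12)
    X <- ecgception:::nn_fwd(m$node$children[[i]], X, m$params, st)$out
  expect_equal(dim(X), c(64, 3))
})

test_that("intermediate lengths match the closed-form arithmetic", {
  for (l in c(250, 750, 1000, 5000)) {
    cfg <- model_config(input_length = l)
    m <- build_model(cfg, seed = 1)
    tr <- model_length_trace(cfg)
    obs <- observed_lengths(m, l)
    expect_equal(unname(obs[c("zeropad", "stem1", "stem_pool", "stem2",
                              "incep1", "post_pool")]),
                 unname(tr[c("zeropad", "stem1", "stem_pool", "stem2",
                             "inception", "post_pool")]))
  }
})

test_that("batch composition does not change per-sample output in eval", {
  m <- build_model(model_config(input_length = 250), seed = 3)
  set.seed(2)
  x <- array(rnorm(30 * 250 * 12), c(30, 250, 12))
  full <- predict_proba(m, x)
  one <- predict_proba(m, x[1, , , drop = FALSE])
  expect_equal(one[1, ], full[1, ], tolerance = 1e-12)
  perm <- sample(30)
  expect_equal(predict_proba(m, x[perm, , ]), full[perm, ],
               tolerance = 1e-12)
})

test_that("inception block concatenates its four paths", {
  blk <- build_inception_block(c(16, 16, 16, 16), in_channels = 64,
                               seed = 1)
  set.seed(3)
  x <- array(rnorm(2 * 50 * 64), c(2, 50, 64))
  out <- block_forward(blk, x)
  expect_equal(dim(out), c(2, 50, 64))

  blk2 <- build_inception_block(c(8, 24, 24, 8), in_channels = 64,
                                seed = 1)
  expect_equal(dim(block_forward(blk2, x)), c(2, 50, 64))

  zero <- block_forward(blk, array(0, c(2, 50, 64)), training = FALSE)
  expect_true(all(is.finite(zero)))
  expect_error(build_inception_block(c(0, 16, 16, 16)), "positive")
})

test_that("parameter counts are stable, monotone, and match arithmetic", {
  cfg <- model_config(input_length = 750)
  expect_equal(count_parameters(build_model(cfg, seed = 1)),
               count_parameters(build_model(cfg, seed = 99)))

  cfg_wide <- model_config(input_length = 750,
                           stem2 = list(kernel = 5L, filters = 128L),
                           inception_path_filters = c(32, 32, 32, 32))
  expect_gt(count_parameters(build_model(cfg_wide, seed = 1)),
            count_parameters(build_model(cfg, seed = 1)))

  # tiny configuration, counted by hand layer by layer:
  tiny <- model_config(input_length = 40, n_channels = 2, n_classes = 3,
                       stem1 = list(kernel = 3L, filters = 4L),
                       stem2 = list(kernel = 3L, filters = 4L),
                       stem_pad = 1L,
                       inception_path_filters = c(1L, 1L, 1L, 1L))
  by_hand <-
    (4 * 2 * 3 + 4) + (2 * 4) +            # stem1 conv + bn
    (4 * 4 * 3 + 4) + (2 * 4) +            # stem2 conv + bn
    2 * ((1 * 4 + 1) + 2 +                 # per block: path a 1-conv + bn
         (1 * 4 + 1) + 2 +                 #   path b bottleneck
         (1 * 1 * 3 + 1) + 2 +             #   path b 3-conv
         (1 * 4 + 1) + 2 +                 #   path c bottleneck
         (1 * 1 * 5 + 1) + 2 +             #   path c 5-conv
         (1 * 4 + 1) + 2) +                #   path d 1-conv
    (3 * 4 + 3)                            # dense head
  expect_equal(count_parameters(build_model(tiny, seed = 1)), by_hand)
})

test_that("configuration invariants are enforced", {
  expect_error(model_config(750, inception_path_filters = c(16, 16, 16, 8)),
               "sum to")
  expect_error(model_config(750, stem1 = list(kernel = 4L, filters = 64L)),
               "odd")
  expect_error(build_model(model_config(input_length = 10)), "too short")
})

test_that("same seed rebuilds identical weights; checkpoints round-trip", {
  cfg <- model_config(input_length = 250, n_classes = 5)
  m1 <- build_model(cfg, seed = 42)
  m2 <- build_model(cfg, seed = 42)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params,
                         build_model(cfg, seed = 43)$params))

  path <- withr::local_tempfile(fileext = ".rds")
  set.seed(1)
  x <- array(rnorm(3 * 250 * 12), c(3, 250, 12))
  save_model(m1, path)
  m3 <- load_model(path)
  expect_equal(predict_proba(m3, x), predict_proba(m1, x))
})
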