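#' Architecture hyperparameters for the 1D Inception ECG classifier
#'
#' Collects every structural hyperparameter of the network: a two-stage
#' convolutional stem (kernel 7 then kernel 5, 64 filters each, with an
#' explicit symmetric zero-pad of 3 before the first convolution and a
#' max-pool of size 3 / stride 2 between them), a stack of 1D Inception
#' blocks, a closing max-pool (size 7 / stride 2), global average pooling
#' and a dense sigmoid head with one output per condition.
#'
#' @param input_length Number of samples per lead fed to the network
#'   (e.g. 750 for 10-second records at 75 Hz).
#' @param n_channels Number of ECG leads (12).
#' @param n_classes Number of sigmoid outputs (30 for the full condition
#'   catalog; smaller for reduced synthetic corpora).
#' @param stem1,stem2 Lists with entries `kernel` and `filters` for the two
#'   stem convolutions.
#' @param stem_pad Symmetric zero padding added before the first stem
#'   convolution.
#' @param stem_pool,post_pool Lists with entries `size` and `stride` for the
#'   max-pool after the stem / after the Inception stack.
#' @param n_inception_blocks Number of stacked Inception blocks.
#' @param inception_path_filters Integer vector of length 4: output filters
#'   of the four parallel paths of each block.  Must sum to `stem2$filters`
#'   so that global average pooling yields a feature vector of that width.
#' @return An object of class `"model_config"`.
#' @export
model_config <- function(input_length,
                         n_channels = 12L,
                         n_classes = 30L,
                         stem1 = list(kernel = 7L, filters = 64L),
                         stem2 = list(kernel = 5L, filters = 64L),
                         stem_pad = 3L,
                         stem_pool = list(size = 3L, stride = 2L),
                         n_inception_blocks = 2L,
                         inception_path_filters = c(16L, 16L, 16L, 16L),
                         post_pool = list(size = 7L, stride = 2L)) {
  cfg <- list(input_length = as.integer(input_length),
              n_channels = as.integer(n_channels),
              n_classes = as.integer(n_classes),
              stem1 = stem1, stem2 = stem2,
              stem_pad = as.integer(stem_pad), stem_pool = stem_pool,
              n_inception_blocks = as.integer(n_inception_blocks),
              inception_path_filters = as.integer(inception_path_filters),
              post_pool = post_pool)
  ks <- c(stem1$kernel, stem2$kernel)
  if (any(ks <= 0) || any(ks %% 2 == 0))
    stop("stem kernel sizes must be odd and positive")
  if (length(cfg$inception_path_filters) != 4 ||
      any(cfg$inception_path_filters <= 0))
    stop("inception_path_filters must be four positive integers")
  if (sum(cfg$inception_path_filters) != stem2$filters)
    stop("inception_path_filters must sum to ", stem2$filters,
         " so global average pooling yields a ", stem2$filters,
         "-wide feature vector")
  if (cfg$input_length < 1) stop("input_length must be positive")
  class(cfg) <- "model_config"
  cfg
}

conv_out_len <- function(l, k, pad, stride) (l + 2L * pad - k) %/% stride + 1L

#' Closed-form trace of the temporal length through the network
#'
#' Applies the standard pad/convolution/pool length arithmetic
#' `l_out = floor((l + 2 pad - k) / stride) + 1` stage by stage.  Used both
#' to validate a configuration at build time and as an oracle for the
#' shapes produced by the live network.
#'
#' @param cfg A [model_config()].
#' @return Named integer vector of the length after each stage.
#' @export
model_length_trace <- function(cfg) {
  l0 <- cfg$input_length
  l_pad <- l0 + 2L * cfg$stem_pad
  l_c1 <- conv_out_len(l_pad, cfg$stem1$kernel, 0L, 1L)
  l_p1 <- conv_out_len(l_c1, cfg$stem_pool$size, 0L, cfg$stem_pool$stride)
  l_c2 <- l_p1                       # same padding
  l_inc <- l_c2                      # inception paths preserve length
  l_p2 <- conv_out_len(l_inc, cfg$post_pool$size, 0L, cfg$post_pool$stride)
  c(input = l0, zeropad = l_pad, stem1 = l_c1, stem_pool = l_p1,
    stem2 = l_c2, inception = l_inc, post_pool = l_p2)
}

# One 1D Inception block as a concat node: (a) 1-conv; (b) 1-conv then
# 3-conv; (c) 1-conv then 5-conv; (d) 3-max-pool stride 1 then 1-conv.
# Every convolution is followed by batch-norm + ReLU; same-padding keeps
# the four branches concatenable.
inception_node <- function(prefix, in_ch, path_filters) {
  f <- as.integer(path_filters)
  cbr <- function(name, k, ic, oc)
    nn_seq(nn_conv(paste0(name, "_conv"), k, ic, oc, pad = (k - 1L) %/% 2L),
           nn_bn(paste0(name, "_bn"), oc), nn_relu())
  nn_concat(list(
    cbr(paste0(prefix, "_a1"), 1L, in_ch, f[1]),
    nn_seq(cbr(paste0(prefix, "_b1"), 1L, in_ch, f[2]),
           cbr(paste0(prefix, "_b3"), 3L, f[2], f[2])),
    nn_seq(cbr(paste0(prefix, "_c1"), 1L, in_ch, f[3]),
           cbr(paste0(prefix, "_c5"), 5L, f[3], f[3])),
    nn_seq(nn_maxpool(3L, 1L, pad = 1L),
           cbr(paste0(prefix, "_d1"), 1L, in_ch, f[4]))))
}

#' Build a standalone 1D Inception block
#'
#' Mainly useful for inspecting the block in isolation; [build_model()]
#' embeds the same structure in the full network.
#'
#' @param path_filters Four positive integers: output filters of the four
#'   parallel paths.
#' @param in_channels Input feature width.
#' @param seed Integer seed for weight initialisation.
#' @return List with the graph `node`, initialised `params`, and batch-norm
#'   `state`, usable with [block_forward()].
#' @export
build_inception_block <- function(path_filters, in_channels = 64L,
                                  seed = 1L) {
  if (length(path_filters) != 4 || any(path_filters <= 0))
    stop("path_filters must be four positive integers")
  node <- inception_node("blk", as.integer(in_channels), path_filters)
  params <- with_seed(seed, nn_init_params(node))
  list(node = node, params = params, state = nn_init_state(node))
}

#' Run an input through a standalone Inception block
#'
#' @param block A block from [build_inception_block()].
#' @param x Array `(batch, length, channels)`.
#' @param training Use batch statistics (`TRUE`) or running statistics.
#' @return Array `(batch, length, sum(path_filters))`.
#' @export
block_forward <- function(block, x, training = FALSE) {
  X <- aperm(x, c(2, 3, 1))
  out <- nn_fwd(block$node, X, block$params, block$state, training)$out
  aperm(out, c(3, 1, 2))
}

#' Build the 1D Inception ECG classification network
#'
#' Layer sequence: zero-pad(stem_pad) -> conv(k=7, 64) -> batch-norm ->
#' ReLU -> max-pool(3, stride 2) -> conv(k=5, 64, same padding) ->
#' batch-norm -> ReLU -> Inception block x2 -> max-pool(7, stride 2) ->
#' global average pool -> dense(n_classes) -> sigmoid.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for the Glorot-uniform weight initialisation.
#' @return An object of class `"ecg_model"`.
#' @export
build_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  trace <- model_length_trace(cfg)
  if (any(trace < 1)) {
    min_l <- min_input_length(cfg)
    stop("input_length ", cfg$input_length, " is too short for the ",
         "pooling cascade; minimum supported length is ", min_l)
  }
  f64 <- cfg$stem2$filters
  blocks <- lapply(seq_len(cfg$n_inception_blocks), function(i)
    inception_node(paste0("incep", i), f64, cfg$inception_path_filters))
  node <- do.call(nn_seq, c(
    list(nn_zeropad(cfg$stem_pad),
         nn_conv("stem1_conv", cfg$stem1$kernel, cfg$n_channels,
                 cfg$stem1$filters, pad = 0L),
         nn_bn("stem1_bn", cfg$stem1$filters), nn_relu(),
         nn_maxpool(cfg$stem_pool$size, cfg$stem_pool$stride),
         nn_conv("stem2_conv", cfg$stem2$kernel, cfg$stem1$filters,
                 cfg$stem2$filters,
                 pad = (cfg$stem2$kernel - 1L) %/% 2L),
         nn_bn("stem2_bn", cfg$stem2$filters), nn_relu()),
    blocks,
    list(nn_maxpool(cfg$post_pool$size, cfg$post_pool$stride),
         nn_gap(),
         nn_dense("head", f64, cfg$n_classes),
         nn_sigmoid())))
  params <- with_seed(seed, nn_init_params(node))
  model <- list(cfg = cfg, node = node, params = params,
                state = nn_init_state(node), seed = as.integer(seed))
  class(model) <- "ecg_model"
  model
}

# Smallest input length that survives both pooling stages.
min_input_length <- function(cfg) {
  # post_pool needs at least post_pool$size samples entering it
  need <- cfg$post_pool$size
  # invert stem max-pool: l_out >= need  =>  l_in >= (need-1)*stride + size
  need <- (need - 1L) * cfg$stem_pool$stride + cfg$stem_pool$size
  # invert stem1 conv + zeropad
  need + cfg$stem1$kernel - 1L - 2L * cfg$stem_pad
}

# Forward pass on a (length, channels, batch) cube; probabilities as a
# (n_classes, batch) matrix plus per-layer caches for backprop.
model_fwd <- function(model, X, training = FALSE) {
  nn_fwd(model$node, X, model$params, model$state, training)
}

#' Predict per-condition probabilities
#'
#' Runs the network in inference mode (batch-norm uses running statistics,
#' so results are independent of batch composition).
#'
#' @param model A trained or freshly built [build_model()] network.
#' @param x Array `(n, length, channels)`.
#' @param batch_size Internal forward batch size.
#' @return Matrix `(n, n_classes)` of probabilities in (0, 1).
#' @export
predict_proba <- function(model, x, batch_size = 64L) {
  if (length(dim(x)) == 2) dim(x) <- c(1L, dim(x))
  n <- dim(x)[1]
  out <- matrix(NA_real_, n, model$cfg$n_classes)
  for (at in seq(1L, n, by = batch_size)) {
    idx <- at:min(at + batch_size - 1L, n)
    X <- aperm(x[idx, , , drop = FALSE], c(2, 3, 1))
    out[idx, ] <- t(model_fwd(model, X, training = FALSE)$out)
  }
  out
}

#' Count trainable parameters
#'
#' Weights, biases and batch-norm scale/shift; running statistics are not
#' trainable and are excluded.
#'
#' @param model An `"ecg_model"` or the list returned by
#'   [build_inception_block()].
#' @return Integer total.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params,
             function(p) sum(vapply(p, length, integer(1))), numeric(1)))
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the configuration, weights, batch-norm running
#' statistics and the initialisation seed, so [load_model()] rebuilds an
#' identical network.  The configuration is additionally written as a
#' JSON sidecar (`<path>.json`) for inspection and exact rebuilds.
#'
#' @param model An `"ecg_model"`.
#' @param path File path for the checkpoint (`.rds`).
#' @export
save_model <- function(model, path) {
  st <- as.list(model$state)
  saveRDS(list(cfg = unclass(model$cfg), params = model$params,
               state = st, seed = model$seed), path)
  jsonlite::write_json(unclass(model$cfg), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  cfg <- obj$cfg
  class(cfg) <- "model_config"
  model <- build_model(cfg, seed = obj$seed)
  model$params <- obj$params
  for (nm in names(obj$state)) assign(nm, obj$state[[nm]], model$state)
  model
}

#' @export
print.ecg_model <- function(x, ...) {
  tr <- model_length_trace(x$cfg)
  cat("1D Inception ECG classifier\n")
  cat("  input: (", x$cfg$input_length, ",", x$cfg$n_channels, ")",
      " -> ", x$cfg$n_classes, " sigmoid outputs\n", sep = "")
  cat("  inception blocks:", x$cfg$n_inception_blocks,
      " path filters:", paste(x$cfg$inception_path_filters, collapse = "/"),
      "\n")
  cat("  temporal trace:", paste(names(tr), tr, sep = "=", collapse = " "),
      "\n")
  cat("  trainable parameters:", count_parameters(x), "\n")
  invisible(x)
}
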