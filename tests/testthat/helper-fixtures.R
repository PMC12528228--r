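# Shared fixtures and small oracles used across test files.

# A quantised random 10 s record (storable losslessly at gain 1000).
random_record <- function(id = "R00001", fs = 50, seed = 1,
                          dx = character(0)) {
  set.seed(seed)
  n <- round(10 * fs)
  sig <- round(matrix(rnorm(12 * n, sd = 0.8), 12, n) * 1000) / 1000
  ecgception:::new_ecg_record(id, sig, fs, age = 57, sex = "female",
                              dx_labels = dx)
}

# Band-limited test signal: sinusoids with integer numbers of cycles over
# the record, all below max_hz.
bandlimited_signal <- function(n, fs, max_hz = 10, seed = 1) {
  set.seed(seed)
  t <- (0:(n - 1)) / fs
  dur <- n / fs
  cycles <- sample(seq_len(floor(max_hz * dur)), 5)
  amps <- runif(5, 0.2, 1)
  rowSums(sapply(seq_along(cycles),
                 function(i) amps[i] * sin(2 * pi * cycles[i] * t / dur)))
}

# Per-lead spectral band-power features for the linear-probe checks.
bandpower_features <- function(x, fs) {
  n <- dim(x)[2]
  freqs <- (0:(n - 1)) * fs / n
  bands <- rbind(c(0.5, 1.5), c(1.5, 2.5), c(2.5, 4), c(4, 6),
                 c(6, 9), c(9, 12.5))
  feat <- matrix(NA_real_, dim(x)[1], 12 * (nrow(bands) + 1))
  for (i in seq_len(dim(x)[1])) {
    f <- c()
    for (lead in 1:12) {
      p <- Mod(fft(x[i, , lead]))^2 / n
      bp <- apply(bands, 1, function(b) sum(p[freqs >= b[1] &
                                               freqs < b[2]]))
      f <- c(f, bp, var(x[i, , lead]))
    }
    feat[i, ] <- f
  }
  feat
}

# Held-out AUROC of a ridge-logistic linear probe on arbitrary features;
# deterministic given the seed.
probe_auroc <- function(feat, y, seed = 1) {
  set.seed(seed)
  n <- nrow(feat)
  tr <- sample(n, floor(n / 2))
  te <- setdiff(seq_len(n), tr)
  fit <- glmnet::cv.glmnet(feat[tr, , drop = FALSE], y[tr],
                           family = "binomial", alpha = 0, nfolds = 4)
  sc <- predict(fit, feat[te, , drop = FALSE], s = "lambda.min")
  ecgception:::auroc_one(y[te], as.numeric(sc))
}

# Small, quickly generated synthetic dataset shared by several files.
tiny_balanced_dataset <- function(n = 60, fs = 25, seed = 5) {
  synth_dataset(synthetic_spec(n, fs = fs, n_classes = 4,
                               prevalence = 0.3, seed = seed))
}

# Scalar-loop reference implementations of the losses and metrics, kept
# deliberately independent of the vectorised package code.
bce_oracle <- function(y, p, eps = 1e-7) {
  tot <- 0
  for (i in seq_len(nrow(y))) for (j in seq_len(ncol(y))) {
    pc <- min(max(p[i, j], eps), 1 - eps)
    tot <- tot - (y[i, j] * log(pc) + (1 - y[i, j]) * log(1 - pc))
  }
  tot / length(y)
}

dsf1_oracle <- function(y, p, corrected = TRUE) {
  per <- numeric(ncol(y))
  for (j in seq_len(ncol(y))) {
    tp <- fp <- fn <- 0
    for (i in seq_len(nrow(y))) {
      tp <- tp + p[i, j] * y[i, j]
      fp <- fp + p[i, j] * (1 - y[i, j])
      fn <- fn + if (corrected) (1 - p[i, j]) * y[i, j]
                 else (1 - p[i, j]) * (1 - y[i, j])
    }
    per[j] <- 1 - 2 * tp / (2 * tp + fp + fn + 1e-16)
  }
  mean(per)
}

acc_oracle <- function(y, b) {
  per <- numeric(ncol(y))
  for (j in seq_len(ncol(y)))
    per[j] <- sum(y[, j] == b[, j]) / nrow(y)
  mean(per)
}

random_pair <- function(seed, n = NULL, C = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(1:20, 1)
  if (is.null(C)) C <- sample(1:5, 1)
  list(y = matrix(rbinom(n * C, 1, 0.4), n, C),
       p = matrix(runif(n * C), n, C))
}

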