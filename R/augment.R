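# Training-time signal augmentations.  Both draw their scale from the
# standard deviation of all values in the record (all 12 leads jointly),
# are identity when that deviation is zero, and are pure functions of
# (signal, seed).  They are meant for training only, never evaluation.

signal_sd <- function(signal) stats::sd(as.numeric(signal))

#' Additive uniform random noise
#'
#' Adds an independent draw, uniform on (-sigma, +sigma), to every sample,
#' where sigma is the standard deviation of all values in the recording.
#' A constant signal (sigma = 0) is returned unchanged.
#'
#' @param signal Matrix `(12, n)` in millivolts.
#' @param seed Integer seed; fixes the draws.
#' @return Matrix of the same shape.
#' @export
add_random_noise <- function(signal, seed) {
  stopifnot(is.matrix(signal), ncol(signal) >= 1)
  sigma <- signal_sd(signal)
  if (sigma == 0) return(signal)
  noise <- with_seed(seed,
    matrix(stats::runif(length(signal), -sigma, sigma),
           nrow(signal), ncol(signal)))
  signal + noise
}

#' Simulated baseline wander
#'
#' Adds a low-frequency cosine to the record.  The default `"index"` form
#' spans exactly one period across the n samples,
#' `A * cos(2 pi i / n + phi)` for `i = 0..n-1`, with a random phase
#' `phi ~ U(0, 2 pi)` and amplitude `A ~ U(-sigma, sigma)` where sigma is
#' the standard deviation of all values in the recording.  One draw of
#' `(A, phi)` is shared by all 12 leads (set `per_lead = TRUE` for
#' independent draws).  The `"verbatim"` form instead places each lead's
#' signal value inside the cosine argument,
#' `A * cos(2 pi y_i / n + phi)`, and is kept for fidelity testing only;
#' it does not produce a single-period drift.
#'
#' @param signal Matrix `(12, n)`, n >= 2.
#' @param seed Integer seed.
#' @param variant `"index"` (one period across the record) or
#'   `"verbatim"`.
#' @param per_lead Draw amplitude and phase independently per lead.
#' @param amplitude,phase Optional fixed overrides of the random draws
#'   (useful for calibration and closed-form checks).
#' @return Matrix of the same shape.
#' @export
add_baseline_wander <- function(signal, seed,
                                variant = c("index", "verbatim"),
                                per_lead = FALSE,
                                amplitude = NULL, phase = NULL) {
  variant <- match.arg(variant)
  stopifnot(is.matrix(signal), ncol(signal) >= 2)
  n <- ncol(signal)
  n_lead <- nrow(signal)
  sigma <- signal_sd(signal)
  if (sigma == 0 && is.null(amplitude)) return(signal)
  draws <- with_seed(seed, {
    k <- if (per_lead) n_lead else 1L
    list(A = stats::runif(k, -sigma, sigma),
         phi = stats::runif(k, 0, 2 * pi))
  })
  A <- if (is.null(amplitude)) draws$A else rep(amplitude, length.out =
                                                if (per_lead) n_lead else 1L)
  phi <- if (is.null(phase)) draws$phi else rep(phase, length.out =
                                                if (per_lead) n_lead else 1L)
  i <- 0:(n - 1)
  if (variant == "index") {
    if (per_lead) {
      wander <- t(vapply(seq_len(n_lead),
                         function(j) A[j] * cos(2 * pi * i / n + phi[j]),
                         numeric(n)))
    } else {
      wander <- matrix(A * cos(2 * pi * i / n + phi), n_lead, n,
                       byrow = TRUE)
    }
  } else {
    Aj <- if (per_lead) A else rep(A, n_lead)
    phij <- if (per_lead) phi else rep(phi, n_lead)
    wander <- t(vapply(seq_len(n_lead),
                       function(j) Aj[j] * cos(2 * pi * signal[j, ] / n +
                                               phij[j]),
                       numeric(n)))
  }
  signal + wander
}

#' Augmentation configuration
#'
#' @param noise_enabled,wander_enabled Switch each transform on.
#' @param rng_seed Base seed; per-record seeds are derived from it.
#' @return List of class `"augment_config"`.
#' @export
augment_config <- function(noise_enabled = FALSE, wander_enabled = FALSE,
                           rng_seed = 1L) {
  structure(list(noise_enabled = noise_enabled,
                 wander_enabled = wander_enabled,
                 rng_seed = as.integer(rng_seed)),
            class = "augment_config")
}

# Apply the configured augmentations to one (12, n) signal; the per-record
# seed offset keeps draws distinct across records and epochs.
apply_augmentation <- function(signal, cfg, offset = 0L) {
  if (cfg$noise_enabled)
    signal <- add_random_noise(signal, cfg$rng_seed + 2L * offset)
  if (cfg$wander_enabled)
    signal <- add_baseline_wander(signal, cfg$rng_seed + 2L * offset + 1L)
  signal
}
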