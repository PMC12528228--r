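#' Canonical 12-lead order
#' @export
LEAD_NAMES <- c("I", "II", "III", "aVR", "aVL", "aVF",
                "V1", "V2", "V3", "V4", "V5", "V6")

#' The 30-condition catalog
#'
#' Ordered table of the 30 cardiac conditions the classifier scores, with
#' their SNOMED-CT diagnosis codes as used in the challenge-style header
#' `# Dx:` lines.  The order of rows defines the index of each condition in
#' label vectors.  The mapping ships as an editable CSV
#' (`extdata/dx_mapping.csv`) and can be overridden per corpus.
#'
#' @param mapping_path Optional path to an alternative mapping CSV with
#'   columns `name`, `abbreviation`, `code` (and optionally `prevalence`).
#' @return Data frame of class `"condition_catalog"` with one row per
#'   condition, in canonical order.
#' @export
condition_catalog <- function(mapping_path = NULL) {
  if (is.null(mapping_path))
    mapping_path <- system.file("extdata", "dx_mapping.csv",
                                package = "ecgception", mustWork = TRUE)
  cat <- utils::read.csv(mapping_path, colClasses = "character")
  if (anyDuplicated(cat$name) || anyDuplicated(cat$code))
    stop("catalog names and codes must be unique")
  cat$index <- seq_len(nrow(cat))
  class(cat) <- c("condition_catalog", "data.frame")
  cat
}

new_ecg_record <- function(record_id, signal, fs, age = NA_real_,
                           sex = "unknown", dx_labels = character(0)) {
  stopifnot(is.matrix(signal))
  if (nrow(signal) != 12)
    stop("unsupported record: expected 12 leads, got ", nrow(signal))
  if (!all(is.finite(signal))) stop("signal contains non-finite values")
  if (fs <= 0) stop("sampling frequency must be positive")
  rec <- list(record_id = record_id, signal = signal, fs = fs,
              duration = ncol(signal) / fs, age = age,
              sex = match.arg(tolower(sex), c("male", "female", "unknown")),
              dx_labels = unique(as.character(dx_labels)))
  class(rec) <- "ecg_record"
  rec
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ecg_record %s: 12 x %d samples @ %g Hz (%.2f s), %s, %s\n",
              x$record_id, ncol(x$signal), x$fs, x$duration,
              if (is.na(x$age)) "age ?" else paste("age", x$age),
              x$sex))
  if (length(x$dx_labels))
    cat("  Dx:", paste(x$dx_labels, collapse = ","), "\n")
  invisible(x)
}

#' Read one ECG record from a challenge-style WFDB header + MAT pair
#'
#' The header's first line carries `id n_leads fs n_samples`; each signal
#' line names the shared `.mat` file and its gain (`<gain>/mV`); comment
#' lines `# Age:`, `# Sex:` and `# Dx:` carry metadata, with diagnosis
#' codes comma-separated.  The `.mat` sibling holds one integer matrix
#' `val` of shape leads x samples; amplitudes are returned in millivolts
#' after dividing by the gain and subtracting the baseline.
#'
#' @param header_path Path to the `.hea` file.
#' @return An `"ecg_record"` with fields `record_id`, `signal` (12 x
#'   n_samples, mV), `fs`, `duration`, `age`, `sex`, `dx_labels`.
#' @export
read_record <- function(header_path) {
  lines <- readLines(header_path, warn = FALSE)
  if (!length(lines)) stop("empty header file: ", header_path)
  head_tok <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(head_tok) < 4)
    stop("malformed header line in ", header_path, ": '", lines[1], "'")
  record_id <- head_tok[1]
  n_sig <- as.integer(head_tok[2])
  fs <- as.numeric(head_tok[3])
  n_samples <- as.integer(head_tok[4])
  if (any(is.na(c(n_sig, fs, n_samples))))
    stop("malformed header line in ", header_path, ": '", lines[1], "'")
  if (n_sig != 12)
    stop("unsupported record ", record_id, ": expected 12 leads, header ",
         "declares ", n_sig)
  sig_lines <- lines[2:(1 + n_sig)]
  gains <- baselines <- numeric(n_sig)
  sig_file <- NA_character_
  for (i in seq_len(n_sig)) {
    tok <- strsplit(trimws(sig_lines[i]), "\\s+")[[1]]
    if (length(tok) < 3)
      stop("malformed signal line in ", header_path, ": '",
           sig_lines[i], "'")
    sig_file <- tok[1]
    g <- suppressWarnings(as.numeric(sub("[(/].*$", "", tok[3])))
    if (is.na(g) || g == 0) g <- 1000
    gains[i] <- g
    base <- regmatches(tok[3], regexec("\\(([-0-9]+)\\)", tok[3]))[[1]]
    baselines[i] <- if (length(base) == 2) as.numeric(base[2]) else 0
  }
  age <- NA_real_; sex <- "unknown"; dx <- character(0)
  for (ln in lines[-seq_len(1 + n_sig)]) {
    val <- trimws(sub("^#\\s*\\w+:", "", ln))
    if (grepl("^#\\s*Age:", ln)) {
      a <- suppressWarnings(as.numeric(val))
      age <- if (length(a) && !is.na(a)) a else NA_real_
    } else if (grepl("^#\\s*Sex:", ln)) {
      sex <- if (tolower(val) %in% c("male", "female")) tolower(val)
             else "unknown"
    } else if (grepl("^#\\s*Dx:", ln)) {
      dx <- trimws(strsplit(val, ",")[[1]])
      dx <- dx[nzchar(dx)]
    }
  }
  mat_path <- file.path(dirname(header_path), sig_file)
  if (!file.exists(mat_path))
    mat_path <- sub("\\.hea$", ".mat", header_path)
  m <- read_mat_v4(mat_path)
  val <- m$data
  if (nrow(val) != n_sig && ncol(val) == n_sig) val <- t(val)
  if (ncol(val) != n_samples)
    stop("signal length ", ncol(val), " disagrees with header (",
         n_samples, ") for ", record_id)
  sig <- (val - baselines) / gains
  new_ecg_record(record_id, sig, fs, age = age, sex = sex, dx_labels = dx)
}

#' Write one ECG record as a header + MAT v4 pair
#'
#' Amplitudes are stored as integers at a gain of 1000 per mV (int16), the
#' challenge convention, so a read-back reproduces the signal exactly at
#' millivolt*1e-3 precision.
#'
#' @param rec An `"ecg_record"`.
#' @param out_dir Output directory (created if missing).
#' @return Character vector `c(header, signal)` of the two paths written.
#' @export
write_record <- function(rec, out_dir) {
  stopifnot(inherits(rec, "ecg_record"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  hea <- file.path(out_dir, paste0(rec$record_id, ".hea"))
  mat <- file.path(out_dir, paste0(rec$record_id, ".mat"))
  n <- ncol(rec$signal)
  sex_str <- c(male = "Male", female = "Female",
               unknown = "Unknown")[[rec$sex]]
  lines <- c(
    sprintf("%s 12 %s %d", rec$record_id, format(rec$fs), n),
    sprintf("%s.mat 16 1000/mV 16 0 0 0 0 %s", rec$record_id, LEAD_NAMES),
    sprintf("# Age: %s", if (is.na(rec$age)) "NaN" else format(rec$age)),
    sprintf("# Sex: %s", sex_str),
    sprintf("# Dx: %s", paste(rec$dx_labels, collapse = ",")))
  writeLines(lines, hea)
  write_mat_v4(rec$signal * 1000, mat, name = "val", storage = "int16")
  invisible(c(header = hea, signal = mat))
}

#' Keep only records of (approximately) 10 seconds
#'
#' @param records List of `"ecg_record"` objects.
#' @param tol Tolerance in seconds on `|duration - 10|`; the default 0
#'   keeps exactly the records whose sample count equals `round(10 * fs)`.
#' @return List with `kept` and `excluded` record lists (order preserved)
#'   and the two counts.
#' @export
filter_ten_second <- function(records, tol = 0) {
  ok <- vapply(records, function(r) abs(r$duration - 10) <= tol,
               logical(1))
  list(kept = records[ok], excluded = records[!ok],
       n_kept = sum(ok), n_excluded = sum(!ok))
}

# Fourier-domain resampling of one numeric vector to m samples: keep the
# shared low-frequency bins, split/fold the Nyquist bin so the inverse
# transform is real, rescale by m/n.  Deterministic and anti-aliased for
# band-limited input.
resample_fft <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  X <- stats::fft(x)
  Y <- rep(0 + 0i, m)
  nm <- min(n, m)
  if (nm %% 2L == 1L) {
    hp <- (nm + 1L) %/% 2L              # DC + positive bins
    hn <- nm %/% 2L                     # negative bins
    Y[seq_len(hp)] <- X[seq_len(hp)]
    if (hn > 0) Y[(m - hn + 1L):m] <- X[(n - hn + 1L):n]
  } else {
    h <- nm %/% 2L
    Y[seq_len(h)] <- X[seq_len(h)]
    if (h > 1) Y[(m - h + 2L):m] <- X[(n - h + 2L):n]
    if (m < n) {
      Y[h + 1L] <- X[h + 1L] + X[n - h + 1L]    # fold both Nyquist bins
    } else {
      Y[h + 1L] <- X[h + 1L] / 2
      Y[m - h + 1L] <- X[h + 1L] / 2
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Resample a record to a new sampling frequency
#'
#' Fourier-domain resampling per lead: deterministic, anti-aliased for
#' band-limited content, duration preserved, output length
#' `round(duration * target_fs)`.
#'
#' @param rec An `"ecg_record"`.
#' @param target_fs Target sampling frequency in Hz (> 0).
#' @return The resampled `"ecg_record"`.
#' @export
resample_record <- function(rec, target_fs) {
  stopifnot(inherits(rec, "ecg_record"))
  if (target_fs <= 0) stop("target_fs must be positive")
  if (target_fs == rec$fs) return(rec)
  m <- as.integer(round(rec$duration * target_fs))
  sig <- t(apply(rec$signal, 1, resample_fft, m = m))
  rec$signal <- sig
  rec$fs <- target_fs
  rec$duration <- m / target_fs
  rec
}

#' Encode diagnosis codes as a 30-bit label vector
#'
#' Bit i is 1 iff the catalog's i-th condition code is present in
#' `dx_labels`.  Codes absent from the catalog are ignored with a warning
#' (records may be annotated only with out-of-scope conditions, yielding
#' the all-zero vector).
#'
#' @param dx_labels Character vector of diagnosis codes.
#' @param catalog A [condition_catalog()].
#' @return Integer vector of length `nrow(catalog)` with entries in {0, 1}.
#' @export
encode_labels <- function(dx_labels, catalog = condition_catalog()) {
  dx <- unique(as.character(dx_labels))
  unknown <- setdiff(dx, catalog$code)
  if (length(unknown))
    warning("ignoring diagnosis codes not in catalog: ",
            paste(unknown, collapse = ", "))
  as.integer(catalog$code %in% dx)
}

#' Assemble a model-ready dataset from a directory of records
#'
#' Reads every `.hea`/`.mat` pair, enforces the 10-second filter, resamples
#' each record to `target_fs`, and stacks signals and encoded labels with
#' index-aligned rows.
#'
#' @param record_dir Directory holding the record pairs.
#' @param target_fs Uniform sampling frequency for the signal tensor.
#' @param catalog A [condition_catalog()].
#' @param duration_tol Tolerance passed to [filter_ten_second()]; records
#'   outside it abort the build (the corpus is expected to be pre-filtered).
#' @return List with `x` (array `(n, l, 12)`, lead order canonical), `y`
#'   (matrix `(n, n_conditions)`), `ids` (character vector).
#' @export
build_dataset <- function(record_dir, target_fs,
                          catalog = condition_catalog(),
                          duration_tol = 0) {
  headers <- sort(list.files(record_dir, pattern = "\\.hea$",
                             full.names = TRUE))
  if (!length(headers)) stop("no .hea files found in ", record_dir)
  records <- lapply(headers, read_record)
  flt <- filter_ten_second(records, tol = duration_tol)
  if (flt$n_excluded > 0)
    stop(flt$n_excluded, " record(s) are not 10 s within tolerance: ",
         paste(vapply(flt$excluded, `[[`, "", "record_id"),
               collapse = ", "))
  records <- lapply(flt$kept, resample_record, target_fs = target_fs)
  l <- ncol(records[[1]]$signal)
  n <- length(records)
  x <- array(NA_real_, c(n, l, 12L))
  y <- matrix(NA_integer_, n, nrow(catalog))
  ids <- character(n)
  for (i in seq_len(n)) {
    x[i, , ] <- t(records[[i]]$signal)
    y[i, ] <- suppressWarnings(encode_labels(records[[i]]$dx_labels,
                                             catalog))
    ids[i] <- records[[i]]$record_id
  }
  list(x = x, y = y, ids = ids, fs = target_fs)
}
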