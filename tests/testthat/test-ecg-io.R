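test_that("header + MAT pair round-trips a record bit-exactly", {
  dir <- withr::local_tempdir()
  rec <- random_record(fs = 500, seed = 1,
                       dx = c("164889003", "59118001"))
  paths <- write_record(rec, dir)
  expect_true(all(file.exists(paths)))
  back <- read_record(paths[["header"]])
  expect_identical(back$signal, rec$signal)
  expect_equal(back$fs, 500)
  expect_equal(back$duration, 10)
  expect_equal(ncol(back$signal), 5000)
  expect_equal(back$age, 57)
  expect_equal(back$sex, "female")
  expect_setequal(back$dx_labels, c("164889003", "59118001"))
})

test_that("record with no diagnoses reads back with an empty label set", {
  dir <- withr::local_tempdir()
  rec <- random_record(id = "R2", fs = 100, seed = 2)
  paths <- write_record(rec, dir)
  back <- read_record(paths[["header"]])
  expect_length(back$dx_labels, 0)
  expect_equal(encode_labels(back$dx_labels), rep(0L, 30))
})

test_that("write/read round trip is lossless over randomized records", {
  dir <- withr::local_tempdir()
  for (i in 1:100) {
    rec <- random_record(id = sprintf("P%03d", i), fs = 40, seed = i)
    write_record(rec, dir)
    back <- read_record(file.path(dir, paste0(rec$record_id, ".hea")))
    expect_identical(back$signal, rec$signal)
  }
})

test_that("malformed headers and wrong lead counts are rejected", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.hea")
  writeLines("bad twelve", bad)
  expect_error(read_record(bad), "malformed header line")
  writeLines(c("bad 8 500 5000", rep("bad.mat 16 1000/mV 16 0 0 0 0 I", 8)),
             bad)
  expect_error(read_record(bad), "expected 12 leads")
})

test_that("ten-second filter partitions the stream and keeps order", {
  recs <- list(random_record("A", fs = 50, seed = 1),
               ecgception:::new_ecg_record(
                 "B", matrix(0, 12, 1500), 50),          # 30 s
               random_record("C", fs = 50, seed = 2),
               ecgception:::new_ecg_record(
                 "D", matrix(0, 12, 400), 50))           # 8 s
  flt <- filter_ten_second(recs, tol = 0)
  expect_equal(flt$n_kept, 2)
  expect_equal(flt$n_excluded, 2)
  expect_equal(vapply(flt$kept, `[[`, "", "record_id"), c("A", "C"))
  expect_equal(vapply(flt$excluded, `[[`, "", "record_id"), c("B", "D"))
  expect_equal(flt$n_kept + flt$n_excluded, length(recs))

  empty <- filter_ten_second(list())
  expect_equal(empty$n_kept, 0)
  expect_equal(empty$n_excluded, 0)
})

test_that("resampling preserves duration and matches a sinusoid oracle", {
  fs <- 500; n <- 5000
  t <- (0:(n - 1)) / fs
  sig <- matrix(rep(sin(2 * pi * 5 * t), each = 12), 12, n, byrow = FALSE)
  rec <- ecgception:::new_ecg_record("S", sig, fs)
  out <- resample_record(rec, 75)
  expect_equal(ncol(out$signal), 750)
  expect_equal(out$duration, 10)

  out100 <- resample_record(rec, 100)
  t2 <- (0:(1000 - 1)) / 100
  inner <- 26:975                       # away from the record edges
  expect_lt(max(abs(out100$signal[1, inner] -
                    sin(2 * pi * 5 * t2[inner]))), 1e-3)

  expect_identical(resample_record(rec, fs)$signal, sig)
  expect_error(resample_record(rec, 0), "positive")
})

test_that("down-up resampling round trip recovers band-limited signals", {
  fs <- 500; n <- 5000
  for (seed in 1:5) {
    x <- bandlimited_signal(n, fs, max_hz = 10, seed = seed)
    down <- ecgception:::resample_fft(x, 1000)
    back <- ecgception:::resample_fft(down, n)
    inner <- 101:4900
    expect_lt(max(abs(back[inner] - x[inner])), 1e-2 * max(abs(x)))
  }
})

test_that("label encoding is 30-wide, order-invariant, warns on unknowns", {
  catalog <- condition_catalog()
  expect_equal(nrow(catalog), 30)
  expect_equal(anyDuplicated(catalog$code), 0)

  af <- catalog$code[catalog$abbreviation == "AF"]
  v <- encode_labels(af, catalog)
  expect_length(v, 30)
  expect_equal(sum(v), 1)
  expect_equal(which(v == 1), which(catalog$abbreviation == "AF"))

  expect_equal(encode_labels(character(0), catalog), rep(0L, 30))

  two <- c(catalog$code[5], catalog$code[12])
  expect_identical(encode_labels(two, catalog),
                   encode_labels(rev(two), catalog))

  expect_warning(v2 <- encode_labels(c(af, "999999"), catalog),
                 "not in catalog")
  expect_equal(sum(v2), 1)
  expect_true(all(v2 %in% c(0L, 1L)))
})

test_that("build_dataset stacks aligned tensors at the target frequency", {
  dir <- withr::local_tempdir()
  spec <- synthetic_spec(20, fs = 500, n_classes = 3, prevalence = 0.4,
                         seed = 3)
  ds <- generate_corpus(spec, dir)
  built <- build_dataset(dir, target_fs = 75)
  expect_equal(dim(built$x), c(20, 750, 12))
  expect_equal(dim(built$y), c(20, 30))
  expect_equal(built$ids, ds$ids)
  # labels survive the disk round trip, in catalog positions
  expect_equal(unname(built$y[, spec$condition_indices]), unname(ds$y))
  expect_true(all(built$y[, -spec$condition_indices] == 0))

  one <- withr::local_tempdir()
  generate_corpus(synthetic_spec(1, fs = 250, n_classes = 2, seed = 4), one)
  single <- build_dataset(one, target_fs = 250)
  expect_equal(dim(single$x), c(1, 2500, 12))
})

test_that("mixed native frequencies become uniform after resampling", {
  dir <- withr::local_tempdir()
  generate_corpus(synthetic_spec(3, fs = 500, n_classes = 2, seed = 5), dir)
  spec257 <- synthetic_spec(2, fs = 257, n_classes = 2, seed = 6)
  ds257 <- synth_dataset(spec257)
  for (i in 1:2) {
    rec <- ecgception:::new_ecg_record(paste0("Z", i), t(ds257$x[i, , ]),
                                       257, dx_labels = character(0))
    write_record(rec, dir)
  }
  built <- build_dataset(dir, target_fs = 75)
  expect_equal(dim(built$x), c(5, 750, 12))
})
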