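test_that("plain-text signal reading parses values in file order", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0.0", "1.5", "-0.5"), f)
  rec <- read_signal_csv(f, fs = 1000, record_id = "r1")
  expect_s3_class(rec, "ecg_record")
  expect_equal(rec$n, 3L)
  expect_equal(rec$samples, c(0.0, 1.5, -0.5))
  expect_equal(rec$fs, 1000)
})

test_that("signal reading rejects degenerate input with informative errors", {
  empty <- withr::local_tempfile()
  writeLines(character(0), empty)
  expect_error(read_signal_csv(empty, fs = 1000), "empty")
  bad <- withr::local_tempfile()
  writeLines(c("1.0", "abc", "2.0"), bad)
  expect_error(read_signal_csv(bad, fs = 1000), "line 2")
  expect_error(read_signal_csv(tempfile(), fs = 1000), "not found")
  good <- withr::local_tempfile()
  writeLines("1.0", good)
  expect_error(read_signal_csv(good, fs = -1), "fs")
})

test_that("delimited signals honour the column selector", {
  f <- withr::local_tempfile()
  writeLines(c("0.001,0.5", "0.002,0.7"), f)
  rec <- read_signal_csv(f, fs = 500, column = 2)
  expect_equal(rec$samples, c(0.5, 0.7))
})

test_that("annotation reading sorts, deduplicates and validates", {
  f <- withr::local_tempfile()
  writeLines(c("100", "350", "600"), f)
  ann <- read_annotations(f, kind = "fetal_reference")
  expect_equal(ann$indices, c(100L, 350L, 600L))

  writeLines(c("350", "100"), f)
  expect_equal(read_annotations(f)$indices, c(100L, 350L))

  writeLines(c("100", "100", "350"), f)
  expect_warning(ann <- read_annotations(f), "duplicate")
  expect_equal(ann$indices, c(100L, 350L))

  writeLines("-5", f)
  expect_error(read_annotations(f), "negative")
  writeLines("12.5", f)
  expect_error(read_annotations(f), "integer")
})

test_that("detection writing round-trips through annotation reading", {
  ann <- annotation_set(c(10, 20), kind = "fetal_detected")
  f <- withr::local_tempfile()
  write_detections(ann, f)
  expect_equal(readLines(f), c("10", "20"))
  expect_equal(read_annotations(f, kind = "fetal_detected")$indices,
               ann$indices)

  set.seed(99)
  idx <- sort(sample.int(3e5, 1000)) - 1L
  big <- annotation_set(idx, kind = "fetal_detected")
  write_detections(big, f)
  expect_identical(read_annotations(f, kind = "fetal_detected")$indices, idx)

  write_detections(annotation_set(integer(0), kind = "fetal_detected"), f)
  expect_equal(length(read_annotations(f)$indices), 0L)
})

test_that("CSV detection output carries index, time and label", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_detections(annotation_set(c(500, 1500), kind = "fetal_detected"),
                   f, csv = TRUE, fs = 1000)
  df <- read.csv(f)
  expect_equal(df$index, c(500, 1500))
  expect_equal(df$time_s, c(0.5, 1.5))
  expect_equal(unique(df$label), "fetal_detected")
})

test_that("WFDB records round-trip within ADC quantisation", {
  set.seed(4)
  ch1 <- ecg_record(round(rnorm(400, sd = 0.5), 3), fs = 1000, channel = "Ab-1")
  ch2 <- ecg_record(round(rnorm(400, sd = 0.5), 3), fs = 1000, channel = "Ab-2")
  stem <- file.path(withr::local_tempdir(), "synthrec")
  write_wfdb_record(list(ch1, ch2), stem, gain = 1000)
  back <- read_wfdb_record(stem, channel = 2)
  expect_equal(back$fs, 1000)
  expect_equal(back$n, 400L)
  expect_lt(max(abs(back$samples - ch2$samples)), 1 / 1000 + 1e-12)
  by_name <- read_wfdb_record(stem, channel = "Ab-1")
  expect_lt(max(abs(by_name$samples - ch1$samples)), 1 / 1000 + 1e-12)
})

test_that("WFDB channel errors list what is available", {
  stem <- file.path(withr::local_tempdir(), "rec")
  write_wfdb_record(ecg_record(sin(1:100 / 5), fs = 250, channel = "Ab-1"),
                    stem)
  expect_error(read_wfdb_record(stem, channel = "Ab-9"), "Ab-1")
  expect_error(read_wfdb_record(stem, channel = 3), "out of range")
  expect_error(read_wfdb_record(file.path(tempdir(), "nope"), 1),
               "header not found")
})

test_that("WFDB annotation files round-trip including long intervals", {
  idx <- c(5L, 900L, 2000L, 70000L, 70100L)   # includes a >1023-sample jump
  f <- withr::local_tempfile(fileext = ".atr")
  fhrcluster:::write_wfdb_annotation_file(idx, f)
  ann <- read_annotations(f, kind = "fetal_reference", dialect = "wfdb")
  expect_identical(ann$indices, idx)
})
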