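test_that("ADC samples convert to millivolts via the header gain", {
  dir <- withr::local_tempdir()
  write_mat_val(c(1000, -1000), file.path(dir, "G00001.mat"))
  write_wfdb_header("G00001", 2, file.path(dir, "G00001.hea"),
                    fs = 300, gain = 1000)
  rec <- read_record(file.path(dir, "G00001.mat"))
  expect_equal(rec$signal, c(1.0, -1.0))
  expect_equal(rec$fs, 300)

  # gain other than the convention is honoured
  write_mat_val(c(500), file.path(dir, "G00002.mat"))
  write_wfdb_header("G00002", 1, file.path(dir, "G00002.hea"),
                    fs = 250, gain = 200)
  rec2 <- read_record(file.path(dir, "G00002.mat"))
  expect_equal(rec2$signal, 2.5)
  expect_equal(rec2$fs, 250)
})

test_that("an 18,000-sample record at 300 Hz spans 60 seconds", {
  dir <- withr::local_tempdir()
  write_fixture_records(dir, n = 1, n_samples = 18000, fs = 300)
  rec <- read_record(file.path(dir, "R00001.mat"))
  expect_equal(duration_s(rec), 60)
})

test_that("degenerate containers and headerless records are handled", {
  dir <- withr::local_tempdir()
  empty <- file.path(dir, "E00001.mat")
  file.create(empty)
  expect_error(read_record(empty), "empty")

  # no header: CinC conventions (300 Hz, gain 1000)
  write_mat_val(c(1000, 2000), file.path(dir, "H00001.mat"))
  rec <- read_record(file.path(dir, "H00001.mat"))
  expect_equal(rec$fs, 300)
  expect_equal(rec$signal, c(1, 2))
})

test_that("label tables parse, reject duplicates and unknown symbols", {
  f <- withr::local_tempfile(lines = c("A00001,N", "A00002,A"))
  tab <- read_labels(f)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$label, c("N", "A"))

  dup <- withr::local_tempfile(lines = c("A00001,N", "A00001,A"))
  expect_error(read_labels(dup), "duplicate")

  bad <- withr::local_tempfile(lines = c("A00001,X"))
  expect_error(read_labels(bad), "outside")
})

test_that("records absent from the label table get label unknown", {
  dir <- withr::local_tempdir()
  write_fixture_records(dir, n = 3, n_samples = 600)
  labels <- withr::local_tempfile(lines = c("R00001,A", "R00003,O"))
  recs <- load_dataset(dir, labels)
  expect_equal(vapply(recs, function(r) r$label, character(1)),
               c("A", "unknown", "O"))
})

test_that("written records re-read bitwise-identical (round trip)", {
  dir <- withr::local_tempdir()
  set.seed(42)
  x <- round(rnorm(3000, sd = 0.5) * 1000) / 1000   # on the int16 mV grid
  rec <- ecg_record("T00001", x, 300, "A")
  write_record(rec, dir)
  back <- read_record(file.path(dir, "T00001.mat"))
  expect_identical(back$signal, rec$signal)
  expect_identical(back$fs, rec$fs)
  expect_identical(back$record_id, rec$record_id)

  # synthetic records use the same grid, so the whole layout round-trips
  recs <- synth_dataset(c(A = 2, N = 2), base_seed = 5,
                        duration_range = c(9, 12))
  write_dataset(recs, file.path(dir, "ds"))
  reread <- load_dataset(file.path(dir, "ds"),
                         file.path(dir, "ds", "REFERENCE.csv"))
  for (i in seq_along(recs)) {
    expect_identical(reread[[i]]$signal, recs[[i]]$signal)
    expect_identical(reread[[i]]$label, recs[[i]]$label)
  }
})

test_that("dataset loads are deterministic, ordered, and skip corrupt files", {
  dir <- withr::local_tempdir()
  write_fixture_records(dir, n = 3, n_samples = 600)
  writeLines("not a mat file", file.path(dir, "R00000.mat"))

  recs <- suppressWarnings(load_dataset(dir))
  expect_length(recs, 3)
  expect_equal(attr(recs, "skipped"), 1L)
  ids <- vapply(recs, function(r) r$record_id, character(1))
  expect_equal(ids, sort(ids))

  recs2 <- suppressWarnings(load_dataset(dir))
  expect_identical(lapply(recs, `[[`, "signal"),
                   lapply(recs2, `[[`, "signal"))

  expect_error(load_dataset(dir, strict = TRUE), "failed to read")
})
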