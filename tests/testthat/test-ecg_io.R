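test_that("CSV dialect round-trips bit-identically and duration arithmetic holds", {
  set.seed(42)
  sig <- matrix(rnorm(180 * 3), ncol = 3,
                dimnames = list(NULL, c("V2", "V3", "V4")))
  rec <- ecg_record(sig, fs = 180)
  expect_equal(rec$duration, 1.0)
  expect_equal(rec$lead_names, c("V2", "V3", "V4"))
  p <- tempfile(fileext = ".csv")
  write_record(rec, p)
  rec2 <- read_record(p, "csv")
  expect_identical(rec2$signal[, "V2"], rec$signal[, "V2"])
  expect_equal(rec2$fs, 180, tolerance = 1e-9)
  # second round trip is byte-identical
  p2 <- tempfile(fileext = ".csv")
  write_record(rec2, p2)
  expect_identical(readLines(p), readLines(p2))
})

test_that("a 12-lead 180 Hz record keeps all leads and its sampling rate", {
  sig <- matrix(0, 360, 12)
  colnames(sig) <- c("I", "II", "III", "aVR", "aVL", "aVF", paste0("V", 1:6))
  rec <- ecg_record(sig, fs = 180)
  p <- tempfile(fileext = ".csv")
  write_record(rec, p)
  rec2 <- read_record(p, "csv")
  expect_length(rec2$lead_names, 12)
  expect_equal(rec2$fs, 180, tolerance = 1e-9)
  expect_equal(rec2$duration, 2.0, tolerance = 1e-9)
})

test_that("max_duration_s truncates the excerpt", {
  rec <- ecg_record(matrix(0, 180 * 30, 1), fs = 180)
  p <- tempfile(fileext = ".csv")
  write_record(rec, p)
  rec2 <- read_record(p, "csv", max_duration_s = 10)
  expect_equal(rec2$duration, 10, tolerance = 1e-9)
})

test_that("malformed CSV input is rejected", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), p)
  expect_error(read_record(p, "csv"), "time_s")
  expect_error(read_record(tempfile(), "csv"), "cannot read")
})

test_that("WFDB format-16 records are read with gain and baseline applied", {
  dir <- tempfile(); dir.create(dir)
  # two signals, 5 samples, gain 200 adu/mV, baselines 0 and 100
  adus <- rbind(c(200L, 300L), c(-200L, 100L), c(0L, 500L),
                c(400L, 100L), c(100L, 100L))
  dat <- file.path(dir, "rec01.dat")
  writeBin(as.integer(t(adus)), dat, size = 2, endian = "little")
  writeLines(c("rec01 2 180 5",
               "rec01.dat 16 200(0)/mV 16 0 0 0 0 V2",
               "rec01.dat 16 200(100)/mV 16 0 0 0 0 V3"),
             file.path(dir, "rec01.hea"))
  rec <- read_record(file.path(dir, "rec01"), "wfdb")
  expect_equal(rec$fs, 180)
  expect_equal(rec$lead_names, c("V2", "V3"))
  expect_equal(rec$signal[, "V2"], adus[, 1] / 200)
  expect_equal(rec$signal[, "V3"], (adus[, 2] - 100) / 200)
  # header/file inconsistency is a format error
  writeLines(c("rec01 2 180 7",
               "rec01.dat 16 200(0)/mV 16 0 0 0 0 V2",
               "rec01.dat 16 200(100)/mV 16 0 0 0 0 V3"),
             file.path(dir, "rec01.hea"))
  expect_error(read_record(file.path(dir, "rec01"), "wfdb"), "mismatch")
})

test_that("lead ranking follows injected noise and ignores common rescaling", {
  bs <- flat_series(40)
  clean <- synthesize_waveform(bs, fs = 180)$signal[, 1]
  set.seed(7)
  sig <- cbind(V2 = clean + rnorm(length(clean), 0, 0.05),
               V3 = clean + rnorm(length(clean), 0, 0.2))
  rec <- ecg_record(sig, fs = 180)
  rq <- rank_leads(rec, c("V2", "V3"))
  expect_equal(rq$lead_name[1], "V2")
  expect_true(all(rq$delineable))
  expect_true(all(diff(rq$snr_db) <= 0))
  # common positive rescaling leaves the ordering unchanged
  rq2 <- rank_leads(ecg_record(sig * 3.7, fs = 180), c("V2", "V3"))
  expect_equal(rq2$lead_name, rq$lead_name)
  expect_equal(rq2$snr_db, rq$snr_db, tolerance = 1e-6)
  # singleton candidate set
  expect_equal(rank_leads(rec, "V3")$lead_name, "V3")
})

test_that("a flat lead is marked non-delineable and ranked last", {
  bs <- flat_series(40)
  clean <- synthesize_waveform(bs, fs = 180)$signal[, 1]
  rec <- ecg_record(cbind(V2 = clean, V3 = rep(0, length(clean))), fs = 180)
  rq <- suppressWarnings(rank_leads(rec, c("V2", "V3")))
  expect_equal(rq$lead_name[2], "V3")
  expect_false(rq$delineable[2])
})

test_that("beat-series CSV round-trips", {
  bs <- flat_series(10)
  bs$valid[3] <- FALSE
  bs$qt_ms[3] <- NA
  p <- tempfile(fileext = ".csv")
  write_beat_series(bs, p)
  bs2 <- read_beat_series(p)
  expect_equal(bs2$t, bs$t)
  expect_equal(bs2$valid, bs$valid)
  expect_equal(bs2$qt_ms, bs$qt_ms)
})
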