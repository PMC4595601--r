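test_that("beat detection recovers metronomic and alternating rhythms", {
  rec <- synthesize_waveform(flat_series(60), fs = 180)
  a <- detect_beats(rec, "V2")
  expect_length(a, 60)
  expect_true(all(abs(diff(a) * 1000 - 1000) <= 3))

  rr <- rep(c(600, 1000), 30)
  t2 <- cumsum(rr) / 1000
  bs2 <- beat_series(t2, rr, qt_ms = 400 * (rr / 1000)^(1 / 3), tpe_ms = 80)
  a2 <- detect_beats(synthesize_waveform(bs2, fs = 180), "V2")
  expect_length(a2, 60)
  expect_true(all(abs(diff(a2) * 1000 - rr[-1]) <= 5))
})

test_that("flat or empty signals yield no beats, short records error", {
  z <- ecg_record(matrix(0, 180 * 20, 1, dimnames = list(NULL, "V2")), 180)
  expect_warning(res <- detect_beats(z, "V2"), "flat")
  expect_length(res, 0)
  short <- ecg_record(matrix(rnorm(180 * 5), ncol = 1,
                             dimnames = list(NULL, "V2")), 180)
  expect_error(detect_beats(short, "V2"), "10 s")
  expect_error(detect_beats(z, "V9"), "lead")
})

test_that("delineation recovers requested QT and Tpe within tolerance", {
  rec <- synthesize_waveform(flat_series(60, rr = 1000, qt = 400, tpe = 90),
                             fs = 180)
  d <- delineate(rec, "V2", detect_beats(rec, "V2"))
  v <- d$valid
  expect_gt(sum(v), 50)
  expect_true(all(abs(d$qt_ms[v] - 400) <= 10))
  expect_true(all(abs(d$tpe_ms[v] - 90) <= 10))
  validate_beat_series(d)
})

test_that("delineation is invariant to a constant baseline offset", {
  bs <- flat_series(30)
  r0 <- synthesize_waveform(bs, fs = 180)
  r1 <- synthesize_waveform(bs, fs = 180, baseline_mv = 0.7)
  d0 <- delineate(r0, "V2", detect_beats(r0, "V2"))
  d1 <- delineate(r1, "V2", detect_beats(r1, "V2"))
  expect_equal(d1$qt_ms, d0$qt_ms, tolerance = 1e-3)
  expect_equal(d1$tpe_ms, d0$tpe_ms, tolerance = 1e-3)
})

test_that("valid-beat fraction stays >= 95% under 0.05 mV noise", {
  rec <- synthesize_waveform(flat_series(60), fs = 180, noise_sd_mv = 0.05,
                             seed = 9)
  d <- delineate(rec, "V2", detect_beats(rec, "V2"))
  expect_gte(mean(d$valid[-1]), 0.95)  # beat 1 has no preceding RR
})

test_that("beats clipped at the record edge and absent T waves are invalid", {
  bs <- flat_series(20)
  rec <- synthesize_waveform(bs, fs = 180)
  # truncate so the last beat's T window exceeds the record
  cut <- ecg_record(rec$signal[seq_len(round((max(bs$t) + 0.15) * 180)), ,
                               drop = FALSE], 180)
  a <- detect_beats(cut, "V2")
  d <- delineate(cut, "V2", a)
  expect_false(d$valid[nrow(d)])
  # zero-amplitude T wave
  rec0 <- synthesize_waveform(bs, fs = 180, t_amp_mv = 0)
  d0 <- delineate(rec0, "V2", detect_beats(rec0, "V2"))
  expect_false(any(d0$valid))
  expect_error(delineate(rec, "V2", anchors = 1.0), "2 anchors")
})

test_that("clean_series flags only genuinely implausible beats", {
  bs <- flat_series(200, rr = 800, qt = 400, tpe = 85)
  set.seed(1)
  bs$qt_ms <- bs$qt_ms + rnorm(200, 0, 5)
  out <- clean_series(bs)
  expect_equal(out$valid, bs$valid)  # clean series unchanged
  # one gross QT outlier is exactly the beat invalidated
  bad <- bs
  bad$qt_ms[100] <- 900
  out2 <- clean_series(bad)
  expect_false(out2$valid[100])
  expect_equal(sum(out2$valid), 199)
  # short series returned unchanged with warning
  s3 <- flat_series(3)
  expect_warning(out3 <- clean_series(s3), "shorter")
  expect_equal(out3$valid, s3$valid)
})

test_that("clean_series flags out-of-range RR and ectopic-compensatory pairs", {
  bs <- flat_series(120, rr = 800)
  bs$rr_ms[50] <- 250   # implausibly short
  bs$rr_ms[80] <- 500   # ectopic: -37.5% ...
  bs$rr_ms[81] <- 1100  # ... then +120% compensation
  out <- clean_series(bs)
  expect_false(out$valid[50])
  expect_false(out$valid[80])
  expect_false(out$valid[81])
})
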