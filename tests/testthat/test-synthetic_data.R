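test_that("RR generator honors schedules and is floored", {
  p <- subject_profile(noise_sd_ms = 0, rr_noise_sd_ms = 0, rr_mean_ms = 800,
                       seed = 1,
                       rr_step_schedule = data.frame(time_s = 1e9,
                                                     level_ms = 800))
  rr <- generate_rr(p, 300)
  # zero noise, single level: exactly constant
  expect_true(all(rr == 800))

  sched <- data.frame(time_s = 300, level_ms = 600)
  p2 <- subject_profile(rr_mean_ms = 1000, seed = 2, rr_step_schedule = sched)
  rr2 <- generate_rr(p2, 600)
  t <- cumsum(rr2) / 1000
  lev1 <- mean(rr2[t < 295])
  lev2 <- mean(rr2[t > 330])
  expect_equal(lev1, 1000, tolerance = 5 / 1000)
  expect_equal(lev2, 600, tolerance = 5 / 600)
})

test_that("AR(1) variability can be silenced only through the schedule level", {
  # a constant-level profile still moves with the AR(1) process, but its
  # 1-min-smoothed range stays small relative to scheduled steps
  p <- subject_profile(seed = 3)
  rr <- generate_rr(p, 1200)
  expect_true(all(rr > 300))
  sched <- attr(rr, "schedule")
  expect_gte(nrow(sched), 3)  # default schedule provides >= 3 steps
})

test_that("generated beat series satisfy the series invariants", {
  for (seed in c(1, 9, 33)) {
    p <- subject_profile(t90_true_s = 50 + 30 * seed %% 4, seed = seed)
    bs <- generate_beat_series(p, 900)
    expect_silent(validate_beat_series(bs))
    expect_true(all(bs$tpe_ms < bs$qt_ms))
    expect_true(!is.null(attr(bs, "z_true")))
    z <- attr(bs, "z_true")
    expect_true(all(z >= min(bs$rr_ms) - 1e-9 & z <= max(bs$rr_ms) + 1e-9))
  }
})

test_that("generators are fully deterministic under a fixed seed", {
  p <- subject_profile(seed = 77)
  expect_identical(generate_beat_series(p, 600), generate_beat_series(p, 600))
  co1 <- generate_cohort(n_healthy = 4, n_tdp = 2, seed = 5)
  co2 <- generate_cohort(n_healthy = 4, n_tdp = 2, seed = 5)
  expect_identical(co1$truth, co2$truth)
  r1 <- synthesize_waveform(flat_series(10), noise_sd_mv = 0.05, seed = 3)
  r2 <- synthesize_waveform(flat_series(10), noise_sd_mv = 0.05, seed = 3)
  expect_identical(r1$signal, r2$signal)
})

test_that("waveform synthesis reproduces requested intervals analytically", {
  bs <- flat_series(40, rr = 1000, qt = 400, tpe = 90)
  rec <- synthesize_waveform(bs, fs = 180)
  expect_equal(rec$fs, 180)
  d <- delineate(rec, "V2", detect_beats(rec, "V2"))
  v <- d$valid
  expect_lte(mean(abs(d$qt_ms[v] - 400)), 1000 / 180)
  expect_lte(mean(abs(d$tpe_ms[v] - 90)), 1000 / 180)
  # infeasible request
  bad <- flat_series(5, qt = 80, tpe = 90)
  expect_error(synthesize_waveform(bad), "infeasible")
})

test_that("cohort calibration draws from the published bands", {
  co <- generate_cohort(n_healthy = 25, n_tdp = 3, seed = 11)
  tr <- co$truth
  h <- tr[tr$group == "healthy", ]
  td <- tr[tr$group == "tdp_sotalol", ]
  expect_true(all(h$drest_true >= 0.025 & h$drest_true <= 0.058))
  expect_true(all(td$drest_true >= 0.18 & td$drest_true <= 0.22))
  expect_true(all(h$rr_mean_ms >= 726 & h$rr_mean_ms <= 974))
  # n_tdp = 3 pins the published individual QTc / RR / adaptation values
  expect_setequal(td$qt_c_true_ms, c(548, 436, 480))
  expect_setequal(td$rr_mean_ms, c(944.6, 1158.1, 902.3))
  expect_setequal(td$t90_tpe_true_s, c(292, 268, 251))
  expect_false(anyDuplicated(tr$subject_id) > 0)
})

test_that("healthy t90 calibration reproduces the published percentile band", {
  # the uniform(27, 277) draw has 20-80 percentiles at exactly [77, 227]
  set.seed(99)
  draws <- runif(1e5, 27, 277)
  expect_equal(unname(quantile(draws, c(0.2, 0.8))), c(77, 227),
               tolerance = 0.02)
  co <- generate_cohort(n_healthy = 25, n_tdp = 3, seed = 21)
  h <- co$truth[co$truth$group == "healthy", ]
  expect_true(all(h$t90_tpe_true_s >= 27 & h$t90_tpe_true_s <= 277))
})
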