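test_that("Fridericia and Bazett corrections match direct evaluation", {
  expect_equal(fridericia(400, 1000), 400)
  expect_equal(fridericia(400, 800), 400 / 0.8^(1 / 3), tolerance = 1e-12)
  expect_equal(round(fridericia(400, 800), 1), 430.9)
  expect_equal(bazett(400, 1000), 400)
  expect_equal(bazett(400, 640), 500)
  expect_equal(bazett(0, 777), 0)
  expect_error(fridericia(400, 0), "positive")
  expect_error(bazett(400, -100), "positive")
})

test_that("Fridericia exactly removes the rate dependence it models", {
  set.seed(2)
  rr <- runif(500, 600, 1200)
  qt <- 410 * (rr / 1000)^(1 / 3)
  qtc <- fridericia(qt, rr)
  expect_equal(qtc, rep(410, 500), tolerance = 1e-10)
  # zero residual slope of corrected interval vs RR
  expect_lt(abs(coef(lm(qtc ~ rr))[2]), 1e-12)
})

test_that("DRest is exact on a noise-free linear relation and zero when flat", {
  set.seed(3)
  z_ms <- runif(600, 600, 1200)
  zz <- data.frame(t = seq_len(600) * 0.8, z_ms = z_ms, valid = TRUE)
  bs <- beat_series(zz$t, 900, qt_ms = 400, tpe_ms = 40 + 0.05 * z_ms)
  est <- estimate_drest(bs, zz, n_boot = 0)
  expect_equal(est$drest, 0.05, tolerance = 1e-12)
  bs$tpe_ms <- 80
  expect_equal(estimate_drest(bs, zz, n_boot = 0)$drest, 0)
})

test_that("DRest is scale-equivariant in Tpe and shift-invariant", {
  set.seed(5)
  z_ms <- runif(400, 650, 1150)
  zz <- data.frame(t = seq_len(400) * 0.8, z_ms = z_ms, valid = TRUE)
  tpe <- 70 + 0.04 * (z_ms - 1000) + rnorm(400, 0, 2)
  b1 <- beat_series(zz$t, 900, 400, tpe)
  b2 <- beat_series(zz$t, 900, 400, 3 * tpe)
  b3 <- beat_series(zz$t, 900, 400, tpe + 17)
  e1 <- estimate_drest(b1, zz, n_boot = 0, seed = 2)
  e2 <- estimate_drest(b2, zz, n_boot = 0, seed = 2)
  e3 <- estimate_drest(b3, zz, n_boot = 0, seed = 2)
  expect_equal(e2$drest, 3 * e1$drest, tolerance = 1e-9)
  expect_equal(e3$drest, e1$drest, tolerance = 1e-9)
})

test_that("Theil-Sen and OLS agree on clean data; bootstrap CI covers truth", {
  set.seed(6)
  z_ms <- runif(500, 650, 1150)
  zz <- data.frame(t = seq_len(500) * 0.8, z_ms = z_ms, valid = TRUE)
  bs <- beat_series(zz$t, 900, 400, 80 + 0.05 * (z_ms - 1000) +
                      rnorm(500, 0, 2))
  ts <- estimate_drest(bs, zz, method = "theil_sen", n_boot = 200, seed = 3)
  ol <- estimate_drest(bs, zz, method = "ols", n_boot = 0)
  expect_equal(ts$drest, ol$drest, tolerance = 0.05)
  expect_true(ts$ci_95[1] <= 0.05 && 0.05 <= ts$ci_95[2])
})

test_that("narrow surrogate-RR range flags a low-confidence estimate", {
  set.seed(7)
  z_ms <- runif(300, 790, 810)
  zz <- data.frame(t = seq_len(300) * 0.8, z_ms = z_ms, valid = TRUE)
  bs <- beat_series(zz$t, 800, 400, 80 + rnorm(300, 0, 2))
  expect_warning(est <- estimate_drest(bs, zz, n_boot = 0), "range")
  expect_true(est$low_confidence)
})

test_that("subject reports separate profile archetypes and survive empty input", {
  tdp <- subject_profile(drest_true = 0.20, t90_true_s = 270, tpe0_ms = 105,
                         qt_c_true_ms = 500, rr_mean_ms = 950, seed = 61)
  row <- suppressWarnings(subject_report(generate_beat_series(tdp, 1800),
                                         "T1", "tdp_sotalol", n_boot = 0))
  expect_gte(row$drest, 0.15)
  expect_gte(row$t90_tpe_s, 200)
  healthy <- subject_profile(drest_true = 0.04, t90_true_s = 120,
                             qt_c_true_ms = 395, seed = 62)
  row2 <- suppressWarnings(subject_report(generate_beat_series(healthy, 1800),
                                          "H1", "healthy", n_boot = 0))
  expect_gte(row2$qtc_ms, 376)
  expect_lte(row2$qtc_ms, 467)
  # empty series: all-missing row, no crash
  row3 <- subject_report(beat_series(numeric(0), numeric(0)), "E0")
  expect_true(is.na(row3$drest) && is.na(row3$qtc_ms))
  expect_equal(row3$n_valid_beats, 0L)
})
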