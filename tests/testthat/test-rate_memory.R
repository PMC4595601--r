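# Hand-built memory model for filter-level tests.
manual_model <- function(weights, mean_rr_s = 0.8, profile = "fir",
                         tau_s = NA_real_) {
  structure(list(weights = weights / sum(weights), g = c(a = 1, b = 0),
                 target = "tpe", window_s = 300, mean_rr_s = mean_rr_s,
                 n_lags = length(weights), degenerate = FALSE,
                 low_confidence = FALSE, profile_type = profile,
                 tau_s = tau_s, residual_rmse_ms = 0),
            class = "memory_model")
}

test_that("a delta-at-lag-0 filter reproduces RR and gives immediate adaptation", {
  m <- manual_model(c(1, rep(0, 99)))
  bs <- flat_series(200, rr = 800)
  bs$rr_ms <- 800 + sin(seq_len(200))  # arbitrary variation
  z <- surrogate_rr(m, bs)
  expect_equal(z$z_ms[z$valid], bs$rr_ms[z$valid])
  expect_lt(compute_t90(m), 1)
})

test_that("sum-to-one weights map constant RR to itself", {
  m <- manual_model(exp(-(0:374) / 40))
  bs <- flat_series(500, rr = 800)
  z <- surrogate_rr(m, bs)
  expect_equal(z$z_ms[z$valid], rep(800, sum(z$valid)))
})

test_that("exponential weights give the closed-form step response and t90", {
  rr_s <- 0.8
  tau <- 30
  beta <- exp(-rr_s / tau)
  L <- 375
  m <- manual_model((1 - beta) * beta^(0:(L - 1)), mean_rr_s = rr_s)
  # t90 of the weight profile: tau * ln 10 ~ 69.08 s
  expect_equal(compute_t90(m), 30 * log(10), tolerance = 0.02)
  # step 1000 -> 600 ms crosses 640 ms (90% of the step) at ~tau*ln10 in
  # elapsed time (the time-based exponential form of the same profile)
  m_exp <- manual_model((1 - beta) * beta^(0:(L - 1)), mean_rr_s = rr_s,
                        profile = "exponential", tau_s = tau)
  n1 <- 600
  rr <- c(rep(1000, n1), rep(600, 1500))
  bs <- beat_series(cumsum(rr) / 1000, rr)
  z <- surrogate_rr(m_exp, bs)
  t_step <- bs$t[n1]  # time of last 1000 ms beat; step begins after it
  cross <- bs$t[which(bs$t > t_step & z$z_ms <= 640)[1]] - t_step
  expect_equal(cross, 30 * log(10), tolerance = 0.05)
})

test_that("surrogate filtering is shift-equivariant", {
  m <- manual_model(exp(-(0:149) / 50))
  set.seed(4)
  rr <- 800 + cumsum(rnorm(600, 0, 5))
  bs1 <- beat_series(cumsum(rr) / 1000, rr)
  rr2 <- c(rep(800, 100), rr)
  bs2 <- beat_series(cumsum(rr2) / 1000, rr2)
  z1 <- surrogate_rr(m, bs1)
  z2 <- surrogate_rr(m, bs2)
  expect_equal(z2$z_ms[100 + 200:500], z1$z_ms[200:500], tolerance = 1e-9)
})

test_that("memory fit recovers an exponential generator (tau = 30 s)", {
  p <- subject_profile(drest_true = 0.05, t90_true_s = 30 * log(10),
                       noise_sd_ms = 2, seed = 21)
  bs <- generate_beat_series(p, 1800)
  mm <- fit_memory_model(bs, "tpe")
  expect_lte(mm$residual_rmse_ms, 3)
  expect_equal(compute_t90(mm), 30 * log(10), tolerance = 0.15)
})

test_that("a memoryless target concentrates weight on the current beat", {
  p <- subject_profile(noise_sd_ms = 0, seed = 3)
  rr <- generate_rr(p, 1500)
  bs <- beat_series(cumsum(rr / 1000), rr, qt_ms = 400,
                    tpe_ms = 40 + 0.05 * rr)
  mm <- fit_memory_model(bs, "tpe")
  expect_lt(compute_t90(mm), 5)
  expect_lt(mm$residual_rmse_ms, 1)
})

test_that("constant RR is flagged degenerate with undefined t90", {
  bs <- flat_series(1500, rr = 800)
  expect_warning(mm <- fit_memory_model(bs, "tpe"), "near-constant|degenerate")
  expect_true(mm$degenerate)
  expect_true(is.na(compute_t90(mm)))
})

test_that("weak heart-rate changes trigger the insufficient-changes warning", {
  set.seed(8)
  # slow +/-15 ms drift: identifiable but under the 50 ms requirement
  tt <- cumsum(rep(0.8, 1500))
  rr <- 800 + 15 * sin(2 * pi * tt / 600) + rnorm(1500, 0, 3)
  bs <- beat_series(cumsum(rr / 1000), rr, qt_ms = 400,
                    tpe_ms = 80 + rnorm(1500, 0, 2))
  expect_warning(mm <- fit_memory_model(bs, "tpe"), "insufficient heart-rate")
  expect_true(mm$low_confidence)
})

test_that("t90 is invariant to affine rescaling of the target interval", {
  p <- subject_profile(drest_true = 0.05, t90_true_s = 80, noise_sd_ms = 1,
                       seed = 31)
  bs <- generate_beat_series(p, 1500)
  m1 <- fit_memory_model(bs, "tpe")
  bs2 <- bs
  bs2$tpe_ms <- 3 * bs$tpe_ms + 25
  m2 <- fit_memory_model(bs2, "tpe")
  expect_equal(compute_t90(m2), compute_t90(m1), tolerance = 0.02)
  expect_equal(m2$g[["a"]], 3 * m1$g[["a"]], tolerance = 0.02)
})

test_that("model fit validates its preconditions", {
  expect_error(fit_memory_model(flat_series(50), "tpe"), "10 min")
  p <- subject_profile(seed = 5)
  bs <- generate_beat_series(p, 700)
  expect_error(fit_memory_model(bs, "tpe", window_s = 50), "window_s")
})

test_that("fitted weights are a proper distribution over the window", {
  p <- subject_profile(t90_true_s = 100, noise_sd_ms = 2, seed = 41)
  bs <- generate_beat_series(p, 1500)
  for (prof in c("fir", "exponential")) {
    mm <- fit_memory_model(bs, "tpe", profile = prof)
    expect_true(all(mm$weights >= -1e-12))
    expect_equal(sum(mm$weights), 1, tolerance = 1e-8)
  }
})
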