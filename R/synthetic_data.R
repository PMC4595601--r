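#' Synthetic subject profile
#'
#' Ground-truth parameters for one simulated subject.  The generators built on
#' a profile emulate the statistical structure the biomarker pipeline assumes:
#' an RR process with sustained heart-rate changes, repolarization intervals
#' driven by an exponential rate-memory filter, a stationary linear Tpe-RR
#' relation with slope `drest_true`, and a Fridericia-stationary QT scale.
#'
#' @param drest_true stationary Tpe-vs-RR slope (ms/ms), dimensionless.
#' @param t90_true_s time to 90% adaptation after an RR step, seconds; the
#'   generator's exponential memory time constant is `t90_true_s / log(10)`.
#' @param tpe0_ms Tpe intercept at the reference RR of 1000 ms.
#' @param qt_c_true_ms Fridericia-stationary QT scale: the generated QT is
#'   `qt_c_true_ms * (z/1000)^(1/3)` at surrogate RR `z`.
#' @param noise_sd_ms measurement noise s.d. added to QT and Tpe, ms.
#' @param rr_noise_sd_ms stationary s.d. of the AR(1) short-term RR
#'   variability (lag-1 correlation 0.8); default 15 ms, 0 silences it.
#' @param rr_mean_ms baseline RR level, ms.
#' @param rr_step_schedule data.frame with columns `time_s`, `level_ms`:
#'   piecewise-constant RR level changes (times strictly increasing).  `NULL`
#'   means a default schedule of steps every ~6 min with levels within
#'   +/-15% of `rr_mean_ms`, drawn when the profile is realized.
#' @param resp_amp_ms amplitude of an optional sinusoidal respiratory
#'   component (0.25 Hz), ms.  Default 0 (off).
#' @param seed integer seed making every generator call on this profile
#'   reproducible.
#' @return a list of class `subject_profile`.
#' @export
subject_profile <- function(drest_true = 0.05, t90_true_s = 100,
                            tpe0_ms = 90, qt_c_true_ms = 400,
                            noise_sd_ms = 2, rr_noise_sd_ms = 15,
                            rr_mean_ms = 850,
                            rr_step_schedule = NULL, resp_amp_ms = 0,
                            seed = 1L) {
  stopifnot(drest_true >= 0, noise_sd_ms >= 0, rr_mean_ms > 300,
            t90_true_s > 0)
  if (!is.null(rr_step_schedule)) {
    stopifnot(is.data.frame(rr_step_schedule),
              all(c("time_s", "level_ms") %in% names(rr_step_schedule)),
              !is.unsorted(rr_step_schedule$time_s, strictly = TRUE))
  }
  structure(list(
    drest_true = drest_true, t90_true_s = t90_true_s, tpe0_ms = tpe0_ms,
    qt_c_true_ms = qt_c_true_ms, noise_sd_ms = noise_sd_ms,
    rr_noise_sd_ms = rr_noise_sd_ms,
    rr_mean_ms = rr_mean_ms, rr_step_schedule = rr_step_schedule,
    resp_amp_ms = resp_amp_ms, seed = as.integer(seed)
  ), class = "subject_profile")
}

default_step_schedule <- function(profile, duration_s) {
  # sustained levels of ~5-7 min so that rate-memory transients complete;
  # levels within +/-15% of the baseline keep the smoothed RR range >= 50 ms
  n_steps <- max(3L, floor(duration_s / 360))
  times <- sort(runif(n_steps, 60, duration_s - 120))
  # enforce >= 180 s between steps
  keep <- c(TRUE, diff(times) >= 180)
  times <- times[keep]
  while (length(times) < 3L && duration_s >= 900) {
    times <- sort(unique(c(times, runif(1, 60, duration_s - 120))))
    keep <- c(TRUE, diff(times) >= 120)
    times <- times[keep]
  }
  levels <- profile$rr_mean_ms * runif(length(times), 0.85, 1.15)
  data.frame(time_s = times, level_ms = levels)
}

#' Generate a per-beat RR sequence
#'
#' Piecewise-constant levels following the profile's step schedule, plus AR(1)
#' short-term variability (lag-1 correlation 0.8, stationary s.d.
#' `rr_noise_sd_ms`) and an optional sinusoidal respiratory component.  All RR are floored at
#' 310 ms.
#'
#' @param profile a [subject_profile()].
#' @param duration_s record duration in seconds (>= 600 s recommended for
#'   DRest-grade records).
#' @return numeric vector of per-beat RR intervals in ms, with the realized
#'   step schedule attached as attribute `schedule`.
#' @export
generate_rr <- function(profile, duration_s = 1800) {
  stopifnot(inherits(profile, "subject_profile"), duration_s > 0)
  set.seed(profile$seed)
  sched <- profile$rr_step_schedule
  if (is.null(sched)) sched <- default_step_schedule(profile, duration_s)
  rho <- 0.8; sd_ar <- profile$rr_noise_sd_ms
  n_max <- ceiling(duration_s / 0.3) + 2L
  rr <- numeric(n_max)
  e <- if (sd_ar > 0) rnorm(1, 0, sd_ar) else 0
  tcur <- 0; k <- 0L
  level_at <- function(t) {
    i <- findInterval(t, sched$time_s)
    if (i == 0) profile$rr_mean_ms else sched$level_ms[i]
  }
  while (tcur < duration_s) {
    k <- k + 1L
    resp <- if (profile$resp_amp_ms > 0)
      profile$resp_amp_ms * sin(2 * pi * 0.25 * tcur) else 0
    r <- max(310, level_at(tcur) + e + resp)
    rr[k] <- r
    tcur <- tcur + r / 1000
    e <- if (sd_ar > 0) rho * e + sqrt(1 - rho^2) * rnorm(1, 0, sd_ar) else 0
  }
  out <- rr[seq_len(k)]
  attr(out, "schedule") <- sched
  out
}

# Exponential rate-memory filter: z_k = z_{k-1} + a_k (rr_k - z_{k-1}),
# a_k = 1 - exp(-rr_k/1000/tau_s).  Time-based per-beat decay, z_1 = rr_1.
exp_memory_filter <- function(rr_ms, tau_s) {
  n <- length(rr_ms)
  z <- numeric(n)
  z[1] <- rr_ms[1]
  al <- 1 - exp(-(rr_ms / 1000) / tau_s)
  for (k in seq_len(n)[-1]) z[k] <- z[k - 1] + al[k] * (rr_ms[k] - z[k - 1])
  z
}

#' Generate a beat series with known memory and restitution structure
#'
#' RR comes from [generate_rr()]; the memory-filtered surrogate RR `z` is an
#' exponential filter with time constant `t90_true_s / log(10)`;
#' `Tpe = tpe0 + drest_true * (z - 1000) + noise` and
#' `QT = qt_c_true * (z/1000)^(1/3) + noise`.
#'
#' @inheritParams generate_rr
#' @return a [beat_series()] with the ground-truth surrogate series attached
#'   as attribute `z_true` and the profile as attribute `profile`.
#' @export
generate_beat_series <- function(profile, duration_s = 1800) {
  rr <- generate_rr(profile, duration_s)
  n <- length(rr)
  set.seed(profile$seed + 1000003L)
  tau <- profile$t90_true_s / log(10)
  z <- exp_memory_filter(rr, tau)
  tpe <- profile$tpe0_ms + profile$drest_true * (z - 1000) +
    rnorm(n, 0, profile$noise_sd_ms)
  qt <- profile$qt_c_true_ms * (z / 1000)^(1 / 3) +
    rnorm(n, 0, profile$noise_sd_ms)
  t <- cumsum(rr / 1000)
  t <- t - t[1]
  out <- beat_series(t, rr, qt, tpe, valid = TRUE)
  attr(out, "z_true") <- z
  attr(out, "profile") <- profile
  attr(out, "schedule") <- attr(rr, "schedule")
  out
}

# Truncated Gaussian lobe with exact compact support on [c-k*s, c+k*s]:
# value and first derivative are zero outside; the edge value is subtracted
# and rescaled so the apex amplitude is exactly `a`.
gauss_lobe <- function(t, center, sigma_l, sigma_r = sigma_l, a = 1, k = 3) {
  u <- ifelse(t < center, (t - center) / sigma_l, (t - center) / sigma_r)
  e0 <- exp(-k^2 / 2)
  v <- (exp(-pmin(u^2, k^2) / 2) - e0) / (1 - e0)
  v[abs(u) >= k] <- 0
  a * v
}

# Tangent-method T end of the asymmetric lobe: max downslope of the
# (untruncated) Gaussian fall side is at apex + sigma_r; the tangent there
# intersects the baseline at apex + sigma_r * (2 - e0*exp(1/2)/(1-e0)).
tangent_factor <- function(k = 3) {
  e0 <- exp(-k^2 / 2)
  2 - e0 * exp(0.5) / (1 - e0)
}

#' Synthesize a raw ECG waveform from a beat series
#'
#' Each beat is a sum of compact-support Gaussian lobes (P, Q, R, S) and an
#' asymmetric T wave whose apex location and tangent-method end reproduce the
#' requested per-beat QT and Tpe analytically: the fall-side width is
#' `sigma_f = tpe / tangent_factor()` and the apex is placed so that QRS onset
#' to tangent-T-end equals the requested QT.  QRS onset is 40 ms before the
#' R anchor.
#'
#' @param series a [beat_series()] with `qt_ms` and `tpe_ms` filled in.
#' @param fs sampling rate in Hz (default 180).
#' @param noise_sd_mv additive white Gaussian noise s.d., mV.
#' @param baseline_mv constant baseline offset, mV.
#' @param wander_amp_mv amplitude of a 0.25 Hz sinusoidal baseline wander, mV.
#' @param t_amp_mv T-wave apex amplitude, mV (0 suppresses the T wave).
#' @param lead_name name given to the single generated lead.
#' @param seed seed for the noise (default: derived from the series profile if
#'   present, else 1).
#' @return an [ecg_record()] with one lead.
#' @export
synthesize_waveform <- function(series, fs = 180, noise_sd_mv = 0,
                                baseline_mv = 0, wander_amp_mv = 0,
                                t_amp_mv = 0.35, lead_name = "V2",
                                seed = NULL) {
  stopifnot(inherits(series, "beat_series"))
  ok <- series$valid & !is.na(series$qt_ms) & !is.na(series$tpe_ms)
  if (any(series$tpe_ms[ok] >= series$qt_ms[ok]))
    stop("infeasible request: tpe_ms must be < qt_ms")
  dur <- max(series$t) + 1.0
  n <- ceiling(dur * fs)
  tt <- (seq_len(n) - 1) / fs
  sig <- numeric(n)
  tf <- tangent_factor()
  on_off <- 0.040  # QRS onset 40 ms before R
  for (i in which(ok)) {
    r <- series$t[i]
    onset <- r - on_off
    qt <- series$qt_ms[i] / 1000
    tpe <- series$tpe_ms[i] / 1000
    sf <- tpe / tf
    sr <- 0.5 * sf
    apex <- onset + qt - tf * sf
    w <- which(tt >= r - 0.25 & tt <= onset + qt + 3 * sf)
    if (!length(w)) next
    x <- tt[w]
    v <- gauss_lobe(x, r - 0.140, 0.020, a = 0.12) +          # P
      gauss_lobe(x, onset + 0.018, 0.006, a = -0.15) +        # Q (support at onset)
      gauss_lobe(x, r, 0.007, a = 1.0) +                      # R
      gauss_lobe(x, r + 0.021, 0.007, a = -0.25) +            # S
      gauss_lobe(x, apex, sr, sf, a = t_amp_mv)               # T
    sig[w] <- sig[w] + v
  }
  if (is.null(seed)) {
    p <- attr(series, "profile")
    seed <- if (!is.null(p)) p$seed + 2000003L else 1L
  }
  set.seed(seed)
  if (noise_sd_mv > 0) sig <- sig + rnorm(n, 0, noise_sd_mv)
  sig <- sig + baseline_mv
  if (wander_amp_mv > 0) sig <- sig + wander_amp_mv * sin(2 * pi * 0.25 * tt)
  ecg_record(matrix(sig, ncol = 1, dimnames = list(NULL, lead_name)), fs)
}

#' Generate a two-group synthetic cohort
#'
#' Healthy profiles draw `drest_true` from uniform(0.025, 0.058); TdP profiles
#' from uniform(0.18, 0.22).  Adaptation times, QTc scales, Tpe intercepts and
#' mean RR are drawn from bands calibrated so that generated cohorts
#' reproduce the published healthy 20-80 percentile ranges and the TdP
#' individual values (when `n_tdp = 3`, the three published TdP QTc / RR /
#' t90 values are assigned directly).
#'
#' @param n_healthy,n_tdp group sizes (default 25 and 3).
#' @param seed master seed; each subject receives a derived sub-seed.
#' @param duration_s record duration passed to downstream generators.
#' @return a list with elements `profiles` (named list of
#'   [subject_profile()]), `group` (character vector), and `truth`
#'   (data.frame of the drawn ground-truth parameters).
#' @export
generate_cohort <- function(n_healthy = 25, n_tdp = 3, seed = 7L,
                            duration_s = 1800) {
  stopifnot(n_healthy >= 1, n_tdp >= 1)
  set.seed(seed)
  n <- n_healthy + n_tdp
  group <- c(rep("healthy", n_healthy), rep("tdp_sotalol", n_tdp))
  # healthy bands: calibrated to published 20-80 percentile bounds
  drest <- c(runif(n_healthy, 0.025, 0.058), runif(n_tdp, 0.18, 0.22))
  t90_tpe <- c(runif(n_healthy, 27, 277), runif(n_tdp, 251, 292))
  rr_mean <- c(runif(n_healthy, 726, 974), runif(n_tdp, 900, 1160))
  tpe0 <- c(runif(n_healthy, 78, 104), runif(n_tdp, 90, 120))
  # healthy QTc: skewed mixture so the 20-80 band is ~[384, 407] while the
  # full range extends toward the high tail seen in whole-range reports
  mix <- runif(n_healthy) < 0.15
  qtc <- numeric(n)
  qtc[seq_len(n_healthy)] <- ifelse(mix, runif(n_healthy, 436, 467),
                                    runif(n_healthy, 378, 409))
  qtc[n_healthy + seq_len(n_tdp)] <- if (n_tdp == 3) c(548, 436, 480) else
    runif(n_tdp, 436, 548)
  if (n_tdp == 3) {
    rr_mean[n_healthy + 1:3] <- c(944.6, 1158.1, 902.3)
    t90_tpe[n_healthy + 1:3] <- c(292, 268, 251)
  }
  sub_seed <- sample.int(2^30, n)
  profiles <- vector("list", n)
  ids <- sprintf("%s%02d", ifelse(group == "healthy", "H", "TDP"),
                 c(seq_len(n_healthy), seq_len(n_tdp)))
  for (i in seq_len(n)) {
    profiles[[i]] <- subject_profile(
      drest_true = drest[i], t90_true_s = t90_tpe[i], tpe0_ms = tpe0[i],
      qt_c_true_ms = qtc[i], noise_sd_ms = 2, rr_mean_ms = rr_mean[i],
      seed = sub_seed[i]
    )
  }
  names(profiles) <- ids
  truth <- data.frame(
    subject_id = ids, group = group, drest_true = drest,
    t90_tpe_true_s = t90_tpe, qt_c_true_ms = qtc, tpe0_ms = tpe0,
    rr_mean_ms = rr_mean, seed = sub_seed
  )
  list(profiles = profiles, group = setNames(group, ids), truth = truth,
       duration_s = duration_s)
}
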