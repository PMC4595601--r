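#' Detect beats (R peaks)
#'
#' Band-passed (5-25 Hz Butterworth, zero-phase) derivative-energy detector:
#' the squared derivative of the band-passed lead is integrated over a
#' 120 ms moving window, candidate beats are energy peaks above an adaptive
#' threshold (a fraction of the rolling upper quantile), a 200 ms refractory
#' period is enforced, and each anchor is refined to sub-sample precision by
#' a quadratic fit around the band-passed R apex.
#'
#' @param record an [ecg_record()] of at least 10 s.
#' @param lead lead name.
#' @return numeric vector of R-peak times in seconds (empty, with a warning,
#'   for a flat signal).
#' @export
detect_beats <- function(record, lead) {
  stopifnot(inherits(record, "ecg_record"))
  if (!lead %in% record$lead_names) stop("lead not present: ", lead)
  if (record$duration < 10) stop("record must be at least 10 s")
  x <- record$signal[, lead]
  fs <- record$fs
  if (diff(range(x)) < 1e-9) {
    warning("flat signal: no beats detected")
    return(numeric(0))
  }
  bf <- signal::butter(2, c(5, 25) / (fs / 2), type = "pass")
  xb <- as.numeric(signal::filtfilt(bf, x))
  e <- c(0, diff(xb))^2
  kint <- max(3L, round(0.120 * fs))
  es <- as.numeric(stats::filter(e, rep(1 / kint, kint), sides = 2))
  es[is.na(es)] <- 0
  # adaptive threshold: fraction of the rolling 98th percentile (10 s blocks)
  blk <- max(1L, round(10 * fs))
  nb <- ceiling(length(es) / blk)
  thr <- numeric(length(es))
  for (i in seq_len(nb)) {
    a <- (i - 1L) * blk + 1L; b <- min(length(es), i * blk)
    q <- quantile(es[max(1, a - blk):min(length(es), b + blk)], 0.98)
    thr[a:b] <- 0.2 * q
  }
  above <- es > thr & es > 1e-12
  pk <- which(diff(sign(diff(es))) < 0) + 1L
  pk <- pk[above[pk]]
  if (!length(pk)) {
    warning("no beats detected")
    return(numeric(0))
  }
  # refractory 200 ms: greedy by descending energy
  ord <- pk[order(-es[pk])]
  refr <- round(0.2 * fs)
  keep <- logical(length(x))
  sel <- integer(0)
  for (p in ord) {
    if (!any(keep[max(1, p - refr):min(length(x), p + refr)])) {
      keep[p] <- TRUE
      sel <- c(sel, p)
    }
  }
  sel <- sort(sel)
  # refine anchor to the band-passed R apex with quadratic interpolation
  half <- round(0.08 * fs)
  anchors <- vapply(sel, function(p) {
    a <- max(2L, p - half); b <- min(length(xb) - 1L, p + half)
    i <- a - 1L + which.max(abs(xb[a:b]))
    y0 <- xb[i - 1L]; y1 <- xb[i]; y2 <- xb[i + 1L]
    den <- y0 - 2 * y1 + y2
    d <- if (abs(den) > 1e-12) 0.5 * (y0 - y2) / den else 0
    d <- max(-0.5, min(0.5, d))
    (i - 1L + d) / fs
  }, 0)
  sort(anchors)
}

# resample a window [t0, t1] of a sampled signal onto a 1 kHz grid (cubic
# spline), returning list(t, v); used for sub-sample delineation
upsample_window <- function(x, fs, t0, t1, dt_out = 0.001) {
  i0 <- max(1L, floor(t0 * fs) + 1L)
  i1 <- min(length(x), ceiling(t1 * fs) + 1L)
  if (i1 - i0 < 4) return(NULL)
  tt <- (seq(i0, i1) - 1) / fs
  g <- seq(max(t0, tt[1]), min(t1, tt[length(tt)]), by = dt_out)
  sp <- spline(tt, x[i0:i1], xout = g, method = "natural")
  list(t = sp$x, v = sp$y)
}

smooth_ma <- function(v, k) {
  if (k < 2) return(v)
  s <- as.numeric(stats::filter(v, rep(1 / k, k), sides = 2))
  i <- which(is.na(s))
  s[i] <- v[i]
  s
}

# tangent-method T end: steepest return-to-baseline slope after the apex,
# extrapolated to the isoelectric baseline.  t, v on a fine uniform grid;
# apex_i an index into t.  Returns the crossing time or NA.
tangent_t_end <- function(t, v, baseline, apex_i) {
  if (apex_i >= length(t) - 2) return(NA_real_)
  s <- sign(v[apex_i] - baseline)
  if (s == 0) return(NA_real_)
  dt <- t[2] - t[1]
  dv <- c(diff(v) / dt, NA)
  seg <- seq(apex_i + 1L, length(t) - 1L)
  slopes <- -s * dv[seg]
  im <- seg[which.max(slopes)]
  sl <- dv[im]
  if (!is.finite(sl) || s * sl >= 0) return(NA_real_)
  tend <- t[im] + (baseline - v[im]) / sl
  if (tend <= t[apex_i] || tend > t[length(t)] + 0.08) return(NA_real_)
  tend
}

#' Delineate QRS onset, T apex and T end
#'
#' For each R anchor: the isoelectric baseline is the median of the PR
#' segment (75-45 ms before R); QRS onset is found by backward search for the
#' earliest sustained derivative-threshold crossing within 60 ms before R
#' (threshold: 2% of the QRS's maximal absolute slope, floored at 4x the
#' baseline-segment slope noise); the T apex is the extremum of the
#' low-pass-filtered T window (80 ms after R to `min(600 ms, 0.7 RR)`),
#' refined by a quadratic fit on the lightly smoothed trace; the T end is
#' found by the tangent method (intersection of the maximal-slope tangent
#' after the apex with the baseline).  All searches run on a cubic-spline
#' 1 kHz upsampling of the lead.  Beats failing any search, with a T-wave
#' amplitude below 0.05 mV, or with windows clipped at the record edges are
#' flagged invalid with missing measurements.
#'
#' @param record an [ecg_record()].
#' @param lead lead name.
#' @param anchors R-peak times from [detect_beats()] (>= 2).
#' @return a [beat_series()].
#' @export
delineate <- function(record, lead, anchors) {
  stopifnot(inherits(record, "ecg_record"))
  if (length(anchors) < 2) stop("need >= 2 anchors to define RR intervals")
  x <- record$signal[, lead]
  fs <- record$fs
  dur <- record$duration
  # stage-specific zero-phase low-pass filtering: 40 Hz keeps QRS slopes for
  # the onset search, 15 Hz suppresses noise without touching the T wave
  xq <- as.numeric(signal::filtfilt(signal::butter(4, min(0.9, 40 / (fs / 2)),
                                                   "low"), x))
  xt <- as.numeric(signal::filtfilt(signal::butter(4, min(0.9, 15 / (fs / 2)),
                                                   "low"), x))
  n <- length(anchors)
  rr <- c(NA_real_, diff(anchors) * 1000)
  qt <- tpe <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  for (k in seq_len(n)) {
    r <- anchors[k]
    rr_win <- if (k < n) (anchors[k + 1] - r) * 1000 else rr[k]
    if (!is.finite(rr_win)) next
    t_hi <- r + min(0.600, 0.7 * rr_win / 1000)
    if (r - 0.25 < 0 || t_hi + 0.05 > dur) next  # clipped at record edge
    base_w <- upsample_window(xt, fs, r - 0.075, r - 0.045)
    if (is.null(base_w)) next
    baseline <- median(base_w$v)
    # QRS onset
    on_w <- upsample_window(xq, fs, r - 0.060, r)
    if (is.null(on_w)) next
    dt <- on_w$t[2] - on_w$t[1]
    dv <- abs(c(diff(on_w$v) / dt, 0))
    base_q <- upsample_window(xq, fs, r - 0.075, r - 0.045)
    noise_sl <- mad(diff(base_q$v) / (base_q$t[2] - base_q$t[1]))
    thr <- max(0.02 * max(dv), 4 * noise_sl)
    run <- max(2L, round(0.005 / dt))
    rl <- rle(dv >= thr)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    cand <- starts[rl$values & rl$lengths >= run]
    if (!length(cand)) next
    onset <- on_w$t[cand[1]]
    # T window
    tw <- upsample_window(xt, fs, r + 0.080, t_hi)
    if (is.null(tw)) next
    twq <- upsample_window(xq, fs, r + 0.080, t_hi)
    v_heavy <- smooth_ma(tw$v, 21)   # 21 ms boxcar for robust apex search
    v_light <- smooth_ma(tw$v, 5)
    aj <- which.max(abs(v_heavy - baseline))
    # amplitude check on the wide-band trace (low-pass smearing of the QRS
    # must not masquerade as a T wave)
    if (is.null(twq) || abs(twq$v[min(aj, length(twq$v))] - baseline) < 0.05)
      next
    # apex refinement: least-squares parabola over +/-10 ms of the wide-band
    # trace (unbiased for a smooth apex, robust to sample noise)
    seg <- max(1L, aj - 10L):min(length(twq$t), aj + 10L)
    if (length(seg) >= 7) {
      ts0 <- twq$t[seg] - twq$t[aj]
      cf <- stats::lm.fit(cbind(1, ts0, ts0^2), twq$v[seg])$coefficients
      dfr <- if (is.finite(cf[3]) && abs(cf[3]) > 1e-9)
        -cf[2] / (2 * cf[3]) else 0
      dfr <- max(-0.01, min(0.01, dfr))
      t_apex <- twq$t[aj] + dfr
    } else t_apex <- tw$t[aj]
    t_end <- tangent_t_end(tw$t, v_light, baseline, aj)
    if (is.na(t_end)) next
    qt_k <- (t_end - onset) * 1000
    tpe_k <- (t_end - t_apex) * 1000
    if (!is.finite(qt_k) || !is.finite(tpe_k) || tpe_k <= 0 ||
        tpe_k >= qt_k) next
    qt[k] <- qt_k; tpe[k] <- tpe_k
    valid[k] <- is.finite(rr[k]) && rr[k] > 0
  }
  beat_series(anchors, rr, qt, tpe, valid)
}

#' Mark implausible beats invalid
#'
#' Invalidates: beats with RR outside \[300, 2500\] ms; beats whose QT or Tpe
#' deviates more than 5 median absolute deviations from a 60-beat running
#' median; and ectopic-adjacent beats (an RR change of more than 30% followed
#' by a compensatory change in the opposite direction).  Series shorter than
#' the running-median window are returned unchanged with a warning.
#'
#' @param series a [beat_series()].
#' @param window running-median window in beats (default 60; forced odd).
#' @return the series with updated `valid` flags.
#' @export
clean_series <- function(series, window = 60) {
  stopifnot(inherits(series, "beat_series"))
  n <- nrow(series)
  k <- as.integer(window) %/% 2L * 2L + 1L
  if (n < k) {
    warning("series shorter than the cleaning window (", n, " < ", k,
            "); returned unchanged")
    return(series)
  }
  bad <- rep(FALSE, n)
  rr <- series$rr_ms
  bad <- bad | (!is.na(rr) & (rr < 300 | rr > 2500))
  for (col in c("qt_ms", "tpe_ms")) {
    v <- series[[col]]
    if (all(is.na(v))) next
    vf <- v
    vf[is.na(vf)] <- median(v, na.rm = TRUE)
    rm <- runmed(vf, k, endrule = "median")
    res <- v - rm
    scale <- max(1, mad(res, na.rm = TRUE))
    bad <- bad | (!is.na(res) & abs(res) > 5 * scale)
  }
  # ectopic-adjacent: >30% RR drop/jump followed by a compensatory change
  if (n >= 3) {
    rel <- diff(rr) / rr[-n]
    for (i in seq_len(n - 2)) {
      if (!is.na(rel[i]) && !is.na(rel[i + 1]) &&
          abs(rel[i]) > 0.3 && sign(rel[i + 1]) == -sign(rel[i]) &&
          abs(rel[i + 1]) > 0.3) {
        bad[i + 0:2] <- TRUE
      }
    }
  }
  series$valid <- series$valid & !bad
  series
}
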