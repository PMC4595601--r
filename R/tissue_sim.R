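#' Transmural strand configuration
#'
#' Geometry, heterogeneity and numerics for the 1D transmural cable of ten
#' Tusscher-Panfilov (2006) myocytes.  The strand runs endocardium (stimulated
#' end) through midmyocardial (M) cells to epicardium, with a virtual
#' unipolar electrode on the fiber axis beyond the epicardial end.
#'
#' @param n_nodes number of cable nodes (>= 50).
#' @param dx_mm node spacing in mm; `dx_mm * n_nodes` must lie in
#'   \[10, 20\] mm (transmural wall thickness).
#' @param diffusion_cm2_ms diffusion coefficient in cm^2/ms.  The default
#'   0.0006 is calibrated, with the default 0.15 mm spacing, to a transmural
#'   conduction velocity of about 47 cm/s, in the 40-70 cm/s range reported
#'   for human transmural propagation.
#' @param fractions named fractions of endo, M and epi cells along the strand
#'   (default 0.25 / 0.35 / 0.40); must sum to 1.
#' @param gkr_scale IKr maximal-conductance multiplier: 1.0 for control, 0.5
#'   for the IC50 dose of an IKr blocker such as sotalol.
#' @param dt_ms time step (<= 0.05 ms; Rush-Larsen gate updates).
#' @param stim_nodes number of nodes stimulated at the endocardial end.
#' @param stim_amp_pa_pf,stim_dur_ms stimulus amplitude (pA/pF, negative =
#'   depolarizing in the total-current convention) and duration.
#' @param electrode_mm electrode distance beyond the epicardial end, mm.
#' @param pre_beats pacing beats to approach steady state before measurement.
#' @return a list of class `tissue_config`.
#' @export
tissue_config <- function(n_nodes = 100, dx_mm = 0.15,
                          diffusion_cm2_ms = 0.0006,
                          fractions = c(endo = 0.25, M = 0.35, epi = 0.40),
                          gkr_scale = 1.0, dt_ms = 0.02,
                          stim_nodes = 3, stim_amp_pa_pf = -52,
                          stim_dur_ms = 1, electrode_mm = 20,
                          pre_beats = 50) {
  stopifnot(n_nodes >= 50, gkr_scale > 0, gkr_scale <= 1,
            abs(sum(fractions) - 1) < 1e-9, dt_ms <= 0.05)
  len <- n_nodes * dx_mm
  if (len < 10 || len > 20)
    stop("strand length ", len, " mm outside [10, 20] mm")
  n_endo <- round(fractions[["endo"]] * n_nodes)
  n_m <- round(fractions[["M"]] * n_nodes)
  type_map <- c(rep(0L, n_endo), rep(1L, n_m),
                rep(2L, n_nodes - n_endo - n_m))
  structure(list(
    n_nodes = n_nodes, dx_mm = dx_mm,
    diffusion_mm2_ms = diffusion_cm2_ms * 100,
    type_map = type_map, gkr_scale = gkr_scale, dt_ms = dt_ms,
    stim_nodes = stim_nodes, stim_amp_pa_pf = stim_amp_pa_pf,
    stim_dur_ms = stim_dur_ms, electrode_mm = electrode_mm,
    pre_beats = pre_beats
  ), class = "tissue_config")
}

#' Fast (scaled-down) strand configuration
#'
#' The test/screening profile: 100 nodes and 10 pre-beats per cycle length.
#' Results obtained with it are labeled scaled-down relative to the full
#' profile (50 pre-beats).
#'
#' @param ... overrides passed to [tissue_config()].
#' @export
tissue_config_fast <- function(...) {
  tissue_config(n_nodes = 100, pre_beats = 10, ...)
}

cell_type_code <- function(cell_type) {
  switch(match.arg(cell_type, c("endo", "M", "epi")),
         endo = 0L, M = 1L, epi = 2L)
}

#' Simulate a single paced myocyte
#'
#' Paces one ten Tusscher-Panfilov cell from the published resting state at a
#' fixed cycle length and returns the membrane potential of the last recorded
#' beats on a 1 ms grid.
#'
#' @param cell_type `"endo"`, `"M"` or `"epi"`.
#' @param cl_ms pacing cycle length, ms.
#' @param n_beats number of beats (default 50 approaches steady state).
#' @param gkr_scale IKr conductance multiplier.
#' @param dt_ms integration step.
#' @param n_record_beats how many final beats to record.
#' @return list with `time_ms` (relative to the first recorded beat) and `v`
#'   (mV).
#' @export
simulate_cell <- function(cell_type = "epi", cl_ms = 1000, n_beats = 50,
                          gkr_scale = 1.0, dt_ms = 0.02,
                          n_record_beats = 1) {
  ct <- cell_type_code(cell_type)
  out <- .tp06_run(ct, gkr_scale, cl_ms, as.integer(n_beats), dt_ms,
                   0.0, 0.0, 1L, -52.0, 1.0, as.integer(n_record_beats), 1.0)
  list(time_ms = out$time_ms, v = out$V[, 1], cl_ms = cl_ms)
}

#' Unstimulated resting drift of a single cell
#'
#' Maximum absolute deviation of the membrane potential from its initial
#' resting value over an unstimulated run; a stability check of the
#' integrator and parameter set.
#'
#' @inheritParams simulate_cell
#' @param duration_s unstimulated duration, seconds.
#' @return maximum |V - V(0)| in mV.
#' @export
resting_drift <- function(cell_type = "epi", duration_s = 10, dt_ms = 0.02) {
  .tp06_rest_drift(cell_type_code(cell_type), duration_s * 1000, dt_ms)
}

# APD90 and activation time from a single-beat V(t) trace (1 ms grid,
# t relative to the stimulus).  Returns c(apd90, act_t, rep_t) or NAs.
apd90_from_trace <- function(time_ms, v) {
  if (max(v) < -40) return(c(apd90 = NA_real_, act = NA_real_,
                             rep = NA_real_))
  vrest <- v[1]
  ipk <- which.max(v)
  dv <- diff(v) / diff(time_ms)
  iact <- which.max(dv[seq_len(max(ipk, 2) - 1L)])
  act_t <- time_ms[iact]
  v90 <- max(v) - 0.9 * (max(v) - vrest)
  below <- which(v[-seq_len(ipk)] <= v90)
  if (!length(below)) return(c(apd90 = NA_real_, act = act_t,
                               rep = NA_real_))
  i2 <- ipk + below[1]
  i1 <- i2 - 1L
  rep_t <- time_ms[i1] + (v90 - v[i1]) * (time_ms[i2] - time_ms[i1]) /
    (v[i2] - v[i1])
  c(apd90 = rep_t - act_t, act = act_t, rep = rep_t)
}

#' Steady-state APD90 of a single paced cell
#'
#' @inheritParams simulate_cell
#' @return APD90 in ms for the final beat.
#' @export
cell_apd90 <- function(cell_type = "epi", cl_ms = 1000, n_beats = 50,
                       gkr_scale = 1.0, dt_ms = 0.02) {
  tr <- simulate_cell(cell_type, cl_ms, n_beats, gkr_scale, dt_ms)
  unname(apd90_from_trace(tr$time_ms, tr$v)["apd90"])
}

#' Simulate the transmural strand at one cycle length
#'
#' Paces the strand from the endocardial end and records the final beats'
#' potential field on a 1 ms grid, then derives per-node activation times
#' (maximal dV/dt), repolarization times (90% repolarization crossing) and
#' APD90 for the final beat.  A node that never activates marks the run as
#' conduction-blocked (flagged, not an error).
#'
#' @param config a [tissue_config()].
#' @param cl_ms cycle length (= stationary RR), ms.
#' @param n_beats total beats; defaults to `config$pre_beats + 2`.
#' @param n_record_beats final beats to record (default 2).
#' @return list of class `strand_result`: `time_ms`, `field` (time x node
#'   mV matrix), `act_ms`, `rep_ms`, `apd90_ms` (per node, final beat),
#'   `blocked` flag, `cl_ms`, `config`.
#' @export
simulate_strand <- function(config, cl_ms, n_beats = NULL,
                            n_record_beats = 2) {
  stopifnot(inherits(config, "tissue_config"))
  if (is.null(n_beats)) n_beats <- config$pre_beats + 2L
  out <- .tp06_run(config$type_map, config$gkr_scale, cl_ms,
                   as.integer(n_beats), config$dt_ms, config$dx_mm,
                   config$diffusion_mm2_ms, as.integer(config$stim_nodes),
                   config$stim_amp_pa_pf, config$stim_dur_ms,
                   as.integer(min(n_record_beats, n_beats)), 1.0)
  tm <- out$time_ms
  nrb <- out$n_record_beats
  t0 <- (nrb - 1) * cl_ms
  seg <- which(tm >= t0 - 1e-9)
  n <- config$n_nodes
  act <- rep_t <- apd <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- apd90_from_trace(tm[seg] - t0, out$V[seg, i])
    apd[i] <- a["apd90"]; act[i] <- a["act"]; rep_t[i] <- a["rep"]
  }
  structure(list(
    time_ms = tm, field = out$V, act_ms = act, rep_ms = rep_t,
    apd90_ms = apd, blocked = anyNA(apd), cl_ms = cl_ms, config = config
  ), class = "strand_result")
}

#' Pseudo-ECG of the final recorded beat
#'
#' Far-field unipolar potential at the virtual electrode:
#' `phi(t) = -sum_i dV_i(t) * d(1/r)/dx` over node interfaces, the discrete
#' form of the standard pseudo-ECG integral for a 1D fiber, with the
#' electrode on the axis `electrode_mm` beyond the epicardial end.  The T
#' apex is the maximum of the T window (after the latest activation), and
#' the T end comes from the same tangent method as the clinical delineator.
#'
#' @param strand a [simulate_strand()] result.
#' @return list of class `pseudo_ecg`: `time_ms`, `phi` (arbitrary units,
#'   final beat), `t_apex_ms`, `t_end_ms`, `tpe_ms`, `r_amp`, `t_amp`,
#'   `flagged` (TRUE when no usable T wave was found).
#' @export
pseudo_ecg <- function(strand) {
  stopifnot(inherits(strand, "strand_result"))
  cfg <- strand$config
  n <- cfg$n_nodes
  x_if <- (seq_len(n - 1) - 0.5) * cfg$dx_mm          # interface positions
  xe <- n * cfg$dx_mm + cfg$electrode_mm
  g <- -(x_if - xe) / abs(x_if - xe)^3                # d(1/r)/dx
  tm <- strand$time_ms
  nrb <- round((max(tm) + 1) / strand$cl_ms)  # recorded beats
  t0 <- (nrb - 1) * strand$cl_ms              # final beat start
  seg <- which(tm >= t0 - 1e-9)
  dV <- strand$field[seg, -1, drop = FALSE] -
    strand$field[seg, -n, drop = FALSE]
  phi <- -as.numeric(dV %*% g)
  tt <- tm[seg] - t0
  base <- mean(phi[tt > strand$cl_ms - 20])
  r_amp <- max(phi) - base
  out <- list(time_ms = tt, phi = phi, t_apex_ms = NA_real_,
              t_end_ms = NA_real_, tpe_ms = NA_real_, r_amp = r_amp,
              t_amp = NA_real_, flagged = TRUE)
  class(out) <- "pseudo_ecg"
  if (strand$blocked || all(is.na(strand$act_ms))) return(out)
  tw0 <- max(strand$act_ms, na.rm = TRUE) + 40
  win <- which(tt >= tw0 & tt <= strand$cl_ms - 10)
  if (length(win) < 20) return(out)
  ai <- win[which.max(phi[win])]
  t_amp <- phi[ai] - base
  out$t_amp <- t_amp
  if (!is.finite(t_amp) || t_amp < 0.02 * r_amp) return(out)
  tend <- tangent_t_end(tt[win], phi[win], base, which(win == ai))
  if (is.na(tend)) return(out)
  out$t_apex_ms <- tt[ai]
  out$t_end_ms <- tend
  out$tpe_ms <- tend - tt[ai]
  out$flagged <- FALSE
  out
}

#' Dynamic restitution over a grid of stationary cycle lengths
#'
#' For each RR level the strand is paced to (approximate) steady state and
#' the per-node APD90 and pseudo-ECG Tpe are recorded.  Restitution slopes
#' are centered finite differences on the RR grid (forward/backward at the
#' ends); `alpha1`/`alpha2` are the maximal/minimal slope across nodes at
#' each RR, `drest_spatial = alpha1 - alpha2`, and `drest_ecg = dTpe/dRR`.
#'
#' @param config a [tissue_config()].
#' @param rr_grid_ms stationary cycle lengths, ms, within \[500, 1500\],
#'   >= 4 levels (default 500 to 1500 in steps of 250).
#' @param n_beats beats per level (default `config$pre_beats + 2`).
#' @param verbose print progress.
#' @return list of class `restitution_set`: `rr_grid_ms`, `apd90` (node x RR
#'   matrix), `tpe_ms`, `slopes` (node x RR), `alpha1`, `alpha2`,
#'   `drest_spatial`, `drest_ecg`, `blocked` (per-RR flag).
#' @export
dynamic_restitution <- function(config, rr_grid_ms = seq(500, 1500, by = 250),
                                n_beats = NULL, verbose = FALSE) {
  stopifnot(length(rr_grid_ms) >= 4,
            all(rr_grid_ms >= 500 & rr_grid_ms <= 1500))
  rr_grid_ms <- sort(rr_grid_ms)
  n <- config$n_nodes
  nr <- length(rr_grid_ms)
  apd <- matrix(NA_real_, n, nr)
  tpe <- rep(NA_real_, nr)
  blocked <- logical(nr)
  for (j in seq_len(nr)) {
    if (verbose) message("RR = ", rr_grid_ms[j], " ms")
    st <- simulate_strand(config, rr_grid_ms[j], n_beats)
    blocked[j] <- st$blocked
    if (!st$blocked) {
      apd[, j] <- st$apd90_ms
      pe <- pseudo_ecg(st)
      tpe[j] <- pe$tpe_ms
    }
  }
  grad_grid <- function(y, x) {
    m <- length(x)
    g <- rep(NA_real_, m)
    for (k in seq_len(m)) {
      lo <- if (k == 1) 1 else k - 1
      hi <- if (k == m) m else k + 1
      g[k] <- (y[hi] - y[lo]) / (x[hi] - x[lo])
    }
    g
  }
  slopes <- t(apply(apd, 1, grad_grid, x = rr_grid_ms))
  alpha1 <- apply(slopes, 2, max)
  alpha2 <- apply(slopes, 2, min)
  structure(list(
    rr_grid_ms = rr_grid_ms, apd90 = apd, tpe_ms = tpe, slopes = slopes,
    alpha1 = alpha1, alpha2 = alpha2, drest_spatial = alpha1 - alpha2,
    drest_ecg = grad_grid(tpe, rr_grid_ms), blocked = blocked,
    gkr_scale = config$gkr_scale
  ), class = "restitution_set")
}

#' Interpolate the ECG-derived restitution-dispersion index at an RR
#'
#' Linear interpolation of `drest_ecg(RR)` between grid points.
#'
#' @param set a [dynamic_restitution()] result.
#' @param rr_ms evaluation RR(s), ms.
#' @return interpolated dTpe/dRR value(s).
#' @export
drest_ecg_at <- function(set, rr_ms) {
  stopifnot(inherits(set, "restitution_set"))
  ok <- is.finite(set$drest_ecg)
  approx(set$rr_grid_ms[ok], set$drest_ecg[ok], xout = rr_ms, rule = 2)$y
}
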