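#' Fridericia rate correction
#'
#' Divides an interval by the cube root of the RR interval in seconds:
#' `corrected = interval / (rr/1000)^(1/3)`.  Used for both QTc and Tpec.
#'
#' @param interval_ms interval to correct, ms (QT or Tpe).
#' @param rr_ms RR interval, ms (must be positive).
#' @return corrected interval in ms.
#' @export
fridericia <- function(interval_ms, rr_ms) {
  if (any(!is.na(rr_ms) & rr_ms <= 0)) stop("rr_ms must be positive")
  interval_ms / (rr_ms / 1000)^(1 / 3)
}

#' Bazett rate correction
#'
#' `corrected = interval / (rr/1000)^(1/2)`.
#'
#' @inheritParams fridericia
#' @return corrected interval in ms.
#' @export
bazett <- function(interval_ms, rr_ms) {
  if (any(!is.na(rr_ms) & rr_ms <= 0)) stop("rr_ms must be positive")
  interval_ms / (rr_ms / 1000)^(1 / 2)
}

theil_sen_slope <- function(x, y, max_pairs = 2e5) {
  n <- length(x)
  if (n > 650) {
    i <- sample.int(n, max_pairs, replace = TRUE)
    j <- sample.int(n, max_pairs, replace = TRUE)
    keep <- x[i] != x[j]
    median((y[i] - y[j])[keep] / (x[i] - x[j])[keep])
  } else {
    dx <- outer(x, x, "-"); dy <- outer(y, y, "-")
    keep <- upper.tri(dx) & dx != 0
    median(dy[keep] / dx[keep])
  }
}

#' Estimate the restitution-dispersion index DRest
#'
#' DRest is the ratio `dTpe / dRR` between stationary states.  With
#' free-living (non-stationary) RR it is realized as the slope of a robust
#' linear fit of Tpe against the memory-compensated surrogate RR `z`, which
#' removes the rate-memory (hysteresis) effect so that each beat's Tpe is
#' paired with its effective stationary RR.  Theil-Sen is the default slope
#' (median of pairwise slopes); OLS is available as a cross-check.
#'
#' @param series a [beat_series()].
#' @param z a [surrogate_rr()] series aligned with `series`.
#' @param method `"theil_sen"` (default) or `"ols"`.
#' @param n_boot bootstrap resamples (over beats) for the 95% CI; default 1000.
#' @param seed seed for the bootstrap and for pair subsampling.
#' @return a list of class `drest_estimate`: `drest` (ms/ms), `ci_95`,
#'   `rr_range_ms` (range of `z` used), `n_beats`, `method`,
#'   `low_confidence` flag (set when the z range is < 50 ms or fewer than
#'   100 joint valid beats are available).
#' @export
estimate_drest <- function(series, z, method = c("theil_sen", "ols"),
                           n_boot = 1000, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(series, "beat_series"), nrow(series) == nrow(z))
  ok <- series$valid & z$valid & is.finite(series$tpe_ms) & is.finite(z$z_ms)
  x <- z$z_ms[ok]; y <- series$tpe_ms[ok]
  n <- length(x)
  low <- FALSE
  if (n < 100) {
    warning("fewer than 100 joint valid beats; DRest flagged low-confidence")
    low <- TRUE
  }
  if (n >= 2 && diff(range(x)) < 50) {
    warning("surrogate-RR range < 50 ms; DRest flagged low-confidence ",
            "(sustained heart-rate changes are required)")
    low <- TRUE
  }
  if (n < 2) {
    out <- list(drest = NA_real_, ci_95 = c(NA_real_, NA_real_),
                rr_range_ms = c(NA_real_, NA_real_), n_beats = n,
                method = method, low_confidence = TRUE)
    class(out) <- "drest_estimate"
    return(out)
  }
  set.seed(seed)
  slope_fun <- if (method == "theil_sen") {
    function(x, y) theil_sen_slope(x, y)
  } else {
    function(x, y) stats::cov(x, y) / stats::var(x)
  }
  est <- slope_fun(x, y)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0 && n >= 10) {
    bs <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (method == "theil_sen") theil_sen_slope(x[i], y[i], max_pairs = 2e4)
      else stats::cov(x[i], y[i]) / stats::var(x[i])
    }, 0)
    ci <- unname(quantile(bs, c(0.025, 0.975), na.rm = TRUE))
  }
  out <- list(drest = est, ci_95 = ci, rr_range_ms = range(x), n_beats = n,
              method = method, low_confidence = low)
  class(out) <- "drest_estimate"
  out
}

#' @export
print.drest_estimate <- function(x, ...) {
  cat("DRest =", signif(x$drest, 4), "ms/ms  (95% CI",
      signif(x$ci_95[1], 3), "-", signif(x$ci_95[2], 3), ",", x$n_beats,
      "beats, z range", round(x$rr_range_ms[1]), "-",
      round(x$rr_range_ms[2]), "ms,", x$method, ")\n")
  if (x$low_confidence) cat("  LOW CONFIDENCE\n")
  invisible(x)
}

#' Per-subject biomarker report
#'
#' Runs the interval-series stages of the pipeline on a delineated beat
#' series: cleaning, rate-memory fits for Tpe and QT, t90 for both, the
#' memory-compensated DRest, and mean per-beat rate-corrected QTc and Tpec
#' over valid beats.  Any failed stage leaves its fields missing rather than
#' aborting the report.
#'
#' @param series a [beat_series()] (already delineated).
#' @param subject_id identifier stored in the row.
#' @param group group label (e.g., `"healthy"`, `"tdp_sotalol"`).
#' @param correction `"fridericia"` (default) or `"bazett"`.
#' @param drest_method passed to [estimate_drest()].
#' @param average `"mean"` (default) or `"median"` per-beat summary for the
#'   corrected intervals.
#' @param clean apply [clean_series()] first (default TRUE).
#' @param n_boot bootstrap resamples for the DRest CI (0 skips it).
#' @param seed seed for the DRest bootstrap.
#' @return a one-row data.frame (class `biomarker_row`) with columns
#'   `subject_id, group, mean_rr_ms, drest, qtc_ms, tpec_ms, t90_qt_s,
#'   t90_tpe_s, n_valid_beats`.
#' @export
subject_report <- function(series, subject_id = "S01", group = NA_character_,
                           correction = c("fridericia", "bazett"),
                           drest_method = c("theil_sen", "ols"),
                           average = c("mean", "median"),
                           clean = TRUE, n_boot = 1000, seed = 1L) {
  correction <- match.arg(correction)
  drest_method <- match.arg(drest_method)
  average <- match.arg(average)
  stopifnot(inherits(series, "beat_series"))
  row <- data.frame(subject_id = subject_id, group = group,
                    mean_rr_ms = NA_real_, drest = NA_real_,
                    qtc_ms = NA_real_, tpec_ms = NA_real_,
                    t90_qt_s = NA_real_, t90_tpe_s = NA_real_,
                    n_valid_beats = 0L)
  class(row) <- c("biomarker_row", "data.frame")
  if (nrow(series) == 0 || !any(series$valid)) return(row)
  if (clean) series <- tryCatch(clean_series(series), error = function(e) series)
  v <- series$valid & is.finite(series$rr_ms)
  row$n_valid_beats <- sum(v)
  row$mean_rr_ms <- mean(series$rr_ms[v])
  corr <- if (correction == "fridericia") fridericia else bazett
  avg <- if (average == "mean") mean else median
  vq <- v & is.finite(series$qt_ms)
  if (any(vq)) row$qtc_ms <- avg(corr(series$qt_ms[vq], series$rr_ms[vq]))
  vt <- v & is.finite(series$tpe_ms)
  if (any(vt)) row$tpec_ms <- avg(corr(series$tpe_ms[vt], series$rr_ms[vt]))
  mm_tpe <- tryCatch(fit_memory_model(series, "tpe"),
                     error = function(e) NULL, warning = function(w) {
                       tryCatch(suppressWarnings(fit_memory_model(series, "tpe")),
                                error = function(e) NULL)
                     })
  if (!is.null(mm_tpe)) {
    row$t90_tpe_s <- compute_t90(mm_tpe)
    zz <- surrogate_rr(mm_tpe, series)
    dr <- tryCatch(suppressWarnings(
      estimate_drest(series, zz, method = drest_method, n_boot = n_boot,
                     seed = seed)),
      error = function(e) NULL)
    if (!is.null(dr)) row$drest <- dr$drest
  }
  mm_qt <- tryCatch(suppressWarnings(fit_memory_model(series, "qt")),
                    error = function(e) NULL)
  if (!is.null(mm_qt)) row$t90_qt_s <- compute_t90(mm_qt)
  row
}
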