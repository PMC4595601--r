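#' Per-beat interval series
#'
#' A `beat_series` is the pipeline's central currency: one row per detected
#' beat, anchored at the R peak, carrying the preceding R-R interval and the
#' delineated QT (QRS onset to T end) and Tpe (T apex to T end) intervals.
#'
#' @param t numeric, beat anchor times in seconds (R-peak times), strictly
#'   increasing.
#' @param rr_ms numeric, preceding R-R interval in ms.
#' @param qt_ms numeric, QT interval in ms (`NA` where not measurable).
#' @param tpe_ms numeric, T-peak-to-T-end interval in ms.
#' @param valid logical quality flag per beat.
#'
#' @return A data.frame of class `beat_series` with columns
#'   `t`, `rr_ms`, `qt_ms`, `tpe_ms`, `valid`.
#' @export
beat_series <- function(t, rr_ms, qt_ms = NA_real_, tpe_ms = NA_real_,
                        valid = TRUE) {
  n <- length(t)
  out <- data.frame(
    t = as.numeric(t),
    rr_ms = rep_len(as.numeric(rr_ms), n),
    qt_ms = rep_len(as.numeric(qt_ms), n),
    tpe_ms = rep_len(as.numeric(tpe_ms), n),
    valid = rep_len(as.logical(valid), n)
  )
  class(out) <- c("beat_series", "data.frame")
  out
}

#' Validate beat-series invariants
#'
#' Checks that anchor times are strictly increasing, that valid beats have
#' positive RR, `0 < tpe < qt` where both are measured, and that the stored RR
#' agrees with successive anchor differences to within 1 ms.
#'
#' @param x a `beat_series`.
#' @param tol_ms tolerance for the RR/anchor-difference consistency check.
#' @return `TRUE` invisibly; stops with a message on the first violation.
#' @export
validate_beat_series <- function(x, tol_ms = 1) {
  stopifnot(inherits(x, "beat_series"))
  if (nrow(x) == 0) return(invisible(TRUE))
  if (any(diff(x$t) <= 0)) stop("beat anchor times must be strictly increasing")
  v <- x$valid & !is.na(x$rr_ms)
  if (any(x$rr_ms[v] <= 0)) stop("valid beats must have rr_ms > 0")
  m <- x$valid & !is.na(x$qt_ms) & !is.na(x$tpe_ms)
  if (any(x$tpe_ms[m] <= 0 | x$tpe_ms[m] >= x$qt_ms[m]))
    stop("valid beats must satisfy 0 < tpe_ms < qt_ms")
  if (nrow(x) >= 2) {
    k <- which(x$valid[-1] & x$valid[-nrow(x)]) + 1L
    dd <- diff(x$t) * 1000
    bad <- k[!is.na(x$rr_ms[k]) & abs(x$rr_ms[k] - dd[k - 1L]) > tol_ms]
    if (length(bad))
      stop("rr_ms inconsistent with anchor differences at beat ", bad[1])
  }
  invisible(TRUE)
}

#' Write a beat series to CSV
#'
#' Columns: `beat_index, t_s, rr_ms, qt_ms, tpe_ms, valid` (valid as 0/1).
#'
#' @param x a `beat_series`.
#' @param path output file path.
#' @export
write_beat_series <- function(x, path) {
  stopifnot(inherits(x, "beat_series"))
  df <- data.frame(
    beat_index = seq_len(nrow(x)),
    t_s = x$t, rr_ms = x$rr_ms, qt_ms = x$qt_ms, tpe_ms = x$tpe_ms,
    valid = as.integer(x$valid)
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a beat series from CSV
#'
#' @param path file written by [write_beat_series()].
#' @return a `beat_series`.
#' @export
read_beat_series <- function(path) {
  df <- read.csv(path)
  need <- c("t_s", "rr_ms", "qt_ms", "tpe_ms", "valid")
  if (!all(need %in% names(df)))
    stop("beat-series CSV must have columns: ", paste(need, collapse = ", "))
  beat_series(df$t_s, df$rr_ms, df$qt_ms, df$tpe_ms, df$valid != 0)
}
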