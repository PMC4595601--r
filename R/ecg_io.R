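#' ECG record container
#'
#' @param signal numeric matrix, one column per lead, samples in mV.
#'   Column names are the lead names.
#' @param fs sampling rate in Hz (> 0).
#' @param start_time record start in seconds (default 0).
#' @return a list of class `ecg_record` with fields `signal`, `fs`,
#'   `lead_names`, `start_time`, `duration` (= n_samples / fs).
#' @export
ecg_record <- function(signal, fs, start_time = 0) {
  signal <- as.matrix(signal)
  stopifnot(is.numeric(signal), fs > 0)
  if (is.null(colnames(signal)))
    colnames(signal) <- paste0("lead", seq_len(ncol(signal)))
  structure(list(
    signal = signal, fs = fs, lead_names = colnames(signal),
    start_time = start_time, duration = nrow(signal) / fs
  ), class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat("ECG record:", ncol(x$signal), "lead(s) [",
      paste(x$lead_names, collapse = ", "), "] at", x$fs, "Hz,",
      round(x$duration, 2), "s\n")
  invisible(x)
}

#' Read an ECG record
#'
#' Two dialects are supported.  `"csv"`: a header row then
#' `time_s, lead1, lead2, ...` with signals in mV; time must be uniformly
#' sampled.  `"wfdb"`: a WFDB header (`.hea`) plus a single binary signal
#' file in format 16 (little-endian 16-bit integers, interleaved), converted
#' to mV via the per-signal gain and baseline; `path` is the header path or
#' the record name without extension.
#'
#' @param path file path (CSV file, or WFDB header / record name).
#' @param format `"csv"` or `"wfdb"`.
#' @param max_duration_s optional truncation (seconds), e.g. 3600 for
#'   first-hour excerpts; `Inf` keeps everything.
#' @return an [ecg_record()].
#' @export
read_record <- function(path, format = c("csv", "wfdb"),
                        max_duration_s = Inf) {
  format <- match.arg(format)
  rec <- if (format == "csv") read_record_csv(path) else read_record_wfdb(path)
  if (is.finite(max_duration_s) && rec$duration > max_duration_s) {
    n <- floor(max_duration_s * rec$fs)
    rec <- ecg_record(rec$signal[seq_len(n), , drop = FALSE], rec$fs,
                      rec$start_time)
  }
  rec
}

read_record_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read ECG record: ", path)
  df <- read.csv(path, check.names = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "time_s")
    stop("CSV dialect must be 'time_s, lead1, lead2, ...' with a header row")
  t <- df[[1]]
  dt <- diff(t)
  if (length(dt) < 1 || any(abs(dt - dt[1]) > 1e-6))
    stop("time_s must be uniformly sampled")
  sig <- as.matrix(df[, -1, drop = FALSE])
  ecg_record(sig, fs = 1 / dt[1], start_time = t[1])
}

#' Write an ECG record to the CSV dialect
#'
#' Inverse of [read_record()] for `format = "csv"`; round-trips bit-exactly
#' for signals representable at the printed precision (full `%.17g` is used,
#' so doubles survive unchanged).
#'
#' @param record an [ecg_record()].
#' @param path output path.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  n <- nrow(record$signal)
  t <- record$start_time + (seq_len(n) - 1) / record$fs
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("time_s", record$lead_names), collapse = ","), con)
  body <- cbind(t, record$signal)
  lines <- apply(body, 1, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(lines, con)
  invisible(path)
}

read_record_wfdb <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("cannot read WFDB header: ", hea)
  lines <- readLines(hea)
  lines <- lines[!grepl("^#", lines)]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n_sig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(sub("/.*", "", top[3])) else 250
  n_samp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  sig_lines <- lines[1 + seq_len(n_sig)]
  dir <- dirname(hea)
  fname <- character(n_sig); fmt <- character(n_sig)
  gain <- numeric(n_sig); base <- numeric(n_sig); lead <- character(n_sig)
  for (i in seq_len(n_sig)) {
    f <- strsplit(trimws(sig_lines[i]), "\\s+")[[1]]
    fname[i] <- f[1]
    fmt[i] <- sub("x.*|:.*|\\+.*", "", f[2])
    gspec <- if (length(f) >= 3) f[3] else "200"
    gain[i] <- as.numeric(sub("\\(.*", "", sub("/.*", "", gspec)))
    base[i] <- if (grepl("\\(", gspec))
      as.numeric(sub(".*\\((-?[0-9]+)\\).*", "\\1", gspec)) else 0
    lead[i] <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ")
      else paste0("sig", i)
    if (gain[i] == 0) gain[i] <- 200
  }
  if (length(unique(fname)) != 1)
    stop("only single-file WFDB records are supported")
  if (any(fmt != "16"))
    stop("only WFDB signal format 16 is supported (got ", fmt[1], ")")
  dat <- file.path(dir, fname[1])
  if (!file.exists(dat)) stop("cannot read WFDB signal file: ", dat)
  raw <- readBin(dat, "integer", n = file.size(dat) / 2, size = 2,
                 signed = TRUE, endian = "little")
  if (length(raw) %% n_sig != 0)
    stop("WFDB signal file length inconsistent with ", n_sig, " signals")
  m <- matrix(raw, ncol = n_sig, byrow = TRUE)
  if (!is.na(n_samp) && nrow(m) != n_samp)
    stop("WFDB sample count mismatch: header says ", n_samp, ", file has ",
         nrow(m))
  sig <- sweep(sweep(m, 2, base, "-"), 2, gain, "/")
  colnames(sig) <- lead
  ecg_record(sig, fs)
}

#' Rank leads by signal-to-noise ratio
#'
#' The analysis lead is the one with the highest SNR.  SNR per lead is
#' estimated from a correlation-aligned median beat template: beats are
#' detected on the lead, windows around each anchor are aligned to the
#' template by maximum cross-correlation within +/-5 samples, and
#' `SNR_dB = 10 log10(template power / residual power)` where the residual
#' is the signal minus the per-beat template over the whole excerpt.  Leads
#' without detectable beats are marked non-delineable and ranked last.
#' The ranking is invariant to a common positive rescaling of all leads.
#'
#' @param record an [ecg_record()].
#' @param candidates lead names to consider (default `V2, V3, V4`
#'   intersected with the record's leads; all leads if none match).
#' @return data.frame of class `lead_quality` with columns `lead_name`,
#'   `snr_db`, `delineable`, ordered by descending SNR.
#' @export
rank_leads <- function(record, candidates = c("V2", "V3", "V4")) {
  stopifnot(inherits(record, "ecg_record"))
  cand <- intersect(candidates, record$lead_names)
  if (!length(cand)) cand <- record$lead_names
  fs <- record$fs
  half <- round(0.25 * fs)
  res <- lapply(cand, function(ld) {
    x <- record$signal[, ld]
    anchors <- tryCatch(suppressWarnings(detect_beats(record, ld)),
                        error = function(e) numeric(0))
    if (length(anchors) < 5)
      return(data.frame(lead_name = ld, snr_db = -Inf, delineable = FALSE))
    idx <- round(anchors * fs) + 1L
    idx <- idx[idx - half >= 1 & idx + half <= length(x)]
    if (length(idx) < 5)
      return(data.frame(lead_name = ld, snr_db = -Inf, delineable = FALSE))
    wins <- vapply(idx, function(i) x[(i - half):(i + half)],
                   numeric(2 * half + 1))
    templ <- apply(wins, 1, median)
    # correlation alignment within +/-5 samples
    shifts <- -5:5
    resid_pow <- 0; n_res <- 0
    for (k in seq_along(idx)) {
      cc <- vapply(shifts, function(s) {
        w <- wins[, k]
        a <- max(1, 1 + s); b <- min(length(w), length(w) + s)
        sum(w[a:b] * templ[(a - s):(b - s)])
      }, 0)
      s <- shifts[which.max(cc)]
      w <- wins[, k]
      a <- max(1, 1 + s); b <- min(length(w), length(w) + s)
      d <- w[a:b] - templ[(a - s):(b - s)]
      resid_pow <- resid_pow + sum(d^2); n_res <- n_res + length(d)
    }
    snr <- 10 * log10(mean(templ^2) / (resid_pow / n_res))
    data.frame(lead_name = ld, snr_db = snr, delineable = TRUE)
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$snr_db), ]
  rownames(out) <- NULL
  class(out) <- c("lead_quality", "data.frame")
  out
}
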