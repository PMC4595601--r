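#' Fit the rate-adaptation (memory) model of QT or Tpe to RR history
#'
#' Repolarization intervals follow the recent history of RR, not just the
#' current beat.  The model is `target(k) = g(z(k)) + noise` with
#' `z(k) = sum_i w_i rr(k - i)` a weighted average of the preceding RR
#' intervals over a history window (weights nonnegative, summing to one) and
#' `g` a linear stationary curve `a*z + b`.  Two weight-profile families are
#' fitted:
#'
#' * `"fir"`: free weights on a graded lag basis (single-beat resolution at
#'   short lags, geometrically widening bins at long lags), estimated by
#'   alternating least squares — ordinary least squares for `g` given the
#'   weights, then nonnegativity- and sum-to-one-constrained least squares
#'   (FISTA with simplex projection) for the weights given `g`, iterated to
#'   convergence from a uniform start.  An optional second-difference
#'   roughness penalty (`lambda`) stabilizes the profile.
#' * `"exponential"`: a single-time-constant profile, with the time constant
#'   found by profiled 1-D minimization of the residual RMSE.
#'
#' With `profile = "auto"` (default) both are fitted and the one with the
#' lower AIC is kept, so a genuinely non-exponential profile is still
#' captured by the free weights while the parsimonious profile wins when the
#' data do not support more structure.
#'
#' @param series a [beat_series()] with at least 10 minutes of valid beats.
#' @param target `"tpe"` or `"qt"`.
#' @param window_s history window length in seconds (default 300).
#' @param lambda roughness-penalty weight on the binned profile, relative to
#'   the scale of the normal equations (default 1e-3); 0 disables it.
#' @param profile `"auto"`, `"fir"` or `"exponential"`.
#' @param max_iter,tol outer alternating-least-squares controls.
#' @return an object of class `memory_model`: per-beat `weights` (lag 0
#'   first), `g` (slope `a`, intercept `b`), `target`, `window_s`,
#'   `mean_rr_s`, `residual_rmse_ms`, `profile_type`, `tau_s` (exponential
#'   profile only), `degenerate` and `low_confidence` flags.
#' @export
fit_memory_model <- function(series, target = c("tpe", "qt"), window_s = 300,
                             lambda = 1e-3, profile = c("auto", "fir",
                                                        "exponential"),
                             max_iter = 50, tol = 1e-4) {
  target <- match.arg(target)
  profile <- match.arg(profile)
  stopifnot(inherits(series, "beat_series"), window_s >= 60)
  rr <- series$rr_ms
  y_all <- if (target == "tpe") series$tpe_ms else series$qt_ms
  ok <- series$valid & is.finite(rr) & is.finite(y_all)
  if (sum(rr[ok]) / 1000 < 600)
    stop("need >= 10 min of valid beats to fit the rate-memory model")
  mean_rr_s <- mean(rr[ok]) / 1000
  L <- max(2L, round(window_s / mean_rr_s))
  n <- length(rr)
  if (n <= L + 50)
    stop("series too short for the requested history window")

  # heart-rate-change precondition: range of 1-min-smoothed RR
  ksm <- min(n, max(5L, round(60 / mean_rr_s)))
  sm <- as.numeric(stats::filter(rr, rep(1 / ksm, ksm), sides = 2))
  rr_range <- diff(range(sm, na.rm = TRUE))
  degenerate <- rr_range < 10
  low_confidence <- rr_range < 50
  if (low_confidence && !degenerate)
    warning("insufficient heart-rate changes (smoothed RR range ",
            round(rr_range, 1), " ms < 50 ms); t90/DRest will be unreliable")

  rows <- which(ok & seq_len(n) > L)
  y <- y_all[rows]
  base <- list(target = target, window_s = window_s, mean_rr_s = mean_rr_s,
               n_lags = L, n_used = length(rows), rr_range_ms = rr_range,
               degenerate = degenerate, low_confidence = low_confidence)
  if (degenerate) {
    w <- rep(1 / L, L)
    out <- c(base, list(weights = w, g = c(a = NA_real_, b = mean(y)),
                        residual_rmse_ms = stats::sd(y),
                        profile_type = "degenerate", tau_s = NA_real_))
    class(out) <- "memory_model"
    warning("near-constant RR: memory model is unidentifiable (degenerate)")
    return(out)
  }

  fits <- list()
  if (profile %in% c("auto", "exponential"))
    fits$exponential <- fit_memory_exp(rr, y, rows, L, mean_rr_s)
  skip_fir <- profile == "auto" &&
    fits$exponential$residual_rmse_ms < 0.01  # already at numerical floor
  if (profile == "fir" || (profile == "auto" && !skip_fir))
    fits$fir <- fit_memory_fir(rr, y, rows, L, lambda, max_iter, tol)
  pick <- if (length(fits) == 1L) fits[[1L]] else {
    aic <- vapply(fits, function(f) f$aic, 0)
    fits[[which.min(aic)]]
  }
  out <- c(base, pick)
  class(out) <- "memory_model"
  out
}

# exponential profile: weights (1-b) b^i truncated at L, profiled over tau
fit_memory_exp <- function(rr, y, rows, L, mean_rr_s) {
  nr <- length(rows)
  obj <- function(log_tau) {
    z <- exp_memory_filter(rr, exp(log_tau))[rows]
    f <- stats::lm.fit(cbind(1, z), y)
    sum(f$residuals^2)
  }
  opt <- optimize(obj, interval = log(c(0.5, 400)))
  tau <- exp(opt$minimum)
  z <- exp_memory_filter(rr, tau)[rows]
  f <- stats::lm.fit(cbind(1, z), y)
  rss <- sum(f$residuals^2)
  beta <- exp(-mean_rr_s / tau)
  w <- (1 - beta) * beta^(0:(L - 1))
  w <- w / sum(w)
  list(weights = w, g = c(a = f$coefficients[[2]], b = f$coefficients[[1]]),
       residual_rmse_ms = sqrt(rss / nr),
       profile_type = "exponential", tau_s = tau,
       aic = nr * log(rss / nr) + 2 * 3)
}

# graded lag bins: single-beat resolution for the first 10 lags, then widths
# growing geometrically (x1.25) to cover the window with ~25 parameters
lag_bins <- function(L) {
  w <- rep(1L, min(10L, L))
  nxt <- 2
  while (sum(w) < L) {
    w <- c(w, min(round(nxt), L - sum(w)))
    nxt <- nxt * 1.25
  }
  cbind(from = cumsum(c(0L, w[-length(w)])), width = w)
}

# projection onto the weighted simplex {theta >= 0, sum(c * theta) = 1}
proj_wsimplex <- function(v, c) {
  f <- function(mu) sum(c * pmax(0, v - mu * c)) - 1
  lo <- (sum(c * v) - 1) / sum(c^2)  # f(lo) >= 0 since max(0,.) >= .
  hi <- max(v / c)                   # all terms clipped to 0 -> f(hi) = -1
  if (hi <= lo) hi <- lo + 1
  for (i in 1:48) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  pmax(0, v - ((lo + hi) / 2) * c)
}

fit_memory_fir <- function(rr, y, rows, L, lambda, max_iter, tol) {
  bins <- lag_bins(L)
  J <- nrow(bins)
  nr <- length(rows)
  # bin-summed lagged design via cumulative sums:
  # M[k, j] = sum_{i in bin j} rr(k - i)
  C <- cumsum(c(0, rr))
  M <- matrix(0, nr, J)
  for (j in seq_len(J)) {
    a <- bins[j, "from"]; b <- a + bins[j, "width"] - 1L
    M[, j] <- C[rows - a + 1L] - C[rows - b]
  }
  cw <- as.numeric(bins[, "width"])
  G0 <- crossprod(M)
  # roughness penalty on per-lag weight heights, scale-matched to G0
  P <- matrix(0, J, J)
  if (J >= 3 && lambda > 0) {
    D <- diff(diag(J), differences = 2)
    P <- crossprod(D) * (sum(diag(G0)) / J)
  }
  theta <- rep(1 / L, J)
  a <- 1; b <- 0
  rmse_prev <- Inf
  G <- G0 + lambda * P
  lip <- {
    v <- rep(1 / sqrt(J), J)
    for (i in 1:30) { v <- G %*% v; v <- v / sqrt(sum(v^2)) }
    as.numeric(crossprod(v, G %*% v)) * 1.05
  }
  for (it in seq_len(max_iter)) {
    z <- as.numeric(M %*% theta)
    fit <- stats::lm.fit(cbind(1, z), y)
    b <- fit$coefficients[[1]]; a <- fit$coefficients[[2]]
    if (!is.finite(a) || a == 0) a <- 1e-8
    yp <- (y - b) / a
    cvec <- as.numeric(crossprod(M, yp))
    x <- theta; u <- theta; tk <- 1
    for (i in 1:150) {
      grad <- as.numeric(G %*% u - cvec)
      xn <- proj_wsimplex(u - grad / lip, cw)
      tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
      u <- xn + ((tk - 1) / tn) * (xn - x)
      x <- xn; tk <- tn
    }
    theta <- x
    res <- y - (a * as.numeric(M %*% theta) + b)
    rmse <- sqrt(mean(res^2))
    if (abs(rmse_prev - rmse) < tol * max(rmse_prev, 1e-6)) break
    rmse_prev <- rmse
  }
  w <- rep(theta, times = cw)[seq_len(L)]
  s <- sum(w); w <- w / s
  rss <- sum(res^2)
  list(weights = w, g = c(a = a * s, b = b),
       residual_rmse_ms = sqrt(rss / nr),
       profile_type = "fir", tau_s = NA_real_,
       aic = nr * log(rss / nr) + 2 * (J + 2))
}

#' Memory-compensated surrogate RR series
#'
#' Applies a fitted memory model's weight profile to a beat series:
#' `z(k) = sum_i w_i rr(k - i)`.  Beats without a full history window are
#' flagged invalid.
#'
#' @param model a [fit_memory_model()] result.
#' @param series a [beat_series()] compatible with the model.
#' @return a data.frame of class `surrogate_rr` with columns `t`, `z_ms`,
#'   `valid`.
#' @export
surrogate_rr <- function(model, series) {
  stopifnot(inherits(model, "memory_model"), inherits(series, "beat_series"))
  if (identical(model$profile_type, "exponential")) {
    # exact recursive form of the exponential profile (no truncation)
    z <- exp_memory_filter(series$rr_ms, model$tau_s)
    valid <- series$valid & seq_len(nrow(series)) > model$n_lags
  } else {
    w <- model$weights
    z <- as.numeric(stats::filter(series$rr_ms, w, sides = 1))
    valid <- !is.na(z) & series$valid
  }
  out <- data.frame(t = series$t, z_ms = z, valid = valid)
  class(out) <- c("surrogate_rr", "data.frame")
  out
}

#' Time to 90% rate adaptation (t90)
#'
#' The step response of the memory filter completes a fraction
#' `W(m) = sum_{i<m} w_i` of its transition after `m` beats; `t90` is the
#' (linearly interpolated) lag at which `W` first reaches 0.90, converted to
#' seconds via the mean RR of the fitting record.  For an
#' exponential-profile model the equivalent closed form `tau * ln(10)` is
#' used, which is free of the history-window truncation.
#'
#' @param model a [fit_memory_model()] result.
#' @return t90 in seconds, or `NA` for a degenerate model.
#' @export
compute_t90 <- function(model) {
  stopifnot(inherits(model, "memory_model"))
  if (isTRUE(model$degenerate)) return(NA_real_)
  if (identical(model$profile_type, "exponential") && is.finite(model$tau_s))
    return(model$tau_s * log(10))
  W <- cumsum(model$weights)
  m <- which(W >= 0.9)[1]
  if (is.na(m)) return(NA_real_)
  W0 <- if (m == 1L) 0 else W[m - 1L]
  s <- (m - 1L) + (0.9 - W0) / (W[m] - W0)
  s * model$mean_rr_s
}

#' @export
print.memory_model <- function(x, ...) {
  cat("Rate-memory model (", x$target, "), profile: ", x$profile_type, "\n",
      sep = "")
  if (!is.na(x$tau_s)) cat("  time constant tau:", round(x$tau_s, 2), "s\n")
  cat("  g: a =", signif(x$g[["a"]], 4), ", b =", signif(x$g[["b"]], 4), "\n")
  cat("  residual RMSE:", round(x$residual_rmse_ms, 2), "ms;  t90:",
      round(compute_t90(x), 1), "s\n")
  if (x$degenerate) cat("  DEGENERATE (near-constant RR)\n")
  invisible(x)
}
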