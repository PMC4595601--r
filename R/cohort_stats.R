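#' Percentile bounds of a biomarker
#'
#' Linear-interpolation (type-7) percentiles, the convention used for the
#' 20-80 percentile summary tables.
#'
#' @param values numeric vector (>= 2 finite values required).
#' @param lo,hi percentiles in \[0, 100\] (defaults 20 and 80).
#' @return numeric length-2 vector `c(lo_val, hi_val)`.
#' @export
percentile_bounds <- function(values, lo = 20, hi = 80) {
  v <- values[is.finite(values)]
  if (length(v) < 2) stop("need at least 2 finite values")
  stopifnot(lo <= hi)
  unname(quantile(v, c(lo, hi) / 100, type = 7))
}

# Mann-Whitney U statistic of group a vs pooled midranks
u_stat <- function(ra, na) sum(ra) - na * (na + 1) / 2

#' Exact Mann-Whitney U test
#'
#' Small-sample two-group comparison.  Without ties the exact p-value comes
#' from the exact null distribution of U; with ties, all
#' `choose(n_a + n_b, n_a)` label assignments are enumerated when that count
#' is at most `max_enum` (default 1e6).  Beyond that, a normal approximation
#' with tie correction and continuity correction is used.  The one-sided
#' exact p is the proportion of assignments with U at least as extreme as
#' observed; the two-sided p is twice the smaller one-sided p, capped at 1.
#'
#' @param a,b numeric vectors (non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (location of `a` relative to `b`).
#' @param max_enum enumeration budget for the tied exact path.
#' @param exact `"auto"` (default) uses the exact path whenever feasible;
#'   `"never"` forces the normal approximation (useful to compare the two).
#' @return list with `u` (U statistic of `a`), `p_value`, and `method`
#'   (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney_exact <- function(a, b, alternative = c("two.sided", "less",
                                                     "greater"),
                               max_enum = 1e6, exact = c("auto", "never")) {
  alternative <- match.arg(alternative)
  exact <- match.arg(exact)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- u_stat(r[seq_len(na)], na)
  ties <- any(duplicated(pooled))
  if (exact == "never") ties <- TRUE
  if (exact == "never") max_enum <- 0
  method <- "exact"
  if (!ties) {
    # exact null distribution of U (no ties)
    p_less <- pwilcox(u_obs, na, nb)
    p_greater <- 1 - if (u_obs >= 1) pwilcox(u_obs - 1, na, nb) else 0
  } else if (choose(n, na) <= max_enum) {
    idx <- utils::combn(n, na)
    u_all <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
    p_less <- mean(u_all <= u_obs)
    p_greater <- mean(u_all >= u_obs)
  } else {
    method <- "normal_approx"
    mu <- na * nb / 2
    tie_tab <- table(pooled)
    tie_corr <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sig <- sqrt(na * nb / 12 * ((n + 1) - tie_corr))
    p_less <- pnorm((u_obs - mu + 0.5) / sig)
    p_greater <- pnorm((u_obs - mu - 0.5) / sig, lower.tail = FALSE)
  }
  p <- switch(alternative,
              less = p_less,
              greater = p_greater,
              two.sided = min(1, 2 * min(p_less, p_greater)))
  list(u = u_obs, p_value = p, method = method)
}

#' Welch's t test (unequal variances, unequal sample sizes)
#'
#' Thin wrapper over [stats::t.test()] with `var.equal = FALSE`
#' (Satterthwaite degrees of freedom).  Degenerate zero-variance inputs are
#' handled explicitly: equal constant groups give p = 1.
#'
#' @param a,b numeric vectors with at least 2 finite values each.
#' @return list with `t`, `df`, `p_value`.
#' @export
welch_t <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 values per group")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = NA_real_, p_value = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_, p_value = 0))
  }
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Standardized distance from a reference group
#'
#' `(x - mean(a)) / sd(a)` with the sample standard deviation: how many
#' reference-group standard deviations a value lies from the reference mean.
#'
#' @param a reference-group values (>= 2, nonzero variance).
#' @param x value(s) to standardize.
#' @return standardized distance(s), same length as `x`.
#' @export
separation_sigmas <- function(a, x) {
  a <- a[is.finite(a)]
  if (length(a) < 2) stop("reference group needs >= 2 values")
  s <- sd(a)
  if (s == 0) stop("reference group has zero variance")
  (x - mean(a)) / s
}

#' Group summary table of cohort biomarkers
#'
#' Collapses a cohort of [subject_report()] rows into one summary row per
#' group: 20-80 percentile bounds when the group has more than `minmax_below`
#' subjects, min-max otherwise (small groups are reported as whole ranges).
#'
#' @param rows data.frame of `biomarker_row`s (rbind of [subject_report()]
#'   outputs) with a `group` column; duplicated `subject_id`s are an error.
#' @param metrics columns to summarize.
#' @param minmax_below groups of this size or smaller are summarized by
#'   min-max instead of percentiles (default 7).
#' @return data.frame with `group`, `n`, and `<metric>_lo` / `<metric>_hi`
#'   columns.
#' @export
cohort_summary <- function(rows, metrics = c("mean_rr_ms", "drest", "qtc_ms",
                                             "t90_tpe_s", "t90_qt_s",
                                             "tpec_ms"),
                           minmax_below = 7) {
  stopifnot(is.data.frame(rows), "group" %in% names(rows))
  if (anyDuplicated(rows$subject_id)) stop("duplicated subject_id")
  groups <- unique(rows$group)
  out <- lapply(groups, function(g) {
    sub <- rows[rows$group == g, , drop = FALSE]
    rec <- data.frame(group = g, n = nrow(sub))
    for (m in metrics) {
      v <- sub[[m]][is.finite(sub[[m]])]
      bounds <- if (length(v) < 2) c(NA_real_, NA_real_)
      else if (length(v) <= minmax_below) range(v)
      else percentile_bounds(v)
      rec[[paste0(m, "_lo")]] <- bounds[1]
      rec[[paste0(m, "_hi")]] <- bounds[2]
    }
    rec
  })
  do.call(rbind, out)
}
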