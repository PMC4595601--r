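# Independent oracles and shared fixtures for the test suite.

# Brute-force Mann-Whitney oracle: U from the counting definition and the
# exact p as the proportion of all group assignments at least as extreme.
mwu_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  cmb <- utils::combn(n, na)
  uval <- apply(cmb, 2, function(idx) {
    aa <- pooled[idx]; bb <- pooled[-idx]
    sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  })
  uobs <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  p_less <- mean(uval <= uobs)
  p_greater <- mean(uval >= uobs)
  list(u = uobs, p_less = p_less, p_greater = p_greater,
       p_two = min(1, 2 * min(p_less, p_greater)))
}

# Permutation oracle on the difference in means (all assignments).
perm_mean_diff_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  cmb <- utils::combn(length(pooled), na)
  d <- apply(cmb, 2, function(idx) mean(pooled[idx]) - mean(pooled[-idx]))
  mean(abs(d) >= abs(mean(a) - mean(b)) - 1e-12)
}

# Regular beat series with fully specified intervals (for unit tests that
# bypass the generators).
flat_series <- function(n = 60, rr = 1000, qt = 400, tpe = 90) {
  t <- seq(0.5, by = rr / 1000, length.out = n)
  beat_series(t, rr, qt, tpe)
}

# The tissue runs are the expensive part of the suite; compute each
# configuration once and share it across test files (helpers are sourced
# into the same session).
.tissue_cache <- new.env(parent = emptyenv())

cached_restitution <- function(gkr = 1.0) {
  key <- sprintf("rest_g%s", gkr)
  if (is.null(.tissue_cache[[key]])) {
    cfg <- tissue_config_fast(gkr_scale = gkr)
    .tissue_cache[[key]] <- dynamic_restitution(cfg)
  }
  .tissue_cache[[key]]
}

cached_strand <- function(key, cfg, cl_ms = 1000) {
  if (is.null(.tissue_cache[[key]]))
    .tissue_cache[[key]] <- simulate_strand(cfg, cl_ms)
  .tissue_cache[[key]]
}

# Single-cell steady-state APD90 reference values (CL 1000 ms, 50 beats from
# the published initial state, APD90 = max-dV/dt activation to 90%
# repolarization on a 1 ms grid), computed with an independent
# implementation of the published 2006 model (scipy LSODA, rapid-buffering
# derivative form).
APD90_ORACLE <- c(endo = 308.32, M = 415.88, epi = 309.60)
APD90_ORACLE_EPI_IKR50 <- 330.55
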