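# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and lm/confint) wherever they check them.

# OLS by explicit normal equations with t-distribution inference
ols_oracle <- function(y, X) {
  X1 <- cbind(1, as.matrix(X))
  n <- length(y)
  p <- ncol(X1)
  xtx_inv <- solve(t(X1) %*% X1)
  beta <- drop(xtx_inv %*% t(X1) %*% y)
  res <- y - drop(X1 %*% beta)
  s2 <- sum(res^2) / (n - p)
  se <- sqrt(diag(xtx_inv) * s2)
  tval <- beta / se
  tc <- stats::qt(0.975, n - p)
  list(beta = beta, se = se,
       p = 2 * stats::pt(-abs(tval), n - p),
       ci_low = beta - tc * se, ci_high = beta + tc * se,
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}

# OLS slope of a*eps + b*eps^5 over a continuous uniform strain window,
# from analytically integrated moments
poly_window_slope_oracle <- function(a_coef, b_coef, lo, hi) {
  mom <- function(k) (hi^(k + 1) - lo^(k + 1)) / ((k + 1) * (hi - lo))
  v <- mom(2) - mom(1)^2
  cov5 <- mom(6) - mom(1) * mom(5)
  a_coef + b_coef * cov5 / v
}

# per-period argmax peak detection for a strictly periodic strain signal
argmax_per_period_oracle <- function(strain, samples_per_period, n_periods) {
  vapply(seq_len(n_periods), function(k) {
    from <- round((k - 1) * samples_per_period) + 1
    to <- min(round(k * samples_per_period), length(strain))
    from - 1 + which.max(strain[from:to])
  }, numeric(1))
}

# brute-force count of voxel centres inside a disc on one slice
disc_count_oracle <- function(dim_xy, voxel_size, center, diameter) {
  count <- 0L
  for (i in seq_len(dim_xy[1])) {
    for (j in seq_len(dim_xy[2])) {
      x <- (i - 0.5) * voxel_size[1]
      y <- (j - 0.5) * voxel_size[2]
      if ((x - center[1])^2 + (y - center[2])^2 <= (diameter / 2)^2) {
        count <- count + 1L
      }
    }
  }
  count
}

# sort-based quantiles with linear interpolation (type 7), written out
quantile_oracle <- function(v, prob) {
  s <- sort(v)
  n <- length(s)
  h <- (n - 1) * prob + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# reference feature targets known to be realisable by the trace generator
draw_feasible_features <- function() {
  repeat {
    ft <- list(low_strain_stiffness = runif(1, 0.5, 5),
               high_strain_stiffness = runif(1, 20, 200),
               hysteresis_loss = runif(1, 20, 70),
               plastic_strain = runif(1, 5, 50))
    ok <- tryCatch({
      generate_mech_trace(ft, delta_eps_pct = 10)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(ft)
  }
}
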