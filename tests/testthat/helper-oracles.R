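# Independent oracles for cross-checking the package implementations.
# These are deliberately written as plain enumerations / brute-force
# numerics, sharing no code with the functions they check.

# Brute-force puncta caller: walk every pixel, collect maximal
# supra-threshold stretches, drop the narrow ones. Returns start/end
# (half-open, 1-based) and the peak value of each surviving stretch.
oracle_detect <- function(intensity, threshold, pixel_size_um, min_width_um) {
  segs <- list()
  i <- 1L
  n <- length(intensity)
  while (i <= n) {
    if (intensity[i] > threshold) {
      j <- i
      while (j < n && intensity[j + 1L] > threshold) j <- j + 1L
      if ((j - i + 1L) * pixel_size_um >= min_width_um)
        segs[[length(segs) + 1L]] <-
          c(start = i, end = j + 1L, peak = max(intensity[i:j]))
      i <- j + 1L
    }
    i <- i + 1L
  }
  if (length(segs) == 0L)
    return(data.frame(start = integer(), end = integer(), peak = numeric()))
  as.data.frame(do.call(rbind, segs))
}

# Fixed-step midpoint-rule integration of the four-pool FRAP label kinetics
# for one channel, from the immediate post-bleach state to time t_end.
oracle_frap_euler <- function(y0, f_surf, k_exo, k_endo, k_ext, t_end,
                              dt = 1e-3) {
  deriv <- function(y) {
    ex_u <- k_exo * y[3L] - k_endo * y[1L]
    ex_b <- k_exo * y[4L] - k_endo * y[2L]
    c(ex_u, ex_b, -ex_u, -ex_b) +
      k_ext * (c(f_surf, 0, 1 - f_surf, 0) - y)
  }
  y <- y0 # S_u, S_b, I_u, I_b
  steps <- round(t_end / dt)
  for (s in seq_len(steps)) {
    y_mid <- y + (dt / 2) * deriv(y)
    y <- y + dt * deriv(y_mid)
  }
  y
}

# Two-sided permutation p-value for the difference of group means.
oracle_perm_p <- function(a, b, B = 100000L, seed = 99L) {
  withr::with_seed(seed, {
    obs <- abs(mean(a) - mean(b))
    pool <- c(a, b)
    na <- length(a); n <- length(pool)
    hits <- 0L
    for (i in seq_len(B)) {
      idx <- sample.int(n, na)
      d <- abs(mean(pool[idx]) - mean(pool[-idx]))
      if (d >= obs - 1e-12) hits <- hits + 1L
    }
    hits / B
  })
}

# Convenience: one standard noisy multi-punctum scan for reuse in tests.
make_test_scan <- function(seed = 42L, background_sd = 5) {
  tr <- scan_truth(
    length_um = 60, background_sd = background_sd,
    puncta = data.frame(center_um = c(10, 20, 30, 42, 51),
                        amplitude = c(60, 80, 100, 70, 90),
                        sigma_um = c(0.4, 0.6, 0.5, 0.8, 0.35)),
    seed = seed)
  gen_linescan(tr)
}
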