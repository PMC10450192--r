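# Independent oracles used to derive expected values, kept deliberately
# separate from the package implementation paths they check.

# --- WLC oracles: plain bisection on the implicit equations ------------

ms_force_oracle <- function(z, P = 50, kT = 0.01380649 * 296.15) {
  (kT / P) * (1 / (4 * (1 - z)^2) - 0.25 + z)
}

# force at fractional extension x, solving F = MS(x - F/K) by bisection
wlc_force_oracle <- function(x, P = 50, K = 1200, kT = 0.01380649 * 296.15) {
  f_lo <- 0
  f_hi <- 1
  g <- function(f) ms_force_oracle(x - f / K, P, kT) - f
  while (g(f_hi) > 0) f_hi <- f_hi * 2
  for (i in 1:200) {
    mid <- (f_lo + f_hi) / 2
    if (g(mid) > 0) f_lo <- mid else f_hi <- mid
  }
  (f_lo + f_hi) / 2
}

# fractional extension at force F: bisection for z on [0, 1), plus F/K
frac_ext_oracle <- function(F, P = 50, K = 1200, kT = 0.01380649 * 296.15) {
  z_lo <- 0
  z_hi <- 1 - 1e-12
  for (i in 1:200) {
    mid <- (z_lo + z_hi) / 2
    if (ms_force_oracle(mid, P, kT) < F) z_lo <- mid else z_hi <- mid
  }
  (z_lo + z_hi) / 2 + F / K
}

# --- exhaustive BIC segmentation oracle --------------------------------

# brute-force minimisation of (2k+2) log n + n log(SSR/n) over all
# placements of at most max_cp change points with min_segment spacing
bic_exhaustive_oracle <- function(y, max_cp = 2, min_segment = 3) {
  n <- length(y)
  ssr <- function(seg) sum((seg - mean(seg))^2)
  bic_of <- function(cps) {
    b <- c(0, cps, n)
    s <- sum(vapply(seq_len(length(b) - 1),
                    function(i) ssr(y[(b[i] + 1):b[i + 1]]), numeric(1)))
    (2 * length(cps) + 2) * log(n) + n * log(max(s, 1e-300) / n)
  }
  best <- list(cps = integer(0), bic = bic_of(integer(0)))
  if (max_cp >= 1) {
    for (k1 in min_segment:(n - min_segment)) {
      b <- bic_of(k1)
      if (b < best$bic) best <- list(cps = k1, bic = b)
    }
  }
  if (max_cp >= 2) {
    for (k1 in min_segment:(n - 2 * min_segment)) {
      for (k2 in (k1 + min_segment):(n - min_segment)) {
        b <- bic_of(c(k1, k2))
        if (b < best$bic) best <- list(cps = c(k1, k2), bic = b)
      }
    }
  }
  best$cps
}

# --- analytic paused-fraction oracle (eta = 1) -------------------------

# Closed-form paused-time fraction of the generator with the per-event
# velocity multiplier held at 1: moving time is the integral of 1/v(x)
# up to the tracking cap, paused time the integral of hazard times mean
# Pareto duration. This is the calibration behind the default pause rate.
paused_fraction_oracle <- function(config = sim_config()) {
  bpp <- config$genome_bp / 100
  A <- base_velocity(100, config)
  cb <- bpp * config$decade_filling / log(10)
  x_cap <- min(cb * log(config$velocity_cap / A), config$genome_bp)
  U <- (cb / A) * (1 - exp(-x_cap / cb))
  Lr <- config$pause_rate_scale * bpp
  Lx <- config$xmin_scale * bpp
  lam0 <- config$pause_rate_100
  mean_dur0 <- config$pareto_xmin_100 * (config$pareto_alpha - 1) /
    (config$pareto_alpha - 2)
  x_p <- min(x_cap, (100 - config$pause_floor_filling) * bpp)
  s <- 1 / (1 / Lr + 1 / Lx)
  P <- lam0 * mean_dur0 * s * (1 - exp(-x_p / s))
  P / (P + U)
}

# --- synthetic trace from a known exited-length path -------------------

# Observes a prescribed exited-length path (bp, sampled at `rate`) through
# the WLC model with the given noise, producing a trace tibble comparable
# to generator output. Ground truth stays in the path itself.
make_trace_from_path <- function(x_bp, rate = 1000, applied = 5,
                                 noise_nm = 3, drift = 0.5,
                                 initial_tether_bp = 5700, seed = 1) {
  withr::with_seed(seed, {
    n <- length(x_bp)
    t <- (seq_len(n) - 1) / rate
    force <- rep(applied, n)
    fe <- fractional_extension(applied)
    ext <- (initial_tether_bp + x_bp) * 0.34 * fe +
      stats::rnorm(n, 0, noise_nm) + drift * t
    out <- tibble::tibble(time_s = t, force_pN = force, extension_nm = ext)
    attr(out, "event_id") <- "path"
    attr(out, "kind") <- "ejection"
    out
  })
}

# piecewise path: constant velocity v (bp/s) with pauses inserted at given
# times (s) and durations (s); returns exited bp at `rate` Hz over total_s
path_with_pauses <- function(v, total_s, pause_start, pause_dur,
                             rate = 1000) {
  t <- seq(0, total_s, by = 1 / rate)
  paused_before <- function(tt) {
    sum(pmin(pmax(tt - pause_start, 0), pause_dur))
  }
  moving <- t - vapply(t, paused_before, numeric(1))
  v * moving
}
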