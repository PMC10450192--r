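make_series <- function(y, rate = 1000) {
  tibble::tibble(time_s = (seq_along(y) - 1) / rate, exited_bp = y)
}

test_that("window velocities recover exact slopes and the OLS noise floor", {
  s <- make_series(100 + 300 * (0:999) / 1000)
  v <- window_velocities(s, 0.5, 0.1)
  expect_true(all(abs(v$velocity_bp_s - 300) < 1e-9))
  s0 <- make_series(rep(42, 1000))
  expect_true(all(abs(window_velocities(s0, 0.5, 0.5)$velocity_bp_s) < 1e-9))
  # white noise sigma = 10 bp at 1 kHz: closed-form slope SE ~ 3.1 bp/s
  sn <- make_series(withr::with_seed(8, rnorm(60000, 0, 10)))
  v <- window_velocities(sn, 0.5, 0.5)
  se_theory <- 10 * sqrt(12 / (500 * (500^2 - 1))) / 0.001
  expect_equal(sd(v$velocity_bp_s), se_theory, tolerance = 0.15)
  expect_error(window_velocities(make_series(1:10), 0.002), "3 samples")
  expect_error(window_velocities(make_series(1:10), 0.5), "shorter")
})

test_that("filling series converts exited length as a genome fraction", {
  s <- make_series(c(0, 1930, 3860, 19300), rate = 1)
  f <- filling_series(s, 19300)
  expect_equal(f$filling_pct, c(100, 90, 80, 0))
  expect_error(filling_series(s, initial_filling = 0), "initial_filling")
})

test_that("exited length is zero for a static trace and errors on bad force", {
  tr <- make_trace_from_path(rep(0, 2000), noise_nm = 0, drift = 0)
  s <- exited_length_series(tr)
  expect_true(all(abs(s$exited_bp) < 1e-9))
  tr$force_pN[5] <- -1
  expect_error(exited_length_series(tr), "force")
})

test_that("event profiles honour binning, coverage and pause exclusion", {
  sam <- tibble::tibble(time_s = 1:3, filling_pct = c(91, 92, 93),
                        velocity_bp_s = c(100, 200, 300), paused = FALSE)
  # half-bin coverage not reached (span 2% < 2.5%) -> bin absent
  expect_equal(nrow(event_profile(sam)), 0)
  sam2 <- tibble::tibble(time_s = 1:4, filling_pct = c(90.5, 92, 93, 94.6),
                         velocity_bp_s = c(100, 200, 300, 400), paused = FALSE)
  p <- event_profile(sam2)
  expect_equal(p$bin_center, 92.5)
  expect_equal(p$mean_velocity, 250)
  # pause exclusion empties the bin entirely
  sam2$paused <- TRUE
  expect_equal(nrow(event_profile(sam2, exclude_paused = TRUE)), 0)
  sam2$paused <- NA
  expect_error(event_profile(sam2, exclude_paused = TRUE), "paused")
  # 100% filling belongs to the top bin
  sam3 <- tibble::tibble(time_s = 1:2, filling_pct = c(100, 96),
                         velocity_bp_s = c(10, 20), paused = FALSE)
  expect_equal(event_profile(sam3)$bin_center, 97.5)
})

test_that("ensemble profile averages events and bootstraps their spread", {
  one_event <- function(v) tibble::tibble(
    bin_lo = 90, bin_hi = 95, bin_center = 92.5,
    mean_velocity = v, n_windows = 10L)
  same <- ensemble_profile(list(one_event(200), one_event(200)),
                           bootstrap_reps = 200, seed = 1)
  expect_equal(same$mean_velocity, 200)
  expect_equal(same$se, 0)
  two <- ensemble_profile(list(one_event(100), one_event(300)),
                          bootstrap_reps = 4000, seed = 1)
  expect_equal(two$mean_velocity, 200)
  # exhaustive enumeration of the 4 equally likely resamples:
  # means {100, 200, 200, 300} -> SD = sqrt(5000) = 70.7
  expect_equal(two$se, sqrt(5000), tolerance = 0.1)
  expect_equal(two$n_events, 2L)
})

test_that("log-linear profile fit recovers an exact exponential law", {
  centers <- seq(82.5, 97.5, by = 5)
  prof <- tibble::tibble(bin_center = centers,
                         mean_velocity = 200 * 10^((100 - centers) / 20))
  f <- fit_exponential_profile(prof)
  expect_equal(f$v_at_100, 200, tolerance = 1e-9)
  expect_equal(f$decade_filling, 20, tolerance = 1e-9)
  expect_equal(predict_profile_fit(f, 80), 2000, tolerance = 1e-6)
  flat <- tibble::tibble(bin_center = centers, mean_velocity = rep(500, 4))
  expect_identical(fit_exponential_profile(flat)$decade_filling, Inf)
  expect_error(fit_exponential_profile(prof[1:2, ]), "3 populated bins")
  prof$mean_velocity[1] <- -5
  expect_error(fit_exponential_profile(prof), "positive")
})

test_that("window velocities integrate back to the exited length", {
  cfg <- sim_config(seed = 6, extension_noise = 0.5, drift = 0)
  tr <- simulate_event(cfg, 1, pauses = FALSE, heterogeneity = FALSE)
  s <- exited_length_series(tr)
  v <- window_velocities(s, 0.5, 0.5)
  total <- sum(v$velocity_bp_s) * 0.5
  covered <- nrow(v) * 0.5
  truth <- approx(s$time_s, s$exited_bp, xout = covered)$y - s$exited_bp[1]
  expect_equal(total, truth, tolerance = 0.05)
})

test_that("pause-excluded bin means are never below pause-included ones", {
  run <- cached_default_run()
  incl <- run$res$profile_incl
  excl <- run$res$profile_excl
  shared <- intersect(incl$bin_center, excl$bin_center)
  vi <- incl$mean_velocity[match(shared, incl$bin_center)]
  ve <- excl$mean_velocity[match(shared, excl$bin_center)]
  expect_true(all(ve >= vi - 1e-9))
})
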