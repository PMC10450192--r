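test_that("velocity law hits its anchors and force/condition factors", {
  cfg <- sim_config()
  expect_equal(base_velocity(100, cfg), 200)
  expect_equal(base_velocity(80, cfg), 2000)
  # 20 pN law is the 5 pN law times the thermal-activation factor
  cfg20 <- sim_config(applied_force = 20)
  fac <- exp(15 * cfg$d_true / thermal_energy(cfg$elastic))
  expect_equal(base_velocity(100, cfg20), 200 * fac, tolerance = 1e-12)
  expect_equal(base_velocity(100, cfg20), 696, tolerance = 1e-3)
  cfg_mg <- sim_config(condition = "mg")
  expect_equal(base_velocity(90, cfg_mg), 0.5 * base_velocity(90, cfg))
  expect_error(base_velocity(101, cfg), "filling")
  expect_error(base_velocity(-1, cfg), "filling")
})

test_that("simulation is deterministic and events are seed-stable", {
  cfg <- sim_config(seed = 5)
  a <- simulate_event(cfg, 3)
  b <- simulate_event(cfg, 3)
  expect_identical(a, b)
  e2 <- simulate_ensemble(cfg, n_events = 2, n_controls = 1,
                          control_duration = 5)
  e3 <- simulate_ensemble(cfg, n_events = 3, n_controls = 1,
                          control_duration = 5)
  # adding an event does not perturb earlier ones
  expect_identical(e2$traces[[2]], e3$traces[[2]])
})

test_that("pause-free noiseless event reproduces the closed-form exit time", {
  cfg <- sim_config(seed = 9, extension_noise = 0, drift = 0,
                    force_jitter = 0)
  tr <- simulate_event(cfg, 1, pauses = FALSE, heterogeneity = FALSE)
  fs <- filling_series(exited_length_series(tr))
  # analytic: integral of (193 bp/%) / v(phi) from 100 to 80
  t80 <- fs$time_s[which(fs$filling_pct <= 80)[1]]
  expect_equal(t80, 19.3 * 0.9 / log(10), tolerance = 2e-3)
  expect_true(all(diff(fs$exited_bp) >= -1e-9))
})

test_that("pause onsets near full capsid are spaced as the hazard dictates", {
  cfg <- sim_config(seed = 21)
  sp <- unlist(lapply(1:20, function(i) {
    tp <- attr(simulate_event(cfg, i), "truth")$pauses
    diff(tp$exited_bp[tp$exited_bp < 800])
  }))
  # hazard 0.030/bp at 100% filling -> mean spacing ~33 bp (10-100 bp range)
  expect_gt(length(sp), 100)
  expect_gt(mean(sp), 15)
  expect_lt(mean(sp), 100)
})

test_that("inter-pause exited lengths are exponential under constant hazard", {
  cfg <- sim_config(seed = 31, pause_rate_scale = 1e9)
  pos <- withr::with_seed(31, ejectr:::.draw_pause_positions(cfg, 80000))
  sp <- diff(pos)
  expect_gt(length(sp), 2000)
  ks <- suppressWarnings(stats::ks.test(sp, "pexp", rate = 1 / mean(sp)))
  expect_gt(ks$p.value, 0.01)
  # MLE rate recovers the configured hazard within 2 SE
  rate <- 1 / mean(sp)
  expect_lt(abs(rate - 0.030), 2 * 0.030 / sqrt(length(sp)))
})

test_that("static controls carry only the configured noise and drift", {
  cfg0 <- sim_config(seed = 4, extension_noise = 0, drift = 0,
                     force_jitter = 0)
  ctl0 <- simulate_control(cfg0, duration = 2)
  expect_lt(diff(range(ctl0$extension_nm)), 1e-9)
  # default drift propagates to ~drift / (rise * frac_ext(5 pN)) bp/s
  cfg <- sim_config(seed = 4)
  ctl <- simulate_control(cfg, duration = 30)
  v <- window_velocities(exited_length_series(ctl), 0.5, 0.5)$velocity_bp_s
  expect_equal(mean(v), 0.5 / (0.34 * fractional_extension(5)),
               tolerance = 0.4)
})

test_that("generator calibration: paused fraction matches the analytic derivation", {
  # the default pause rate was derived analytically (eta = 1) so that
  # paused time / total time ~ 0.57; the closed form is the documented oracle
  expect_equal(paused_fraction_oracle(sim_config()), 0.567, tolerance = 0.005)
  cfg <- sim_config(seed = 13)
  ens <- simulate_ensemble(cfg, n_events = 16, n_controls = 1,
                           control_duration = 5, heterogeneity = FALSE)
  paused <- sum(vapply(ens$traces, function(x) attr(x, "truth")$paused_time,
                       numeric(1)))
  total <- sum(vapply(ens$traces, function(x) attr(x, "truth")$t_total,
                      numeric(1)))
  expect_equal(paused / total, paused_fraction_oracle(cfg), tolerance = 0.08)
})

test_that("exit-time heterogeneity spans roughly an order of magnitude", {
  cfg <- sim_config(seed = 2026)
  times <- vapply(1:39, function(i) attr(simulate_event(cfg, i), "truth")$t_total,
                  numeric(1))
  expect_gt(max(times) / min(times), 4)
  expect_gt(median(times), 5)
  expect_lt(median(times), 120)
})
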