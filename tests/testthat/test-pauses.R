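test_that("KV finds a clean step and leaves pure noise unsegmented", {
  y <- c(rep(0, 50), rep(100, 50))
  expect_identical(kv_changepoints(y), 50L)
  hits <- vapply(1:40, function(s) {
    length(kv_changepoints(withr::with_seed(s, rnorm(500)))) == 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  expect_error(kv_changepoints(rnorm(4), min_segment = 3), "too short")
})

test_that("greedy KV matches exhaustive BIC search on small instances", {
  cases <- list(
    list(steps = integer(0), levels = 0),
    list(steps = 20L, levels = c(0, 5)),
    list(steps = c(13L, 27L), levels = c(0, 5, 10)),
    list(steps = c(10L, 30L), levels = c(0, -6, 2))
  )
  # fixed seeds giving instances whose BIC optimum has at most two change
  # points (with near-threshold noise features the optimum can acquire
  # spurious extra steps, where a greedy search need not coincide with a
  # k-restricted exhaustive one)
  for (cs in cases) {
    for (seed in c(3, 4, 6)) {
      mu <- rep(cs$levels, diff(c(0, cs$steps, 40)))
      y <- withr::with_seed(seed, mu + rnorm(40))
      expect_identical(kv_changepoints(y, 3),
                       as.integer(bic_exhaustive_oracle(y, 2, 3)),
                       info = sprintf("steps=%s seed=%d",
                                      paste(cs$steps, collapse = ","), seed))
    }
  }
})

test_that("control calibration measures the noise floor and drift", {
  cfg0 <- sim_config(seed = 3, extension_noise = 0, drift = 0,
                     force_jitter = 0)
  ctl0 <- simulate_control(cfg0, duration = 25)
  nm0 <- calibrate_noise(list(ctl0), dt_grid = c(0.1, 0.5, 2))
  expect_true(all(nm0$table$sd_bp_s < 1e-9))
  expect_lt(nm0$resolution_bp, 1e-9)

  cfg <- sim_config(seed = 3)
  ctls <- list(simulate_control(cfg, 40, 1), simulate_control(cfg, 40, 2))
  nm <- calibrate_noise(ctls)
  # SD decreases with longer averaging intervals
  expect_true(all(diff(nm$table$sd_bp_s) < 0))
  expect_true(all(diff(nm$table$net_sd_bp_s) < 0))
  # OLS slope SD at 0.5 s close to the closed form for 3 nm extension noise
  sig_bp <- 3 / (0.34 * fractional_extension(5))
  theory <- sig_bp * sqrt(12 / (500 * (500^2 - 1))) / 0.001
  got <- nm$table$sd_bp_s[nm$table$dt_s == 0.5]
  expect_equal(got, theory, tolerance = 0.25)
  # drift recovered in bp/s
  expect_equal(nm$drift_bp_s, 0.5 / (0.34 * fractional_extension(5)),
               tolerance = 0.25)
  expect_error(calibrate_noise(list(simulate_control(cfg, 2))), "insufficient")
})

test_that("an inserted one-second pause is recovered once with its duration", {
  x <- path_with_pauses(300, 10, pause_start = 4.5, pause_dur = 1.0)
  tr <- make_trace_from_path(x, seed = 11)
  cfg <- sim_config(seed = 12)
  nm <- calibrate_noise(list(simulate_control(cfg, 40, 1),
                             simulate_control(cfg, 40, 2)))
  det <- detect_pauses(tr, nm)
  expect_equal(nrow(det$pauses), 1)
  expect_equal(det$pauses$duration_s, 1.0, tolerance = 0.1)
  expect_equal(det$pauses$start_s, 4.5, tolerance = 0.1)
  # pause-free path yields no pauses
  x0 <- path_with_pauses(300, 10, numeric(0), numeric(0))
  det0 <- detect_pauses(make_trace_from_path(x0, seed = 13), nm)
  expect_equal(nrow(det0$pauses), 0)
})

test_that("pauses separated by a sub-resolution advance are merged", {
  # two 0.5 s pauses separated by a 2 bp step (below the length resolution)
  x <- path_with_pauses(300, 8, pause_start = c(3.0, 3.5 + 2 / 300),
                        pause_dur = c(0.5, 0.5))
  tr <- make_trace_from_path(x, seed = 21)
  cfg <- sim_config(seed = 22)
  nm <- calibrate_noise(list(simulate_control(cfg, 40, 1),
                             simulate_control(cfg, 40, 2)))
  det <- detect_pauses(tr, nm)
  expect_equal(nrow(det$pauses), 1)
  expect_equal(det$pauses$duration_s, 1.0, tolerance = 0.12)
})

test_that("resolvable inserted pauses are detected with high power and few false calls", {
  cfg <- sim_config(seed = 42)
  nm <- calibrate_noise(list(simulate_control(cfg, 40, 1),
                             simulate_control(cfg, 40, 2)))
  n_hit <- 0; n_true <- 0; n_false <- 0; n_det <- 0
  for (rep in 1:3) {
    t0 <- seq(2, 56, by = 3)
    durs <- withr::with_seed(40 + rep, runif(length(t0), 0.15, 0.8))
    t1 <- t0 + durs
    x <- path_with_pauses(300, 60, t0, durs)
    p <- detect_pauses(make_trace_from_path(x, seed = 60 + rep), nm)$pauses
    hit <- vapply(seq_along(t0), function(i) {
      any(pmin(p$end_s, t1[i]) - pmax(p$start_s, t0[i]) > 0.5 * durs[i])
    }, logical(1))
    false_call <- vapply(seq_len(nrow(p)), function(j) {
      all(pmin(p$end_s[j], t1) - pmax(p$start_s[j], t0) < 0.25 * p$duration_s[j])
    }, logical(1))
    n_hit <- n_hit + sum(hit); n_true <- n_true + length(hit)
    n_false <- n_false + sum(false_call); n_det <- n_det + nrow(p)
  }
  expect_gte(n_hit / n_true, 0.95)
  expect_lte(n_false / n_det, 0.05)
})

test_that("pause time bookkeeping is conserved and pauses are well formed", {
  run <- cached_small_run()
  p <- run$res$pauses
  expect_true(all(p$duration_s > 0))
  expect_equal(p$duration_s, p$end_s - p$start_s)
  for (id in unique(p$event_id)) {
    pe <- p[p$event_id == id, ]
    pe <- pe[order(pe$start_s), ]
    if (nrow(pe) > 1) expect_true(all(pe$start_s[-1] >= pe$end_s[-nrow(pe)]))
    fs <- run$res$series[[id]]
    total <- max(fs$time_s) - min(fs$time_s) + (fs$time_s[2] - fs$time_s[1])
    expect_lte(sum(pe$duration_s), total)
    expect_gte(min(pe$start_s), min(fs$time_s) - 0.02)
    expect_lte(max(pe$end_s), max(fs$time_s) + 0.02)
  }
  # summary pools paused over total exactly
  ps <- pause_summary(p, run$res$series)
  expect_equal(ps$fraction_paused,
               sum(p$duration_s) / sum(ps$per_event$total_time_s))
})

test_that("per-bin pause metrics compute fractions, frequencies and absences", {
  fs <- tibble::tibble(time_s = seq(0, 10, by = 0.01),
                       exited_bp = seq(0, 965, length.out = 1001)) |>
    filling_series(19300)
  pauses <- tibble::tibble(event_id = "e1", start_s = c(1, 5),
                           end_s = c(4, 8),
                           duration_s = c(3, 3),
                           filling_pct = c(99.6, 97.6),
                           exited_bp = c(96.5, 482.5))
  m <- pause_metrics_by_bin(pauses, list(e1 = fs), bootstrap_reps = 100,
                            seed = 1)
  top <- m[m$bin_center == 97.5, ]
  expect_equal(top$fraction_paused, 0.6)
  expect_equal(top$n_pauses, 2L)
  expect_equal(top$frequency_per_kb, 2 / 0.965, tolerance = 1e-6)
  expect_equal(top$mean_duration_s, 3)
  # no pauses at all: zero frequency and fraction, absent duration
  m0 <- pause_metrics_by_bin(pauses[0, ], list(e1 = fs),
                             bootstrap_reps = 100, seed = 1)
  expect_true(all(m0$frequency_per_kb == 0))
  expect_true(all(m0$fraction_paused == 0))
  expect_true(all(is.na(m0$mean_duration_s)))
})

test_that("pause frequency and duration decline toward lower filling", {
  run <- cached_default_run()
  pb <- run$res$pause_bins
  top <- pb[pb$bin_center == 97.5, ]
  low <- pb[pb$bin_center == 82.5, ]
  expect_gt(top$frequency_per_kb, low$frequency_per_kb)
  expect_gt(top$fraction_paused, low$fraction_paused)
})
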