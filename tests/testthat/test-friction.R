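test_that("internal and total driving forces interpolate the knot curve", {
  expect_equal(internal_force(100), 25)
  expect_equal(internal_force(93), 15)
  expect_equal(internal_force(50), 0)
  expect_equal(internal_force(95), 17.5) # midway between 15 and 20
  expect_equal(total_driving_force(93, 5), 20)
  expect_equal(total_driving_force(100, 20), 45)
  expect_equal(total_driving_force(50, 0), 0)
  expect_error(internal_force(101), "outside")
  expect_error(total_driving_force(90, -1), "applied")
  expect_error(force_filling_curve(cbind(c(0, 50, 40), c(0, 1, 2))),
               "increasing")
})

test_that("PT velocity ratio follows the thermal-activation factor", {
  expect_equal(pt_predicted_ratio(0, 0.34), 1)
  expect_equal(pt_predicted_ratio(15, 0.34), 3.48, tolerance = 2e-3)
  r <- pt_predicted_ratio(10, c(0.2, 0.4, 0.8))
  expect_true(all(diff(r) > 0))
  expect_error(pt_predicted_ratio(5, -0.1), "positive")
})

test_that("per-bin d fitting inverts the friction law exactly", {
  kT <- thermal_energy()
  centers <- seq(82.5, 97.5, by = 5)
  v_lo <- base_velocity(centers, sim_config())
  for (d_true in c(0.1, 0.33, 0.5, 1.0)) {
    v_hi <- v_lo * pt_predicted_ratio(15, d_true)
    fit <- fit_d_per_bin(tibble::tibble(bin_center = centers, mean_velocity = v_lo),
                         tibble::tibble(bin_center = centers, mean_velocity = v_hi),
                         bootstrap_reps = 0)
    expect_equal(fit$per_bin$d_nm, rep(d_true, 4), tolerance = 1e-12)
    expect_equal(fit$d_overall, d_true, tolerance = 1e-12)
  }
  # hand value: v 200 -> 696 over Delta F = 15 pN gives d ~ 0.34 nm
  f1 <- fit_d_per_bin(tibble::tibble(bin_center = 100, mean_velocity = 200),
                      tibble::tibble(bin_center = 100, mean_velocity = 696),
                      bootstrap_reps = 0)
  expect_equal(f1$d_overall, 0.34, tolerance = 1e-3)
  expect_equal(f1$per_bin$mu_bp_s, 200 * exp(-30 * f1$d_overall / kT),
               tolerance = 1e-9)
  # degenerate: equal velocities -> d = 0, flagged
  expect_warning(
    f0 <- fit_d_per_bin(tibble::tibble(bin_center = 90, mean_velocity = 500),
                        tibble::tibble(bin_center = 90, mean_velocity = 500),
                        bootstrap_reps = 0),
    "non-positive")
  expect_equal(f0$d_overall, 0)
  expect_error(fit_d_per_bin(tibble::tibble(bin_center = 90, mean_velocity = 0),
                             tibble::tibble(bin_center = 90, mean_velocity = 5),
                             bootstrap_reps = 0), "positive")
})

test_that("d fitting works with any monotone force curve and bin order", {
  crv <- force_filling_curve(cbind(c(0, 60, 90, 100), c(0, 2, 11, 30)))
  centers <- c(92.5, 87.5, 97.5, 82.5) # scrambled
  v_lo <- 100 + 50 * seq_along(centers)
  v_hi <- v_lo * pt_predicted_ratio(15, 0.42)
  fit <- fit_d_per_bin(tibble::tibble(bin_center = centers, mean_velocity = v_lo),
                       tibble::tibble(bin_center = centers, mean_velocity = v_hi),
                       curve = crv, bootstrap_reps = 0)
  expect_equal(fit$d_overall, 0.42, tolerance = 1e-12)
  fit2 <- fit_d_per_bin(
    tibble::tibble(bin_center = sort(centers),
                   mean_velocity = v_lo[order(centers)]),
    tibble::tibble(bin_center = sort(centers),
                   mean_velocity = v_hi[order(centers)]),
    curve = crv, bootstrap_reps = 0)
  expect_equal(fit2$d_overall, fit$d_overall)
})

test_that("the linear-mobility ratio test separates PT from v = mu F data", {
  centers <- seq(82.5, 97.5, by = 5)
  v_lo <- base_velocity(centers, sim_config())
  # PT world: velocity ratio ~ 3.48 exceeds the force ratio
  v_hi <- v_lo * pt_predicted_ratio(15, 0.34)
  tt <- linear_mobility_test(tibble::tibble(bin_center = centers, mean_velocity = v_lo),
                             tibble::tibble(bin_center = centers, mean_velocity = v_hi))
  expect_true(all(tt$linear_rejected))
  expect_true(all(tt$velocity_ratio > tt$force_ratio))
  # linear world: ratios agree, nothing rejected
  Flo <- total_driving_force(centers, 5)
  Fhi <- total_driving_force(centers, 20)
  tl <- linear_mobility_test(
    tibble::tibble(bin_center = centers, mean_velocity = 0.3 * Flo),
    tibble::tibble(bin_center = centers, mean_velocity = 0.3 * Fhi))
  expect_equal(tl$velocity_ratio, tl$force_ratio, tolerance = 1e-12)
  expect_false(any(tl$linear_rejected))
  # single shared bin -> table of length 1
  t1 <- linear_mobility_test(tibble::tibble(bin_center = 90, mean_velocity = 100),
                             tibble::tibble(bin_center = 90, mean_velocity = 300))
  expect_equal(nrow(t1), 1)
})

test_that("packaging friction is clamped, monotone and matches hand values", {
  centers <- seq(82.5, 97.5, by = 5)
  v_lo <- base_velocity(centers, sim_config())
  v_hi <- v_lo * pt_predicted_ratio(15, 0.34)
  fit <- fit_d_per_bin(tibble::tibble(bin_center = c(centers, 100),
                                      mean_velocity = c(v_lo, 200)),
                       tibble::tibble(bin_center = c(centers, 100),
                                      mean_velocity = c(v_hi, 696)),
                       bootstrap_reps = 0)
  mu100 <- fit$per_bin$mu_bp_s[fit$per_bin$bin_center == 100]
  expect_equal(mu100, 16.5, tolerance = 0.05)
  expect_equal(packaging_friction(mu100, 100, fit), 0)
  expect_equal(packaging_friction(11, 100, fit), 0)
  expect_equal(packaging_friction(160, 100, fit), 27, tolerance = 0.5)
  v <- c(20, 50, 100, 200)
  f <- packaging_friction(v, rep(100, 4), fit)
  expect_true(all(diff(f) >= 0))
  expect_error(packaging_friction(100, 60, fit), "mobility")
  expect_error(packaging_friction(-5, 100, fit), "positive")
})

test_that("motor-speed friction prediction stays below 0.1 pN across filling", {
  grid <- seq(80, 100, by = 1)
  v_pack <- approx(c(80, 100), c(55, 11), xout = grid)$y
  pf <- predicted_packaging_friction(v_pack, grid)
  expect_lte(max(pf$friction_pN), 0.1)
  # mobility at full capsid matches the calibrated value
  expect_equal(pf$mu_bp_s[grid == 100], 16.5, tolerance = 0.05)
})
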