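# Prandtl-Tomlinson friction analysis: internal-force curve, total driving
# force, fitting of the friction periodicity d and mobility mu from paired
# force-condition velocity profiles, the linear-mobility ratio test, and
# the packaging-friction prediction.

#' Internal force versus capsid filling curve
#'
#' Monotone piecewise-linear interpolation knots for the internal force
#' resisting DNA confinement, as established by optical-tweezers packaging
#' measurements: zero up to half filling, rising to ~25 pN at 100%. The
#' knots between the published anchors are smooth calibrated defaults and
#' fully configurable.
#'
#' @param knots A two-column data frame or matrix (filling %, force pN)
#'   with strictly increasing filling and non-decreasing force.
#' @return A `force_filling_curve` tibble with columns `filling_pct`,
#'   `force_pN`.
#' @export
force_filling_curve <- function(knots = cbind(
  filling_pct = c(0, 50, 70, 80, 90, 93, 97, 100),
  force_pN = c(0, 0, 3, 10, 14, 15, 20, 25))) {
  k <- tibble::as_tibble(as.data.frame(knots))
  names(k) <- c("filling_pct", "force_pN")
  if (any(diff(k$filling_pct) <= 0)) {
    rlang::abort("knot fillings must be strictly increasing")
  }
  if (any(diff(k$force_pN) < 0)) {
    rlang::abort("knot forces must be non-decreasing")
  }
  structure(k, class = c("force_filling_curve", class(k)))
}

#' Internal force at a filling level
#'
#' @param filling Filling in %, within the knot range.
#' @param curve A [force_filling_curve()].
#' @return Internal force in pN, vectorised.
#' @examples
#' internal_force(c(50, 93, 100))
#' @export
internal_force <- function(filling, curve = force_filling_curve()) {
  rng <- range(curve$filling_pct)
  if (any(!is.finite(filling)) || any(filling < rng[1] | filling > rng[2])) {
    rlang::abort("filling outside the knot range of the force curve")
  }
  stats::approx(curve$filling_pct, curve$force_pN, xout = filling)$y
}

#' Total driving force
#'
#' Internal force plus the externally applied pulling force; during
#' overdamped exit its magnitude equals the friction force opposing exit.
#'
#' @param filling Filling in %.
#' @param applied Applied force in pN, `>= 0`.
#' @param curve A [force_filling_curve()].
#' @return Total force in pN.
#' @export
total_driving_force <- function(filling, applied,
                                curve = force_filling_curve()) {
  if (any(applied < 0)) rlang::abort("applied force must be >= 0")
  internal_force(filling, curve) + applied
}

#' Velocity ratio predicted by the Prandtl-Tomlinson relationship
#'
#' For thermally activated sliding over a periodic potential of period `d`,
#' `F = (kT/d) ln(v/mu)`, so a force change `dF` at fixed mobility
#' multiplies the velocity by `exp(dF * d / kT)` (natural-log convention).
#'
#' @param delta_force Force difference in pN.
#' @param d Periodicity in nm (> 0).
#' @param temperature Temperature in K.
#' @return Dimensionless velocity ratio.
#' @examples
#' pt_predicted_ratio(15, 0.34) # ~3.48
#' @export
pt_predicted_ratio <- function(delta_force, d, temperature = 296.15) {
  if (any(d <= 0)) rlang::abort("d must be positive")
  exp(delta_force * d / (.kB * temperature))
}

#' Fit the Prandtl-Tomlinson periodicity d per filling bin
#'
#' From paired velocity profiles at two applied forces sharing filling
#' bins, inverts the friction law bin by bin:
#' `d = kT ln(v_hi / v_lo) / (F_hi - F_lo)` with `F` the total driving
#' force at the bin centre. The overall `d` is the unweighted mean of the
#' per-bin values (bins with inverted velocity ratios, `d <= 0`, are kept
#' in the table but excluded from the mean with a warning). The mobility is
#' `mu = v_lo exp(-F_lo d / kT)` per bin. If both profiles carry per-event
#' bin means (see [ensemble_profile()]), a bootstrap over events in each
#' ensemble yields `d_se`.
#'
#' @param profile_lo,profile_hi `velocity_profile` tibbles (or any tibble
#'   with `bin_center`, `mean_velocity`).
#' @param applied_lo,applied_hi Applied forces in pN for the two profiles.
#' @param curve A [force_filling_curve()].
#' @param temperature Temperature in K.
#' @param bootstrap_reps Bootstrap resamples for `d_se` (0 to skip).
#' @param seed Optional bootstrap seed.
#' @return An object of class `pt_fit`: list with `per_bin` (tibble of
#'   `bin_center`, `v_lo`, `v_hi`, `F_lo`, `F_hi`, `d_nm`, `mu_bp_s`),
#'   `d_overall`, `d_se`, `temperature`, `curve`.
#' @export
fit_d_per_bin <- function(profile_lo, profile_hi, applied_lo = 5,
                          applied_hi = 20, curve = force_filling_curve(),
                          temperature = 296.15, bootstrap_reps = 1000,
                          seed = NULL) {
  shared <- intersect(profile_lo$bin_center, profile_hi$bin_center)
  if (!length(shared)) rlang::abort("profiles share no populated bins")
  kT <- .kB * temperature
  tab_d <- function(v_lo, v_hi, centers) {
    if (any(v_lo <= 0) || any(v_hi <= 0)) {
      rlang::abort("velocities must be positive")
    }
    F_lo <- total_driving_force(centers, applied_lo, curve)
    F_hi <- total_driving_force(centers, applied_hi, curve)
    if (any(F_hi == F_lo)) rlang::abort("equal total forces; d undefined")
    kT * log(v_hi / v_lo) / (F_hi - F_lo)
  }
  v_lo <- profile_lo$mean_velocity[match(shared, profile_lo$bin_center)]
  v_hi <- profile_hi$mean_velocity[match(shared, profile_hi$bin_center)]
  d_nm <- tab_d(v_lo, v_hi, shared)
  usable <- d_nm > 0
  if (!all(usable)) {
    rlang::warn(sprintf(
      "%d bin(s) with non-positive fitted d excluded from the overall mean",
      sum(!usable)))
  }
  d_overall <- if (any(usable)) mean(d_nm[usable]) else 0
  F_lo <- total_driving_force(shared, applied_lo, curve)
  per_bin <- tibble::tibble(
    bin_center = shared, v_lo = v_lo, v_hi = v_hi,
    F_lo = F_lo, F_hi = total_driving_force(shared, applied_hi, curve),
    d_nm = d_nm,
    mu_bp_s = v_lo * exp(-F_lo * d_overall / kT)
  )
  d_se <- NA_real_
  em_lo <- attr(profile_lo, "event_means")
  em_hi <- attr(profile_hi, "event_means")
  if (!is.null(em_lo) && !is.null(em_hi) && bootstrap_reps > 0) {
    boot_mean <- function(em, ids) {
      dplyr::inner_join(em, tibble::tibble(event_id = ids), by = "event_id",
                        relationship = "many-to-many") |>
        dplyr::group_by(.data$bin_center) |>
        dplyr::summarise(v = mean(.data$mean_velocity), .groups = "drop")
    }
    ids_lo <- unique(em_lo$event_id)
    ids_hi <- unique(em_hi$event_id)
    d_reps <- withr::with_seed(
      if (is.null(seed)) stats::runif(1, 1, 2^30) else seed, {
        purrr::map_dbl(seq_len(bootstrap_reps), function(i) {
          mlo <- boot_mean(em_lo, sample(ids_lo, replace = TRUE))
          mhi <- boot_mean(em_hi, sample(ids_hi, replace = TRUE))
          sh <- intersect(intersect(mlo$bin_center, mhi$bin_center), shared)
          if (!length(sh)) return(NA_real_)
          vl <- mlo$v[match(sh, mlo$bin_center)]
          vh <- mhi$v[match(sh, mhi$bin_center)]
          if (any(vl <= 0) || any(vh <= 0)) return(NA_real_)
          dd <- tab_d(vl, vh, sh)
          if (!any(dd > 0)) return(NA_real_)
          mean(dd[dd > 0])
        })
      })
    d_se <- stats::sd(d_reps, na.rm = TRUE)
  }
  structure(list(per_bin = per_bin, d_overall = d_overall, d_se = d_se,
                 temperature = temperature, curve = curve,
                 applied_lo = applied_lo, applied_hi = applied_hi),
            class = "pt_fit")
}

#' Linear-mobility (hydrodynamic drag) ratio test
#'
#' Under a linear force-velocity law `v = mu F`, the ratio of velocities at
#' two applied forces equals the ratio of total driving forces. The test
#' compares the two ratios per shared filling bin; the linear model is
#' rejected in a bin when the velocity ratio exceeds the force ratio by
#' more than the propagated bootstrap error of the velocity ratio.
#'
#' @inheritParams fit_d_per_bin
#' @return A tibble with `bin_center`, `velocity_ratio`, `ratio_se`,
#'   `force_ratio`, `linear_rejected`.
#' @export
linear_mobility_test <- function(profile_lo, profile_hi, applied_lo = 5,
                                 applied_hi = 20,
                                 curve = force_filling_curve()) {
  shared <- intersect(profile_lo$bin_center, profile_hi$bin_center)
  if (!length(shared)) rlang::abort("profiles share no populated bins")
  ilo <- match(shared, profile_lo$bin_center)
  ihi <- match(shared, profile_hi$bin_center)
  v_lo <- profile_lo$mean_velocity[ilo]
  v_hi <- profile_hi$mean_velocity[ihi]
  if (any(v_lo == 0)) rlang::abort("zero velocity in denominator")
  F_lo <- total_driving_force(shared, applied_lo, curve)
  F_hi <- total_driving_force(shared, applied_hi, curve)
  if (any(F_lo == 0)) rlang::abort("zero total force in denominator")
  vr <- v_hi / v_lo
  se_lo <- if ("se" %in% names(profile_lo)) profile_lo$se[ilo] else 0
  se_hi <- if ("se" %in% names(profile_hi)) profile_hi$se[ihi] else 0
  ratio_se <- vr * sqrt((se_lo / v_lo)^2 + (se_hi / v_hi)^2)
  fr <- F_hi / F_lo
  tibble::tibble(bin_center = shared, velocity_ratio = vr,
                 ratio_se = ratio_se, force_ratio = fr,
                 linear_rejected = vr - ratio_se > fr * (1 + 1e-9))
}

#' Prandtl-Tomlinson friction force at a given velocity and mobility
#'
#' `F = max(0, (kT/d) ln(v/mu))`, clamped at zero in the thermally assisted
#' regime `v <= mu` where the net friction vanishes.
#'
#' @param v Sliding velocity in bp/s (> 0).
#' @param mu Mobility in bp/s (> 0).
#' @param d Periodicity in nm.
#' @param temperature Temperature in K.
#' @return Friction force in pN.
#' @export
pt_friction_force <- function(v, mu, d, temperature = 296.15) {
  if (any(v <= 0) || any(mu <= 0) || any(d <= 0)) {
    rlang::abort("v, mu and d must be positive")
  }
  pmax(0, (.kB * temperature / d) * log(v / mu))
}

#' Predicted friction during motor-driven packaging
#'
#' Evaluates the fitted friction law at packaging velocities: looks up the
#' mobility of the filling bin containing `filling` in a `pt_fit` and
#' returns `max(0, (kT/d) ln(v_pack/mu))`.
#'
#' @param v_pack Packaging velocity in bp/s (> 0).
#' @param filling Filling level in %.
#' @param fit A `pt_fit` from [fit_d_per_bin()].
#' @return Predicted friction force in pN, vectorised over
#'   `v_pack`/`filling`.
#' @export
packaging_friction <- function(v_pack, filling, fit) {
  if (any(v_pack <= 0)) rlang::abort("v_pack must be positive")
  bw <- min(diff(sort(unique(fit$per_bin$bin_center))))
  if (!is.finite(bw)) bw <- 5
  idx <- vapply(filling, function(f) {
    i <- which(abs(fit$per_bin$bin_center - f) <= bw / 2)
    if (!length(i)) NA_integer_ else i[1]
  }, integer(1))
  if (any(is.na(idx))) {
    rlang::abort("no fitted mobility for a requested filling level")
  }
  pt_friction_force(v_pack, fit$per_bin$mu_bp_s[idx], fit$d_overall,
                    fit$temperature)
}

#' Analytic packaging-friction prediction from a calibrated velocity law
#'
#' Computes the mobility profile implied by an exit velocity law and force
#' curve, `mu(phi) = v(phi) exp(-F_total(phi) d / kT)`, then evaluates the
#' Prandtl-Tomlinson friction at packaging velocities on the same filling
#' grid. This is the closed-form counterpart of fitting `mu` from data.
#'
#' @param v_pack Packaging velocities in bp/s (recycled against `filling`).
#' @param filling Filling grid in %.
#' @param applied Applied force of the reference exit condition, pN.
#' @param curve A [force_filling_curve()].
#' @param config A [sim_config()] supplying the exit velocity law.
#' @param d Periodicity in nm.
#' @return Tibble with `filling_pct`, `v_pack_bp_s`, `mu_bp_s`,
#'   `friction_pN`.
#' @export
predicted_packaging_friction <- function(v_pack, filling, applied = 5,
                                         curve = force_filling_curve(),
                                         config = sim_config(),
                                         d = 0.34) {
  kT <- thermal_energy(config$elastic)
  Ftot <- total_driving_force(filling, applied, curve)
  mu <- base_velocity(filling, config) * exp(-Ftot * d / kT)
  tibble::tibble(filling_pct = filling, v_pack_bp_s = v_pack,
                 mu_bp_s = mu,
                 friction_pN = pmax(0, (kT / d) * log(v_pack / mu)))
}
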