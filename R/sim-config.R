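# Configuration of the stochastic force-clamp trace generator.

#' Simulation configuration for synthetic DNA-exit traces
#'
#' Collects every parameter of the forward model used by [simulate_event()],
#' [simulate_control()] and [simulate_ensemble()]. The defaults are
#' calibrated to the published statistical structure of phi29 DNA ejection
#' under a 5 pN force clamp with Na+ screening: exit velocity rising
#' exponentially from ~200 bp/s at 100% capsid filling to ~2000 bp/s at 80%
#' (one decade per 20% filling), a ~12 kb/s tracking cap, Poisson pause
#' onsets in exited length (~33 bp mean spacing at full capsid), power-law
#' pause durations (density exponent 2.3), and a per-event lognormal
#' velocity multiplier reproducing the large event-to-event heterogeneity.
#'
#' @param genome_bp Genome length in bp defining 100% filling (19300).
#' @param sample_rate Acquisition rate in Hz (1000).
#' @param applied_force Force-clamp setpoint in pN, 5 or 20.
#' @param condition Ionic screening condition, `"na"` or `"mg"`.
#' @param v100 Velocity-law anchor at 100% filling, bp/s (200).
#' @param decade_filling Filling decrease per tenfold velocity increase, %
#'   (20).
#' @param velocity_cap Maximum trackable velocity, bp/s (12000); an event
#'   ends when the instantaneous velocity reaches it.
#' @param pause_rate_100 Pause-onset hazard per bp exited at 100% filling
#'   (0.030).
#' @param pause_rate_scale e-folding filling scale of the hazard, % (7).
#' @param pareto_alpha Power-law density exponent of pause durations (2.3;
#'   must exceed 2 so the mean duration is finite).
#' @param pareto_xmin_100 Pareto scale (minimum duration) at 100% filling,
#'   s (0.09).
#' @param xmin_scale e-folding filling scale of the Pareto scale, % (15).
#' @param heterogeneity_sigma Log-scale SD of the mean-one lognormal
#'   per-event velocity multiplier (0.6).
#' @param extension_noise Gaussian extension noise per sample, nm (3.0).
#' @param drift Linear instrument drift, nm/s (0.5).
#' @param force_jitter SD of the force-clamp residual, pN (0.3).
#' @param mg_velocity_factor,mg_rate_factor,mg_xmin_factor Multipliers
#'   applied under Mg2+ screening to the velocity law, the pause hazard and
#'   the duration scale (0.5, 1.2, 1.5).
#' @param highforce_rate_factor,highforce_xmin_factor Multipliers applied at
#'   20 pN applied force to the pause hazard and duration scale (0.6, 0.7).
#' @param d_true Friction periodicity in nm used to derive the velocity law
#'   at non-reference applied force via the Prandtl-Tomlinson factor (0.34).
#' @param pause_floor_filling Filling level in % below which pauses are
#'   disabled (50).
#' @param initial_tether_bp Contour length of DNA outside the capsid at the
#'   start of exit, bp (5700: a 25 kb construct minus the 19.3 kb genome).
#' @param elastic An [elastic_params()] object.
#' @param seed Integer master seed; per-event sub-seeds derive from it.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genome_bp = 19300, sample_rate = 1000,
                       applied_force = 5, condition = c("na", "mg"),
                       v100 = 200, decade_filling = 20, velocity_cap = 12000,
                       pause_rate_100 = 0.030, pause_rate_scale = 7,
                       pareto_alpha = 2.3, pareto_xmin_100 = 0.09,
                       xmin_scale = 15, heterogeneity_sigma = 0.6,
                       extension_noise = 3.0, drift = 0.5,
                       force_jitter = 0.3,
                       mg_velocity_factor = 0.5, mg_rate_factor = 1.2,
                       mg_xmin_factor = 1.5,
                       highforce_rate_factor = 0.6,
                       highforce_xmin_factor = 0.7,
                       d_true = 0.34, pause_floor_filling = 50,
                       initial_tether_bp = 5700,
                       elastic = elastic_params(), seed = 1L) {
  condition <- match.arg(condition)
  if (!applied_force %in% c(5, 20)) {
    rlang::abort("applied_force must be 5 or 20 pN")
  }
  if (pareto_alpha <= 2) {
    rlang::abort("pareto_alpha must exceed 2 (finite mean pause duration)")
  }
  pos <- c(genome_bp, sample_rate, v100, decade_filling, velocity_cap,
           pause_rate_100, pause_rate_scale, pareto_xmin_100, xmin_scale,
           mg_velocity_factor, mg_rate_factor, mg_xmin_factor,
           highforce_rate_factor, highforce_xmin_factor, d_true,
           initial_tether_bp)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    rlang::abort("rates, scales and anchors must be strictly positive")
  }
  cfg <- list(genome_bp = genome_bp, sample_rate = sample_rate,
              applied_force = applied_force, condition = condition,
              v100 = v100, decade_filling = decade_filling,
              velocity_cap = velocity_cap,
              pause_rate_100 = pause_rate_100,
              pause_rate_scale = pause_rate_scale,
              pareto_alpha = pareto_alpha,
              pareto_xmin_100 = pareto_xmin_100, xmin_scale = xmin_scale,
              heterogeneity_sigma = heterogeneity_sigma,
              extension_noise = extension_noise, drift = drift,
              force_jitter = force_jitter,
              mg_velocity_factor = mg_velocity_factor,
              mg_rate_factor = mg_rate_factor,
              mg_xmin_factor = mg_xmin_factor,
              highforce_rate_factor = highforce_rate_factor,
              highforce_xmin_factor = highforce_xmin_factor,
              d_true = d_true, pause_floor_filling = pause_floor_filling,
              initial_tether_bp = initial_tether_bp,
              elastic = elastic, seed = as.integer(seed))
  structure(cfg, class = "sim_config")
}

# bp of DNA exited per % of filling
.bp_per_pct <- function(config) config$genome_bp / 100

# Deterministic per-event sub-seed; a counter-based mix so that inserting
# or removing events does not reshuffle the others.
.sub_seed <- function(seed, index) {
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 48271 +
                as.numeric(index) * 69621) %% 2147483647)
}

#' Ensemble-mean exit velocity law
#'
#' Exponential velocity-versus-filling law anchored at `v100` bp/s at 100%
#' filling, increasing tenfold per `decade_filling` percent of filling
#' decrease. Under Mg2+ screening the whole law is scaled by
#' `mg_velocity_factor`; at applied force other than the 5 pN reference the
#' Prandtl-Tomlinson factor `exp((F - 5) d_true / kT)` is applied, so the
#' high-force law is the thermally activated friction prediction of the
#' low-force law.
#'
#' @param filling Capsid filling in % (0-100), vectorised.
#' @param config A [sim_config()] object.
#' @return Ensemble-mean unpaused velocity in bp/s.
#' @examples
#' base_velocity(c(100, 80), sim_config())
#' @export
base_velocity <- function(filling, config = sim_config()) {
  if (any(!is.finite(filling)) || any(filling < 0 | filling > 100)) {
    rlang::abort("filling must lie in [0, 100]")
  }
  v <- config$v100 * 10^((100 - filling) / config$decade_filling)
  if (config$condition == "mg") v <- v * config$mg_velocity_factor
  if (config$applied_force != 5) {
    kT <- thermal_energy(config$elastic)
    v <- v * exp((config$applied_force - 5) * config$d_true / kT)
  }
  v
}

# Pause-onset hazard per bp exited at a given filling (%).
.pause_hazard <- function(filling, config) {
  h <- config$pause_rate_100 * exp(-(100 - filling) / config$pause_rate_scale)
  if (config$condition == "mg") h <- h * config$mg_rate_factor
  if (config$applied_force != 5) h <- h * config$highforce_rate_factor
  h
}

# Pareto scale (minimum pause duration, s) at a given filling (%).
.pause_xmin <- function(filling, config) {
  x <- config$pareto_xmin_100 * exp(-(100 - filling) / config$xmin_scale)
  if (config$condition == "mg") x <- x * config$mg_xmin_factor
  if (config$applied_force != 5) x <- x * config$highforce_xmin_factor
  x
}

# Pareto (power-law density exponent alpha, scale xmin) deviates.
.rpareto <- function(n, alpha, xmin) {
  xmin * stats::runif(n)^(-1 / (alpha - 1))
}
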