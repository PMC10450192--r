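# Forward model: stochastic force-clamp DNA-exit traces and static
# control tethers.
#
# Between pauses the exited length advances deterministically at
# eta * base_velocity(filling); pause onsets are an inhomogeneous Poisson
# process in exited length and pause durations are Pareto with a
# filling-dependent scale. Both the motion and the pause-onset process have
# closed-form inverses, so events are simulated exactly (no time stepping)
# and then sampled on the acquisition clock.

# e-folding length (bp exited) of the velocity law
.vel_scale_bp <- function(config) {
  .bp_per_pct(config) * config$decade_filling / log(10)
}

# Draw pause onset positions (bp exited) on [0, x_stop] by inverting the
# cumulative hazard of the exponentially decaying Poisson process.
.draw_pause_positions <- function(config, x_stop) {
  Lr <- config$pause_rate_scale * .bp_per_pct(config)
  lam0 <- .pause_hazard(100, config)
  pos <- numeric(0)
  u <- 1 # e^{-x/Lr} at current position
  u_stop <- exp(-x_stop / Lr)
  repeat {
    u <- u - stats::rexp(1) / (lam0 * Lr)
    if (u <= u_stop) break
    pos <- c(pos, -Lr * log(u))
  }
  pos
}

#' Simulate one force-clamp DNA-exit event
#'
#' Generates a single synthetic ejection trace: exited length advances along
#' the exponential velocity law (scaled by a per-event lognormal multiplier),
#' interrupted by Poisson-in-length pause onsets with Pareto durations, and
#' is observed through the worm-like-chain model with Gaussian extension
#' noise, linear drift and force-clamp jitter. The event terminates when the
#' instantaneous velocity reaches the tracking cap.
#'
#' @param config A [sim_config()] object.
#' @param event_index Integer event counter; combined with `config$seed` it
#'   determines the per-event random stream.
#' @param pauses Set `FALSE` to disable pausing.
#' @param heterogeneity Set `FALSE` to fix the per-event velocity multiplier
#'   at 1.
#' @return A tibble with columns `time_s`, `force_pN`, `extension_nm` and
#'   attributes `event_id`, `kind` (`"ejection"`), `eta` (the velocity
#'   multiplier), `config`, and `truth` (ground-truth pause table and time
#'   budget, used by tests).
#' @examples
#' tr <- simulate_event(sim_config(seed = 7), 1)
#' head(tr)
#' @export
simulate_event <- function(config = sim_config(), event_index = 1L,
                           pauses = TRUE, heterogeneity = TRUE) {
  withr::with_seed(.sub_seed(config$seed, event_index), {
    eta <- 1
    if (heterogeneity && config$heterogeneity_sigma > 0) {
      s <- config$heterogeneity_sigma
      eta <- exp(stats::rnorm(1, -s^2 / 2, s)) # mean-one lognormal
    }
    A <- base_velocity(100, config) * eta # bp/s at 100% filling
    cb <- .vel_scale_bp(config)
    x_cap <- if (A >= config$velocity_cap) 0 else cb * log(config$velocity_cap / A)
    x_cap <- min(x_cap, config$genome_bp)
    x_floor <- (100 - config$pause_floor_filling) * .bp_per_pct(config)

    pause_x <- if (pauses) .draw_pause_positions(config, min(x_cap, x_floor)) else numeric(0)
    pause_fill <- 100 - pause_x / .bp_per_pct(config)
    pause_dur <- if (length(pause_x)) {
      .pause_xmin(pause_fill, config) *
        stats::runif(length(pause_x))^(-1 / (config$pareto_alpha - 1))
    } else numeric(0)

    # segment bookkeeping: alternate moving / paused intervals
    move_time <- function(x0, x1) (cb / A) * (exp(-x0 / cb) - exp(-x1 / cb))
    bnd <- c(0, pause_x, x_cap)
    seg_x0 <- c(rbind(bnd[-length(bnd)], c(pause_x, NA)))
    seg_x0 <- seg_x0[!is.na(seg_x0)][seq_len(2 * length(pause_x) + 1)]
    seg_type <- rep(c("move", "pause"), length.out = 2 * length(pause_x) + 1)
    seg_dur <- numeric(length(seg_type))
    seg_dur[seg_type == "move"] <- move_time(bnd[-length(bnd)], bnd[-1])
    seg_dur[seg_type == "pause"] <- pause_dur
    seg_t0 <- cumsum(c(0, seg_dur[-length(seg_dur)]))
    t_total <- sum(seg_dur)

    n <- max(2L, floor(t_total * config$sample_rate) + 1L)
    t <- (seq_len(n) - 1L) / config$sample_rate
    idx <- findInterval(t, seg_t0)
    x <- numeric(n)
    mv <- seg_type[idx] == "move"
    x[!mv] <- seg_x0[idx[!mv]]
    x[mv] <- -cb * log(pmax(exp(-seg_x0[idx[mv]] / cb) -
                              A * (t[mv] - seg_t0[idx[mv]]) / cb,
                            exp(-x_cap / cb)))

    force <- config$applied_force +
      stats::rnorm(n, 0, config$force_jitter)
    force <- pmax(force, 0.1)
    frac <- .fractional_extension_fun(range(force), config$elastic)
    tether_bp <- config$initial_tether_bp + x
    ext <- tether_bp * config$elastic$rise_per_bp * frac(force) +
      stats::rnorm(n, 0, config$extension_noise) + config$drift * t

    truth <- list(
      eta = eta, x_cap = x_cap, t_total = t_total,
      moving_time = sum(seg_dur[seg_type == "move"]),
      paused_time = sum(pause_dur),
      pauses = tibble::tibble(
        start_s = seg_t0[seg_type == "pause"],
        duration_s = pause_dur,
        exited_bp = pause_x,
        filling_pct = pause_fill
      )
    )
    out <- tibble::tibble(time_s = t, force_pN = force, extension_nm = ext)
    attr(out, "event_id") <- sprintf("ev%03d", event_index)
    attr(out, "kind") <- "ejection"
    attr(out, "eta") <- eta
    attr(out, "config") <- config
    attr(out, "truth") <- truth
    out
  })
}

#' Simulate a static control tether
#'
#' A tether of constant true contour length observed with the same
#' extension noise, drift and force jitter as ejection traces. Controls
#' calibrate the velocity noise floor used to qualify pauses.
#'
#' @param config A [sim_config()] object.
#' @param duration Trace duration in s.
#' @param event_index Integer counter for the random stream.
#' @return A trace tibble as in [simulate_event()], with `kind = "control"`.
#' @export
simulate_control <- function(config = sim_config(), duration = 60,
                             event_index = 0L) {
  if (!is.finite(duration) || duration <= 0) {
    rlang::abort("duration must be positive")
  }
  withr::with_seed(.sub_seed(config$seed, 100000 + event_index), {
    n <- floor(duration * config$sample_rate) + 1L
    t <- (seq_len(n) - 1L) / config$sample_rate
    force <- config$applied_force + stats::rnorm(n, 0, config$force_jitter)
    force <- pmax(force, 0.1)
    frac <- .fractional_extension_fun(range(force), config$elastic)
    ext <- config$initial_tether_bp * config$elastic$rise_per_bp *
      frac(force) + stats::rnorm(n, 0, config$extension_noise) +
      config$drift * t
    out <- tibble::tibble(time_s = t, force_pN = force, extension_nm = ext)
    attr(out, "event_id") <- sprintf("ctrl%03d", event_index)
    attr(out, "kind") <- "control"
    attr(out, "eta") <- 1
    attr(out, "config") <- config
    out
  })
}

#' Simulate an ensemble of exit events plus controls
#'
#' Events receive deterministic per-event sub-seeds derived from
#' `config$seed`, so the same configuration always reproduces the same
#' ensemble and adding events does not perturb existing ones.
#'
#' @param config A [sim_config()] object.
#' @param n_events Number of ejection events.
#' @param n_controls Number of static control traces.
#' @param control_duration Duration of each control trace, s.
#' @param pauses,heterogeneity Passed to [simulate_event()].
#' @param dir Optional directory; when given, traces are written as TSV via
#'   [write_trace()] and a JSON manifest recording every parameter is
#'   written alongside.
#' @return A list with elements `traces` (list of ejection trace tibbles),
#'   `controls` (list of control trace tibbles) and `manifest` (tibble of
#'   event id, kind, sub-seed, velocity multiplier and file name).
#' @examples
#' ens <- simulate_ensemble(sim_config(seed = 1), n_events = 2,
#'                          n_controls = 1, control_duration = 5)
#' ens$manifest
#' @export
simulate_ensemble <- function(config = sim_config(), n_events = 39,
                              n_controls = 3, control_duration = 60,
                              pauses = TRUE, heterogeneity = TRUE,
                              dir = NULL) {
  if (n_events < 1) rlang::abort("n_events must be >= 1")
  traces <- purrr::map(seq_len(n_events), function(i) {
    simulate_event(config, i, pauses = pauses, heterogeneity = heterogeneity)
  })
  controls <- purrr::map(seq_len(n_controls), function(i) {
    simulate_control(config, control_duration, i)
  })
  all <- c(traces, controls)
  manifest <- tibble::tibble(
    event_id = purrr::map_chr(all, ~ attr(.x, "event_id")),
    kind = purrr::map_chr(all, ~ attr(.x, "kind")),
    sub_seed = c(purrr::map_int(seq_len(n_events), ~ .sub_seed(config$seed, .x)),
                 purrr::map_int(seq_len(n_controls),
                                ~ .sub_seed(config$seed, 100000 + .x))),
    eta = purrr::map_dbl(all, ~ attr(.x, "eta")),
    file = paste0(purrr::map_chr(all, ~ attr(.x, "event_id")), ".tsv")
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    purrr::walk2(all, manifest$file,
                 ~ write_trace(.x, file.path(dir, .y)))
    write_manifest(manifest, config, file.path(dir, "manifest.json"))
  }
  list(traces = traces, controls = controls, manifest = manifest)
}
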