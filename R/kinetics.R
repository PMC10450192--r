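# Trace kinetics: exited-length and filling series, sliding-window
# velocities, and binned ensemble velocity-versus-filling profiles.

#' Exited DNA length versus time
#'
#' Converts a force-clamp trace to the length of DNA (bp) that has exited
#' the capsid since the start of the trace. The tether contour length is
#' obtained per sample from the measured extension and force through the
#' extensible WLC model, and the first sample defines the zero.
#'
#' @param trace A trace tibble with columns `time_s`, `force_pN`,
#'   `extension_nm` (at least 2 rows).
#' @param params An [elastic_params()] object.
#' @return A tibble with columns `time_s`, `exited_bp`.
#' @export
exited_length_series <- function(trace, params = elastic_params()) {
  if (nrow(trace) < 2) rlang::abort("trace must have at least 2 samples")
  if (any(trace$force_pN <= 0)) {
    rlang::abort("trace contains non-positive forces; tether length undefined")
  }
  frac <- .fractional_extension_fun(range(trace$force_pN), params)
  tether <- trace$extension_nm / (frac(trace$force_pN) * params$rise_per_bp)
  tibble::tibble(time_s = trace$time_s, exited_bp = tether - tether[1])
}

#' Capsid filling versus time
#'
#' @param lengths A tibble with columns `time_s`, `exited_bp` (from
#'   [exited_length_series()]).
#' @param genome_bp Genome length defining 100% filling.
#' @param initial_filling Filling in % at the first sample (default 100).
#' @return `lengths` with an added `filling_pct` column, clipped at 0.
#' @export
filling_series <- function(lengths, genome_bp = 19300,
                           initial_filling = 100) {
  if (initial_filling <= 0 || initial_filling > 100) {
    rlang::abort("initial_filling must lie in (0, 100]")
  }
  dplyr::mutate(
    lengths,
    filling_pct = pmax(0, initial_filling - 100 * .data$exited_bp / genome_bp)
  )
}

#' Sliding-window exit velocities
#'
#' Ordinary least-squares slope of exited length versus time in a sliding
#' window (default 0.5 s, stepped by 0.1 s). Each window is assigned the
#' time and filling at its midpoint sample. Slopes are computed with running
#' sums, so the cost is linear in trace length.
#'
#' @param series A tibble with `time_s`, `exited_bp` and optionally
#'   `filling_pct` (regular sampling assumed).
#' @param window Window length in s (must span at least 3 samples).
#' @param step Step between window starts in s.
#' @return A tibble of velocity samples: `time_s` (window midpoint),
#'   `filling_pct` (if available), `velocity_bp_s`, `paused` (`NA` until
#'   [mark_paused_windows()] is applied).
#' @export
window_velocities <- function(series, window = 0.5, step = 0.1) {
  n <- nrow(series)
  dt <- series$time_s[2] - series$time_s[1]
  w <- round(window / dt)
  if (w < 3) rlang::abort("window must span at least 3 samples")
  if (n < w) rlang::abort("series shorter than one window")
  stp <- max(1L, round(step / dt))
  y <- series$exited_bp
  i0 <- seq_len(n) - 1
  S <- c(0, cumsum(y))
  Q <- c(0, cumsum(y * i0))
  a <- seq(1L, n - w + 1L, by = stp)
  sy <- S[a + w] - S[a]
  qy <- Q[a + w] - Q[a]
  rbar <- (w - 1) / 2
  num <- qy - (a - 1) * sy - rbar * sy    # sum y * (r - rbar)
  den <- w * (w^2 - 1) / 12               # sum (r - rbar)^2
  slope <- num / den / dt
  mid <- a + floor(rbar)
  out <- tibble::tibble(
    time_s = series$time_s[mid],
    velocity_bp_s = slope,
    paused = NA
  )
  if ("filling_pct" %in% names(series)) {
    out$filling_pct <- series$filling_pct[mid]
    out <- dplyr::relocate(out, "filling_pct", .after = "time_s")
  }
  out
}

#' Flag velocity windows that overlap detected pauses
#'
#' A window contributes to pause-excluded statistics only if it lies wholly
#' outside every detected pause; windows straddling a pause boundary are
#' flagged along with those inside pauses.
#'
#' @param samples Velocity samples from [window_velocities()].
#' @param pauses A pause table with `start_s`, `end_s` columns.
#' @param window The window length in s used to build `samples`.
#' @return `samples` with the `paused` flag filled in.
#' @export
mark_paused_windows <- function(samples, pauses, window = 0.5) {
  lo <- samples$time_s - window / 2
  hi <- samples$time_s + window / 2
  flag <- rep(FALSE, nrow(samples))
  if (!is.null(pauses) && nrow(pauses)) {
    for (i in seq_len(nrow(pauses))) {
      flag <- flag | (hi > pauses$start_s[i] & lo < pauses$end_s[i])
    }
  }
  samples$paused <- flag
  samples
}

# Half-open filling bins [lo, hi), top bin closed at 100.
.bin_lo <- function(filling, bin_width) {
  pmin(bin_width * floor(filling / bin_width), 100 - bin_width)
}

#' Per-event binned velocity profile
#'
#' Averages window velocities in filling bins (default 5% wide, half-open
#' `[lo, hi)` with the top bin closed at 100%). A bin is retained only if
#' the event traverses at least half of it; optionally windows overlapping
#' pauses are excluded first.
#'
#' @param samples Velocity samples with `filling_pct`, `velocity_bp_s` and
#'   (if `exclude_paused`) a filled-in `paused` flag.
#' @param exclude_paused Drop windows overlapping pauses before averaging.
#' @param bin_width Bin width in % of genome length.
#' @return A tibble with `bin_lo`, `bin_hi`, `bin_center`, `mean_velocity`,
#'   `n_windows`. Bins the event does not qualify for are absent.
#' @export
event_profile <- function(samples, exclude_paused = FALSE, bin_width = 5) {
  if (!nrow(samples)) rlang::abort("samples is empty")
  span_lo <- min(samples$filling_pct)
  span_hi <- max(samples$filling_pct)
  use <- samples
  if (exclude_paused) {
    if (all(is.na(samples$paused))) {
      rlang::abort("paused flags not set; run mark_paused_windows() first")
    }
    use <- dplyr::filter(samples, !.data$paused)
  }
  if (!nrow(use)) return(tibble::tibble(bin_lo = numeric(0), bin_hi = numeric(0),
                                        bin_center = numeric(0),
                                        mean_velocity = numeric(0),
                                        n_windows = integer(0)))
  prof <- use |>
    dplyr::mutate(bin_lo = .bin_lo(.data$filling_pct, bin_width)) |>
    dplyr::group_by(.data$bin_lo) |>
    dplyr::summarise(mean_velocity = mean(.data$velocity_bp_s),
                     n_windows = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(bin_hi = .data$bin_lo + bin_width,
                  bin_center = .data$bin_lo + bin_width / 2) |>
    dplyr::relocate("bin_lo", "bin_hi", "bin_center")
  # coverage rule: event must traverse >= half the bin (in filling span)
  covered <- pmin(prof$bin_hi, span_hi) - pmax(prof$bin_lo, span_lo)
  dplyr::filter(prof, covered >= bin_width / 2) |>
    dplyr::arrange(.data$bin_lo)
}

#' Ensemble velocity-versus-filling profile with bootstrap errors
#'
#' Averages per-event bin means across events (each event contributes one
#' value per bin it qualifies for) and attaches a bootstrap standard error
#' obtained by resampling whole events with replacement.
#'
#' @param profiles A list of per-event profiles from [event_profile()].
#' @param bootstrap_reps Number of bootstrap resamples of events.
#' @param seed Optional seed making the bootstrap reproducible.
#' @return A `velocity_profile` tibble with `bin_lo`, `bin_hi`,
#'   `bin_center`, `mean_velocity`, `se`, `n_events`; the per-event bin
#'   means are kept in the `"event_means"` attribute for downstream
#'   bootstraps.
#' @export
ensemble_profile <- function(profiles, bootstrap_reps = 1000, seed = NULL) {
  if (!length(profiles)) rlang::abort("need at least one event profile")
  if (is.null(names(profiles))) {
    names(profiles) <- sprintf("ev%03d", seq_along(profiles))
  }
  long <- purrr::list_rbind(profiles, names_to = "event_id")
  if (!nrow(long)) rlang::abort("no populated bins in any event profile")
  boot_once <- function(ids) {
    long |>
      dplyr::inner_join(tibble::tibble(event_id = ids),
                        by = "event_id", relationship = "many-to-many") |>
      dplyr::group_by(.data$bin_lo) |>
      dplyr::summarise(m = mean(.data$mean_velocity), .groups = "drop")
  }
  est <- long |>
    dplyr::group_by(.data$bin_lo, .data$bin_hi, .data$bin_center) |>
    dplyr::summarise(mean_velocity = mean(.data$mean_velocity),
                     n_events = dplyr::n(), .groups = "drop")
  ids <- unique(long$event_id)
  reps <- withr::with_seed(
    if (is.null(seed)) stats::runif(1, 1, 2^30) else seed, {
      purrr::map(seq_len(bootstrap_reps), function(i) {
        boot_once(sample(ids, replace = TRUE))
      })
    })
  boot <- purrr::list_rbind(reps, names_to = "rep") |>
    dplyr::group_by(.data$bin_lo) |>
    dplyr::summarise(se = stats::sd(.data$m), .groups = "drop")
  out <- dplyr::left_join(est, boot, by = "bin_lo") |>
    dplyr::relocate("se", .after = "mean_velocity") |>
    dplyr::arrange(.data$bin_lo)
  class(out) <- c("velocity_profile", class(out))
  attr(out, "event_means") <- long
  out
}

#' Log-linear fit of a velocity profile
#'
#' Fits `log10(mean velocity)` against bin-center filling by least squares
#' over a filling range and reports the implied anchor velocity at 100%
#' filling and the filling decrease per tenfold velocity increase.
#'
#' @param profile A `velocity_profile` (or any tibble with `bin_center` and
#'   `mean_velocity`).
#' @param range Filling interval (%) whose bins enter the fit; at least 3
#'   populated bins are required and all bin means must be positive.
#' @return An object of class `profile_fit`: a list with `v_at_100`
#'   (bp/s), `decade_filling` (% per decade; `Inf` for a flat profile),
#'   `slope`, `intercept`, `n_bins` and the fitted `lm`.
#' @export
fit_exponential_profile <- function(profile, range = c(80, 100)) {
  use <- dplyr::filter(profile, .data$bin_center >= range[1],
                       .data$bin_center <= range[2])
  if (nrow(use) < 3) rlang::abort("need at least 3 populated bins in range")
  if (any(use$mean_velocity <= 0)) {
    rlang::abort("all bin means must be positive for a log-linear fit")
  }
  fit <- stats::lm(log10(mean_velocity) ~ bin_center, data = use)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  structure(list(
    v_at_100 = 10^(intercept + slope * 100),
    decade_filling = if (slope == 0) Inf else -1 / slope,
    slope = slope, intercept = intercept,
    n_bins = nrow(use), lm = fit
  ), class = "profile_fit")
}

#' Evaluate a fitted exponential velocity law
#'
#' @param fit A `profile_fit` from [fit_exponential_profile()].
#' @param filling Filling values in %.
#' @return Fitted velocity in bp/s.
#' @export
predict_profile_fit <- function(fit, filling) {
  10^(fit$intercept + fit$slope * filling)
}
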