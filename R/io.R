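# File formats, configuration and end-to-end orchestration.

.trace_cols <- c("time_s", "force_pN", "extension_nm")

#' Read a force-clamp trace from TSV
#'
#' Traces are tab-separated UTF-8 text with a header naming at least the
#' columns `time_s`, `force_pN`, `extension_nm` (any column order; gzip
#' accepted transparently). Malformed rows and non-monotone time stamps are
#' rejected with the offending location.
#'
#' @param path File path.
#' @return A trace tibble with the three canonical columns.
#' @export
read_trace <- function(path) {
  df <- suppressWarnings(
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_double()),
                    progress = FALSE, show_col_types = FALSE))
  missing <- setdiff(.trace_cols, names(df))
  if (length(missing)) {
    rlang::abort(paste0("trace file ", path, " is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  pr <- readr::problems(df)
  if (nrow(pr)) {
    rlang::abort(paste0("non-numeric cell(s) in ", path, " at line(s) ",
                        paste(utils::head(pr$row, 5) + 1, collapse = ", ")))
  }
  df <- df[.trace_cols]
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad)) {
    rlang::abort(paste0("time stamps not strictly increasing in ", path,
                        " at data row ", bad[1] + 1))
  }
  df
}

#' Write a force-clamp trace to TSV
#'
#' @param trace A trace tibble.
#' @param path Output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  readr::write_tsv(trace[.trace_cols], path, progress = FALSE)
  invisible(path)
}

#' Write an ensemble manifest as JSON
#'
#' Records the full simulation configuration snapshot and the per-event
#' table (id, kind, sub-seed, velocity multiplier, file name).
#'
#' @param manifest Manifest tibble from [simulate_ensemble()].
#' @param config The [sim_config()] used.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, config, path) {
  cfg <- unclass(config)
  cfg$elastic <- unclass(cfg$elastic)
  jsonlite::write_json(list(config = cfg, events = manifest), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ensemble manifest
#'
#' @param path Manifest JSON path.
#' @return A list with `config` (a reconstructed [sim_config()]) and
#'   `events` (tibble).
#' @export
read_manifest <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- j$config
  elastic <- do.call(elastic_params, cfg$elastic)
  cfg$elastic <- NULL
  config <- do.call(sim_config, c(cfg, list(elastic = elastic)))
  list(config = config, events = tibble::as_tibble(j$events))
}

#' Analysis configuration
#'
#' Bundles every tunable of the trace-to-results pipeline.
#'
#' @param window Velocity window in s.
#' @param step Window step in s.
#' @param bin_width Filling bin width in % (must divide 100).
#' @param bootstrap_reps Bootstrap resamples (>= 100).
#' @param detection_rate Change-point detection rate in Hz.
#' @param dt_grid Control-noise interval durations in s.
#' @param min_pause_duration Minimum reportable pause, s.
#' @param genome_bp Genome length defining 100% filling.
#' @param filling_range_stats Filling range (%) pooled for pause-duration
#'   distribution fits.
#' @param elastic An [elastic_params()].
#' @param force_curve A [force_filling_curve()].
#' @param seed Integer seed for all pipeline randomness (bootstraps).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(window = 0.5, step = 0.1, bin_width = 5,
                            bootstrap_reps = 1000, detection_rate = 100,
                            dt_grid = c(0.05, 0.1, 0.2, 0.5, 1, 2),
                            min_pause_duration = 0.03, genome_bp = 19300,
                            filling_range_stats = c(90, 95),
                            elastic = elastic_params(),
                            force_curve = force_filling_curve(),
                            seed = 1L) {
  if (window < 3 / detection_rate) {
    rlang::abort("window must span at least 3 samples at the detection rate")
  }
  if (100 %% bin_width != 0) rlang::abort("bin_width must divide 100")
  if (bootstrap_reps < 100) rlang::abort("bootstrap_reps must be >= 100")
  structure(list(window = window, step = step, bin_width = bin_width,
                 bootstrap_reps = bootstrap_reps,
                 detection_rate = detection_rate, dt_grid = dt_grid,
                 min_pause_duration = min_pause_duration,
                 genome_bp = genome_bp,
                 filling_range_stats = filling_range_stats,
                 elastic = elastic, force_curve = force_curve,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Run the full trace-analysis pipeline
#'
#' Orchestrates the canonical analysis order: control-noise calibration,
#' exited length and filling, change-point pause detection, windowed
#' velocities, binned ensemble profiles (with and without pauses), per-bin
#' pause metrics, and distributional fits of inter-pause spacings and pause
#' durations. Deterministic given `config$seed`.
#'
#' @param traces List of ejection trace tibbles (>= 1), optionally named by
#'   event id.
#' @param controls List of static control trace tibbles (>= 1).
#' @param config An [analysis_config()].
#' @param verbose Emit per-stage progress messages.
#' @return An object of class `ejection_results`: list with `noise`,
#'   `pauses` (catalog with event ids), `profile_incl`, `profile_excl`,
#'   `pause_bins`, `pause_overall`, `spacing_fit`, `duration_fit`,
#'   `samples` (per-event velocity samples), `series` (per-event filling
#'   series) and `provenance`.
#' @export
run_pipeline <- function(traces, controls, config = analysis_config(),
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (!length(traces)) rlang::abort("need at least one ejection trace")
  if (!length(controls)) rlang::abort("need at least one control trace")
  ids <- purrr::imap_chr(traces, function(tr, i) {
    id <- attr(tr, "event_id")
    if (!is.null(id)) id
    else if (is.character(i)) i
    else sprintf("ev%03d", as.integer(i))
  })
  names(traces) <- ids
  say("calibrating noise from %d control(s)", length(controls))
  noise <- calibrate_noise(controls, config$elastic, config$dt_grid)
  say("detecting pauses in %d event(s)", length(traces))
  per_event <- purrr::imap(traces, function(tr, id) {
    det <- tryCatch(
      detect_pauses(tr, noise, config$elastic, config$genome_bp,
                    config$detection_rate, min_duration = config$min_pause_duration),
      error = function(e) rlang::abort(
        paste0("pause detection failed for event ", id, ": ",
               conditionMessage(e))))
    samples <- window_velocities(det$series, config$window, config$step) |>
      mark_paused_windows(det$pauses, config$window)
    list(pauses = det$pauses, series = det$series, samples = samples)
  })
  pauses <- purrr::imap(per_event, ~ dplyr::mutate(.x$pauses, event_id = .y)) |>
    purrr::list_rbind() |>
    dplyr::relocate("event_id")
  series_list <- purrr::map(per_event, "series")
  samples_list <- purrr::map(per_event, "samples")
  say("building velocity profiles")
  prof_incl <- ensemble_profile(
    purrr::map(samples_list, event_profile, exclude_paused = FALSE,
               bin_width = config$bin_width),
    config$bootstrap_reps, seed = config$seed)
  prof_excl <- ensemble_profile(
    purrr::map(samples_list, event_profile, exclude_paused = TRUE,
               bin_width = config$bin_width),
    config$bootstrap_reps, seed = config$seed + 1L)
  say("pause metrics")
  pause_bins <- if (nrow(pauses)) {
    pause_metrics_by_bin(pauses, series_list, config$bin_width,
                         config$genome_bp, config$bootstrap_reps,
                         seed = config$seed + 2L)
  } else NULL
  pause_overall <- pause_summary(pauses, series_list)
  rng <- config$filling_range_stats
  spacings <- pauses |>
    dplyr::group_by(.data$event_id) |>
    dplyr::arrange(.data$exited_bp, .by_group = TRUE) |>
    dplyr::mutate(spacing_bp = .data$exited_bp - dplyr::lag(.data$exited_bp)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$spacing_bp), .data$spacing_bp > 0,
                  .data$filling_pct >= rng[1], .data$filling_pct <= rng[2])
  spacing_fit <- if (nrow(spacings) >= 2) {
    fit_exponential(spacings$spacing_bp)
  } else NULL
  durations <- dplyr::filter(pauses, .data$filling_pct >= rng[1],
                             .data$filling_pct <= rng[2])$duration_s
  duration_fit <- if (length(durations) >= 50) {
    csn_powerlaw_fit(durations)
  } else NULL
  res <- list(noise = noise, pauses = pauses,
              profile_incl = prof_incl, profile_excl = prof_excl,
              pause_bins = pause_bins, pause_overall = pause_overall,
              spacing_fit = spacing_fit, duration_fit = duration_fit,
              samples = samples_list, series = series_list,
              provenance = list(
                n_events = length(traces), n_controls = length(controls),
                config = config, seed = config$seed,
                config_hash = rlang::hash(config),
                package_version = as.character(utils::packageVersion("ejectr"))))
  class(res) <- "ejection_results"
  res
}

#' Serialise an analysis results bundle
#'
#' Writes one JSON bundle (profiles, pause metrics, fits, provenance) plus
#' per-event TSV sidecars (pause catalog, velocity samples).
#'
#' @param results An `ejection_results` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  bundle <- list(
    profile_incl = as.data.frame(results$profile_incl),
    profile_excl = as.data.frame(results$profile_excl),
    pause_bins = if (!is.null(results$pause_bins)) as.data.frame(results$pause_bins),
    pause_overall = results$pause_overall[c("fraction_paused", "total_paused_s",
                                            "total_time_s", "n_pauses")],
    spacing_fit = unclass(results$spacing_fit),
    duration_fit = unclass(results$duration_fit),
    noise = as.data.frame(results$noise$table),
    resolution_bp = results$noise$resolution_bp,
    provenance = list(
      n_events = results$provenance$n_events,
      n_controls = results$provenance$n_controls,
      seed = results$provenance$seed,
      config_hash = results$provenance$config_hash,
      package_version = results$provenance$package_version))
  jsonlite::write_json(bundle, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  readr::write_tsv(results$pauses, file.path(dir, "pauses.tsv"),
                   progress = FALSE)
  invisible(dir)
}

#' @export
print.ejection_results <- function(x, ...) {
  cat("<ejection_results>\n")
  cat(sprintf("  events: %d   controls: %d\n", x$provenance$n_events,
              x$provenance$n_controls))
  cat(sprintf("  pauses detected: %d   fraction of time paused: %.3f\n",
              nrow(x$pauses), x$pause_overall$fraction_paused))
  cat(sprintf("  velocity bins (pause-excluded): %d\n", nrow(x$profile_excl)))
  if (!is.null(x$duration_fit)) {
    cat(sprintf("  pause-duration power-law tail: alpha = %.2f (xmin = %.3f s, n = %d)\n",
                x$duration_fit$alpha, x$duration_fit$xmin,
                x$duration_fit$n_tail))
  }
  invisible(x)
}
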