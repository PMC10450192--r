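# Pause detection: Kalafut-Visscher BIC change-point segmentation of the
# exited-length series, qualification of segments against control-tether
# noise (1-SD rule), merging/filtering, and per-bin pause metrics.

#' Kalafut-Visscher change-point detection
#'
#' Greedy stepwise segmentation of a series under a piecewise-constant
#' Gaussian model with a shared variance re-estimated at each step. At each
#' iteration the single change point whose addition lowers the Schwarz
#' (Bayesian) information criterion the most is added; the procedure stops
#' when no addition lowers it. With k change points the criterion is
#' `BIC = (2k + 2) log n + n log(SSR_k / n)`: k + 1 segment means, k
#' change-point locations and one variance. Counting the locations keeps
#' the penalty strong enough that pure noise is left unsegmented.
#'
#' @param y Numeric series (length at least `2 * min_segment`).
#' @param min_segment Minimum segment length in samples.
#' @return Sorted integer vector of change points; change point `k` splits
#'   samples `1..k` from `k+1..n`.
#' @export
kv_changepoints <- function(y, min_segment = 3L) {
  n <- length(y)
  if (n < 2 * min_segment) rlang::abort("series too short for segmentation")
  S1 <- cumsum(y)
  S2 <- cumsum(y * y)
  pre1 <- function(i) if (i > 1) S1[i - 1] else 0
  pre2 <- function(i) if (i > 1) S2[i - 1] else 0
  ssr <- function(i, j) {
    s <- S1[j] - pre1(i)
    max((S2[j] - pre2(i)) - s * s / (j - i + 1), 0)
  }
  best_split <- function(i, j) {
    ks <- seq.int(i + min_segment - 1, j - min_segment)
    if (!length(ks) || ks[1] > ks[length(ks)]) return(c(NA_real_, -Inf))
    n1 <- ks - i + 1
    s1 <- S1[ks] - pre1(i)
    q1 <- S2[ks] - pre2(i)
    n2 <- j - ks
    s2 <- S1[j] - S1[ks]
    q2 <- S2[j] - S2[ks]
    gain <- ssr(i, j) - ((q1 - s1^2 / n1) + (q2 - s2^2 / n2))
    k <- which.max(gain)
    c(ks[k], gain[k])
  }
  segs <- list(c(1L, n))
  splits <- list(best_split(1L, n))
  cps <- integer(0)
  SSR <- ssr(1L, n)
  logn <- log(n)
  repeat {
    gains <- vapply(splits, function(s) s[2], numeric(1))
    b <- which.max(gains)
    g <- gains[b]
    if (!is.finite(g) || g <= 0 || SSR <= 0) break
    new_ssr <- max(SSR - g, 0)
    dbic <- n * log(max(new_ssr, 1e-300) / SSR) + 2 * logn
    if (dbic >= 0) break
    kk <- as.integer(splits[[b]][1])
    ij <- segs[[b]]
    cps <- c(cps, kk)
    SSR <- new_ssr
    segs[[b]] <- c(ij[1], kk)
    splits[[b]] <- best_split(ij[1], kk)
    segs[[length(segs) + 1L]] <- c(kk + 1L, ij[2])
    splits[[length(splits) + 1L]] <- best_split(kk + 1L, ij[2])
  }
  sort(cps)
}

#' Calibrate the velocity noise floor from static control tethers
#'
#' Estimates the instrument drift (global slope of the control
#' exited-length series) and, after removing it, the distribution of
#' control velocities in intervals of each duration in `dt_grid`, with two
#' estimators: the OLS slope over the interval, and the net displacement
#' between the interval's endpoint blocks divided by its duration. The
#' net-displacement distribution defines the 1-SD pause qualification band
#' and the length resolution, `SD(net change at the smallest dt)`; the OLS
#' distribution characterises the velocity noise floor of the windowed
#' velocity estimates.
#'
#' @param controls A list of control trace tibbles.
#' @param params An [elastic_params()] object.
#' @param dt_grid Interval durations in s.
#' @param block Endpoint block size in s for net-displacement velocities
#'   (match the pause-detection rate; default 0.01 s = 100 Hz blocks).
#' @return An object of class `noise_model`: list with `table` (tibble of
#'   `dt_s`, `mean_bp_s`, `sd_bp_s`, `net_mean_bp_s`, `net_sd_bp_s`, `n`,
#'   computed on drift-corrected control series), `drift_bp_s` (the
#'   control-calibrated instrument drift), `resolution_bp` and
#'   `min_duration_s` (smallest grid duration).
#' @export
calibrate_noise <- function(controls, params = elastic_params(),
                            dt_grid = c(0.05, 0.1, 0.2, 0.5, 1, 2),
                            block = 0.01) {
  if (!length(controls)) rlang::abort("need at least one control trace")
  series <- purrr::map(controls, exited_length_series, params = params)
  total <- sum(purrr::map_dbl(series, ~ max(.x$time_s) - min(.x$time_s)))
  if (total < 10 * max(dt_grid)) {
    rlang::abort("insufficient control data: need total duration >= 10 * max(dt_grid)")
  }
  dt_grid <- sort(dt_grid)
  # instrument drift (bp/s): duration-weighted mean of per-control global
  # slopes; control series are detrended by it before windowing, and the
  # same correction is applied to ejection traces before pause detection
  w <- purrr::map_dbl(series, ~ max(.x$time_s) - min(.x$time_s))
  drift <- sum(purrr::map_dbl(series, ~ .ols_slope(.x$time_s, .x$exited_bp)) * w) / sum(w)
  series <- purrr::map(series, function(s) {
    dplyr::mutate(s, exited_bp = .data$exited_bp -
                    drift * (.data$time_s - .data$time_s[1]))
  })
  blocked <- purrr::map(series, function(s) {
    dt <- s$time_s[2] - s$time_s[1]
    k <- max(1L, round(block / dt))
    nb <- floor(nrow(s) / k)
    tibble::tibble(
      time_s = colMeans(matrix(s$time_s[seq_len(nb * k)], nrow = k)),
      exited_bp = colMeans(matrix(s$exited_bp[seq_len(nb * k)], nrow = k)))
  })
  tab <- purrr::map(dt_grid, function(dt) {
    v <- unlist(purrr::map(series, function(s) {
      if (max(s$time_s) - min(s$time_s) < dt) return(numeric(0))
      window_velocities(s, window = dt, step = dt)$velocity_bp_s
    }))
    vn <- unlist(purrr::map(blocked, function(b) {
      m <- round(dt / (b$time_s[2] - b$time_s[1]))
      if (m < 1 || nrow(b) <= m) return(numeric(0))
      i <- seq(1L, nrow(b) - m, by = m)
      (b$exited_bp[i + m] - b$exited_bp[i]) / dt
    }))
    tibble::tibble(dt_s = dt, mean_bp_s = mean(v), sd_bp_s = stats::sd(v),
                   net_mean_bp_s = mean(vn), net_sd_bp_s = stats::sd(vn),
                   n = length(v))
  }) |> purrr::list_rbind()
  structure(list(table = tab, drift_bp_s = drift,
                 resolution_bp = tab$net_sd_bp_s[1] * tab$dt_s[1],
                 min_duration_s = tab$dt_s[1]),
            class = "noise_model")
}

# Interpolate control mean and SD at an arbitrary interval duration:
# means linear in log(dt); SDs log-log linear (they follow power laws in
# dt), clamped at the grid ends. The `net_*` entries are the
# net-displacement estimator used for pause qualification.
.noise_at <- function(noise, dt) {
  tab <- noise$table
  ldt <- log(pmin(pmax(dt, min(tab$dt_s)), max(tab$dt_s)))
  ip <- function(y, logy = FALSE) {
    if (logy) exp(stats::approx(log(tab$dt_s), log(y), xout = ldt, rule = 2)$y)
    else stats::approx(log(tab$dt_s), y, xout = ldt, rule = 2)$y
  }
  list(mean = ip(tab$mean_bp_s), sd = ip(tab$sd_bp_s, TRUE),
       net_mean = ip(tab$net_mean_bp_s), net_sd = ip(tab$net_sd_bp_s, TRUE))
}

# OLS slope of y on t (>= 2 points)
.ols_slope <- function(t, y) {
  tc <- t - mean(t)
  sum(tc * y) / sum(tc * tc)
}

#' Classify change-point segments into pauses
#'
#' A segment is a pause iff its OLS velocity is statistically
#' indistinguishable from a static control: within one SD of the control
#' net-displacement velocity distribution at the segment's duration.
#' (Because the OLS estimate is much sharper than the net-displacement
#' criterion, true pauses are accepted with near-unit probability while
#' movements faster than the noise floor are rejected.) Adjacent pauses
#' separated by a movement whose net length change is below the noise-model
#' length resolution are merged; pauses shorter than the minimum resolvable
#' duration are discarded. If the full-rate series is supplied, all segment
#' boundaries are first refined on it by a local piecewise-constant fit and
#' segment velocities/durations are measured between the refined
#' boundaries.
#'
#' @param series Detection-rate tibble with `time_s`, `exited_bp` and
#'   optionally `filling_pct`.
#' @param changepoints Change points from [kv_changepoints()].
#' @param noise A `noise_model` from [calibrate_noise()].
#' @param min_duration Minimum pause duration in s.
#' @param full_series Optional full-rate series for boundary refinement.
#' @return A pause tibble: `start_s`, `end_s`, `duration_s`,
#'   `filling_pct` (at onset, if available), `exited_bp` (at onset).
#' @export
classify_pauses <- function(series, changepoints, noise,
                            min_duration = 0.03, full_series = NULL) {
  n <- nrow(series)
  dt <- series$time_s[2] - series$time_s[1]
  t_lo <- series$time_s[1] - dt / 2
  t_hi <- series$time_s[n] + dt / 2
  # boundary times between segments, refined on the full-rate series when
  # available: at high velocity a one-sample placement error at the
  # detection rate would otherwise dominate short-segment velocities
  bt <- series$time_s[changepoints] + dt / 2
  ref <- series
  if (!is.null(full_series) && length(bt)) {
    bt <- vapply(bt, .refine_boundary, numeric(1),
                 full_series = full_series, halfwin = dt)
    bt <- sort(pmin(pmax(bt, t_lo), t_hi))
    ref <- full_series
  } else if (!is.null(full_series)) {
    ref <- full_series
  }
  edges <- c(t_lo, bt, t_hi)
  ns <- length(edges) - 1L
  seg_idx <- findInterval(ref$time_s, edges, rightmost.closed = TRUE)
  seg_idx[seg_idx < 1] <- 1L
  seg_idx[seg_idx > ns] <- ns
  dur <- diff(edges)
  # Static test for an interval [a, b]: OLS velocity within one SD of the
  # control net-velocity distribution at the interval duration. Applied
  # twice: to the full interval, and (when long enough) to the interior
  # with the ends trimmed, judged at the interior duration. The trimmed
  # variant rescues genuine pauses whose boundaries are off by ~1 detection
  # sample (at high exit velocity that spill-over alone exceeds the band);
  # the untrimmed variant keeps full sensitivity for slow traces where
  # trimming would only widen the band.
  local_speed <- function(a, b) {
    s <- which(ref$time_s >= a & ref$time_s <= b)
    if (length(s) < 3) return(Inf)
    abs(.ols_slope(ref$time_s[s], ref$exited_bp[s]))
  }
  interval_static <- function(a, b) {
    s0 <- which(ref$time_s >= a & ref$time_s <= b)
    if (length(s0) < 2) return(FALSE)
    v <- .ols_slope(ref$time_s[s0], ref$exited_bp[s0])
    th <- .noise_at(noise, b - a)
    if (abs(v - th$net_mean) <= th$net_sd) return(TRUE)
    # the trimmed fallback is allowed only where the flanking movement is
    # fast enough that a one-sample boundary error alone would exceed the
    # length resolution; on slow traces trimming would merely widen the
    # band and admit genuine slow movement
    if (b - a >= 0.12) {
      v_nb <- max(local_speed(a - 0.08, a), local_speed(b, b + 0.08))
      if (v_nb * 0.015 > noise$resolution_bp) {
        s1 <- s0[ref$time_s[s0] >= a + 0.025 & ref$time_s[s0] <= b - 0.025]
        if (length(s1) >= 2) {
          v1 <- .ols_slope(ref$time_s[s1], ref$exited_bp[s1])
          th1 <- .noise_at(noise, b - a - 0.05)
          return(abs(v1 - th1$net_mean) <= th1$net_sd)
        }
      }
    }
    FALSE
  }
  ymean <- vapply(seq_len(ns), function(k) {
    s <- which(seg_idx == k)
    if (!length(s)) return(NA_real_)
    mean(ref$exited_bp[s])
  }, numeric(1))
  vel0 <- vapply(seq_len(ns), function(k) {
    s <- which(seg_idx == k)
    if (length(s) < 2) return(0)
    .ols_slope(ref$time_s[s], ref$exited_bp[s])
  }, numeric(1))
  is_pause <- vapply(seq_len(ns), function(k) {
    interval_static(edges[k], edges[k + 1L])
  }, logical(1))

  p_seg <- which(is_pause)
  if (!length(p_seg)) {
    return(tibble::tibble(start_s = numeric(0), end_s = numeric(0),
                          duration_s = numeric(0), filling_pct = numeric(0),
                          exited_bp = numeric(0)))
  }
  # group pause segments that are contiguous or separated by movements
  # with sub-resolution net level change (exited length is monotone, so
  # the level difference between two plateaus is the DNA advanced between
  # them). Each group is merged only if the merged interval still looks
  # static as a whole; otherwise it is split recursively at its largest
  # internal level jump, so a wrongly bridged stretch never drags down a
  # genuine pause, and spurious micro-plateaus carved out of steady motion
  # by the segmentation fail their collective test.
  merge_rec <- function(members) {
    if (length(members) == 1) {
      return(tibble::tibble(a = edges[members], b = edges[members + 1L]))
    }
    a <- edges[members[1]]
    b <- edges[members[length(members)] + 1L]
    if (interval_static(a, b)) return(tibble::tibble(a = a, b = b))
    j <- which.max(abs(diff(ymean[members])))
    dplyr::bind_rows(merge_rec(members[seq_len(j)]),
                     merge_rec(members[(j + 1):length(members)]))
  }
  linked <- if (length(p_seg) > 1) {
    vapply(seq_len(length(p_seg) - 1), function(i) {
      !is.na(ymean[p_seg[i]]) && !is.na(ymean[p_seg[i + 1]]) &&
        abs(ymean[p_seg[i + 1]] - ymean[p_seg[i]]) <= noise$resolution_bp
    }, logical(1))
  } else logical(0)
  grp <- cumsum(c(1, !linked))
  merged <- purrr::map(split(p_seg, grp), merge_rec) |>
    purrr::list_rbind()
  # minimum resolvable duration scales inversely with the local moving
  # velocity: a pause during which steady local motion would have advanced
  # the DNA by less than ~5 length resolutions cannot be told from the
  # flat stretches that piecewise-constant segmentation carves out of
  # steadily moving noise. Local velocity is measured over fixed brackets
  # flanking the candidate.
  v_loc <- purrr::map2_dbl(merged$a, merged$b, function(a, b) {
    sb <- which(ref$time_s >= a - 0.15 & ref$time_s < a)
    sa <- which(ref$time_s > b & ref$time_s <= b + 0.15)
    v <- c(if (length(sb) >= 3) abs(.ols_slope(ref$time_s[sb], ref$exited_bp[sb])),
           if (length(sa) >= 3) abs(.ols_slope(ref$time_s[sa], ref$exited_bp[sa])))
    if (!length(v)) Inf else max(v)
  })
  out <- tibble::tibble(start_s = merged$a, end_s = merged$b) |>
    dplyr::mutate(duration_s = .data$end_s - .data$start_s) |>
    dplyr::filter(.data$duration_s >=
                    pmax(max(min_duration, noise$min_duration_s),
                         5 * noise$resolution_bp / v_loc))
  ref <- if (!is.null(full_series)) full_series else series
  out$exited_bp <- stats::approx(ref$time_s, ref$exited_bp,
                                 xout = out$start_s, rule = 2)$y
  if ("filling_pct" %in% names(ref)) {
    out$filling_pct <- stats::approx(ref$time_s, ref$filling_pct,
                                     xout = out$start_s, rule = 2)$y
  } else {
    out$filling_pct <- NA_real_
  }
  dplyr::relocate(out, "start_s", "end_s", "duration_s", "filling_pct",
                  "exited_bp")
}

# Refine a pause boundary on the full-rate series: within +/- halfwin of
# the coarse boundary, place the step of a two-mean fit over a +/- 5*halfwin
# context window where it minimises the residual sum of squares.
.refine_boundary <- function(t0, full_series, halfwin) {
  tt <- full_series$time_s
  sel <- which(tt >= t0 - 5 * halfwin & tt <= t0 + 5 * halfwin)
  if (length(sel) < 6) return(t0)
  y <- full_series$exited_bp[sel]
  t <- tt[sel]
  cand <- which(t >= t0 - halfwin & t <= t0 + halfwin)
  cand <- cand[cand >= 2 & cand <= length(y) - 1]
  if (!length(cand)) return(t0)
  S1 <- cumsum(y); S2 <- cumsum(y * y)
  k <- cand
  nl <- k; nr <- length(y) - k
  ssr <- (S2[k] - S1[k]^2 / nl) +
    ((S2[length(y)] - S2[k]) - (S1[length(y)] - S1[k])^2 / nr)
  t[k[which.min(ssr)]]
}

# Segment a series in chunks local in exited length, so the shared-variance
# BIC is estimated from data of comparable velocity (the exit velocity and
# hence the residual scale varies by orders of magnitude over a whole
# event). Chunk boundaries are added as change points; pauses spanning a
# boundary are re-joined when adjacent pause segments are collapsed.
.chunked_changepoints <- function(y, x, min_segment = 3L, chunk_bp = 500) {
  n <- length(y)
  cm <- cummax(x)
  grp <- floor((cm - cm[1]) / chunk_bp)
  starts <- which(c(TRUE, diff(grp) > 0))
  bounds <- 1L
  for (s in starts[-1]) {
    if (s - bounds[length(bounds)] >= 2 * min_segment &&
        n - s + 1 >= 2 * min_segment) {
      bounds <- c(bounds, s)
    }
  }
  lo <- bounds
  hi <- c(bounds[-1] - 1L, n)
  cps <- purrr::map2(lo, hi, function(i, j) {
    if (j - i + 1 < 2 * min_segment) return(integer(0))
    kv_changepoints(y[i:j], min_segment) + i - 1L
  })
  sort(unique(c(unlist(cps), bounds[-1] - 1L)))
}

#' Detect pauses in one ejection trace
#'
#' Convenience wrapper: converts the trace to an exited-length/filling
#' series, removes the control-calibrated instrument drift (so pauses are
#' flat plateaus rather than drift staircases), block-averages to the
#' detection rate, runs [kv_changepoints()] within chunks local in exited
#' length (so the shared noise variance is estimated from data of
#' comparable velocity) and [classify_pauses()] (with boundary refinement
#' on the full-rate series).
#'
#' @param trace An ejection trace tibble.
#' @param noise A `noise_model` from [calibrate_noise()].
#' @param params An [elastic_params()] object.
#' @param genome_bp Genome length for the filling conversion.
#' @param detection_rate Segmentation rate in Hz (block means).
#' @param min_segment Minimum KV segment, samples at the detection rate.
#' @param min_duration Minimum pause duration, s.
#' @return A list with `pauses` (pause tibble), `series` (full-rate
#'   filling series) and `series_detect` (detection-rate series).
#' @export
detect_pauses <- function(trace, noise, params = elastic_params(),
                          genome_bp = 19300, detection_rate = 100,
                          min_segment = 3L, min_duration = 0.03) {
  raw <- exited_length_series(trace, params)
  # remove the control-calibrated instrument drift so pauses are plateaus
  raw$exited_bp <- raw$exited_bp - noise$drift_bp_s * (raw$time_s - raw$time_s[1])
  full <- filling_series(raw, genome_bp)
  rate <- 1 / (full$time_s[2] - full$time_s[1])
  k <- max(1L, round(rate / detection_rate))
  nb <- floor(nrow(full) / k)
  if (nb < 2 * min_segment) rlang::abort("trace too short for pause detection")
  blk <- function(x) colMeans(matrix(x[seq_len(nb * k)], nrow = k))
  ds <- tibble::tibble(time_s = blk(full$time_s),
                       exited_bp = blk(full$exited_bp),
                       filling_pct = blk(full$filling_pct))
  cps <- .chunked_changepoints(ds$exited_bp, ds$exited_bp,
                               min_segment = min_segment,
                               chunk_bp = 0.025 * genome_bp)
  pauses <- classify_pauses(ds, cps, noise, min_duration = min_duration,
                            full_series = full)
  list(pauses = pauses, series = full, series_detect = ds)
}

# Monotone (running-minimum) filling envelope crossing time: first time the
# envelope reaches `level`; NA if never.
.crossing_time <- function(time_s, filling_mono, level, t_end) {
  i <- which(filling_mono <= level)[1]
  if (is.na(i)) t_end else time_s[i]
}

#' Per-bin pause metrics
#'
#' Pause frequency (pauses per kb of DNA exited), mean pause duration and
#' fraction of time paused, per filling bin. Frequency and duration are
#' computed per event and then averaged across events (bootstrap SE over
#' events); the paused-time fraction is pooled.
#'
#' @param pauses Pause tibble with an `event_id` column.
#' @param series_list Named list of per-event filling series (full rate).
#' @param bin_width Bin width in %.
#' @param genome_bp Genome length in bp.
#' @param bootstrap_reps Bootstrap resamples for the frequency SE.
#' @param seed Optional bootstrap seed.
#' @return A tibble with one row per populated bin: `bin_lo`, `bin_hi`,
#'   `bin_center`, `frequency_per_kb`, `frequency_se`, `mean_duration_s`,
#'   `fraction_paused`, `n_events`, `n_pauses`.
#' @export
pause_metrics_by_bin <- function(pauses, series_list, bin_width = 5,
                                 genome_bp = 19300, bootstrap_reps = 1000,
                                 seed = NULL) {
  per_event <- purrr::imap(series_list, function(fs, id) {
    dt <- fs$time_s[2] - fs$time_s[1]
    t_end <- fs$time_s[nrow(fs)] + dt
    fmono <- cummin(fs$filling_pct)
    f_hi <- fmono[1]
    f_lo <- fmono[length(fmono)]
    bins <- seq(.bin_lo(f_lo, bin_width), .bin_lo(min(f_hi, 99.999), bin_width),
                by = bin_width)
    ev_p <- dplyr::filter(pauses, .data$event_id == id)
    purrr::map(bins, function(blo) {
      bhi <- blo + bin_width
      t_in <- .crossing_time(fs$time_s, fmono, min(bhi, f_hi), t_end)
      t_out <- .crossing_time(fs$time_s, fmono, blo, t_end)
      span <- min(bhi, f_hi) - max(blo, f_lo)
      if (span <= 0 || t_out <= t_in) return(NULL)
      inbin <- dplyr::filter(ev_p, .data$filling_pct >= blo,
                             .data$filling_pct < bhi)
      paused <- if (nrow(ev_p)) {
        sum(pmax(0, pmin(ev_p$end_s, t_out) - pmax(ev_p$start_s, t_in)))
      } else 0
      tibble::tibble(
        event_id = id, bin_lo = blo, bin_hi = bhi,
        bin_center = blo + bin_width / 2,
        kb_exited = span * genome_bp / 100 / 1000,
        n_pauses = nrow(inbin),
        mean_duration_s = if (nrow(inbin)) mean(inbin$duration_s) else NA_real_,
        time_in_bin_s = t_out - t_in, paused_time_s = paused
      )
    }) |> purrr::compact() |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  summarise_bins <- function(pe) {
    pe |>
      dplyr::group_by(.data$bin_lo, .data$bin_hi, .data$bin_center) |>
      dplyr::summarise(
        frequency_per_kb = mean(.data$n_pauses / .data$kb_exited),
        mean_duration_s = if (all(is.na(.data$mean_duration_s))) NA_real_
          else mean(.data$mean_duration_s, na.rm = TRUE),
        fraction_paused = sum(.data$paused_time_s) / sum(.data$time_in_bin_s),
        n_events = dplyr::n(), n_pauses = sum(.data$n_pauses),
        .groups = "drop")
  }
  est <- summarise_bins(per_event)
  ids <- unique(per_event$event_id)
  se <- withr::with_seed(
    if (is.null(seed)) stats::runif(1, 1, 2^30) else seed, {
      purrr::map(seq_len(bootstrap_reps), function(i) {
        pe <- dplyr::inner_join(per_event,
                                tibble::tibble(event_id = sample(ids, replace = TRUE)),
                                by = "event_id", relationship = "many-to-many")
        dplyr::group_by(pe, .data$bin_lo) |>
          dplyr::summarise(f = mean(.data$n_pauses / .data$kb_exited),
                           .groups = "drop")
      }) |> purrr::list_rbind() |>
        dplyr::group_by(.data$bin_lo) |>
        dplyr::summarise(frequency_se = stats::sd(.data$f), .groups = "drop")
    })
  dplyr::left_join(est, se, by = "bin_lo") |>
    dplyr::relocate("frequency_se", .after = "frequency_per_kb") |>
    dplyr::arrange(dplyr::desc(.data$bin_lo))
}

#' Overall pause summary
#'
#' Pooled fraction of total exit time spent paused, total pause count and
#' per-event totals.
#'
#' @param pauses Pause tibble with `event_id`.
#' @param series_list Named list of per-event series (defines each event's
#'   total exit time).
#' @return A list with `fraction_paused` (pooled), `total_paused_s`,
#'   `total_time_s`, `n_pauses` and a per-event tibble.
#' @export
pause_summary <- function(pauses, series_list) {
  per_event <- purrr::imap(series_list, function(fs, id) {
    dt <- fs$time_s[2] - fs$time_s[1]
    tibble::tibble(
      event_id = id,
      total_time_s = fs$time_s[nrow(fs)] - fs$time_s[1] + dt,
      paused_time_s = sum(pauses$duration_s[pauses$event_id == id]),
      n_pauses = sum(pauses$event_id == id)
    )
  }) |> purrr::list_rbind()
  list(fraction_paused = sum(per_event$paused_time_s) /
         sum(per_event$total_time_s),
       total_paused_s = sum(per_event$paused_time_s),
       total_time_s = sum(per_event$total_time_s),
       n_pauses = sum(per_event$n_pauses),
       per_event = per_event)
}
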