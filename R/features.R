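# Waveform feature extraction: tonic EMG level, P and N peak detection on
# the 0-50 ms analysis window, peak-to-peak amplitude, the PN/EMG amplitude
# ratio, two-trial replicability, and staircase threshold determination.
#
# Peak picking and replicability are computed on a Gaussian-smoothed copy of
# the trace (default kernel SD 1 ms, matched to the response bandwidth);
# this is the quantitative analogue of judging reproducibility on visually
# smoothed averages and is what makes the correlation criterion usable at
# 25-50 epoch averaging. The raw samples are never modified.

.ms_to_idx <- function(trace, t_ms) {
  pmin(pmax(as.integer(round(t_ms * trace$fs_hz / 1000)) + 1L, 1L),
       length(trace$samples))
}

#' Tonic EMG level of a trace
#'
#' Mean rectified (absolute) voltage over a window. The default window is
#' the post-response 50-150 ms segment, so the evoked response itself does
#' not contaminate the EMG estimate; pass `window_ms = c(0, 150)` for the
#' whole-epoch definition.
#'
#' @param trace A `vemp_trace`.
#' @param window_ms Two-element window in ms from stimulus onset.
#' @return EMG level in microvolts.
#' @export
emg_level <- function(trace, window_ms = c(50, 150)) {
  stopifnot(inherits(trace, "vemp_trace"), length(window_ms) == 2L)
  dur <- 1000 * length(trace$samples) / trace$fs_hz
  if (window_ms[2] <= window_ms[1])
    stop("empty EMG window", call. = FALSE)
  if (window_ms[1] < 0 || window_ms[1] >= dur)
    stop("EMG window outside the trace", call. = FALSE)
  i <- .ms_to_idx(trace, window_ms[1]):.ms_to_idx(trace, min(window_ms[2], dur))
  mean(abs(trace$samples[i]))
}

#' Detect the P and N peaks of a c-VEMP trace
#'
#' P is the largest positive deflection in the P search window (default
#' 8-18 ms after stimulus onset); N is the most negative deflection between
#' P + 2 ms and `n_max_ms`. The response is called present when the
#' peak-to-peak amplitude exceeds `k` times a robust noise scale estimated
#' from the trace outside the response window.
#'
#' @param trace A `vemp_trace` covering at least 0-30 ms.
#' @param p_window_ms Search window for P, ms.
#' @param n_max_ms Upper bound of the N search window, ms.
#' @param k Detection multiple of the noise scale.
#' @param smooth_ms Gaussian smoothing SD applied before peak picking, ms
#'   (0 disables).
#' @return List with `p_latency_ms`, `n_latency_ms`, `pn_amplitude_uv`,
#'   `response_present`, `noise_uv`.
#' @export
detect_pn <- function(trace, p_window_ms = c(8, 18), n_max_ms = 30,
                      k = 3, smooth_ms = 1) {
  stopifnot(inherits(trace, "vemp_trace"))
  dur <- 1000 * length(trace$samples) / trace$fs_hz
  if (dur < n_max_ms)
    stop(sprintf("trace too short: need >= %g ms", n_max_ms), call. = FALSE)
  x <- .gauss_smooth(trace$samples, smooth_ms * trace$fs_hz / 1000)
  t_ms <- trace_time_ms(trace)

  ip <- which(t_ms >= p_window_ms[1] & t_ms <= p_window_ms[2])
  p_i <- ip[which.max(x[ip])]
  p_lat <- t_ms[p_i]
  in_ <- which(t_ms >= p_lat + 2 & t_ms <= n_max_ms)
  n_i <- in_[which.min(x[in_])]
  n_lat <- t_ms[n_i]
  # peak amplitudes read from the raw trace, averaged over +/- 0.3 ms around
  # the smoothed-peak latencies (cursor-style measurement, avoids the
  # smoothing attenuation of the peak height)
  hw <- max(1L, as.integer(round(0.3 * trace$fs_hz / 1000)))
  peak_val <- function(i) {
    j <- max(1L, i - hw):min(length(trace$samples), i + hw)
    mean(trace$samples[j])
  }
  pp <- peak_val(p_i) - peak_val(n_i)

  # robust noise scale from outside the response window (beyond 50 ms when
  # the trace allows, otherwise the pre/post-response remainder)
  noise_idx <- which(t_ms >= 50)
  if (length(noise_idx) < 20L)
    noise_idx <- which(t_ms < 5 | t_ms > n_max_ms)
  noise <- stats::mad(x[noise_idx], center = mean(x[noise_idx]))

  present <- is.finite(pp) && pp > 0 && pp >= k * noise
  list(p_latency_ms = p_lat, n_latency_ms = n_lat, pn_amplitude_uv = pp,
       response_present = present, noise_uv = noise)
}

#' PN/EMG amplitude ratio
#'
#' Normalizes the peak-to-peak response amplitude by the tonic EMG level,
#' removing the dependence on muscle-contraction strength.
#'
#' @param pn_amplitude_uv Peak-to-peak amplitude, microvolts (>= 0).
#' @param emg_uv EMG level, microvolts (> 0).
#' @return Dimensionless amplitude ratio.
#' @export
amplitude_ratio <- function(pn_amplitude_uv, emg_uv) {
  if (any(!is.finite(emg_uv)) || any(emg_uv <= 0))
    stop("EMG level must be > 0", call. = FALSE)
  if (any(pn_amplitude_uv < 0))
    stop("peak-to-peak amplitude must be >= 0", call. = FALSE)
  pn_amplitude_uv / emg_uv
}

#' Are two successive averages replicable?
#'
#' Quantifies the protocol's "reproducible on two successive trials" rule:
#' both traces must carry a detected response, their smoothed mean-centered
#' 0-50 ms segments must correlate at `r_min` or better, and the P latencies
#' must agree within `max_dp_ms`.
#'
#' @param trace_a,trace_b Two `vemp_trace`s at the same sampling rate and
#'   stimulation level.
#' @param r_min Minimum Pearson correlation (default 0.7).
#' @param max_dp_ms Maximum P-latency difference, ms.
#' @param window_ms Correlation window, ms.
#' @param ... Passed to [detect_pn()].
#' @return Logical.
#' @export
is_replicable <- function(trace_a, trace_b, r_min = 0.7, max_dp_ms = 2,
                          window_ms = c(0, 50), ...) {
  stopifnot(inherits(trace_a, "vemp_trace"), inherits(trace_b, "vemp_trace"))
  if (trace_a$fs_hz != trace_b$fs_hz)
    stop("traces have different sampling rates", call. = FALSE)
  la <- trace_a$meta$level_dbnhl; lb <- trace_b$meta$level_dbnhl
  if (!is.null(la) && !is.null(lb) && !isTRUE(all.equal(la, lb)))
    stop("traces were recorded at different stimulation levels",
         call. = FALSE)
  da <- detect_pn(trace_a, ...)
  db <- detect_pn(trace_b, ...)
  if (!da$response_present || !db$response_present) return(FALSE)
  if (abs(da$p_latency_ms - db$p_latency_ms) > max_dp_ms) return(FALSE)
  dots <- list(...)
  sm <- if (!is.null(dots$smooth_ms)) dots$smooth_ms else 1
  seg <- function(tr) {
    i <- .ms_to_idx(tr, window_ms[1]):.ms_to_idx(tr, window_ms[2])
    x <- .gauss_smooth(tr$samples, sm * tr$fs_hz / 1000)[i]
    x - mean(x)
  }
  a <- seg(trace_a); b <- seg(trace_b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(FALSE)
  stats::cor(a, b) >= r_min
}

.session_traces <- function(session, ear, mode) {
  keep <- vapply(session$traces, function(tr)
    identical(tr$meta$ear, ear) && identical(tr$meta$mode, mode),
    logical(1))
  session$traces[keep]
}

#' Staircase threshold from a recorded session
#'
#' Walks the 5-dB staircase for one ear and mode: starting at the reference
#' level and descending while the two replicate averages at each level are
#' replicable; the threshold is the lowest replicable level. When the
#' reference level itself is not replicable, the ascending branch is tried
#' up to the device ceiling; if no level replicates there either, the
#' response is reported absent.
#'
#' @param session A `vemp_session` (or any list with a `traces` component).
#' @param ear `"R"` or `"L"`.
#' @param mode `"AC"` or `"BC"`.
#' @param r_min,max_dp_ms,... Replicability settings, see [is_replicable()].
#' @return Object of class `vemp_threshold`: `threshold_dbnhl` (`NA` when
#'   absent), `response_absent`, `levels_tested`, `replicable_at`.
#' @export
find_threshold <- function(session, ear, mode, r_min = 0.7, max_dp_ms = 2,
                           ...) {
  trs <- .session_traces(session, ear, mode)
  if (length(trs) == 0L)
    stop("session has no traces for this ear and mode", call. = FALSE)
  levels <- sort(unique(vapply(trs, function(tr) tr$meta$level_dbnhl,
                               numeric(1))))
  ref <- reference_level_nhl(mode)
  start <- if (ref %in% levels) ref else max(levels[levels <= ref], levels[1])

  rep_at <- function(lv) {
    pair <- Filter(function(tr) isTRUE(all.equal(tr$meta$level_dbnhl, lv)) &&
                     !identical(tr$meta$purpose, "reference"), trs)
    if (length(pair) < 2L) return(FALSE)
    is_replicable(pair[[1]], pair[[2]], r_min = r_min,
                  max_dp_ms = max_dp_ms, ...)
  }

  tested <- numeric(0)
  replicable <- numeric(0)
  if (rep_at(start)) {
    tested <- start; replicable <- start
    for (lv in sort(levels[levels < start], decreasing = TRUE)) {
      tested <- c(tested, lv)
      if (rep_at(lv)) replicable <- c(replicable, lv) else break
    }
  } else {
    tested <- start
    for (lv in sort(levels[levels > start])) {
      tested <- c(tested, lv)
      if (rep_at(lv)) { replicable <- lv; break }
    }
  }

  thr <- if (length(replicable)) min(replicable) else NA_real_
  structure(
    list(threshold_dbnhl = thr, response_absent = !length(replicable),
         levels_tested = tested, replicable_at = sort(replicable)),
    class = "vemp_threshold"
  )
}

#' @export
print.vemp_threshold <- function(x, ...) {
  cat(sprintf("<vemp_threshold> %s\n",
              if (x$response_absent) "response absent"
              else sprintf("%g dB nHL", x$threshold_dbnhl)))
  cat("  levels tested:", paste(x$levels_tested, collapse = ", "), "\n")
  invisible(x)
}

#' Extract the full feature set of a session
#'
#' For each recorded ear x mode: threshold determination over the staircase,
#' and reference-level features (P/N latencies, peak-to-peak amplitude, EMG
#' level and PN/EMG amplitude ratio) averaged over the two replicate
#' reference averages.
#'
#' @param session A `vemp_session`.
#' @param r_min,max_dp_ms Replicability settings, see [is_replicable()].
#' @param ... Detection settings passed to [detect_pn()].
#' @return Data frame in the cohort feature-table layout, one row per
#'   ear x mode (see [read_feature_csv()] for the schema).
#' @export
session_features <- function(session, r_min = 0.7, max_dp_ms = 2, ...) {
  combos <- unique(do.call(rbind, lapply(session$traces, function(tr)
    data.frame(ear = tr$meta$ear, mode = tr$meta$mode))))
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    ear <- combos$ear[i]; mode <- combos$mode[i]
    ref <- reference_level_nhl(mode)
    thr <- find_threshold(session, ear, mode, r_min = r_min,
                          max_dp_ms = max_dp_ms, ...)
    at_ref <- Filter(function(tr)
      isTRUE(all.equal(tr$meta$level_dbnhl, ref)),
      .session_traces(session, ear, mode))
    trs <- Filter(function(tr) identical(tr$meta$purpose, "reference"),
                  at_ref)
    if (length(trs) == 0L) trs <- at_ref
    feats <- lapply(trs, detect_pn, ...)
    present <- length(feats) > 0 &&
      all(vapply(feats, `[[`, logical(1), "response_present")) &&
      !thr$response_absent
    emg <- mean(vapply(trs, function(tr) tr$meta$emg_uv, numeric(1)))
    pn <- mean(vapply(feats, `[[`, numeric(1), "pn_amplitude_uv"))
    data.frame(
      subject_id = session$subject_id, group = session$group,
      age_years = session$age_years, sex = session$sex,
      ear = ear, mode = mode,
      pn_uv = if (present) pn else NA_real_,
      emg_uv = emg,
      amplitude_ratio = if (present) amplitude_ratio(pn, emg) else NA_real_,
      p_latency_ms = if (present)
        mean(vapply(feats, `[[`, numeric(1), "p_latency_ms")) else NA_real_,
      n_latency_ms = if (present)
        mean(vapply(feats, `[[`, numeric(1), "n_latency_ms")) else NA_real_,
      threshold_dbnhl = thr$threshold_dbnhl
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
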