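# Per-session waveform synthesis. Each epoch is tonic sternocleidomastoid
# EMG (band-limited Gaussian noise) plus, when the stimulus is above the
# subject's threshold, a biphasic response modeled as a positive and a
# negative Gaussian bump at the P and N latencies. Amplitudes are scaled so
# that, noise aside, the peak-to-peak response at the reference stimulation
# level equals `true_ratio * emg_level`, which makes the PN/EMG amplitude
# ratio a genuine recovery target for the feature extractor.
#
# EMG convention: `emg_uv` is the *rectified-mean* EMG (the quantity the
# recording device displays and the 100-500 uV target band refers to); the
# Gaussian noise RMS is therefore emg_uv * sqrt(pi/2), so that the rectified
# mean of the synthetic background equals emg_uv.

#' Waveform synthesis configuration
#'
#' @param fs_hz Sampling rate (default 10 kHz).
#' @param epoch_ms Epoch length from stimulus onset (default 150 ms, the EMG
#'   quantification window).
#' @param n_epochs_children,n_epochs_adults Epochs per average at the
#'   reference level.
#' @param n_epochs_threshold Epochs per average on staircase levels below the
#'   reference (acquisition is increased for threshold determination).
#' @param noise_scale Multiplier on the EMG background (1 = nominal; 0 gives
#'   noiseless traces).
#' @param response_width_ms Gaussian half-width of the P and N bumps, ms.
#' @param noise_corr_ms Correlation scale of the EMG background, ms (Gaussian
#'   smoothing of white noise; the 0.1 ms default gives a broadband
#'   background on the order of the evoked-potential amplifier band).
#' @return List of class `vemp_waveform_config`.
#' @export
waveform_config <- function(fs_hz = 10000, epoch_ms = 150,
                            n_epochs_children = 25L, n_epochs_adults = 50L,
                            n_epochs_threshold = 50L, noise_scale = 1,
                            response_width_ms = 2, noise_corr_ms = 0.1) {
  n_samp <- fs_hz * epoch_ms / 1000
  stopifnot(fs_hz > 2000, epoch_ms > 0, abs(n_samp - round(n_samp)) < 1e-9,
            n_epochs_children >= 2, n_epochs_adults >= 2,
            n_epochs_threshold >= 2, noise_scale >= 0,
            response_width_ms > 0, noise_corr_ms >= 0)
  structure(as.list(environment()), class = "vemp_waveform_config")
}

#' Construct an averaged-trace object
#'
#' @param samples Sampled voltages in microvolts; sample 1 is stimulus onset.
#' @param fs_hz Sampling rate in Hz.
#' @param meta Named list of metadata (ear, mode, level_dbnhl, replicate,
#'   n_epochs, emg_uv, ...).
#' @return Object of class `vemp_trace`.
#' @export
vemp_trace <- function(samples, fs_hz, meta = list()) {
  stopifnot(is.numeric(samples), all(is.finite(samples)), fs_hz > 2000)
  structure(list(samples = as.numeric(samples), fs_hz = fs_hz, meta = meta),
            class = "vemp_trace")
}

#' @export
print.vemp_trace <- function(x, ...) {
  dur <- 1000 * length(x$samples) / x$fs_hz
  m <- x$meta
  cat(sprintf("<vemp_trace> %d samples @ %g Hz (%.1f ms)\n",
              length(x$samples), x$fs_hz, dur))
  if (length(m))
    cat("  ", paste(names(m), unlist(m), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Time axis of a trace in milliseconds
#' @param trace A `vemp_trace`.
#' @return Numeric vector, ms from stimulus onset.
#' @export
trace_time_ms <- function(trace) {
  (seq_along(trace$samples) - 1) / trace$fs_hz * 1000
}

# Gaussian-kernel smoothing with reflective padding (no edge attenuation).
.gauss_smooth <- function(x, sd_samples) {
  if (sd_samples <= 0) return(x)
  hw <- max(1L, ceiling(4 * sd_samples))
  k <- stats::dnorm(seq(-hw, hw), sd = sd_samples)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rev(x[seq_len(min(hw, n))]), x, rev(x[seq.int(n, by = -1,
                                                        length.out = min(hw, n))]))
  sm <- stats::filter(xp, k, sides = 2)
  as.numeric(sm[(hw + 1):(hw + n)])
}

# Band-limited Gaussian EMG background: smoothed white noise rescaled to the
# requested RMS. Returns an n_samples x n_epochs matrix.
.emg_noise <- function(n_samples, n_epochs, rms, corr_samples) {
  if (rms <= 0) return(matrix(0, n_samples, n_epochs))
  w <- stats::rnorm(n_samples * n_epochs)
  sm <- .gauss_smooth(w, corr_samples)
  sm <- sm * (rms / stats::sd(sm))
  matrix(sm, n_samples, n_epochs)
}

# Amplitude growth above threshold: zero below the subject's threshold,
# rising linearly from 0 at (threshold - 5 dB) to 1 at the reference level,
# clamped to [0, 1]. The span is at least one 5-dB step so that subjects
# whose threshold sits at or above the reference still grow.
.growth <- function(level_nhl, threshold_nhl, ref_nhl) {
  if (!is.finite(threshold_nhl) || level_nhl < threshold_nhl) return(0)
  span <- max(ref_nhl - (threshold_nhl - 5), 5)
  min((level_nhl - (threshold_nhl - 5)) / span, 1)
}

# Noiseless biphasic response with unit positive/negative Gaussian bumps,
# scaled to a target peak-to-peak amplitude.
.response_wave <- function(t_ms, t_p, t_n, width_ms, pp_target) {
  u <- exp(-(t_ms - t_p)^2 / (2 * width_ms^2)) -
    exp(-(t_ms - t_n)^2 / (2 * width_ms^2))
  if (pp_target <= 0) return(u * 0)
  pp_u <- max(u) - min(u)
  u * (pp_target / pp_u)
}

#' Synthesize one stimulus-locked epoch
#'
#' @param subject One row of a [sample_cohort()] table (the ear/mode whose
#'   epoch is wanted).
#' @param level_nhl Stimulation level in dB nHL.
#' @param wconfig A [waveform_config()].
#' @param seed Optional integer seed.
#' @return A `vemp_trace` of one epoch.
#' @export
synth_epoch <- function(subject, level_nhl, wconfig = waveform_config(),
                        seed = NULL) {
  tr <- .synth_average(subject, level_nhl, n_epochs = 1L, wconfig, seed)
  tr$meta$n_epochs <- 1L
  tr
}

# Core generator: average of n_epochs epochs plus per-epoch EMG measurement.
.synth_average <- function(subject, level_nhl, n_epochs, wconfig,
                           seed = NULL, replicate = 1L,
                           purpose = "threshold") {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                       globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  stopifnot(nrow(subject) == 1L)
  fs <- wconfig$fs_hz
  ns <- as.integer(round(fs * wconfig$epoch_ms / 1000))
  t_ms <- (seq_len(ns) - 1) / fs * 1000
  w <- wconfig$response_width_ms
  if (wconfig$epoch_ms < subject$t_n_ms + 3 * w)
    stop("epoch too short for the response (need >= t_N + 3 widths)",
         call. = FALSE)

  ref <- reference_level_nhl(subject$mode)
  g <- if (isTRUE(subject$response_absent)) 0 else
    .growth(level_nhl, subject$true_threshold_dbnhl, ref)
  pp <- if (g > 0) subject$true_ratio * subject$emg_uv * g else 0
  resp <- .response_wave(t_ms, subject$t_p_ms, subject$t_n_ms, w, pp)

  rms <- subject$emg_uv * sqrt(pi / 2) * wconfig$noise_scale
  corr_samples <- wconfig$noise_corr_ms * fs / 1000
  noise <- .emg_noise(ns, n_epochs, rms, corr_samples)
  epochs <- noise + resp

  # EMG quantified per individual epoch (rectified mean over the post-response
  # 50-150 ms segment), then averaged across epochs
  emg_win <- t_ms >= 50
  emg_meas <- if (wconfig$noise_scale > 0)
    mean(colMeans(abs(epochs[emg_win, , drop = FALSE]))) else subject$emg_uv

  vemp_trace(rowMeans(epochs), fs, meta = list(
    subject_id = subject$subject_id, ear = subject$ear, mode = subject$mode,
    level_dbnhl = level_nhl, replicate = replicate, n_epochs = n_epochs,
    emg_uv = emg_meas, purpose = purpose
  ))
}

#' Synthesize a full recording session for one subject
#'
#' Runs the staircase protocol for every requested ear x mode. Every
#' staircase level (the reference included) gets two replicate averages at
#' the increased epoch count used for threshold determination; the reference
#' level additionally gets two replicate averages at the group's standard
#' epoch count (25 in children, 50 in adults), which are the traces used for
#' between-subject feature comparison. The staircase descends in 5-dB steps
#' down to two steps below the subject's true threshold, or ascends up to
#' the device ceiling when the threshold lies above the reference. Ears or
#' modes with an absent response get noise-only traces up to the ceiling.
#'
#' @param subject_rows Rows of a [sample_cohort()] table for one subject (one
#'   row per ear x mode to record).
#' @param wconfig A [waveform_config()].
#' @param seed Integer seed; each ear x mode gets its own derived stream.
#' @return Object of class `vemp_session`: list with `subject_id`, `group`,
#'   `age_years`, `sex`, and `traces` (list of `vemp_trace`).
#' @export
synth_session <- function(subject_rows, wconfig = waveform_config(),
                          seed = 1L) {
  stopifnot(nrow(subject_rows) >= 1L,
            length(unique(subject_rows$subject_id)) == 1L)
  n_ref <- if (subject_rows$group[1] == "child") wconfig$n_epochs_children
  else wconfig$n_epochs_adults
  traces <- list()
  for (i in seq_len(nrow(subject_rows))) {
    row <- subject_rows[i, ]
    ref <- reference_level_nhl(row$mode)
    lad <- staircase_levels(ref, 5, floor = ref - 30, ceiling = ref + 10)
    thr <- row$true_threshold_dbnhl
    levels <- if (isTRUE(row$response_absent) || !is.finite(thr)) {
      sort(unique(c(lad$descending[1], lad$ascending)))
    } else if (thr > ref) {
      sort(unique(c(ref, lad$ascending)))
    } else {
      lad$descending[lad$descending >= thr - 10]
    }
    for (lv in levels) {
      reps <- if (lv == ref) 4L else 2L
      for (rep_i in seq_len(reps)) {
        n_ep <- if (rep_i > 2L) n_ref else wconfig$n_epochs_threshold
        sd_i <- as.integer((as.numeric(seed) * 1009 + i * 131 +
                              lv * 7 + rep_i * 499) %% 2147483647)
        traces[[length(traces) + 1L]] <-
          .synth_average(row, lv, n_ep, wconfig, seed = sd_i,
                         replicate = rep_i,
                         purpose = if (rep_i > 2L) "reference" else
                           "threshold")
      }
    }
  }
  structure(
    list(subject_id = subject_rows$subject_id[1],
         group = subject_rows$group[1],
         age_years = subject_rows$age_years[1], sex = subject_rows$sex[1],
         traces = traces),
    class = "vemp_session"
  )
}

#' @export
print.vemp_session <- function(x, ...) {
  cat(sprintf("<vemp_session> %s (%s, %.1f y, %s): %d traces\n",
              x$subject_id, x$group, x$age_years, x$sex, length(x$traces)))
  invisible(x)
}
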