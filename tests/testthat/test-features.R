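# Feature extraction: EMG quantification, P/N peak detection, amplitude
# ratio, replicability, and staircase threshold estimation.

test_that("EMG level is the rectified mean and matches the folded-Gaussian identity", {
  tr <- vemp_trace(rep(5, 1500), 10000)
  expect_equal(emg_level(tr, c(0, 150)), 5)
  neg <- vemp_trace(rep(-5, 1500), 10000)
  expect_equal(emg_level(neg, c(0, 150)), emg_level(tr, c(0, 150)))
  # Gaussian noise of RMS sigma has rectified mean sigma * sqrt(2/pi)
  set.seed(11)
  big <- make_noise_trace(sd = 200, dur_ms = 2000)
  expect_equal(emg_level(big, c(0, 2000)), 200 * sqrt(2 / pi),
               tolerance = 0.02)
  expect_error(emg_level(tr, c(50, 50)), "empty")
  expect_error(emg_level(tr, c(200, 300)), "window")
})

test_that("peak detection recovers noiseless latencies to within a sample", {
  for (tp in c(11, 13, 15)) {
    tr <- make_bump_trace(t_p = tp, t_n = tp + 6.3, pp = 300)
    d <- detect_pn(tr, smooth_ms = 0)
    expect_lt(abs(d$p_latency_ms - tp), 0.1 + 1e-9)
    expect_lt(abs(d$n_latency_ms - (tp + 6.3)), 0.1 + 1e-9)
    expect_true(d$response_present)
    expect_equal(d$pn_amplitude_uv, 300, tolerance = 0.02)
  }
  flat <- vemp_trace(rep(0, 1500), 10000)
  expect_false(detect_pn(flat)$response_present)
  expect_error(detect_pn(vemp_trace(rep(0, 100), 10000)), "short")
})

test_that("peak detection is scale-equivariant and shift-equivariant", {
  set.seed(12)
  base <- make_bump_trace(t_p = 13, pp = 400)
  noisy <- vemp_trace(base$samples + stats::rnorm(1500, 0, 40), 10000)
  d1 <- detect_pn(noisy)
  d3 <- detect_pn(vemp_trace(noisy$samples * 3, 10000))
  expect_equal(d1$p_latency_ms, d3$p_latency_ms)
  expect_equal(d1$n_latency_ms, d3$n_latency_ms)
  expect_equal(3 * d1$pn_amplitude_uv, d3$pn_amplitude_uv, tolerance = 1e-9)
  expect_equal(d1$response_present, d3$response_present)
  # one-millisecond time shift moves both latencies by one millisecond
  sh <- make_bump_trace(t_p = 14, t_n = 20.3, pp = 400)
  d0 <- detect_pn(make_bump_trace(t_p = 13, t_n = 19.3, pp = 400),
                  smooth_ms = 0)
  ds <- detect_pn(sh, smooth_ms = 0)
  expect_equal(ds$p_latency_ms - d0$p_latency_ms, 1, tolerance = 0.05)
  expect_equal(ds$n_latency_ms - d0$n_latency_ms, 1, tolerance = 0.05)
})

test_that("amplitude ratio is the PN/EMG quotient with guarded domain", {
  expect_equal(amplitude_ratio(300, 150), 2)
  expect_equal(amplitude_ratio(0, 200), 0)
  expect_error(amplitude_ratio(300, 0), "EMG")
  expect_error(amplitude_ratio(-1, 200), "amplitude")
  # invariance to a common gain rescaling
  expect_equal(amplitude_ratio(300 * 2.7, 150 * 2.7), 2)
})

test_that("replicability accepts identical responses and rejects noise and inversions", {
  tr <- make_bump_trace(pp = 400)
  expect_true(is_replicable(tr, tr))
  inv <- vemp_trace(-tr$samples, tr$fs_hz, tr$meta)
  expect_false(is_replicable(tr, inv))
  # independent pure-noise pairs essentially never replicate
  set.seed(13)
  hits <- sum(replicate(30, {
    is_replicable(make_noise_trace(60), make_noise_trace(60))
  }))
  expect_lte(hits, 2)
  # mismatched metadata is an error
  a <- make_bump_trace(level = 88)
  b <- make_bump_trace(level = 83)
  expect_error(is_replicable(a, b), "level")
  c2 <- make_bump_trace(fs = 5000)
  expect_error(is_replicable(a, c2), "sampling")
})

test_that("the staircase finds the lowest replicable level", {
  subj <- make_subject_row(true_ratio = 2.2, true_threshold = 73)
  sess <- synth_session(subj, waveform_config(), seed = 17)
  thr <- find_threshold(sess, "R", "AC")
  expect_false(thr$response_absent)
  expect_lte(abs(thr$threshold_dbnhl - 73), 5)
  expect_equal(thr$threshold_dbnhl, min(thr$replicable_at))
  expect_true(all((thr$levels_tested - 88) %% 5 == 0))

  # absent response: never replicable up to the ceiling
  ab <- make_subject_row(mode = "BC", absent = TRUE, age = 15.5,
                         true_threshold = NA)
  sa <- synth_session(ab, waveform_config(), seed = 18)
  ta <- find_threshold(sa, "R", "BC")
  expect_true(ta$response_absent)
  expect_true(is.na(ta$threshold_dbnhl))
  expect_error(find_threshold(sess, "L", "BC"), "no traces")
})

test_that("raising the true threshold never lowers the estimate", {
  wc <- waveform_config()
  for (s in 1:4) {
    lo <- make_subject_row(true_ratio = 1.8, true_threshold = 73)
    hi <- lo; hi$true_threshold_dbnhl <- 83
    t_lo <- find_threshold(synth_session(lo, wc, seed = 40 + s), "R", "AC")
    t_hi <- find_threshold(synth_session(hi, wc, seed = 40 + s), "R", "AC")
    e_lo <- if (t_lo$response_absent) Inf else t_lo$threshold_dbnhl
    e_hi <- if (t_hi$response_absent) Inf else t_hi$threshold_dbnhl
    expect_gte(e_hi, e_lo)
  }
})

test_that("session features recover the latent ratio and latencies", {
  rows <- rbind(make_subject_row(ear = "R", true_ratio = 2.0),
                make_subject_row(ear = "L", true_ratio = 1.6))
  sess <- synth_session(rows, waveform_config(), seed = 23)
  f <- session_features(sess)
  expect_equal(nrow(f), 2)
  expect_true(all(is.finite(f$amplitude_ratio)))
  m <- merge(f, rows[, c("ear", "true_ratio", "t_p_ms")], by = "ear")
  expect_true(all(abs(m$amplitude_ratio - m$true_ratio) / m$true_ratio < 0.35))
  expect_true(all(abs(m$p_latency_ms - m$t_p_ms) < 1.5))
  expect_equal(f$amplitude_ratio, f$pn_uv / f$emg_uv, tolerance = 1e-12)
})
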