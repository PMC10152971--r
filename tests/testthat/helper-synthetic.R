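# Shared builders for the test suite: all fixtures are generated in code.

# One latent-subject row in the sample_cohort() layout.
make_subject_row <- function(mode = "AC", true_ratio = 2,
                             true_threshold = 78, t_p = 13, t_n = 19.3,
                             emg = 300, age = 6, sex = "M", ear = "R",
                             group = "child", absent = FALSE) {
  data.frame(subject_id = "T01", group = group, age_years = age, sex = sex,
             ear = ear, mode = mode, true_ratio = true_ratio,
             true_threshold_dbnhl = true_threshold, t_p_ms = t_p,
             t_n_ms = t_n, emg_uv = emg, response_absent = absent)
}

# Noiseless biphasic trace with known latencies and peak-to-peak amplitude.
make_bump_trace <- function(t_p = 13, t_n = 19.3, pp = 300, fs = 10000,
                            dur_ms = 150, width_ms = 2, level = 88,
                            meta = list()) {
  t_ms <- (seq_len(fs * dur_ms / 1000) - 1) / fs * 1000
  u <- exp(-(t_ms - t_p)^2 / (2 * width_ms^2)) -
    exp(-(t_ms - t_n)^2 / (2 * width_ms^2))
  u <- u * (pp / (max(u) - min(u)))
  vemp_trace(u, fs, meta = c(list(level_dbnhl = level), meta))
}

# Gaussian-noise trace (white; adequate for rectification/correlation tests).
make_noise_trace <- function(sd = 200, fs = 10000, dur_ms = 150,
                             level = 88, meta = list()) {
  vemp_trace(stats::rnorm(fs * dur_ms / 1000, 0, sd), fs,
             meta = c(list(level_dbnhl = level), meta))
}

# Reference-level average pair for a subject (independent noise streams).
make_ref_pair <- function(subject, n_epochs = 25,
                          wconfig = waveform_config(), seeds = c(NULL, NULL)) {
  ref <- reference_level_nhl(subject$mode)
  list(vempnorm:::.synth_average(subject, ref, n_epochs, wconfig),
       vempnorm:::.synth_average(subject, ref, n_epochs, wconfig))
}

# Closed-form one-way ICC of the cohort generator on the raw ratio scale,
# from the log-normal moment identities (age-mean variance included).
generator_icc_oracle <- function(config, curve) {
  ages <- seq(config$age_range_children[1], config$age_range_children[2],
              length.out = 2001)
  mM <- curve_mean(curve, ages, "M")
  mF <- curve_mean(curve, ages, "F")
  p <- config$sex_ratio
  EM <- mean(p * mM + (1 - p) * mF)
  EM2 <- mean(p * mM^2 + (1 - p) * mF^2)
  tau2 <- config$tau^2; rho <- config$rho
  covRL <- EM2 * exp((1 + rho) * tau2) - EM^2 * exp(tau2)
  varR <- EM2 * exp(2 * tau2) - EM^2 * exp(tau2)
  covRL / varR
}
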