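# The cohort and waveform generators: determinism, degenerate limits, and
# agreement of sample moments with the generator's own closed forms.

test_that("sample_cohort is deterministic and respects degenerate correlation", {
  cfg <- cohort_config(n_children = 40, n_adults = 10, seed = 7)
  a <- sample_cohort(cfg)
  b <- sample_cohort(cfg)
  expect_identical(a, b)

  cfg1 <- cohort_config(n_children = 30, n_adults = 0, rho = 1, seed = 3)
  co <- sample_cohort(cfg1)
  pr <- ear_pairs(co, "AC", "true_ratio")
  expect_equal(pr$right, pr$left, tolerance = 1e-12)
})

test_that("generator rejects non-positive variance parameters", {
  expect_error(cohort_config(tau = 0), "variance")
  expect_error(cohort_config(tau = -1), "variance")
})

test_that("cohort moments match the generator's closed forms", {
  cfg <- cohort_config(n_children = 5000, n_adults = 0, seed = 21)
  co <- sample_cohort(cfg)
  ac <- co[co$mode == "AC", ]
  # threshold is negatively related to the amplitude ratio
  expect_lt(stats::cor(ac$true_threshold_dbnhl, ac$true_ratio), 0)
  # one-way ICC of raw right/left ratios vs the moment oracle
  pr <- ear_pairs(co, "AC", "true_ratio")
  icc_hat <- icc(pr$right, pr$left)$estimate
  icc_true <- generator_icc_oracle(cfg, default_curves()$AC)
  expect_lt(abs(icc_hat - icc_true), 0.05)
  # mean ratio at a fixed age matches m(age) * exp(tau^2 / 2)
  cfg6 <- cohort_config(n_children = 5000, n_adults = 0, sex_ratio = 1,
                        age_range_children = c(5.99, 6.01), seed = 22)
  co6 <- sample_cohort(cfg6)
  m6 <- curve_mean(default_curves()$AC, 6, "M") * exp(cfg6$tau^2 / 2)
  samp <- co6$true_ratio[co6$mode == "AC"]
  expect_lt(abs(mean(samp) - m6), 3 * stats::sd(samp) / sqrt(length(samp)))
})

test_that("default maturation curves peak in early childhood, males above females", {
  ages <- seq(0.5, 16, by = 0.01)
  for (md in c("AC", "BC")) {
    cv <- default_curves()[[md]]
    peak_age <- ages[which.max(curve_mean(cv, ages, "M"))]
    expect_gte(peak_age, 4)
    expect_lte(peak_age, 6)
    expect_true(all(curve_mean(cv, ages, "M") > curve_mean(cv, ages, "F")))
  }
})

test_that("latent latencies are ordered and thresholds sit on the 5-dB grid", {
  co <- sample_cohort(cohort_config(n_children = 200, n_adults = 50, seed = 9))
  expect_true(all(co$t_p_ms < co$t_n_ms))
  thr <- co$true_threshold_dbnhl
  ref <- ifelse(co$mode == "BC", 86, 88)
  expect_true(all(is.na(thr) | (thr - ref) %% 5 == 0))
  expect_true(all(co$emg_uv >= 100 & co$emg_uv <= 500))
  # absent responses only in BC at older ages
  ab <- co[co$response_absent, ]
  expect_true(all(ab$mode == "BC"))
  expect_true(all(ab$age_years >= 15))
})

test_that("noiseless epochs reproduce the exact peak-to-peak amplitude", {
  subj <- make_subject_row(true_ratio = 1.8, emg = 250)
  wc0 <- waveform_config(noise_scale = 0)
  tr <- synth_epoch(subj, reference_level_nhl("AC"), wc0)
  expect_equal(max(tr$samples) - min(tr$samples),
               subj$true_ratio * subj$emg_uv, tolerance = 1e-9)
  # far below threshold: pure zero trace
  tr0 <- synth_epoch(subj, subj$true_threshold_dbnhl - 10, wc0)
  expect_true(all(tr0$samples == 0))
  # epoch shorter than the response is refused
  expect_error(synth_epoch(subj, 88, waveform_config(epoch_ms = 15)),
               "epoch")
})

test_that("averaging reduces background noise roughly as 1/sqrt(n)", {
  subj <- make_subject_row(true_ratio = 2, true_threshold = 78)
  wc <- waveform_config()
  set.seed(31)
  below <- subj$true_threshold_dbnhl - 10  # noise only
  one <- vempnorm:::.synth_average(subj, below, 1L, wc)
  avg <- vempnorm:::.synth_average(subj, below, 25L, wc)
  r <- stats::sd(one$samples) / stats::sd(avg$samples)
  expect_gt(r, 5 * 0.8)
  expect_lt(r, 5 * 1.2)
})

test_that("sessions are deterministic and stop two steps below threshold", {
  rows <- rbind(make_subject_row(ear = "R"), make_subject_row(ear = "L"))
  s1 <- synth_session(rows, waveform_config(), seed = 5)
  s2 <- synth_session(rows, waveform_config(), seed = 5)
  expect_identical(lapply(s1$traces, `[[`, "samples"),
                   lapply(s2$traces, `[[`, "samples"))
  lv <- vapply(s1$traces, function(tr) tr$meta$level_dbnhl, numeric(1))
  expect_equal(min(lv), rows$true_threshold_dbnhl[1] - 10)
  expect_equal(max(lv), reference_level_nhl("AC"))
  # absent-response ear gets noise-only traces up to the ceiling
  ab <- make_subject_row(mode = "BC", absent = TRUE, age = 15.5,
                         true_threshold = NA)
  sa <- synth_session(ab, waveform_config(), seed = 6)
  lva <- vapply(sa$traces, function(tr) tr$meta$level_dbnhl, numeric(1))
  expect_equal(max(lva), reference_level_nhl("BC") + 10)
})
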