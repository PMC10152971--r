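# Interaural asymmetry, its empirical limits, ICC, and descriptive tables.

test_that("interaural asymmetry identities hold exactly", {
  expect_equal(interaural_asymmetry(2, 2), 0)
  expect_equal(interaural_asymmetry(1, 0), 100)
  expect_equal(interaural_asymmetry(0, 1), -100)
  expect_equal(interaural_asymmetry(1.5, 1.0), 20)
  # antisymmetry under ear swap
  set.seed(71)
  r <- runif(50, 0.1, 4); l <- runif(50, 0.1, 4)
  expect_equal(interaural_asymmetry(r, l), -interaural_asymmetry(l, r))
  expect_true(all(abs(interaural_asymmetry(r, l)) <= 100))
  expect_error(interaural_asymmetry(0, 0), "> 0")
})

test_that("asymmetry limits are empirical central percentiles", {
  a <- c(-30, -10, -5, 0, 0, 5, 10, 12, 20, 25, rep(0, 12))
  lim <- asymmetry_limits(a, coverage = 90)
  expect_equal(lim$lower, unname(quantile(a, 0.05, type = 7)))
  expect_equal(lim$upper, unname(quantile(a, 0.95, type = 7)))
  # degenerate: identical ears
  lim0 <- asymmetry_limits(rep(0, 25))
  expect_equal(c(lim0$lower, lim0$upper), c(0, 0))
  # near-invariance under duplication (type-7 interpolation positions shift
  # by O(1/n))
  lim2 <- asymmetry_limits(c(a, a))
  expect_equal(c(lim2$lower, lim2$upper), c(lim$lower, lim$upper),
               tolerance = 0.5)
  # narrower coverage gives a narrower band
  lim80 <- asymmetry_limits(a, coverage = 80)
  expect_gte(lim80$lower, lim$lower)
  expect_lte(lim80$upper, lim$upper)
  expect_error(asymmetry_limits(a[1:5]), "at least")
})

test_that("exchangeable ears give limits symmetric about zero", {
  co <- sample_cohort(cohort_config(n_children = 2000, n_adults = 0,
                                    seed = 72))
  pr <- ear_pairs(co, "AC", "true_ratio")
  lim <- asymmetry_limits(pr$asymmetry_pct)
  expect_lt(abs(lim$lower + lim$upper), 2.5)
  expect_lt(lim$lower, 0)
  expect_gt(lim$upper, 0)
})

test_that("ICC is exact on duplicated ears and null for independent ones", {
  set.seed(73)
  x <- rexp(100) + 0.5
  expect_equal(icc(x, x)$estimate, 1)
  a <- rnorm(5000); b <- rnorm(5000)
  expect_lt(abs(icc(a, b)$estimate), 0.05)
  # invariance to a common affine rescaling
  r <- rnorm(200, 10); l <- r + rnorm(200, 0, 0.5)
  expect_equal(icc(2 * r + 3, 2 * l + 3)$estimate, icc(r, l)$estimate,
               tolerance = 1e-12)
  expect_error(icc(rep(1, 50), rep(1, 50)), "variance")
  expect_error(icc(1:5, 1:5), "pairs")
})

test_that("ICC recovers the generator's interaural correlation at fixed age", {
  cfg <- cohort_config(n_children = 2000, n_adults = 0,
                       age_range_children = c(5.9, 6.1), seed = 74)
  co <- sample_cohort(cfg)
  pr <- ear_pairs(co, "AC", "true_ratio")
  est <- icc(pr$right, pr$left)$estimate
  expect_lt(abs(est - cfg$rho), 0.05)
  # two-way forms are available and close to the one-way value here
  est2 <- icc(pr$right, pr$left, type = "consistency")$estimate
  expect_lt(abs(est2 - est), 0.02)
})

test_that("descriptive tables follow the age-band layout", {
  co <- sample_cohort(cohort_config(n_children = 150, n_adults = 30,
                                    seed = 75))
  co$amplitude_ratio <- co$true_ratio
  co$p_latency_ms <- co$t_p_ms
  co$n_latency_ms <- co$t_n_ms
  co$threshold_dbnhl <- co$true_threshold_dbnhl
  tab <- descriptive_table(co)
  expect_true(all(c("age_band", "mode", "n_ears", "ratio_mean",
                    "thr_median") %in% names(tab)))
  expect_true(all(tab$n_ears > 0))
  # single-record band: mean = median = min = max
  one <- co[1, ]
  t1 <- descriptive_table(one, age_breaks = c(0, 16))
  expect_equal(t1$ratio_mean, t1$ratio_median)
  expect_equal(t1$ratio_min, t1$ratio_max)
  # invariance to record order
  sh <- sample(nrow(co))
  expect_equal(descriptive_table(co[sh, ]), descriptive_table(co))
})
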