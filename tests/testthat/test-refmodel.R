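# Box-Cox transform, fractional polynomials, and the Royston-Wright
# reference-interval fit: closed-form limits, parameter recovery, centile
# behavior and classification.

test_that("boxcox branches and round trip behave", {
  expect_equal(boxcox(3, 1), 2)
  expect_equal(boxcox(1, 0), 0)
  expect_equal(boxcox(4, 0.5), 2)
  # continuity at lambda = 0
  expect_equal(boxcox(2.5, 1e-9), log(2.5), tolerance = 1e-6)
  expect_error(boxcox(-1, 0.5), "> 0")
  for (lam in seq(-2, 2, by = 0.25)) {
    y <- c(0.05, 0.3, 1, 2.7, 8)
    expect_equal(inv_boxcox(boxcox(y, lam), lam), y, tolerance = 1e-10)
  }
  expect_warning(inv_boxcox(-5, 0.5), "clamping")
})

test_that("fractional-polynomial designs honor the power conventions", {
  age <- c(1, 2, 4, 8)
  X <- fp_design(age, c(0, 2))
  expect_equal(X[, 2], log(age))
  expect_equal(X[, 3], age^2)
  Xr <- fp_design(age, c(1, 1))  # repeated power
  expect_equal(Xr[, 2], age)
  expect_equal(Xr[, 3], age * log(age))
  expect_equal(fp_eval(age, numeric(0), 3.5), rep(3.5, 4))
  expect_error(fp_design(c(-1, 2), 1))
  expect_error(fp_design(age, c(1, 2, 3)), "degree")
})

test_that("a Gaussian constant-mean sample is recovered with lambda fixed at 1", {
  set.seed(61)
  age <- runif(300, 1, 15)
  y <- rnorm(300, 5, 0.7)
  m <- fit_ref_model(age, y, lambda = 1)
  # closed test should retain the null (constant) mean model
  expect_length(m$mu$powers, 0)
  expect_equal(ref_mu(m, 8) + 1, 5, tolerance = 0.15)       # inv bc at lambda 1
  expect_equal(ref_sigma(m, 8), 0.7, tolerance = 0.1)
  expect_lt(abs(m$diagnostics$z_mean), 2 / sqrt(300))
  expect_lt(abs(m$diagnostics$z_sd - 1), 2 / sqrt(300))
  # z_score closed forms
  ratio_at_mu <- inv_boxcox(ref_mu(m, 8), 1)
  expect_equal(z_score(m, 8, ratio_at_mu), 0, tolerance = 1e-9)
  ratio_1sd <- inv_boxcox(ref_mu(m, 8) + ref_sigma(m, 8), 1)
  expect_equal(z_score(m, 8, ratio_1sd), 1, tolerance = 1e-9)
})

test_that("log-normal age-varying data are recovered on the lambda grid", {
  set.seed(62)
  n <- 500
  age <- runif(n, 0.6, 15.5)
  mu_t <- 0.3 + 0.45 * log(age)
  y <- exp(mu_t + rnorm(n, 0, 0.3))
  m <- fit_ref_model(age, y)
  expect_lt(abs(m$lambda), 0.3)
  ages_g <- seq(1, 15, length.out = 50)
  med_hat <- centile(m, ages_g, 50)
  med_true <- exp(0.3 + 0.45 * log(ages_g))
  expect_lt(sqrt(mean(((med_hat - med_true) / med_true)^2)), 0.05)
  sd_hat <- ref_sigma(m, ages_g)
  if (abs(m$lambda) < 1e-9)
    expect_lt(sqrt(mean((sd_hat / 0.3 - 1)^2)), 0.1)
  expect_true(gof_check(m)$ok)
})

test_that("lambda grid-profile matches brute-force joint optimization", {
  set.seed(63)
  age <- runif(50, 1, 15)
  y <- exp(0.3 + 0.4 * log(age) + rnorm(50, 0, 0.25))
  m <- fit_ref_model(age, y, mu_powers = 1, sigma_powers = numeric(0))
  nll <- function(par) {
    B <- boxcox(y, par[1])
    mu <- par[2] + par[3] * age
    s <- exp(par[4])
    -(-length(y) * log(s) - 0.5 * sum(((B - mu) / s)^2) +
        (par[1] - 1) * sum(log(y)))
  }
  o <- stats::optim(c(0.5, 0, 0, 0), nll, method = "BFGS")
  expect_lte(abs(m$lambda - o$par[1]), 0.05 + 1e-9)
})

test_that("centiles are monotone in p, calibrated, and refuse out-of-domain ages", {
  set.seed(64)
  age <- runif(5000, 0.6, 15.5)
  y <- exp(0.5 + 0.3 * log(age) + rnorm(5000, 0, 0.35))
  m <- fit_ref_model(age, y)
  ps <- c(1, 5, 10, 25, 50, 75, 90, 95, 99)
  cs <- vapply(ps, function(p) centile(m, 8, p), numeric(1))
  expect_true(all(diff(cs) > 0))
  # empirical coverage of the 95th centile
  expect_equal(mean(y <= centile(m, age, 95)), 0.95, tolerance = 0.01)
  expect_error(centile(m, 20, 95), "domain")
  expect_error(z_score(m, 0.2, 1), "domain")
  expect_error(centile(m, 8, 0), "p >")
})

test_that("fitting is invariant to record order and to dataset duplication", {
  set.seed(65)
  age <- runif(200, 0.6, 15.5)
  y <- exp(0.4 + 0.3 * log(age) + rnorm(200, 0, 0.3))
  m1 <- fit_ref_model(age, y)
  sh <- sample(200)
  m2 <- fit_ref_model(age[sh], y[sh])
  expect_equal(m1$lambda, m2$lambda)
  expect_equal(m1$mu$beta, m2$mu$beta, tolerance = 1e-8)
  # duplicating the whole data set: same lambda (profile doubles pointwise);
  # the centile curves agree over the central ages, up to the wiggle the
  # sample-size-dependent polynomial selection is allowed near the edges
  m3 <- fit_ref_model(c(age, age), c(y, y), min_n = 30)
  expect_equal(m1$lambda, m3$lambda)
  ages_g <- seq(2, 13, by = 0.5)
  expect_lt(max(abs(centile(m3, ages_g, 50) / centile(m1, ages_g, 50) - 1)),
            0.06)
})

test_that("degenerate inputs are refused with informative errors", {
  expect_error(fit_ref_model(runif(10, 1, 15), rexp(10) + 0.1), "at least")
  expect_error(fit_ref_model(rep(8, 50), rexp(50) + 0.1), "degenerate")
  expect_error(fit_ref_model(runif(50, 1, 15), c(rep(-1, 50))), "> 0")
})

test_that("normative tables are monotone across percentiles and deterministic", {
  set.seed(66)
  mk <- function(mult) {
    age <- runif(150, 0.6, 15.5)
    y <- mult * exp(0.3 + 0.3 * log(age) + rnorm(150, 0, 0.3))
    fit_ref_model(age, y)
  }
  models <- list(M = mk(1.15), F = mk(1))
  tab <- make_normative_table(models)
  expect_equal(nrow(tab), 30)
  expect_true(all(tab$p5 <= tab$p10 & tab$p10 <= tab$p90 &
                    tab$p90 <= tab$p95))
  expect_true(all(tab$p10 <= tab$mean & tab$mean <= tab$p90))
  expect_true(all(tab$p5 > 0))
  expect_identical(tab, make_normative_table(models))
})

test_that("classification flags match the normative criteria", {
  set.seed(67)
  age <- runif(200, 0.6, 15.5)
  y <- exp(0.4 + 0.3 * log(age) + rnorm(200, 0, 0.3))
  m <- fit_ref_model(age, y)
  med <- centile(m, 8, 50)
  cl <- classify_subject(m, 8, ratio_right = med, ratio_left = med,
                         threshold_right = 81, threshold_left = 81,
                         p_latency_right = 13, p_latency_left = 13.2)
  expect_true(all(cl$flags))
  expect_true(cl$overall)
  expect_equal(cl$asymmetry_pct, 0)
  # a ratio below the 5th centile fails the band check
  low <- centile(m, 8, 5) * 0.9
  cl2 <- classify_subject(m, 8, ratio_right = low, ratio_left = med,
                          threshold_right = 81, threshold_left = 81,
                          p_latency_right = 13, p_latency_left = 13)
  expect_false(cl2$flags[["ratio_in_band"]])
  expect_false(cl2$overall)
  # missing threshold yields an indeterminate flag, not a failure
  cl3 <- classify_subject(m, 8, ratio_right = med, ratio_left = med)
  expect_true(is.na(cl3$flags[["threshold_ok"]]))
  expect_true(is.na(cl3$flags[["p_latency_ok"]]))
  expect_true(cl3$overall)  # available flags are all ok
  # interaural threshold difference beyond 5 dB fails
  cl4 <- classify_subject(m, 8, ratio_right = med, ratio_left = med,
                          threshold_right = 73, threshold_left = 83)
  expect_false(cl4$flags[["threshold_asym_ok"]])
})

test_that("stratified fits share lambda across sexes within a mode", {
  set.seed(68)
  mk_records <- function(mode) {
    n <- 160
    age <- runif(n, 0.6, 15.5)
    sex <- rep(c("M", "F"), n / 2)
    mult <- ifelse(sex == "M", 1.15, 0.95)
    data.frame(age_years = age, sex = sex, mode = mode,
               amplitude_ratio = mult *
                 exp(0.3 + 0.3 * log(age) + rnorm(n, 0, 0.3)))
  }
  rec <- rbind(mk_records("AC"), mk_records("BC"))
  fits <- fit_reference_models(rec)
  expect_named(fits, c("AC", "BC"))
  for (md in c("AC", "BC")) {
    expect_equal(fits[[md]]$M$lambda, fits[[md]]$F$lambda)
    expect_s3_class(fits[[md]]$M, "vemp_refmodel")
  }
})
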