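# Age- and sex-specific reference intervals for the c-VEMP amplitude ratio,
# following the Royston-Wright approach used for growth-type references:
#
#   1. a Box-Cox transform of the amplitude ratio, B = bc(y; lambda), removes
#      the right skew;
#   2. the mean of B is modeled as a low-order fractional polynomial of age,
#      mu(age);
#   3. the SD of B is modeled by regressing sqrt(pi/2) * |residual| (an
#      unbiased estimator of a Gaussian SD) on a fractional polynomial of
#      age, sigma(age);
#   4. Z = (B - mu(age)) / sigma(age) must be standard normal under a
#      correct model, which is checked (Shapiro-Wilk; residual trends).
#
# lambda is chosen by profiling a Gaussian log-likelihood (including the
# Box-Cox Jacobian) over a grid; mean and SD curves are refitted at the
# selected lambda with closed-test fractional-polynomial selection and one
# weighted-least-squares reweighting pass. The SD curve is always rescaled
# to its maximum-likelihood scale (mean(Z^2) = 1 on the training data), both
# inside the profile and in the final fit. Centiles on the measurement scale
# are inverse-transformed Gaussian quantiles.

.rw_core <- function(B, preps_mu, preps_sig, logy_sum, lambda,
                     mu_idx = NULL, sig_idx = NULL, alpha = 0.05,
                     sigma_floor = 1e-3, select = c("rss", "closed"),
                     reweight = TRUE) {
  select <- match.arg(select)
  n <- length(B)
  pick <- function(preps, y, forced) {
    if (!is.null(forced)) return(forced)
    if (select == "rss") {
      rss <- vapply(preps, .fp_rss, numeric(1), y = y)
      which.min(rss)
    } else .fp_select(preps, y, alpha = alpha)
  }
  i_mu <- pick(preps_mu, B, mu_idx)
  mu_fit <- .fp_fit(preps_mu[[i_mu]], B)
  resid <- B - mu_fit$fitted

  fit_sigma <- function(r, forced) {
    a <- sqrt(pi / 2) * abs(r)
    i_sig <- pick(preps_sig, a, forced)
    sfit <- .fp_fit(preps_sig[[i_sig]], a)
    list(idx = i_sig, fit = sfit)
  }
  s <- fit_sigma(resid, sig_idx)
  sigma <- pmax(s$fit$fitted, sigma_floor)

  if (reweight) {
    # one weighted refit of the mean with weights 1/sigma^2, then
    # re-estimate sigma from the new residuals (same selected bases)
    Xmu <- preps_mu[[i_mu]]$X
    w <- 1 / sigma^2
    wfit <- stats::lm.wfit(Xmu, B, w)
    beta <- wfit$coefficients
    beta[is.na(beta)] <- 0
    mu_fit <- list(powers = preps_mu[[i_mu]]$powers, beta = unname(beta),
                   fitted = drop(Xmu %*% beta))
    resid <- B - mu_fit$fitted
    s <- fit_sigma(resid, s$idx)
    sigma <- pmax(s$fit$fitted, sigma_floor)
  }

  # maximum-likelihood rescale of the SD curve: with the shape fixed, the
  # profile likelihood is maximized at mean((resid/sigma)^2) = 1
  scl <- sqrt(mean((resid / sigma)^2))
  if (is.finite(scl) && scl > 0) {
    s$fit$beta <- s$fit$beta * scl
    sigma <- pmax(sigma * scl, sigma_floor)
  }

  z <- resid / sigma
  ll <- -n / 2 * log(2 * pi) - sum(log(sigma)) - 0.5 * sum(z^2) +
    (lambda - 1) * logy_sum
  list(mu = mu_fit, sig = s$fit, sigma = sigma, resid = resid, z = z,
       loglik = ll, mu_idx = i_mu, sig_idx = s$idx)
}

# Profile log-likelihood over a lambda grid for one stratum. Selection inside
# the profile is by minimum RSS (i.e. maximum likelihood over the candidate
# class); parsimony pruning is applied only at the selected lambda.
.rw_profile <- function(age, y, lambda_grid, preps_mu, preps_sig, shift = 0,
                        sigma_floor = 1e-3, mu_idx = NULL, sig_idx = NULL) {
  logy_sum <- sum(log(y + shift))
  vapply(lambda_grid, function(l) {
    B <- boxcox(y, l, shift)
    .rw_core(B, preps_mu, preps_sig, logy_sum, l, select = "rss",
             mu_idx = mu_idx, sig_idx = sig_idx,
             sigma_floor = sigma_floor, reweight = FALSE)$loglik
  }, numeric(1))
}

#' Fit an age-specific reference-interval model for the amplitude ratio
#'
#' Fits the Box-Cox / fractional-polynomial reference model described above
#' to one stratum (one sex within one conduction mode).
#'
#' @param age Ages in years (> 0).
#' @param ratio Amplitude ratios (PN/EMG, > 0), same length as `age`.
#' @param stratum Optional label, e.g. `list(sex = "M", mode = "AC")`.
#' @param lambda If supplied, the Box-Cox power is fixed at this value
#'   instead of being profiled (used e.g. to share lambda across strata).
#' @param shift Box-Cox location shift (default 0; ratios are positive).
#' @param lambda_grid Grid over which lambda is profiled.
#' @param mu_degree,sigma_degree Maximum fractional-polynomial degree for the
#'   mean and SD curves (2 and 1 by default).
#' @param mu_powers,sigma_powers Optional forced power vectors; bypass model
#'   selection (useful for simulation oracles).
#' @param alpha Significance level of the closed-test polynomial selection.
#' @param sigma_floor Positivity floor for the fitted SD.
#' @param age_domain Fitted age domain in years; records outside it are
#'   dropped before fitting (the default excludes infants under 6 months)
#'   and predictions outside it are refused.
#' @param min_n Minimum number of records required.
#' @return Object of class `vemp_refmodel` with components `lambda`, `shift`,
#'   `mu` and `sigma` (each `list(powers, beta)`), `age_domain`, `stratum`,
#'   `diagnostics` (normality p-value, Z moments, residual-age correlations)
#'   and `profile` (the lambda grid and its profile log-likelihood).
#' @export
fit_ref_model <- function(age, ratio, stratum = NULL, lambda = NULL,
                          shift = 0, lambda_grid = seq(-2, 2, by = 0.05),
                          mu_degree = 2, sigma_degree = 1,
                          mu_powers = NULL, sigma_powers = NULL,
                          alpha = 0.05, sigma_floor = 1e-3,
                          age_domain = c(0.5, 16), min_n = 30L) {
  stopifnot(length(age) == length(ratio))
  keep <- is.finite(age) & is.finite(ratio)
  age <- age[keep]; ratio <- ratio[keep]
  if (any(ratio <= 0)) stop("amplitude ratios must be > 0", call. = FALSE)
  inside <- age >= age_domain[1] & age <= age_domain[2]
  if (!all(inside)) {
    age <- age[inside]; ratio <- ratio[inside]
  }
  n <- length(age)
  if (n < min_n)
    stop(sprintf("need at least %d records in the stratum (have %d)",
                 min_n, n), call. = FALSE)
  if (length(unique(age)) < 3L)
    stop("degenerate age spread: need at least 3 distinct ages",
         call. = FALSE)

  force_idx <- function(preps, powers) {
    if (is.null(powers)) return(NULL)
    for (i in seq_along(preps))
      if (identical(sort(powers), sort(preps[[i]]$powers)) ||
          (length(powers) == 0L && length(preps[[i]]$powers) == 0L))
        return(i)
    stop("requested powers are not in the candidate set", call. = FALSE)
  }

  preps_mu <- .fp_prepare(age, mu_degree)
  preps_sig <- .fp_prepare(age, sigma_degree)
  mu_idx <- force_idx(preps_mu, mu_powers)
  sig_idx <- force_idx(preps_sig, sigma_powers)

  profile <- NULL
  if (is.null(lambda)) {
    ll <- .rw_profile(age, ratio, lambda_grid, preps_mu, preps_sig,
                      shift = shift, sigma_floor = sigma_floor,
                      mu_idx = mu_idx, sig_idx = sig_idx)
    lambda <- lambda_grid[which.max(ll)]
    profile <- list(lambda = lambda_grid, loglik = ll)
  }

  logy_sum <- sum(log(ratio + shift))
  B <- boxcox(ratio, lambda, shift)
  fit <- .rw_core(B, preps_mu, preps_sig, logy_sum, lambda,
                  mu_idx = mu_idx, sig_idx = sig_idx, alpha = alpha,
                  sigma_floor = sigma_floor, select = "closed",
                  reweight = TRUE)

  # guard against a fitted SD going non-positive anywhere on the domain
  grid <- seq(age_domain[1], age_domain[2], length.out = 201L)
  sig_grid <- fp_eval(grid, fit$sig$powers, fit$sig$beta)
  if (any(sig_grid <= 0)) {
    warning("fitted SD curve non-positive on the age domain; ",
            "falling back to a constant SD", call. = FALSE)
    const <- sqrt(mean(fit$resid^2))
    fit$sig <- list(powers = numeric(0), beta = const,
                    fitted = rep(const, n))
    fit$sigma <- pmax(fit$sig$fitted, sigma_floor)
    fit$z <- fit$resid / fit$sigma
  }

  z <- fit$z
  sw <- if (n >= 3 && n <= 5000) stats::shapiro.test(z)$p.value else NA_real_
  diagnostics <- list(
    n = n, normality_p = sw, z_mean = mean(z), z_sd = stats::sd(z),
    cor_z_age = stats::cor(z, age), cor_absz_age = stats::cor(abs(z), age),
    loglik = fit$loglik
  )

  structure(
    list(lambda = lambda, shift = shift,
         mu = list(powers = fit$mu$powers, beta = fit$mu$beta),
         sigma = list(powers = fit$sig$powers, beta = fit$sig$beta),
         age_domain = age_domain, stratum = stratum,
         diagnostics = diagnostics, profile = profile),
    class = "vemp_refmodel"
  )
}

.check_model_age <- function(model, age) {
  if (any(age < model$age_domain[1] | age > model$age_domain[2]))
    stop(sprintf("age outside the fitted domain [%g, %g] years",
                 model$age_domain[1], model$age_domain[2]), call. = FALSE)
  age
}

#' Modeled mean and SD of the transformed ratio at given ages
#'
#' @param model A `vemp_refmodel`.
#' @param age Ages in years within the fitted domain.
#' @return Numeric vector.
#' @export
ref_mu <- function(model, age) {
  .check_model_age(model, age)
  fp_eval(age, model$mu$powers, model$mu$beta)
}

#' @rdname ref_mu
#' @export
ref_sigma <- function(model, age) {
  .check_model_age(model, age)
  pmax(fp_eval(age, model$sigma$powers, model$sigma$beta), 1e-10)
}

#' Z-score of an amplitude ratio under a fitted reference model
#'
#' `Z = (B - mu(age)) / sigma(age)` with `B` the Box-Cox transformed ratio;
#' standard normal for measurements drawn from the reference population.
#'
#' @inheritParams ref_mu
#' @param ratio Amplitude ratio(s) (> 0).
#' @return Z-score(s).
#' @export
z_score <- function(model, age, ratio) {
  .check_model_age(model, age)
  if (any(ratio <= 0, na.rm = TRUE))
    stop("amplitude ratios must be > 0", call. = FALSE)
  (boxcox(ratio, model$lambda, model$shift) - ref_mu(model, age)) /
    ref_sigma(model, age)
}

#' Centile curve of the amplitude ratio at a given age
#'
#' Inverse Box-Cox of `mu(age) + z_p * sigma(age)` where `z_p` is the
#' standard normal quantile of `p`.
#'
#' @inheritParams ref_mu
#' @param p Percentile in (0, 100), scalar.
#' @return Ratio value(s) on the measurement scale, one per age.
#' @export
centile <- function(model, age, p) {
  stopifnot(length(p) == 1L, p > 0, p < 100)
  .check_model_age(model, age)
  b <- ref_mu(model, age) + stats::qnorm(p / 100) * ref_sigma(model, age)
  inv_boxcox(b, model$lambda, model$shift)
}

#' Goodness-of-fit check of a reference model
#'
#' A fitted model is adequate when the training Z-scores are compatible with
#' a standard normal distribution (Shapiro-Wilk) and show no residual age
#' trend in location or scale.
#'
#' @param model A `vemp_refmodel`.
#' @param alpha Normality-test level (default 0.05).
#' @param max_trend Maximum tolerated |correlation| of Z (and |Z|) with age.
#' @return List with logical `normal_ok`, `location_trend_ok`,
#'   `scale_trend_ok`, and overall `ok`.
#' @export
gof_check <- function(model, alpha = 0.05, max_trend = 0.1) {
  d <- model$diagnostics
  normal_ok <- !is.na(d$normality_p) && d$normality_p >= alpha
  loc_ok <- abs(d$cor_z_age) < max_trend
  sc_ok <- abs(d$cor_absz_age) < max_trend
  list(normal_ok = normal_ok, location_trend_ok = loc_ok,
       scale_trend_ok = sc_ok, ok = normal_ok && loc_ok && sc_ok)
}

#' @export
print.vemp_refmodel <- function(x, ...) {
  s <- x$stratum
  lab <- if (is.null(s)) "" else
    paste0(" [", paste(unlist(s), collapse = " / "), "]")
  cat(sprintf("<vemp_refmodel>%s n = %d\n", lab, x$diagnostics$n))
  cat(sprintf("  Box-Cox lambda = %.2f (shift %.2f)\n", x$lambda, x$shift))
  fmt_fp <- function(f) if (length(f$powers) == 0) "constant" else
    paste0("FP(", paste(f$powers, collapse = ", "), ")")
  cat(sprintf("  mu(age): %s; sigma(age): %s\n",
              fmt_fp(x$mu), fmt_fp(x$sigma)))
  cat(sprintf("  Z: mean %.3f, sd %.3f; normality p = %.3f\n",
              x$diagnostics$z_mean, x$diagnostics$z_sd,
              x$diagnostics$normality_p))
  invisible(x)
}

#' Fit reference models for all sex strata of each conduction mode
#'
#' Fits one model per sex within each mode. The Box-Cox lambda is shared
#' across the two sexes of a mode (profiled on the summed profile
#' log-likelihood) for stability at normative-study sample sizes; set
#' `share_lambda = FALSE` for fully independent fits.
#'
#' @param records Data frame with columns `age_years`, `sex` (`"M"`/`"F"`),
#'   `mode` (`"AC"`/`"BC"`) and `amplitude_ratio`; typically a feature table
#'   (one row per ear, ears pooled as independent observations).
#' @param modes Modes to fit.
#' @param share_lambda Share lambda across sexes within a mode.
#' @param ... Passed to [fit_ref_model()].
#' @return Nested list `models[[mode]][[sex]]` of `vemp_refmodel` objects.
#' @export
fit_reference_models <- function(records, modes = c("AC", "BC"),
                                 share_lambda = TRUE, ...) {
  stopifnot(all(c("age_years", "sex", "mode", "amplitude_ratio") %in%
                  names(records)))
  out <- list()
  for (md in modes) {
    sub <- records[records$mode == md & is.finite(records$amplitude_ratio), ]
    fits <- list()
    if (share_lambda) {
      dots <- list(...)
      grid <- if (!is.null(dots$lambda_grid)) dots$lambda_grid else
        seq(-2, 2, by = 0.05)
      tot <- 0
      for (sx in c("M", "F")) {
        d <- sub[sub$sex == sx, ]
        m_tmp <- tryCatch(
          do.call(fit_ref_model,
                  c(list(age = d$age_years, ratio = d$amplitude_ratio),
                    dots)),
          error = function(e) stop("stratum ", sx, "/", md, ": ",
                                   conditionMessage(e), call. = FALSE))
        tot <- tot + m_tmp$profile$loglik
      }
      lam <- grid[which.max(tot)]
      for (sx in c("M", "F")) {
        d <- sub[sub$sex == sx, ]
        fits[[sx]] <- fit_ref_model(d$age_years, d$amplitude_ratio,
                                    stratum = list(sex = sx, mode = md),
                                    lambda = lam, ...)
      }
    } else {
      for (sx in c("M", "F")) {
        d <- sub[sub$sex == sx, ]
        fits[[sx]] <- fit_ref_model(d$age_years, d$amplitude_ratio,
                                    stratum = list(sex = sx, mode = md), ...)
      }
    }
    out[[md]] <- fits
  }
  out
}

#' Normative table of amplitude-ratio centiles by age and sex
#'
#' Lays out the fitted 5th/10th percentile, mean, and 90th/95th percentile of
#' the amplitude ratio at integer ages for both sexes ("mean" is the
#' back-transformed mu(age), i.e. the modeled median-type center).
#'
#' @param models List with components `M` and `F`, each a `vemp_refmodel`
#'   (both strata of one conduction mode).
#' @param ages Integer ages (years), default 1 to 15.
#' @return Data frame with columns `sex`, `age_years`, `p5`, `p10`, `mean`,
#'   `p90`, `p95`.
#' @export
make_normative_table <- function(models, ages = 1:15) {
  stopifnot(all(c("M", "F") %in% names(models)))
  rows <- lapply(c("M", "F"), function(sx) {
    m <- models[[sx]]
    data.frame(
      sex = sx, age_years = ages,
      p5 = centile(m, ages, 5),
      p10 = centile(m, ages, 10),
      mean = inv_boxcox(ref_mu(m, ages), m$lambda, m$shift),
      p90 = centile(m, ages, 90),
      p95 = centile(m, ages, 95)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a subject's measurements against the normative criteria
#'
#' Applies the normality criteria for children: amplitude ratio of each ear
#' within the age- and sex-specific 90% reference band (5th-95th centile);
#' interaural amplitude-ratio asymmetry below the configured limit; threshold
#' at or below the cutoff with an interaural threshold difference of at most
#' 5 dB; P-wave latency within the normal range. Criteria whose inputs are
#' missing are reported as `NA` (indeterminate), not as failures.
#'
#' @param model `vemp_refmodel` for the subject's sex and the tested mode.
#' @param age Age in years, within the model's domain.
#' @param ratio_right,ratio_left Amplitude ratios per ear (`NA` if absent).
#' @param threshold_right,threshold_left Thresholds in dB nHL (`NA` if
#'   absent/not measured).
#' @param p_latency_right,p_latency_left P-wave latencies in ms.
#' @param asym_limit Asymmetry limit in percent (default 35; the empirical
#'   whole-population limit 32 can be configured instead).
#' @param threshold_max Threshold cutoff in dB nHL (default 85, i.e. about
#'   95 dB HL).
#' @param threshold_diff_max Maximum interaural threshold difference in dB.
#' @param p_latency_range Normal P-latency range in ms.
#' @return Object of class `vemp_classification`: per-ear `z` and `centile`,
#'   the asymmetry, logical `flags`, and `overall` (conjunction of the
#'   available flags).
#' @export
classify_subject <- function(model, age,
                             ratio_right = NA, ratio_left = NA,
                             threshold_right = NA, threshold_left = NA,
                             p_latency_right = NA, p_latency_left = NA,
                             asym_limit = 35, threshold_max = 85,
                             threshold_diff_max = 5,
                             p_latency_range = c(12.6, 13.8)) {
  .check_model_age(model, age)
  ratios <- c(right = ratio_right, left = ratio_left)
  z <- cent <- c(right = NA_real_, left = NA_real_)
  band <- c(centile(model, age, 5), centile(model, age, 95))
  for (ear in c("right", "left")) {
    if (is.finite(ratios[[ear]]) && ratios[[ear]] > 0) {
      z[[ear]] <- z_score(model, age, ratios[[ear]])
      cent[[ear]] <- 100 * stats::pnorm(z[[ear]])
    }
  }

  in_band <- ifelse(is.finite(ratios),
                    ratios >= band[1] & ratios <= band[2], NA)
  ratio_ok <- if (all(is.na(in_band))) NA else all(in_band[!is.na(in_band)])

  asym <- if (all(is.finite(ratios)) && sum(ratios) > 0)
    interaural_asymmetry(ratios[["right"]], ratios[["left"]]) else NA_real_
  asym_ok <- if (is.na(asym)) NA else abs(asym) < asym_limit

  thr <- c(threshold_right, threshold_left)
  thr_ok <- if (all(is.na(thr))) NA else all(thr[is.finite(thr)] <= threshold_max)
  thr_asym_ok <- if (all(is.finite(thr)))
    abs(thr[1] - thr[2]) <= threshold_diff_max else NA

  pl <- c(p_latency_right, p_latency_left)
  pl_ok <- if (all(is.na(pl))) NA else
    all(pl[is.finite(pl)] >= p_latency_range[1] &
          pl[is.finite(pl)] <= p_latency_range[2])

  flags <- c(ratio_in_band = ratio_ok, asymmetry_ok = asym_ok,
             threshold_ok = thr_ok, threshold_asym_ok = thr_asym_ok,
             p_latency_ok = pl_ok)
  avail <- flags[!is.na(flags)]
  overall <- if (length(avail) == 0L) NA else all(avail)

  structure(
    list(z = z, centile = cent, asymmetry_pct = asym,
         reference_band = band, flags = flags, overall = overall),
    class = "vemp_classification"
  )
}

#' @export
print.vemp_classification <- function(x, ...) {
  cat("<vemp_classification>\n")
  cat(sprintf("  Z right/left: %.2f / %.2f (centiles %.1f / %.1f)\n",
              x$z[["right"]], x$z[["left"]],
              x$centile[["right"]], x$centile[["left"]]))
  cat(sprintf("  asymmetry: %.1f%%\n", x$asymmetry_pct))
  for (nm in names(x$flags))
    cat(sprintf("  %-18s %s\n", nm,
                ifelse(is.na(x$flags[[nm]]), "indeterminate",
                       ifelse(x$flags[[nm]], "ok", "ABNORMAL"))))
  cat(sprintf("  overall: %s\n",
              ifelse(is.na(x$overall), "indeterminate",
                     ifelse(x$overall, "within normal limits", "ABNORMAL"))))
  invisible(x)
}
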