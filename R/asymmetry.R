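# Cohort-level statistics: interaural relative asymmetry of the amplitude
# ratio with empirical reference limits, intraclass correlation for
# right-left ear agreement, and descriptive tables by age band.

#' Interaural relative asymmetry
#'
#' `100 * (R - L) / (R + L)` in percent: 0 for symmetric ears, +100/-100
#' when only one ear responds; antisymmetric under ear swap.
#'
#' @param right,left Amplitude ratios (or other nonnegative measures) of the
#'   right and left ear.
#' @return Asymmetry in percent, in `[-100, 100]` for nonnegative inputs.
#' @examples
#' interaural_asymmetry(1.5, 1.0) # 20
#' @export
interaural_asymmetry <- function(right, left) {
  stopifnot(length(right) == length(left))
  s <- right + left
  if (any(is.finite(s) & s <= 0))
    stop("right + left must be > 0", call. = FALSE)
  100 * (right - left) / s
}

#' Empirical reference limits of the interaural asymmetry
#'
#' Central-coverage percentile band of the asymmetry distribution: for the
#' conventional 90% band, the 5th and 95th empirical percentiles. Quantiles
#' use linear interpolation between order statistics (type 7).
#'
#' @param asymmetry Vector of per-subject asymmetries in percent (one value
#'   per ear pair), `NA`s dropped.
#' @param coverage Central coverage in percent (default 90).
#' @param min_pairs Minimum number of pairs required.
#' @return List of class `vemp_asym_limits`: `lower`, `upper` (percent),
#'   `coverage`, `n`, `quantile_type`.
#' @export
asymmetry_limits <- function(asymmetry, coverage = 90, min_pairs = 20L) {
  a <- asymmetry[is.finite(asymmetry)]
  if (length(a) < min_pairs)
    stop(sprintf("need at least %d ear pairs (have %d)",
                 min_pairs, length(a)), call. = FALSE)
  stopifnot(coverage > 0, coverage < 100)
  p <- c((100 - coverage) / 2, 100 - (100 - coverage) / 2) / 100
  q <- stats::quantile(a, probs = p, type = 7, names = FALSE)
  structure(list(lower = q[1], upper = q[2], coverage = coverage,
                 n = length(a), quantile_type = 7L),
            class = "vemp_asym_limits")
}

#' @export
print.vemp_asym_limits <- function(x, ...) {
  cat(sprintf("<vemp_asym_limits> %g%% band: [%.1f, %.1f]%% (n = %d pairs)\n",
              x$coverage, x$lower, x$upper, x$n))
  invisible(x)
}

#' Build right/left ear pairs from a feature table
#'
#' @param records Feature table (one row per subject x ear x mode).
#' @param mode Conduction mode to pair.
#' @param value Column to pair (default `amplitude_ratio`).
#' @return Data frame with `subject_id`, `right`, `left`, `asymmetry_pct`
#'   (complete pairs only).
#' @export
ear_pairs <- function(records, mode = "AC", value = "amplitude_ratio") {
  sub <- records[records$mode == mode, ]
  r <- sub[sub$ear == "R", c("subject_id", value)]
  l <- sub[sub$ear == "L", c("subject_id", value)]
  names(r)[2] <- "right"; names(l)[2] <- "left"
  m <- merge(r, l, by = "subject_id")
  m <- m[is.finite(m$right) & is.finite(m$left), ]
  m$asymmetry_pct <- interaural_asymmetry(m$right, m$left)
  m[order(m$subject_id), ]
}

#' Intraclass correlation for right-left ear agreement
#'
#' Default is the one-way random-effects, absolute-agreement, single-
#' measurement ICC (ears nested in subject), with its large-sample
#' F-distribution confidence interval. Two-way forms (consistency and
#' absolute agreement with a systematic ear effect) are available via
#' `type`.
#'
#' @param right,left Paired measurements (complete pairs only are used).
#' @param type `"oneway"` (default), `"consistency"` (two-way mixed,
#'   ICC(3,1)) or `"agreement"` (two-way random, ICC(2,1)).
#' @param conf_level Confidence level for the interval.
#' @param min_pairs Minimum number of complete pairs.
#' @return List of class `vemp_icc`: `estimate`, `conf_int`, `type`, `n`.
#' @export
icc <- function(right, left, type = c("oneway", "consistency", "agreement"),
                conf_level = 0.95, min_pairs = 10L) {
  type <- match.arg(type)
  ok <- is.finite(right) & is.finite(left)
  x <- right[ok]; y <- left[ok]
  n <- length(x)
  if (n < min_pairs)
    stop(sprintf("need at least %d complete pairs (have %d)",
                 min_pairs, n), call. = FALSE)
  k <- 2
  m_subj <- (x + y) / 2
  grand <- mean(m_subj)
  if (stats::var(c(x, y)) == 0)
    stop("zero total variance: ICC undefined", call. = FALSE)
  msb <- k * stats::var(m_subj)                       # between subjects
  msw <- sum((x - m_subj)^2 + (y - m_subj)^2) / n     # within subjects
  mean_ear <- c(mean(x), mean(y))
  msc <- n * sum((mean_ear - grand)^2) / (k - 1)      # between ears
  # residual mean square: SSW - SSC over (n-1)(k-1) df
  mse <- (msw * n * (k - 1) - msc * (k - 1)) / ((n - 1) * (k - 1))

  alpha <- 1 - conf_level
  if (type == "oneway") {
    est <- (msb - msw) / (msb + (k - 1) * msw)
    f0 <- msb / msw
    fl <- f0 / stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
    fu <- f0 * stats::qf(1 - alpha / 2, n * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else if (type == "consistency") {
    est <- (msb - mse) / (msb + (k - 1) * mse)
    f0 <- msb / mse
    fl <- f0 / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- f0 * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    est <- (msb - mse) /
      (msb + (k - 1) * mse + k / n * (msc - mse))
    # Satterthwaite-type interval (McGraw-Wong)
    a <- k * est / (n * (1 - est)); b <- 1 + k * est * (n - 1) / (n * (1 - est))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    ci <- c(n * (msb - fl * mse) /
              (fl * (k * msc + (k * n - k - n) * mse) + n * msb),
            n * (fu * msb - mse) /
              (k * msc + (k * n - k - n) * mse + n * fu * msb))
  }
  structure(list(estimate = unname(est),
                 conf_int = pmin(pmax(unname(ci), -1), 1),
                 conf_level = conf_level, type = type, n = n),
            class = "vemp_icc")
}

#' @export
print.vemp_icc <- function(x, ...) {
  cat(sprintf("<vemp_icc> %s: %.3f [%.3f, %.3f] (%d pairs, %g%% CI)\n",
              x$type, x$estimate, x$conf_int[1], x$conf_int[2], x$n,
              100 * x$conf_level))
  invisible(x)
}

#' Descriptive statistics by age band
#'
#' Mean (SD) and median (min; max) of the amplitude ratio, latencies and
#' threshold per age band and conduction mode, in the layout of a normative
#' study's characteristics table. Default bands are yearly through childhood
#' then 16-21, 21-41 and 41-62 years.
#'
#' @param records Feature table (one row per subject x ear x mode).
#' @param age_breaks Band edges in years (left-closed, right-open).
#' @return Data frame, one row per band x mode, with `n_ears` and
#'   mean/sd/median/min/max columns per measure; empty bands are omitted.
#' @export
descriptive_table <- function(records,
                              age_breaks = c(0:16, 21, 41, 62)) {
  stopifnot(length(age_breaks) >= 2L, !is.unsorted(age_breaks))
  band <- cut(records$age_years, breaks = age_breaks, right = FALSE,
              include.lowest = FALSE)
  measures <- c(ratio = "amplitude_ratio", p_lat = "p_latency_ms",
                n_lat = "n_latency_ms", thr = "threshold_dbnhl")
  out <- list()
  for (bd in levels(band)) {
    for (md in sort(unique(records$mode))) {
      sub <- records[!is.na(band) & band == bd & records$mode == md, ]
      if (nrow(sub) == 0L) next
      row <- data.frame(age_band = bd, mode = md, n_ears = nrow(sub))
      for (nm in names(measures)) {
        v <- sub[[measures[[nm]]]]
        v <- v[is.finite(v)]
        row[[paste0(nm, "_mean")]] <- if (length(v)) mean(v) else NA_real_
        row[[paste0(nm, "_sd")]] <- if (length(v) > 1) stats::sd(v) else
          if (length(v) == 1) 0 else NA_real_
        row[[paste0(nm, "_median")]] <- if (length(v)) stats::median(v) else
          NA_real_
        row[[paste0(nm, "_min")]] <- if (length(v)) min(v) else NA_real_
        row[[paste0(nm, "_max")]] <- if (length(v)) max(v) else NA_real_
      }
      out[[paste(bd, md)]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
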