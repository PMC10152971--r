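# Synthetic normative cohorts. The generator emulates the statistical
# structure a pediatric c-VEMP normative study assumes: an amplitude ratio
# whose population mean rises rapidly over the first years of life, peaks
# around 4-6 years and then declines slowly; log-normal between-subject and
# between-ear variability with a high interaural correlation; males somewhat
# above females; thresholds negatively related to the amplitude ratio and
# quantized to the 5-dB staircase grid; P/N latencies drifting slightly
# upward with age; and occasional absent bone-conduction responses from
# mid-adolescence onward.

#' Maturation curve of the mean amplitude ratio
#'
#' Parametric mean curve
#' `m(age) = s * [b + g * (age/t) * exp(1 - age/t)] * exp(-d * max(0, age - t))`
#' with baseline `b`, peak gain `g` (the bump term equals `g` at `age = t`),
#' peak age `t`, and a relative post-peak decline rate `d`; `s` is a sex
#' multiplier. The multiplicative decline keeps the curve positive over the
#' whole age domain, including adulthood.
#'
#' @param baseline Baseline ratio `b` (>= 0).
#' @param gain Peak gain `g`.
#' @param peak_age Peak age `t` in years (> 0).
#' @param decline Post-peak relative decline rate `d`, per year.
#' @param sex_multiplier Named vector `c(M = , F = )` of multipliers.
#' @return Object of class `vemp_curve`.
#' @export
maturation_curve <- function(baseline, gain, peak_age, decline,
                             sex_multiplier = c(M = 1, F = 1)) {
  stopifnot(baseline >= 0, peak_age > 0, decline >= 0,
            all(c("M", "F") %in% names(sex_multiplier)))
  structure(list(baseline = baseline, gain = gain, peak_age = peak_age,
                 decline = decline, sex_multiplier = sex_multiplier),
            class = "vemp_curve")
}

#' Evaluate a maturation curve
#'
#' @param curve A `vemp_curve`.
#' @param age Ages in years (>= 0).
#' @param sex `"M"` or `"F"` (scalar or vector).
#' @return Mean amplitude ratio(s); an error is raised if the curve goes
#'   negative at any requested age.
#' @export
curve_mean <- function(curve, age, sex = "M") {
  s <- curve$sex_multiplier[sex]
  x <- age / curve$peak_age
  m <- s * (curve$baseline + curve$gain * x * exp(1 - x)) *
    exp(-curve$decline * pmax(0, age - curve$peak_age))
  if (any(m < 0))
    stop("maturation curve is negative on the requested age range",
         call. = FALSE)
  unname(m)
}

#' Default maturation curves per conduction mode
#'
#' Air conduction is markedly age-dependent (steep early rise, peak near
#' 5 years); bone conduction is flatter with a slightly faster late decline.
#' Magnitudes are on the scale of published pediatric amplitude-ratio tables
#' (population means roughly 0.8-2.1). Males run above females.
#'
#' @return Named list of `vemp_curve` objects, one per mode.
#' @export
default_curves <- function() {
  list(
    AC = maturation_curve(baseline = 0.35, gain = 1.45, peak_age = 5,
                          decline = 0.010,
                          sex_multiplier = c(M = 1.15, F = 0.90)),
    BC = maturation_curve(baseline = 0.60, gain = 1.30, peak_age = 5,
                          decline = 0.018,
                          sex_multiplier = c(M = 1.10, F = 0.95))
  )
}

#' Cohort generator configuration
#'
#' Defaults emulate a normative study of 118 children (6 months to 16 years)
#' and 41 adults (16 to 62 years), both ears tested in both modes.
#'
#' @param n_children,n_adults Group sizes.
#' @param age_range_children,age_range_adults Age ranges in years (uniform
#'   sampling).
#' @param sex_ratio Fraction male.
#' @param rho Interaural correlation of the log amplitude ratio (default
#'   0.85).
#' @param tau Total SD of the log amplitude ratio around the maturation mean
#'   (subject + ear components).
#' @param mode_cor Correlation of the subject effect between AC and BC.
#' @param theta0 Named vector: threshold intercept per mode, dB nHL at
#'   amplitude ratio 0.
#' @param theta1 Threshold decrease per unit amplitude ratio, dB.
#' @param threshold_sd SD of the threshold noise, dB.
#' @param p_absent_bc Probability of an absent BC response from
#'   `absent_bc_age` on.
#' @param absent_bc_age Age (years) from which BC responses may be absent.
#' @param emg_range Tonic EMG target band, rectified-mean microvolts.
#' @param seed Optional integer seed.
#' @return List of class `vemp_cohort_config`.
#' @export
cohort_config <- function(n_children = 118L, n_adults = 41L,
                          age_range_children = c(0.5, 16),
                          age_range_adults = c(16, 62),
                          sex_ratio = 0.5, rho = 0.85, tau = 0.35,
                          mode_cor = 0.6,
                          theta0 = c(AC = 86, BC = 84), theta1 = 4,
                          threshold_sd = 2.5,
                          p_absent_bc = 0.15, absent_bc_age = 15,
                          emg_range = c(100, 500), seed = NULL) {
  stopifnot(n_children >= 0, n_adults >= 0,
            diff(age_range_children) > 0, diff(age_range_adults) > 0,
            sex_ratio >= 0, sex_ratio <= 1,
            rho >= 0, rho <= 1, mode_cor >= 0, mode_cor <= 1,
            p_absent_bc >= 0, p_absent_bc <= 1,
            emg_range[1] > 0, diff(emg_range) >= 0)
  if (tau <= 0 || threshold_sd < 0)
    stop("variance parameters must be positive", call. = FALSE)
  structure(as.list(environment()), class = "vemp_cohort_config")
}

# 5-dB grid in dB nHL anchored at the mode's reference level, clamped to the
# staircase range (floor = reference - 30, ceiling = device maximum).
.quantize_threshold <- function(thr, mode) {
  ref <- reference_level_nhl(mode)
  q <- ref + 5 * round((thr - ref) / 5)
  pmin(pmax(q, ref - 30), ref + 10)
}

#' Sample a synthetic cohort of latent ("true") subject characteristics
#'
#' Draws one row per subject x ear x mode. The true amplitude ratio is
#' `m(age, sex) * exp(eta_subject + eta_ear)` with independent Gaussian
#' effects on the log scale (`var(eta_subject) = rho * tau^2`,
#' `var(eta_ear) = (1 - rho) * tau^2`), so the interaural correlation of the
#' log ratio equals `rho`. Thresholds are
#' `theta0 - theta1 * ratio + noise`, rounded onto the mode's 5-dB nHL
#' staircase grid. Latencies follow a weak linear age drift. The generator
#' is deterministic for a fixed seed.
#'
#' @param config A [cohort_config()].
#' @param curves Named list of per-mode [maturation_curve()]s.
#' @param seed Integer seed (overrides `config$seed`).
#' @return Data frame with columns `subject_id`, `group`, `age_years`, `sex`,
#'   `ear`, `mode`, `true_ratio`, `true_threshold_dbnhl` (`NA` when the
#'   response is absent), `t_p_ms`, `t_n_ms`, `emg_uv`, `response_absent`.
#' @export
sample_cohort <- function(config = cohort_config(), curves = default_curves(),
                          seed = config$seed) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                       globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  cfg <- config
  n <- cfg$n_children + cfg$n_adults
  if (n == 0L) return(NULL)
  age <- c(stats::runif(cfg$n_children, cfg$age_range_children[1],
                        cfg$age_range_children[2]),
           stats::runif(cfg$n_adults, cfg$age_range_adults[1],
                        cfg$age_range_adults[2]))
  group <- rep(c("child", "adult"), c(cfg$n_children, cfg$n_adults))
  sex <- ifelse(stats::runif(n) < cfg$sex_ratio, "M", "F")
  emg <- stats::runif(n, cfg$emg_range[1], cfg$emg_range[2])
  id <- sprintf("S%03d", seq_len(n))

  sd_subj <- sqrt(cfg$rho) * cfg$tau
  sd_ear <- sqrt(1 - cfg$rho) * cfg$tau
  eta_common <- stats::rnorm(n, 0, sd_subj)

  rows <- list()
  for (md in names(curves)) {
    m <- curve_mean(curves[[md]], age, sex)
    eta_mode <- stats::rnorm(n, 0, sd_subj)
    eta_subj <- sqrt(cfg$mode_cor) * eta_common +
      sqrt(1 - cfg$mode_cor) * eta_mode
    for (ear in c("R", "L")) {
      eta_ear <- stats::rnorm(n, 0, sd_ear)
      ratio <- m * exp(eta_subj + eta_ear)
      thr <- .quantize_threshold(
        cfg$theta0[[md]] - cfg$theta1 * ratio +
          stats::rnorm(n, 0, cfg$threshold_sd), md)
      tp <- 12.8 + 0.05 * age + stats::rnorm(n, 0, 0.4)
      tn <- pmax(tp + 6.3 + stats::rnorm(n, 0, 0.8), tp + 2)
      rows[[paste(md, ear)]] <- data.frame(
        subject_id = id, group = group, age_years = age, sex = sex,
        ear = ear, mode = md, true_ratio = ratio,
        true_threshold_dbnhl = thr, t_p_ms = tp, t_n_ms = tn, emg_uv = emg,
        response_absent = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)

  # absent BC responses from mid-adolescence onward (subject-level event,
  # both ears lost together)
  if ("BC" %in% names(curves) && cfg$p_absent_bc > 0) {
    absent_subj <- id[age >= cfg$absent_bc_age &
                        stats::runif(n) < cfg$p_absent_bc]
    sel <- out$mode == "BC" & out$subject_id %in% absent_subj
    out$response_absent[sel] <- TRUE
    out$true_ratio[sel] <- NA_real_
    out$true_threshold_dbnhl[sel] <- NA_real_
  }

  out <- out[order(out$subject_id, out$mode, out$ear), ]
  rownames(out) <- NULL
  out
}
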