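# End-to-end pipeline: simulate a cohort, synthesize and analyze the
# waveform sessions, fit the reference models per sex x mode, and write the
# normative tables, asymmetry limits, ICC summaries and a classification
# demonstration, together with a manifest of content hashes. Re-running with
# the same configuration and seed reproduces every output byte for byte.

#' Pipeline configuration
#'
#' @param cohort A [cohort_config()].
#' @param waveform A [waveform_config()].
#' @param seed Master seed; every stage derives its stream from it.
#' @param r_min Replicability correlation threshold.
#' @param lambda_grid Box-Cox profile grid for the reference fits.
#' @param table_ages Ages of the normative tables.
#' @param asym_coverage Central coverage of the asymmetry limits, percent.
#' @return List of class `vemp_pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            waveform = waveform_config(),
                            seed = 1L, r_min = 0.7,
                            lambda_grid = seq(-2, 2, by = 0.05),
                            table_ages = 1:15, asym_coverage = 90) {
  structure(as.list(environment()), class = "vemp_pipeline_config")
}

#' Run the full normative pipeline
#'
#' Stages: (1) sample the synthetic cohort truth table; (2) synthesize each
#' subject's recording session and extract its features (reference-level
#' amplitude ratio, EMG, latencies, staircase threshold); (3) fit the
#' Box-Cox / fractional-polynomial reference models per sex within each
#' mode on the pooled-ear children data; (4) lay out the normative centile
#' tables; (5) compute interaural asymmetry limits and ICC per mode;
#' (6) classify the first child subject against its stratum model as a
#' demonstration. All artifacts are written under `out_dir` along with
#' `manifest.json` (configuration echo and MD5 content hashes).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory artifacts (`truth`,
#'   `features`, `models`, `tables`, `asymmetry`, `icc`, `classification`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "vemp_pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  truth <- stage("simulate", {
    if (config$cohort$n_children == 0L)
      stop("cohort has no children; reference fitting needs child records")
    sample_cohort(config$cohort, seed = config$seed)
  })
  write_feature_like <- file.path(out_dir, "cohort_truth.csv")
  utils::write.csv(format(truth, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   write_feature_like, row.names = FALSE, quote = FALSE)

  features <- stage("features", {
    ids <- unique(truth$subject_id)
    rows <- lapply(seq_along(ids), function(i) {
      sess <- synth_session(truth[truth$subject_id == ids[i], ],
                            wconfig = config$waveform,
                            seed = as.integer((as.numeric(config$seed) +
                                                 i * 7919) %% 2147483647))
      session_features(sess, r_min = config$r_min)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
  feat_path <- file.path(out_dir, "features.csv")
  write_feature_csv(features, feat_path)

  models <- stage("fit", {
    child <- features[features$group == "child", ]
    fit_reference_models(child, lambda_grid = config$lambda_grid)
  })
  model_path <- file.path(out_dir, "models.json")
  write_ref_models(models, model_path)

  tables <- stage("tables", {
    lapply(models, make_normative_table, ages = config$table_ages)
  })
  table_paths <- character(0)
  for (md in names(tables)) {
    p <- file.path(out_dir, sprintf("normative_table_%s.csv", md))
    utils::write.csv(format(tables[[md]], digits = 6, trim = TRUE,
                            scientific = FALSE),
                     p, row.names = FALSE, quote = FALSE)
    table_paths <- c(table_paths, p)
  }

  asym <- stage("asymmetry", {
    lapply(stats::setNames(nm = names(models)), function(md) {
      pr <- ear_pairs(features, mode = md)
      asymmetry_limits(pr$asymmetry_pct, coverage = config$asym_coverage)
    })
  })
  icc_by_mode <- stage("icc", {
    lapply(stats::setNames(nm = names(models)), function(md) {
      pr <- ear_pairs(features, mode = md)
      icc(pr$right, pr$left)
    })
  })
  stats_path <- file.path(out_dir, "cohort_stats.json")
  jsonlite::write_json(
    list(asymmetry_limits = lapply(asym, unclass),
         icc = lapply(icc_by_mode, unclass)),
    stats_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  classification <- stage("classify", {
    child <- features[features$group == "child" &
                        features$mode == "AC" &
                        is.finite(features$amplitude_ratio), ]
    child <- child[child$age_years >= 1 & child$age_years <= 15, ]
    sid <- child$subject_id[1]
    rows <- child[child$subject_id == sid, ]
    r <- rows[rows$ear == "R", ][1, ]; l <- rows[rows$ear == "L", ][1, ]
    classify_subject(models$AC[[rows$sex[1]]], rows$age_years[1],
                     ratio_right = r$amplitude_ratio,
                     ratio_left = l$amplitude_ratio,
                     threshold_right = r$threshold_dbnhl,
                     threshold_left = l$threshold_dbnhl,
                     p_latency_right = r$p_latency_ms,
                     p_latency_left = l$p_latency_ms)
  })
  class_path <- file.path(out_dir, "classification_demo.json")
  jsonlite::write_json(unclass(classification), class_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  paths <- c(write_feature_like, feat_path, model_path, table_paths,
             stats_path, class_path)
  manifest <- list(
    package = "vempnorm",
    version = as.character(utils::packageVersion("vempnorm")),
    seed = config$seed,
    config = list(
      n_children = config$cohort$n_children,
      n_adults = config$cohort$n_adults,
      rho = config$cohort$rho, tau = config$cohort$tau,
      r_min = config$r_min, asym_coverage = config$asym_coverage
    ),
    files = lapply(stats::setNames(nm = basename(paths)), function(b)
      unname(tools::md5sum(file.path(out_dir, b))))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(truth = truth, features = features, models = models,
                 tables = tables, asymmetry = asym, icc = icc_by_mode,
                 classification = classification, manifest = manifest))
}
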