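# File formats: the cohort feature table (CSV, one row per subject x ear x
# mode), delimited-text traces with '#'-prefixed header lines, and reference
# models as JSON. Absent responses are written as the explicit sentinel
# "absent" (an absent response is a finding, not missing data); writers are
# locale-independent with a stable column order.

.FEATURE_COLUMNS <- c("subject_id", "group", "age_years", "sex", "ear",
                      "mode", "pn_uv", "emg_uv", "amplitude_ratio",
                      "p_latency_ms", "n_latency_ms", "threshold_dbnhl")

#' Write a cohort feature table to CSV
#'
#' @param records Feature data frame (see [read_feature_csv()] for the
#'   schema).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(records, path) {
  missing_cols <- setdiff(.FEATURE_COLUMNS, names(records))
  if (length(missing_cols))
    stop("feature table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- records[, c(.FEATURE_COLUMNS,
                     setdiff(names(records), .FEATURE_COLUMNS))]
  thr <- out$threshold_dbnhl
  out$threshold_dbnhl <- ifelse(is.na(thr), "absent", format(thr, digits = 15))
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) format(x, digits = 15, trim = TRUE,
                                                  scientific = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort feature table from CSV
#'
#' The schema has one row per subject x ear x mode with columns
#' `subject_id`, `group` (child/adult), `age_years`, `sex` (M/F), `ear`
#' (R/L), `mode` (AC/BC), `pn_uv`, `emg_uv`, `amplitude_ratio`,
#' `p_latency_ms`, `n_latency_ms`, `threshold_dbnhl` (number or the sentinel
#' `"absent"`). Extra columns are kept. Rows whose `amplitude_ratio` is
#' inconsistent with `pn_uv / emg_uv` beyond `tol` trigger one warning
#' reporting the number of offending rows.
#'
#' @param path CSV file path.
#' @param tol Consistency tolerance for `amplitude_ratio` vs
#'   `pn_uv / emg_uv`.
#' @return Typed data frame; absent thresholds become `NA` (the in-memory
#'   representation of the sentinel).
#' @export
read_feature_csv <- function(path, tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(.FEATURE_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("feature CSV lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  num_cols <- c("age_years", "pn_uv", "emg_uv", "amplitude_ratio",
                "p_latency_ms", "n_latency_ms")
  out <- raw
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- which(!is.na(raw[[cl]]) & nzchar(raw[[cl]]) &
                   raw[[cl]] != "NA" & is.na(v))
    if (length(bad))
      stop(sprintf("unparseable value in column '%s' at data row %d",
                   cl, bad[1]), call. = FALSE)
    out[[cl]] <- v
  }
  thr_raw <- raw$threshold_dbnhl
  thr <- suppressWarnings(as.numeric(thr_raw))
  not_num <- is.na(thr) & !is.na(thr_raw) & nzchar(thr_raw)
  bad_thr <- which(not_num & thr_raw != "absent" & thr_raw != "NA")
  if (length(bad_thr))
    stop(sprintf("unparseable threshold at data row %d (use a number or %s)",
                 bad_thr[1], '"absent"'), call. = FALSE)
  out$threshold_dbnhl <- thr

  chk <- is.finite(out$amplitude_ratio) & is.finite(out$pn_uv) &
    is.finite(out$emg_uv) & out$emg_uv > 0
  bad_ratio <- sum(chk &
                     abs(out$amplitude_ratio - out$pn_uv / out$emg_uv) >
                     tol * pmax(out$amplitude_ratio, 1))
  if (bad_ratio > 0)
    warning(sprintf(
      "%d row(s) have amplitude_ratio inconsistent with pn_uv/emg_uv",
      bad_ratio), call. = FALSE)
  out
}

#' Write a trace to a delimited text file
#'
#' Format: '#'-prefixed `key=value` header lines (`fs_hz`, `level_dbnhl`,
#' `ear`, `mode`, `replicate`, `n_epochs`, `emg_uv`, ...) followed by one
#' sample (microvolts) per row.
#'
#' @param trace A `vemp_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "vemp_trace"))
  meta <- c(list(fs_hz = trace$fs_hz), trace$meta)
  hdr <- sprintf("# %s=%s", names(meta),
                 vapply(meta, function(v) format(v, digits = 15),
                        character(1)))
  writeLines(c(hdr, format(trace$samples, digits = 15, trim = TRUE,
                           scientific = FALSE)), path)
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' @param path File path.
#' @return A `vemp_trace`.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  kv <- sub("^#\\s*", "", lines[is_hdr])
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  meta <- as.list(vals)
  names(meta) <- keys
  for (nm in names(meta)) {
    v <- suppressWarnings(as.numeric(meta[[nm]]))
    if (!is.na(v)) meta[[nm]] <- v
  }
  fs <- meta$fs_hz
  if (is.null(fs)) stop("trace header lacks fs_hz", call. = FALSE)
  meta$fs_hz <- NULL
  samples <- as.numeric(lines[!is_hdr])
  if (any(is.na(samples)))
    stop("unparseable sample values in ", path, call. = FALSE)
  vemp_trace(samples, fs, meta)
}

#' Serialize fitted reference models to JSON
#'
#' @param models Nested list `models[[mode]][[sex]]` of `vemp_refmodel`s
#'   (as returned by [fit_reference_models()]), or one `vemp_refmodel`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ref_models <- function(models, path) {
  strip <- function(m) {
    stopifnot(inherits(m, "vemp_refmodel"))
    list(lambda = m$lambda, shift = m$shift,
         mu = list(powers = m$mu$powers, beta = m$mu$beta),
         sigma = list(powers = m$sigma$powers, beta = m$sigma$beta),
         age_domain = m$age_domain, stratum = m$stratum,
         diagnostics = m$diagnostics)
  }
  obj <- if (inherits(models, "vemp_refmodel")) strip(models) else
    lapply(models, function(md) lapply(md, strip))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read reference models written by [write_ref_models()]
#'
#' @param path JSON file path.
#' @return Nested list of `vemp_refmodel` objects (or a single model if the
#'   file holds one).
#' @export
read_ref_models <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rebuild <- function(o) {
    structure(
      list(lambda = o$lambda, shift = o$shift,
           mu = list(powers = as.numeric(o$mu$powers),
                     beta = as.numeric(o$mu$beta)),
           sigma = list(powers = as.numeric(o$sigma$powers),
                        beta = as.numeric(o$sigma$beta)),
           age_domain = as.numeric(o$age_domain), stratum = o$stratum,
           diagnostics = o$diagnostics, profile = NULL),
      class = "vemp_refmodel")
  }
  if (!is.null(obj$lambda)) return(rebuild(obj))
  lapply(obj, function(md) lapply(md, rebuild))
}
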