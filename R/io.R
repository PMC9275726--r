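# Readers and writers for the interchange formats. CSV is canonical; cohort
# tables are additionally readable from XLSX (via readxl) with a
# column-mapping configuration for externally produced sheets.

read_table_checked <- function(path, required, what) {
  if (!file.exists(path)) abort(paste0(what, " file not found: ", path))
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss))
    abort(paste0(what, " ", path, " missing required columns: ",
                 paste(miss, collapse = ", ")))
  d
}

fail_rows <- function(bad, path, msg) {
  # data row numbers as in the file (header is line 1)
  abort(paste0(path, ": ", msg, " at line(s) ",
               paste(head(bad, 5L) + 1L, collapse = ", "),
               if (length(bad) > 5L) " ..."))
}

#' Read or write a syllectogram trace CSV
#'
#' Format: header `t_s, ch1[, ch2]`, plain decimal values, strictly
#' ascending times.
#'
#' @param path File path.
#' @param sample_id Sample identifier; defaults to the file stem.
#' @param trace A [syl_trace()] (for writing).
#' @return [read_trace()] returns a [syl_trace()].
#' @export
read_trace <- function(path, sample_id = NULL) {
  d <- read_table_checked(path, c("t_s", "ch1"), "trace")
  bad <- which(diff(d$t_s) <= 0)
  if (length(bad)) fail_rows(bad + 1L, path, "non-ascending time t_s")
  bad <- which(!is.finite(d$ch1) | d$ch1 < 0 |
                 (if ("ch2" %in% names(d)) !is.finite(d$ch2) | d$ch2 < 0 else FALSE))
  if (length(bad)) fail_rows(bad, path, "negative or non-numeric intensity")
  syl_trace(d, sample_id = sample_id %||%
              tools::file_path_sans_ext(basename(path)))
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "syl_trace"))
  readr::write_csv(as_tibble(trace), path)
  invisible(path)
}

#' Read or write a Westergren series CSV
#'
#' Format: header `t_min, h_mm`, ascending times, non-negative distances.
#'
#' @param path File path.
#' @param sample_id Sample identifier; defaults to the file stem.
#' @param resolution Reading resolution, mm.
#' @param series A [westergren_series()] (for writing).
#' @return [read_westergren()] returns a [westergren_series()].
#' @export
read_westergren <- function(path, sample_id = NULL, resolution = 0.5) {
  d <- read_table_checked(path, c("t_min", "h_mm"), "westergren series")
  bad <- which(diff(d$t_min) <= 0)
  if (length(bad)) fail_rows(bad + 1L, path, "non-ascending time t_min")
  bad <- which(!is.finite(d$h_mm) | d$h_mm < 0)
  if (length(bad)) fail_rows(bad, path, "negative or non-numeric distance")
  westergren_series(d, sample_id = sample_id %||%
                      tools::file_path_sans_ext(basename(path)),
                    resolution = resolution)
}

#' @rdname read_westergren
#' @export
write_westergren <- function(series, path) {
  stopifnot(inherits(series, "westergren_series"))
  readr::write_csv(as_tibble(series), path)
  invisible(path)
}

#' Read a cohort table (CSV or XLSX)
#'
#' Canonical columns: `sample_id, donor, fib_level, ht, ai5, ai10, ai30,
#' ai60, ai120, wg_esr_1h, ve, alpha, lambda_s`; only `sample_id`, `ht` and
#' `ai5` are required. Externally produced sheets with different headers are
#' ingested by supplying `mapping`, a named character vector
#' `c(canonical = "source column")` applied before validation. XLSX files
#' are read with readxl (read-only support).
#'
#' @param path CSV or XLSX file.
#' @param mapping Optional named character vector renaming source columns to
#'   canonical names.
#' @param sheet XLSX sheet (name or index), passed to readxl.
#' @return A cohort tibble.
#' @export
read_cohort <- function(path, mapping = NULL, sheet = 1) {
  if (!file.exists(path)) abort(paste0("cohort file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  d <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      abort("reading XLSX cohorts requires the 'readxl' package")
    as_tibble(readxl::read_excel(path, sheet = sheet))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  if (!is.null(mapping)) {
    miss <- setdiff(unname(mapping), names(d))
    if (length(miss))
      abort(paste0("mapping refers to absent source columns: ",
                   paste(miss, collapse = ", ")))
    for (i in seq_along(mapping))
      names(d)[names(d) == mapping[[i]]] <- names(mapping)[i]
  }
  miss <- setdiff(cohort_required, names(d))
  if (length(miss))
    abort(paste0("cohort ", path, " missing required columns: ",
                 paste(miss, collapse = ", ")))
  bad <- which(d$ht <= 0 | d$ht >= 1)
  if (length(bad)) fail_rows(bad, path, "hematocrit outside (0, 1)")
  bad <- which(d$ai5 < 0 | d$ai5 > 1)
  if (length(bad)) fail_rows(bad, path, "ai5 outside [0, 1]")
  d
}

#' @rdname read_cohort
#' @param cohort Cohort tibble (for writing; CSV only).
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(as_tibble(cohort), path)
  invisible(path)
}

#' Write a sedimentation curve with its parameter sidecar
#'
#' The curve goes to `<path>` as `t_min, h_mm`; the model parameters (`ht`,
#' `ve_mm_min`, `alpha`, `lambda_s`, `tau_min`, `h_inf_mm`) go to
#' `<path>.json`.
#'
#' @param curve An `esr_curve`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "esr_curve"))
  readr::write_csv(select(as_tibble(curve), "t_min", "h_mm"), path)
  p <- curve_params(curve)
  jsonlite::write_json(p[c("ht", "ve_mm_min", "alpha", "lambda_s",
                           "tau_min", "h_inf_mm")],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
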