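#' Read a delimited laboratory results extract
#'
#' Reads a CSV or TSV export with one row per reported result. Required
#' columns: `patient_id`, `analyte`, `timestamp` (ISO 8601), `value`;
#' optional `sex` and `age`. Rows that fail validation -- non-positive or
#' non-numeric values, unparseable timestamps, empty patient identifiers --
#' are dropped with a counted warning, never silently. Timezone-naive
#' timestamps are taken as given and only compared within the file.
#'
#' @param path Path to the delimited file; the delimiter is inferred from
#'   the extension (`.tsv`/`.tab` means tab, otherwise comma) unless
#'   `delim` is supplied.
#' @param delim Optional explicit field delimiter.
#' @return Tibble of validated records with attribute `n_dropped`.
#' @export
read_results_csv <- function(path, delim = NULL) {
  if (!file.exists(path)) rlang::abort(sprintf("input file not found: %s", path))
  delim <- delim %||% (if (grepl("\\.(tsv|tab)$", path)) "\t" else ",")
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(raw) == 0L) rlang::abort(sprintf("input file is empty: %s", path))
  required <- c("patient_id", "analyte", "timestamp", "value")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    rlang::abort(paste0(
      "required column(s) missing from ", path, ": ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  n_in <- nrow(raw)
  out <- raw |>
    dplyr::mutate(
      value = suppressWarnings(as.numeric(.data$value)),
      timestamp = suppressWarnings(readr::parse_datetime(.data$timestamp)),
      age = if ("age" %in% names(raw)) suppressWarnings(as.numeric(.data$age)) else NULL,
      sex = if ("sex" %in% names(raw)) {
        dplyr::if_else(.data$sex %in% c("F", "M"), .data$sex, NA_character_)
      } else NULL
    ) |>
    dplyr::filter(
      !is.na(.data$patient_id), nzchar(.data$patient_id),
      !is.na(.data$analyte),
      !is.na(.data$timestamp),
      is.finite(.data$value), .data$value > 0
    )
  n_dropped <- n_in - nrow(out)
  if (n_dropped > 0) {
    rlang::warn(sprintf(
      "dropped %d of %d row(s) failing validation (non-positive value, bad timestamp, or missing identifier)",
      n_dropped, n_in
    ))
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Run the full indirect CV_I pipeline on a results table
#'
#' End-to-end orchestration: filter to analyte and subgroup, build
#' consecutive-result ratios, attach data-sufficiency warnings, fit the
#' central peak, optionally bootstrap, convert to CVs and subtract the
#' analytical CV. Pure orchestration -- every number in the report is
#' reproducible by calling the underlying functions with the same seed.
#'
#' @param input Path to a results file (see [read_results_csv()]) or a
#'   data frame of records.
#' @param analyte Analyte code to estimate.
#' @param cv_a Long-term analytical CV in percent.
#' @param sex,age_range Subgroup filters, see [filter_records()].
#' @param scale,threshold Conversion-scale control, see [estimate_cvi()].
#' @param n_boot Bootstrap replicates; 0 (default) gives point estimates
#'   with empty interval fields.
#' @param seed Integer seed for the bootstrap and any subsampling.
#' @param min_gap,max_gap,disjoint Pairing options, see [build_ratios()].
#' @param pathological_fraction Optional analyst-supplied estimate of the
#'   pathological ratio fraction, used only for the sufficiency warning.
#' @param config A [fit_config()]; its seed is overridden by `seed`.
#' @return A one-row tibble of class `cvi_report` mirroring the standard
#'   reporting layout: subgroup, number of ratios, CV_A, peak SD with CI,
#'   indirect CV_I with CI, scale used, and accumulated warnings
#'   (semicolon-separated), plus 1-decimal display columns.
#' @export
run_estimate <- function(input, analyte, cv_a, sex = NULL,
                         age_range = c(18, 110),
                         scale = c("auto", "gaussian", "lognormal"),
                         threshold = 20, n_boot = 0, seed = 1L,
                         min_gap = 0, max_gap = Inf, disjoint = FALSE,
                         pathological_fraction = NULL,
                         config = fit_config()) {
  scale <- rlang::arg_match(scale)
  records <- if (is.character(input)) read_results_csv(input) else dplyr::as_tibble(input)
  config$seed <- as.integer(seed)

  recs <- filter_records(records, analyte, sex = sex, age_range = age_range)
  sample <- build_ratios(recs, min_gap = min_gap, max_gap = max_gap, disjoint = disjoint)
  warnings <- withCallingHandlers(
    check_sufficiency(sample, pathological_fraction),
    warning = function(w) invokeRestart("muffleWarning")
  )

  est <- if (n_boot > 0) {
    bootstrap_cvi(sample, cv_a, config, n_boot = n_boot, seed = seed,
                  scale = scale, threshold = threshold)
  } else {
    estimate_cvi(sample, cv_a, config, scale = scale, threshold = threshold)
  }

  subgroup <- if (is.null(sex)) "All" else c(F = "Female", M = "Male")[[sex]]
  report <- tibble::tibble(
    analyte = analyte,
    subgroup = subgroup,
    n_ratios = n_ratios(sample),
    cv_a = cv_a,
    lambda = est$fit$lambda,
    boxcox_sigma = est$fit$sigma_t,
    sigma_lo = est$ci_sigma[1], sigma_hi = est$ci_sigma[2],
    cv_total = est$cv_total,
    cv_i = est$cv_i,
    cv_i_lo = est$ci_cv_i[1], cv_i_hi = est$ci_cv_i[2],
    scale_used = est$scale_used,
    seed = as.integer(seed),
    warnings = paste(warnings, collapse = "; "),
    boxcox_sigma_display = format_cv(est$fit$sigma_t, 3),
    cv_i_display = format_cv(est$cv_i, 1)
  )
  class(report) <- c("cvi_report", class(report))
  report
}

report_columns <- c(
  "analyte", "subgroup", "n_ratios", "cv_a", "lambda",
  "boxcox_sigma", "sigma_lo", "sigma_hi", "cv_total",
  "cv_i", "cv_i_lo", "cv_i_hi", "scale_used", "seed", "warnings",
  "boxcox_sigma_display", "cv_i_display"
)

#' Write or re-read an indirect CV_I report
#'
#' TSV output follows the standard reporting column order (subgroup, number
#' of ratios, CV_A, peak SD with CI, indirect CV_I with CI); JSON output
#' keeps full precision plus the 1-decimal display fields and round-trips
#' losslessly through [read_report_json()].
#'
#' @param report A `cvi_report` (rows may be bound together first).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `report`, invisibly.
#' @export
write_report <- function(report, path, format = c("tsv", "json")) {
  format <- rlang::arg_match(format)
  ok <- tryCatch({
    if (format == "tsv") {
      readr::write_tsv(report[report_columns], path)
    } else {
      jsonlite::write_json(report[report_columns], path,
                           auto_unbox = FALSE, digits = NA, pretty = TRUE)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    rlang::abort(sprintf("could not write report to '%s': %s", path, conditionMessage(ok)))
  }
  invisible(report)
}

#' @rdname write_report
#' @export
read_report_json <- function(path) {
  df <- dplyr::as_tibble(jsonlite::fromJSON(path))
  df$n_ratios <- as.integer(df$n_ratios)
  df$seed <- as.integer(df$seed)
  class(df) <- c("cvi_report", class(df))
  df
}
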