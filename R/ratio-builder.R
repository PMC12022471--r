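#' Filter a result table to one analyte and subgroup
#'
#' Subsets a tidy table of laboratory results (one row per reported result)
#' to a single analyte, optionally restricted by sex and age. The default
#' age window of 18--110 years keeps adult results only. Row order is
#' preserved.
#'
#' @param records Data frame with at least `patient_id`, `analyte`,
#'   `timestamp`, `value`; optional `sex` (`"F"`/`"M"`) and `age` (years).
#' @param analyte Analyte code to keep.
#' @param sex Optional `"F"` or `"M"`; rows with missing sex are dropped
#'   when a filter is requested.
#' @param age_range Inclusive `c(lower, upper)` age bounds in years, applied
#'   only when an `age` column is present. Default `c(18, 110)`.
#' @return A tibble of the surviving rows. An analyte absent from the table
#'   yields an empty tibble with a warning, never an error.
#' @examples
#' recs <- tibble::tibble(
#'   patient_id = c("a", "a", "b"), analyte = c("crea", "crea", "alb"),
#'   timestamp = as.POSIXct("2020-01-01") + 0:2, value = c(80, 84, 41),
#'   sex = c("F", "F", "M"), age = c(44, 44, 61)
#' )
#' filter_records(recs, "crea")
#' @export
filter_records <- function(records, analyte, sex = NULL, age_range = c(18, 110)) {
  stopifnot(is.data.frame(records), length(analyte) == 1L)
  out <- dplyr::as_tibble(records)
  if (!analyte %in% out$analyte) {
    rlang::warn(sprintf("analyte '%s' not present in the supplied records", analyte))
  }
  out <- dplyr::filter(out, .data$analyte == .env$analyte)
  if (!is.null(sex)) {
    stopifnot(sex %in% c("F", "M"))
    if (!"sex" %in% names(out)) {
      rlang::abort("a sex filter was requested but the records have no `sex` column")
    }
    out <- dplyr::filter(out, !is.na(.data$sex), .data$sex == .env$sex)
  }
  if (!is.null(age_range) && "age" %in% names(out)) {
    stopifnot(length(age_range) == 2L, age_range[1] <= age_range[2])
    out <- dplyr::filter(
      out,
      is.na(.data$age) | (.data$age >= age_range[1] & .data$age <= age_range[2])
    )
  }
  out
}

#' Build consecutive-result ratios per patient
#'
#' Sorts each patient's results by time and forms the ratio of every
#' chronologically adjacent pair, later value over earlier value, so a
#' patient with k results contributes k - 1 overlapping ratios. The central
#' peak of these ratios carries the within-subject plus analytical variation
#' that the downstream peak fit estimates. Duplicate (patient, timestamp)
#' rows are ordered deterministically by ascending value and reported via a
#' message.
#'
#' @param records Data frame of results for a single analyte (see
#'   [filter_records()]).
#' @param min_gap,max_gap Inclusive bounds on the time gap between the two
#'   results of a pair, in days. Defaults keep every adjacent pair.
#' @param disjoint If `TRUE`, pairs do not share results: a series
#'   r1, r2, r3, r4 yields r2/r1 and r4/r3 only. Default `FALSE`
#'   (overlapping pairs, maximal n).
#' @return A `ratio_sample`: a tibble with columns `patient_id`, `ratio`,
#'   `gap_days`, carrying the analyte, subgroup label, and patient count as
#'   attributes. `n_ratios(x)` and `n_patients(x)` read the counts.
#' @examples
#' recs <- tibble::tibble(
#'   patient_id = "a", analyte = "crea",
#'   timestamp = as.POSIXct("2020-01-01") + c(0, 86400, 172800),
#'   value = c(2, 3, 1.5)
#' )
#' build_ratios(recs)$ratio # 1.5, 0.5
#' @export
build_ratios <- function(records, min_gap = 0, max_gap = Inf, disjoint = FALSE) {
  stopifnot(is.data.frame(records), min_gap >= 0, max_gap >= min_gap)
  req <- c("patient_id", "timestamp", "value")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    rlang::abort(paste0("records are missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (any(records$value <= 0, na.rm = TRUE)) {
    rlang::abort("result values must be strictly positive; validate input with read_results_csv()")
  }
  analyte <- if ("analyte" %in% names(records)) unique(records$analyte) else NA_character_
  if (length(analyte) > 1L) {
    rlang::abort("build_ratios() expects records for a single analyte; use filter_records() first")
  }

  df <- dplyr::as_tibble(records)
  n_dup <- sum(duplicated(df[c("patient_id", "timestamp")]))
  if (n_dup > 0) {
    rlang::inform(sprintf(
      "%d duplicate (patient, timestamp) row(s); ordered by ascending value", n_dup
    ))
  }
  pairs <- df |>
    dplyr::arrange(.data$patient_id, .data$timestamp, .data$value) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(
      ratio = .data$value / dplyr::lag(.data$value),
      gap_days = as.numeric(difftime(.data$timestamp, dplyr::lag(.data$timestamp), units = "days")),
      .pair_idx = dplyr::row_number()
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$ratio))
  if (disjoint) {
    pairs <- dplyr::filter(pairs, .data$.pair_idx %% 2L == 0L)
  }
  pairs <- dplyr::filter(pairs, .data$gap_days >= min_gap, .data$gap_days <= max_gap)

  new_ratio_sample(
    pairs[c("patient_id", "ratio", "gap_days")],
    analyte = analyte,
    subgroup = attr(records, "subgroup", exact = TRUE) %||% "All",
    n_patients = dplyr::n_distinct(df$patient_id)
  )
}

new_ratio_sample <- function(df, analyte = NA_character_, subgroup = "All",
                             n_patients = NA_integer_) {
  out <- dplyr::as_tibble(df)
  attr(out, "analyte") <- analyte
  attr(out, "subgroup") <- subgroup
  attr(out, "n_patients") <- n_patients
  class(out) <- c("ratio_sample", class(out))
  out
}

#' @rdname build_ratios
#' @param x A `ratio_sample`.
#' @export
n_ratios <- function(x) {
  if (inherits(x, "ratio_sample")) nrow(x) else length(x)
}

#' @rdname build_ratios
#' @export
n_patients <- function(x) attr(x, "n_patients", exact = TRUE)

#' Extract the bare ratio vector from a sample or numeric input
#'
#' Most estimation functions accept either a `ratio_sample` or a plain
#' numeric vector of ratios; this helper normalises both to a validated
#' positive numeric vector.
#'
#' @param x `ratio_sample` or numeric vector.
#' @return Numeric vector of strictly positive, finite ratios.
#' @export
ratio_values <- function(x) {
  z <- if (inherits(x, "ratio_sample")) x$ratio else x
  if (!is.numeric(z)) rlang::abort("expected a ratio_sample or a numeric vector of ratios")
  z <- z[!is.na(z)]
  if (any(!is.finite(z)) || any(z <= 0)) {
    rlang::abort("ratios must be finite and strictly positive")
  }
  z
}

#' Data-sufficiency warnings for an indirect CV_I estimate
#'
#' Robust indirect estimation needs enough ratios and a bounded pathological
#' fraction: fewer than 5,000 ratios or a pathological fraction of 30 % or
#' more each trigger a warning. The check never blocks execution -- the
#' warnings travel with the report so the analyst can judge.
#'
#' @param sample `ratio_sample` or numeric ratio vector.
#' @param pathological_fraction Optional estimated proportion of ratios that
#'   reflect genuine clinical change rather than random variation.
#' @return Character vector of warning texts (zero-length when sufficient),
#'   also signalled as R warnings.
#' @export
check_sufficiency <- function(sample, pathological_fraction = NULL) {
  msgs <- character()
  n <- n_ratios(sample)
  if (n < 5000) {
    msgs <- c(msgs, sprintf(
      "only %d ratios; at least 5,000 are recommended for a robust indirect CV_I estimate", n
    ))
  }
  if (!is.null(pathological_fraction)) {
    stopifnot(pathological_fraction >= 0, pathological_fraction <= 1)
    if (pathological_fraction >= 0.30) {
      msgs <- c(msgs, sprintf(
        "estimated pathological fraction %.0f %% is at or above the 30 %% robustness limit",
        100 * pathological_fraction
      ))
    }
  }
  for (m in msgs) rlang::warn(m)
  invisible(msgs)
}

#' Histogram of a ratio sample
#'
#' Quick look at the ratio distribution on the log scale, where the central
#' non-pathological peak should appear symmetric around 1.
#'
#' @param object A `ratio_sample`.
#' @param bins Number of histogram bins.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.ratio_sample <- function(object, bins = 100, ...) {
  df <- tibble::tibble(ratio = ratio_values(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", colour = NA) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "result ratio (log scale)", y = "count",
      title = attr(object, "analyte") %||% "ratio sample",
      subtitle = sprintf("%d ratios", nrow(object))
    )
}

#' @export
print.ratio_sample <- function(x, ...) {
  cat(sprintf(
    "<ratio_sample> %s / %s: %d ratios from %s patients\n",
    attr(x, "analyte") %||% "?", attr(x, "subgroup") %||% "All",
    nrow(x), format(attr(x, "n_patients"))
  ))
  NextMethod()
}
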