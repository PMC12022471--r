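#' Box-Cox power transformation
#'
#' Applies the Box-Cox transform `(z^lambda - 1) / lambda` (natural
#' logarithm at `lambda = 0`) to strictly positive values. The transform is
#' continuous in `lambda` at 0 and monotone increasing in `z` for every
#' `lambda`, which is what makes it usable for normalising skewed result-ratio
#' distributions without reordering the sample.
#'
#' @param z Numeric vector of strictly positive values.
#' @param lambda Single finite exponent. `lambda = 0` uses the exact
#'   logarithm branch, not a small-lambda approximation.
#' @return Numeric vector of transformed values, same length as `z`.
#' @examples
#' box_cox(c(0.5, 1, 2), lambda = 0.5)
#' box_cox(exp(1), lambda = 0) # exactly 1
#' @export
box_cox <- function(z, lambda) {
  stopifnot(is.numeric(z), length(lambda) == 1L, is.finite(lambda))
  bad <- !is.na(z) & z <= 0
  if (any(bad)) {
    rlang::abort(sprintf(
      "box_cox() requires strictly positive input; first offending value: %g",
      z[which(bad)[1L]]
    ))
  }
  # expm1 form avoids catastrophic cancellation for lambda near 0
  if (lambda == 0) log(z) else expm1(lambda * log(z)) / lambda
}

#' Gaussian-ratio conversion: transformed-ratio SD to CV percent
#'
#' For two independent measurements drawn from the same positive Gaussian
#' distribution, the ratio `Z = X1/X2` has, near its centre,
#' `sd(Z) ~ sqrt(2) * CV(X)`. Inverting gives the total coefficient of
#' variation of a single measurement from the standard deviation of the
#' (Box-Cox normalised) ratio peak: `CV% = sigma / sqrt(2) * 100`.
#'
#' @param sigma Positive standard deviation of the transformed ratio peak.
#' @return CV of a single measurement, in percent.
#' @seealso [lncv_from_ratio_sigma()] for lognormal parents,
#'   [subtract_cva()] to remove analytical variation.
#' @examples
#' cv_from_ratio_sigma(0.076) # ~5.37 %
#' @export
cv_from_ratio_sigma <- function(sigma) {
  check_sigma(sigma)
  sigma / sqrt(2) * 100
}

#' Lognormal conversion: transformed-ratio SD to ln-CV percent
#'
#' When both measurements come from the same lognormal distribution,
#' `ln Z = ln X1 - ln X2` is exactly Gaussian with SD `sqrt(2) * sigma_x`
#' where `sigma_x` is the log-scale SD of a single measurement. The CV of a
#' lognormal variable is `sqrt(exp(sigma_x^2) - 1) * 100`, so the peak SD
#' converts as `sqrt(exp((sigma / sqrt(2))^2) - 1) * 100`.
#'
#' Always at least as large as the Gaussian-path [cv_from_ratio_sigma()]
#' value, with equality only in the small-sigma limit.
#'
#' @inheritParams cv_from_ratio_sigma
#' @return ln-CV of a single measurement, in percent.
#' @examples
#' lncv_from_ratio_sigma(0.244) # ~17.4 %
#' @export
lncv_from_ratio_sigma <- function(sigma) {
  check_sigma(sigma)
  sx2 <- (sigma / sqrt(2))^2
  out <- sqrt(exp(sx2) - 1) * 100
  if (any(!is.finite(out))) {
    rlang::abort("lncv_from_ratio_sigma() overflowed: sigma is too large for a meaningful ln-CV")
  }
  out
}

#' Log-scale SD that yields a target lognormal CV
#'
#' Closed-form inverse of [lncv_from_ratio_sigma()] on the single-measurement
#' scale: returns `sigma_x` with `sqrt(exp(sigma_x^2) - 1) * 100 = cv`.
#' Used by the simulator to build lognormal parents with a prescribed CV;
#' multiplying by `sqrt(2)` gives the corresponding ratio-peak SD.
#'
#' @param cv Target CV in percent, > 0.
#' @return Log-scale standard deviation of the parent distribution.
#' @examples
#' sigma_for_target_lncv(50) # sqrt(log(1.25))
#' @export
sigma_for_target_lncv <- function(cv) {
  stopifnot(is.numeric(cv), all(cv > 0))
  sqrt(log1p((cv / 100)^2))
}

#' Remove analytical variation in quadrature
#'
#' The total random variation of a single routine result combines
#' within-subject biological variation and analytical imprecision:
#' `CV_Total^2 = CV_I^2 + CV_A^2`. Given a long-term analytical CV from
#' quality-control material, the indirect within-subject estimate is
#' `CV_I = sqrt(CV_Total^2 - CV_A^2)`.
#'
#' @param cv_total Total CV of a single measurement, percent.
#' @param cv_a Long-term analytical CV, percent, with `0 <= cv_a < cv_total`.
#' @return Indirect CV_I in percent. Errors when `cv_a >= cv_total`, i.e.
#'   when analytical noise swamps the biological signal and the estimate is
#'   undefined.
#' @examples
#' subtract_cva(5.374, 3.0)
#' @export
subtract_cva <- function(cv_total, cv_a) {
  stopifnot(
    is.numeric(cv_total), is.numeric(cv_a),
    all(is.finite(cv_total)), all(is.finite(cv_a)), all(cv_a >= 0)
  )
  if (any(cv_a >= cv_total)) {
    rlang::abort(paste0(
      "analytical variation (CV_A = ", format(max(cv_a)), " %) is at or above ",
      "the total CV (", format(min(cv_total)), " %): the within-subject ",
      "estimate is undefined because analytical noise swamps the signal"
    ))
  }
  sqrt(cv_total^2 - cv_a^2)
}

#' Choose the conversion scale for a fitted ratio peak
#'
#' Result ratios do not reveal whether the parent distribution was Gaussian
#' or lognormal, and for small CVs the two conversions agree closely. The
#' Gaussian-ratio approximation degrades above roughly 20 % CV, so by default
#' the lognormal (ln-CV) path is used whenever the Gaussian-path estimate of
#' the total CV exceeds `threshold`; a value exactly at the threshold keeps
#' the Gaussian scale. Callers may override the choice per analyte.
#'
#' @param cv_total_gaussian Gaussian-path total CV estimate, percent.
#' @param threshold Switch-over CV in percent (default 20).
#' @return `"gaussian"` or `"lognormal"`.
#' @examples
#' choose_scale(5.4)  # "gaussian"
#' choose_scale(24.0) # "lognormal"
#' @export
choose_scale <- function(cv_total_gaussian, threshold = 20) {
  stopifnot(is.numeric(cv_total_gaussian), length(threshold) == 1L, threshold > 0)
  ifelse(cv_total_gaussian > threshold, "lognormal", "gaussian")
}

#' Round-half-even display formatting for CV columns
#'
#' Reports carry full precision internally; display values are rounded to
#' `digits` decimals with the IEEE round-half-even rule (base `round()`),
#' one decimal for CV columns and three for the peak SD.
#'
#' @param x Numeric vector.
#' @param digits Decimals to keep (default 1).
#' @return Character vector with a fixed number of decimals.
#' @examples
#' format_cv(4.4587)
#' @export
format_cv <- function(x, digits = 1) {
  formatC(round(x, digits), format = "f", digits = digits)
}

check_sigma <- function(sigma) {
  if (!is.numeric(sigma) || any(!is.finite(sigma)) || any(sigma <= 0)) {
    rlang::abort("`sigma` must be a positive, finite ratio-peak standard deviation")
  }
  invisible(sigma)
}
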