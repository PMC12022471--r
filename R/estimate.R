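# Fit the core at one fixed exponent (used by bootstrap replicates when the
# exponent is pinned to the full-sample estimate).
fit_at_fixed_lambda <- function(z, lambda, config, chi2_scale = 1) {
  final <- fit_core_at_lambda(box_cox(sort(z), lambda), config,
                              expand = TRUE, chi2_scale = chi2_scale)
  structure(
    list(lambda = lambda, mu_t = final$mu, sigma_t = final$sigma,
         score = final$score, n_used = final$n_core, n_ratios = length(z),
         band_final = final$band_final,
         diagnostics = tibble::tibble(lambda = lambda, score = final$score,
                                      sigma = final$sigma, n_core = final$n_core)),
    class = "peak_fit"
  )
}

cv_total_from_fit <- function(sigma_t, scale_used) {
  switch(scale_used,
    gaussian = cv_from_ratio_sigma(sigma_t),
    lognormal = lncv_from_ratio_sigma(sigma_t),
    rlang::abort("scale must be 'gaussian' or 'lognormal'")
  )
}

#' Estimate within-subject biological variation from result ratios
#'
#' Full point-estimation pipeline: fit the central Box-Cox-normal peak,
#' choose the conversion scale (Gaussian-ratio vs lognormal, unless
#' overridden), convert the peak SD to a total CV, and remove the
#' analytical CV in quadrature. Every intermediate (fit, Gaussian-path CV,
#' scale decision) is kept in the returned object.
#'
#' @inheritParams fit_central_peak
#' @param cv_a Long-term analytical CV from quality-control material, in
#'   percent (0 for none).
#' @param scale `"auto"` (default: [choose_scale()] with `threshold`),
#'   `"gaussian"`, or `"lognormal"`.
#' @param threshold Scale switch-over CV in percent, see [choose_scale()].
#' @return Object of class `cv_estimate`: `cv_total`, `cv_i`, `scale_used`,
#'   `cv_a`, `n_ratios`, the underlying `fit`, and (after
#'   [bootstrap_cvi()]) percentile confidence intervals `ci_sigma`,
#'   `ci_cv_i`.
#' @examples
#' set.seed(1)
#' z <- exp(rnorm(5000, 0, sqrt(2) * sigma_for_target_lncv(10)))
#' estimate_cvi(z, cv_a = 3)
#' @export
estimate_cvi <- function(ratios, cv_a, config = fit_config(),
                         scale = c("auto", "gaussian", "lognormal"),
                         threshold = 20) {
  scale <- rlang::arg_match(scale)
  stopifnot(length(cv_a) == 1L, is.finite(cv_a), cv_a >= 0)
  fit <- fit_central_peak(ratios, config)
  cv_gauss <- cv_from_ratio_sigma(fit$sigma_t)
  scale_used <- if (scale == "auto") choose_scale(cv_gauss, threshold) else scale
  cv_total <- cv_total_from_fit(fit$sigma_t, scale_used)
  cv_i <- if (cv_a == 0) cv_total else subtract_cva(cv_total, cv_a)
  structure(
    list(
      cv_total = cv_total, cv_i = cv_i, scale_used = scale_used,
      cv_total_gaussian = cv_gauss, cv_a = cv_a,
      n_ratios = fit$n_ratios, fit = fit,
      ci_sigma = c(NA_real_, NA_real_), ci_cv_i = c(NA_real_, NA_real_),
      n_boot = 0L, n_boot_failed = 0L, ci_unreliable = FALSE
    ),
    class = "cv_estimate"
  )
}

#' Percentile-bootstrap confidence intervals for the indirect CV_I
#'
#' Nonparametric case resampling of the ratio sample: each replicate is
#' resampled with replacement, the central peak is refitted (with the
#' Box-Cox exponent pinned to the full-sample estimate by default, or
#' re-searched when `config$refit_lambda` is `TRUE`), and the replicate SD
#' is pushed through the scale conversion chosen on the full sample and the
#' quadrature subtraction. The 2.5/97.5 percentiles of the replicate
#' distribution form the intervals for the peak SD and the indirect CV_I.
#' Replicates where the analytical CV meets or exceeds the replicate total
#' CV fail, are counted, and (above 10 % of replicates) flag the interval
#' as unreliable. Fully reproducible from `seed`.
#'
#' @inheritParams estimate_cvi
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed driving the resampling.
#' @return A `cv_estimate` whose point estimates come from the full sample
#'   and whose `ci_sigma` / `ci_cv_i` are percentile intervals.
#' @export
bootstrap_cvi <- function(ratios, cv_a, config = fit_config(), n_boot = 1000,
                          seed = 1L, scale = c("auto", "gaussian", "lognormal"),
                          threshold = 20) {
  scale <- rlang::arg_match(scale)
  stopifnot(n_boot >= 1)
  z <- ratio_values(ratios)
  point <- estimate_cvi(z, cv_a, config, scale, threshold)
  lam <- point$fit$lambda

  reps <- withr::with_seed(seed, {
    purrr::map(seq_len(n_boot), function(b) {
      zb <- z[sample.int(length(z), length(z), replace = TRUE)]
      fit_b <- tryCatch(
        if (config$refit_lambda) fit_central_peak(zb, config)
        else fit_at_fixed_lambda(zb, lam, config, chi2_scale = 0.5),
        error = function(e) NULL
      )
      if (is.null(fit_b) || !is.finite(fit_b$sigma_t) || fit_b$sigma_t <= 0) {
        return(tibble::tibble(sigma = NA_real_, cv_i = NA_real_))
      }
      cv_tot_b <- cv_total_from_fit(fit_b$sigma_t, point$scale_used)
      tibble::tibble(
        sigma = fit_b$sigma_t,
        cv_i = if (cv_a < cv_tot_b) sqrt(cv_tot_b^2 - cv_a^2) else NA_real_
      )
    }) |> purrr::list_rbind()
  })

  n_failed <- sum(is.na(reps$cv_i))
  point$ci_sigma <- unname(stats::quantile(reps$sigma, c(0.025, 0.975), na.rm = TRUE))
  point$ci_cv_i <- unname(stats::quantile(reps$cv_i, c(0.025, 0.975), na.rm = TRUE))
  point$n_boot <- as.integer(n_boot)
  point$n_boot_failed <- as.integer(n_failed)
  point$ci_unreliable <- n_failed > 0.10 * n_boot
  if (point$ci_unreliable) {
    rlang::warn(sprintf(
      "%d of %d bootstrap replicates failed (CV_A at or above replicate CV_Total); the interval is unreliable",
      n_failed, n_boot
    ))
  }
  point
}

#' @export
print.cv_estimate <- function(x, ...) {
  cat(sprintf(
    "<cv_estimate> CV_Total = %s %%, indirect CV_I = %s %% (%s scale, CV_A = %s %%, n = %d)\n",
    format_cv(x$cv_total), format_cv(x$cv_i), x$scale_used,
    format_cv(x$cv_a), x$n_ratios
  ))
  if (x$n_boot > 0) {
    cat(sprintf(
      "  95 %% CI: sigma [%s, %s], CV_I [%s, %s] (%d replicates%s)\n",
      format_cv(x$ci_sigma[1], 3), format_cv(x$ci_sigma[2], 3),
      format_cv(x$ci_cv_i[1]), format_cv(x$ci_cv_i[2]), x$n_boot,
      if (x$ci_unreliable) ", UNRELIABLE" else ""
    ))
  }
  invisible(x)
}

#' Tidy an indirect CV_I estimate
#'
#' @param x A `cv_estimate`.
#' @param ... Ignored.
#' @return One-row tibble with the peak SD, total CV, indirect CV_I,
#'   confidence bounds and scale used.
#' @export
tidy.cv_estimate <- function(x, ...) {
  tibble::tibble(
    n_ratios = x$n_ratios, cv_a = x$cv_a,
    lambda = x$fit$lambda, boxcox_sigma = x$fit$sigma_t,
    sigma_lo = x$ci_sigma[1], sigma_hi = x$ci_sigma[2],
    cv_total = x$cv_total, cv_i = x$cv_i,
    cv_i_lo = x$ci_cv_i[1], cv_i_hi = x$ci_cv_i[2],
    scale_used = x$scale_used
  )
}

#' @rdname tidy.cv_estimate
#' @export
glance.cv_estimate <- function(x, ...) {
  tibble::tibble(
    cv_i = x$cv_i, cv_total = x$cv_total, scale_used = x$scale_used,
    n_ratios = x$n_ratios, n_boot = x$n_boot,
    n_boot_failed = x$n_boot_failed, ci_unreliable = x$ci_unreliable
  )
}
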