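lognormal_sample <- function(cv, n, seed) {
  simulate_ratios("lognormal", cv, n, seed = seed)
}

test_that("the fit is deterministic: identical input and seed give identical results", {
  s <- lognormal_sample(10, 5000, seed = 3)
  f1 <- fit_central_peak(s, fit_config(seed = 11))
  f2 <- fit_central_peak(s, fit_config(seed = 11))
  expect_identical(f1[c("lambda", "mu_t", "sigma_t", "score", "n_used")],
                   f2[c("lambda", "mu_t", "sigma_t", "score", "n_used")])
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(fit_central_peak(rep(1.1, 499)), "at least 500")
  expect_error(fit_central_peak(rep(1.1, 600)), "zero variance")
  expect_error(profile_ml_boxcox_fit(rep(2, 100)), "zero variance")
})

test_that("profile ML finds the log transform for lognormal ratios", {
  s <- lognormal_sample(20, 3e4, seed = 5)
  o <- profile_ml_boxcox_fit(s)
  expect_true(abs(o$lambda) <= 0.1)
  # sigma_z = sqrt(2) * sigma_x exactly for lognormal parents
  expect_equal(o$sigma_t, sqrt(2) * sigma_for_target_lncv(20), tolerance = 0.02)
})

test_that("an exactly normal sample around 1 recovers its SD", {
  set.seed(8)
  z <- 1 + rnorm(3e4, 0, 0.05)
  o <- profile_ml_boxcox_fit(z)
  expect_equal(o$sigma_t, 0.05, tolerance = 0.02)
  f <- fit_central_peak(z)
  expect_equal(f$sigma_t, 0.05, tolerance = 0.03)
})

test_that("replacing every ratio by its reciprocal leaves the lognormal-path CV unchanged", {
  s <- lognormal_sample(15, 3e4, seed = 13)
  f1 <- fit_central_peak(s)
  f2 <- fit_central_peak(1 / ratio_values(s))
  cv1 <- lncv_from_ratio_sigma(f1$sigma_t)
  cv2 <- lncv_from_ratio_sigma(f2$sigma_t)
  expect_equal(cv1, cv2, tolerance = 0.02)
})

test_that("estimate_cvi composes fit, scale choice and quadrature subtraction", {
  s <- lognormal_sample(10, 2e4, seed = 21)
  est0 <- estimate_cvi(s, cv_a = 0)
  expect_equal(est0$cv_i, est0$cv_total)
  expect_equal(est0$scale_used, "gaussian") # 10 % is below the 20 % threshold
  est3 <- estimate_cvi(s, cv_a = 3)
  expect_equal(est3$cv_i, sqrt(est3$cv_total^2 - 9), tolerance = 1e-10)
  expect_true(est3$cv_i < est3$cv_total)
  # per-analyte override is honoured and recorded
  estln <- estimate_cvi(s, cv_a = 3, scale = "lognormal")
  expect_equal(estln$scale_used, "lognormal")
  expect_true(estln$cv_total > est3$cv_total)
  # analytical noise swamping the signal is a hard error
  expect_error(estimate_cvi(s, cv_a = 50), "swamps")
})

test_that("large Gaussian-path estimates switch to the lognormal scale automatically", {
  s <- lognormal_sample(30, 2e4, seed = 33)
  est <- estimate_cvi(s, cv_a = 5)
  expect_equal(est$scale_used, "lognormal")
})

test_that("a single bootstrap replicate yields a degenerate but valid interval", {
  s <- lognormal_sample(10, 3000, seed = 2)
  est <- bootstrap_cvi(s, cv_a = 2, n_boot = 1, seed = 4)
  expect_equal(est$ci_sigma[1], est$ci_sigma[2])
  expect_equal(est$ci_cv_i[1], est$ci_cv_i[2])
  expect_equal(est$n_boot, 1L)
  expect_false(est$ci_unreliable)
})

test_that("bootstrap intervals are reproducible and bracket the point estimate", {
  for (seed in c(1, 7, 19)) {
    s <- lognormal_sample(12, 5000, seed = seed)
    est <- bootstrap_cvi(s, cv_a = 3, n_boot = 200, seed = seed + 100)
    expect_lte(est$ci_cv_i[1], est$cv_i)
    expect_gte(est$ci_cv_i[2], est$cv_i)
    expect_lte(est$ci_sigma[1], est$fit$sigma_t)
    expect_gte(est$ci_sigma[2], est$fit$sigma_t)
  }
  s <- lognormal_sample(12, 5000, seed = 5)
  e1 <- bootstrap_cvi(s, cv_a = 3, n_boot = 50, seed = 9)
  e2 <- bootstrap_cvi(s, cv_a = 3, n_boot = 50, seed = 9)
  expect_identical(e1$ci_cv_i, e2$ci_cv_i)
})

test_that("bootstrap interval width shrinks roughly as one over root n", {
  # the root-n law is cleanest with the fixed robust band (the adaptive
  # expansion level can differ across n, mixing efficiency regimes)
  cfg <- fit_config(band_expand = numeric(0))
  widths <- purrr::map_dbl(c(2500, 10000, 40000), function(n) {
    s <- lognormal_sample(10, n, seed = n)
    est <- bootstrap_cvi(s, cv_a = 3, config = cfg, n_boot = 200, seed = 1)
    diff(est$ci_cv_i)
  })
  expect_true(all(diff(widths) < 0))
  # factor ~2 per 4x n; allow generous slack around it
  expect_gt(widths[1] / widths[2], 1.3)
  expect_lt(widths[1] / widths[2], 3.1)
  expect_gt(widths[2] / widths[3], 1.3)
  expect_lt(widths[2] / widths[3], 3.1)
  # the default adaptive estimator still shrinks monotonically
  widths_default <- purrr::map_dbl(c(2500, 40000), function(n) {
    s <- lognormal_sample(10, n, seed = n)
    est <- bootstrap_cvi(s, cv_a = 3, n_boot = 200, seed = 1)
    diff(est$ci_cv_i)
  })
  expect_lt(widths_default[2], widths_default[1])
})

test_that("tidy and glance expose the fitted quantities as one-row tibbles", {
  s <- lognormal_sample(10, 2000, seed = 6)
  f <- fit_central_peak(s)
  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_equal(td$sigma_t, f$sigma_t)
  est <- estimate_cvi(s, cv_a = 2)
  te <- tidy(est)
  expect_equal(te$cv_i, est$cv_i)
  expect_equal(glance(est)$n_boot, 0L)
})
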