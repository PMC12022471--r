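test_that("box_cox matches its defining cases and rejects non-positive input", {
  for (lam in c(-2, -0.5, 0, 0.5, 1, 2)) {
    expect_equal(box_cox(1, lam), 0)
  }
  expect_equal(box_cox(2, 1), 1)
  expect_equal(box_cox(exp(1), 0), 1)
  expect_equal(box_cox(c(0.5, 2), -1), c(1 - 1 / 0.5, 1 - 1 / 2))
  expect_error(box_cox(c(1, -3), 0.5), "positive")
  expect_error(box_cox(0, 1), "positive")
})

test_that("box_cox is continuous in lambda at 0", {
  z <- c(0.01, 0.1, 0.5, 1, 2, 10, 100)
  expect_equal(box_cox(z, 1e-8), log(z), tolerance = 1e-6)
  expect_equal(box_cox(z, -1e-8), log(z), tolerance = 1e-6)
})

test_that("box_cox has unit slope at z = 1 so concentrated samples keep their SD", {
  set.seed(42)
  z <- 1 + rnorm(5000, 0, 0.001)
  for (lam in c(-2, -0.5, 0, 0.7, 2)) {
    expect_equal(sd(box_cox(z, lam)), sd(z), tolerance = 1e-3)
  }
})

test_that("Gaussian-ratio conversion follows sigma / sqrt(2) x 100", {
  expect_equal(cv_from_ratio_sigma(0.076), 5.374012, tolerance = 1e-6)
  expect_equal(cv_from_ratio_sigma(sqrt(2)), 100)
  expect_equal(cv_from_ratio_sigma(0.052), 3.676955, tolerance = 1e-6)
  expect_error(cv_from_ratio_sigma(-0.1), "positive")
})

test_that("lognormal conversion matches the closed form and dominates the Gaussian one", {
  # frozen from sqrt(exp((sigma/sqrt(2))^2) - 1) * 100
  expect_equal(lncv_from_ratio_sigma(0.244), 17.38261, tolerance = 1e-5)
  expect_equal(lncv_from_ratio_sigma(0.584), 43.11970, tolerance = 1e-5)
  sig <- c(0.01, 0.05, 0.2, 0.5, 1, 2)
  expect_true(all(lncv_from_ratio_sigma(sig) > cv_from_ratio_sigma(sig)))
  # small-sigma limit: the two scales agree
  expect_equal(lncv_from_ratio_sigma(1e-4) / cv_from_ratio_sigma(1e-4), 1,
               tolerance = 1e-6)
  expect_error(lncv_from_ratio_sigma(60), "overflow")
})

test_that("sigma_for_target_lncv inverts the lognormal conversion", {
  expect_equal(sigma_for_target_lncv(50), sqrt(log(1.25)), tolerance = 1e-12)
  expect_equal(sigma_for_target_lncv(10), sqrt(log(1.01)), tolerance = 1e-12)
  for (cv in seq(5, 50, by = 5)) {
    expect_equal(lncv_from_ratio_sigma(sqrt(2) * sigma_for_target_lncv(cv)), cv,
                 tolerance = 1e-10)
  }
})

test_that("quadrature subtraction of CV_A behaves and round-trips", {
  # frozen from sqrt((0.076 / sqrt(2) * 100)^2 - 3^2)
  expect_equal(subtract_cva(5.374012, 3.0), 4.458699, tolerance = 1e-5)
  expect_equal(subtract_cva(7.3, 0), 7.3)
  expect_error(subtract_cva(3.0, 3.0), "swamps")
  expect_error(subtract_cva(2.0, 3.0), "swamps")
  # monotone in cv_total, antitone in cv_a
  expect_true(subtract_cva(10, 3) < subtract_cva(11, 3))
  expect_true(subtract_cva(10, 4) < subtract_cva(10, 3))
  # quadrature round-trip
  for (ct in c(5, 12, 30)) {
    ci <- subtract_cva(ct, 4)
    expect_equal(sqrt(ci^2 + 4^2), ct, tolerance = 1e-12)
  }
})

test_that("scale selection switches to lognormal above the threshold, tie to gaussian", {
  expect_equal(choose_scale(5.4), "gaussian")
  expect_equal(choose_scale(24.0), "lognormal")
  expect_equal(choose_scale(20.0, threshold = 20), "gaussian")
  expect_equal(choose_scale(c(5, 25)), c("gaussian", "lognormal"))
})

test_that("display formatting rounds half to even at fixed decimals", {
  expect_equal(format_cv(4.4587), "4.5")
  expect_equal(format_cv(3.2062), "3.2")
  expect_equal(format_cv(12.4507), "12.5")
  expect_equal(format_cv(0.0515499, 3), "0.052")
  expect_equal(format_cv(2.25, 1), "2.2") # half to even
})
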