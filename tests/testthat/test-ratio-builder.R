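make_records <- function(patient_id, values, analyte = "x",
                         start = as.POSIXct("2020-01-01", tz = "UTC"),
                         gap_days = 1, sex = "F", age = 50) {
  tibble::tibble(
    patient_id = patient_id, analyte = analyte,
    timestamp = start + (seq_along(values) - 1) * gap_days * 86400,
    value = values, sex = sex, age = age
  )
}

test_that("filter_records subsets by analyte, sex, and inclusive age bounds", {
  recs <- dplyr::bind_rows(
    make_records("a", c(80, 84), analyte = "crea", sex = "F", age = 44),
    make_records("b", c(41, 42), analyte = "alb", sex = "M", age = 61),
    make_records("c", c(90, 91), analyte = "crea", sex = "M", age = 15),
    make_records("d", c(70, 72), analyte = "crea", sex = "M", age = 18)
  )
  out <- filter_records(recs, "crea")
  expect_true(all(out$analyte == "crea"))
  expect_false("c" %in% out$patient_id) # 15-year-old excluded by default
  expect_true("d" %in% out$patient_id) # bound is inclusive
  males <- filter_records(recs, "crea", sex = "M")
  expect_setequal(unique(males$patient_id), "d")
  expect_warning(empty <- filter_records(recs, "nope"), "not present")
  expect_equal(nrow(empty), 0)
})

test_that("consecutive ratios are later over earlier, overlapping by default", {
  recs <- make_records("a", c(2, 3, 1.5))
  s <- build_ratios(recs)
  expect_equal(s$ratio, c(3 / 2, 1.5 / 3))
  expect_equal(n_ratios(s), 2)
  # single-result patients contribute nothing
  lone <- dplyr::bind_rows(make_records("a", 5), make_records("b", 7))
  expect_equal(n_ratios(build_ratios(lone)), 0)
  # 10 patients x 3 results -> 20 ratios (k - 1 each)
  many <- purrr::map(1:10, ~ make_records(paste0("p", .x), c(1, 2, 3))) |>
    dplyr::bind_rows()
  expect_equal(n_ratios(build_ratios(many)), 20)
  expect_equal(n_patients(build_ratios(many)), 10)
})

test_that("ratio count matches the brute-force sum over patients and survives row shuffles", {
  set.seed(7)
  recs <- purrr::map(1:40, function(p) {
    k <- sample(1:6, 1)
    make_records(paste0("p", p), exp(rnorm(k, 0, 0.2)) * 50,
                 gap_days = runif(1, 0.5, 20))
  }) |> dplyr::bind_rows()
  k_per <- table(recs$patient_id)
  expected_n <- sum(pmax(0, k_per - 1))
  s <- build_ratios(recs)
  expect_equal(n_ratios(s), expected_n)
  # input order must not matter
  shuffled <- recs[sample(nrow(recs)), ]
  s2 <- build_ratios(shuffled)
  expect_equal(sort(s2$ratio), sort(s$ratio))
  expect_true(all(s$ratio > 0) && all(is.finite(log(s$ratio))))
})

test_that("duplicate timestamps are tie-broken by ascending value, deterministically", {
  recs <- make_records("a", c(5, 2), gap_days = 0) # same timestamp
  recs <- dplyr::bind_rows(recs, make_records("a", 4, start = recs$timestamp[1] + 86400))
  expect_message(s <- build_ratios(recs), "duplicate")
  expect_equal(s$ratio, c(5 / 2, 4 / 5))
  expect_equal(build_ratios(recs)$ratio, s$ratio) |> suppressMessages()
})

test_that("disjoint pairing and time-gap limits prune pairs as documented", {
  recs <- make_records("a", c(1, 2, 4, 8), gap_days = 2)
  expect_equal(build_ratios(recs, disjoint = TRUE)$ratio, c(2, 2))
  expect_equal(n_ratios(build_ratios(recs, min_gap = 3)), 0)
  expect_equal(n_ratios(build_ratios(recs, max_gap = 1)), 0)
  expect_equal(n_ratios(build_ratios(recs, min_gap = 1, max_gap = 3)), 3)
})

test_that("multi-analyte input and non-positive values are rejected", {
  mixed <- dplyr::bind_rows(
    make_records("a", c(1, 2), analyte = "x"),
    make_records("b", c(1, 2), analyte = "y")
  )
  expect_error(build_ratios(mixed), "single analyte")
  bad <- make_records("a", c(1, -2))
  expect_error(build_ratios(bad), "positive")
})

test_that("sufficiency checks warn on low counts and high pathological fractions", {
  small <- new_sample <- structure(
    tibble::tibble(ratio = rep(1, 4999)),
    class = c("ratio_sample", class(tibble::tibble()))
  )
  expect_warning(msgs <- check_sufficiency(small), "5,000")
  expect_length(msgs, 1)
  ok <- structure(tibble::tibble(ratio = rep(1, 6882)),
                  class = c("ratio_sample", class(tibble::tibble())))
  expect_no_warning(msgs2 <- check_sufficiency(ok, pathological_fraction = 0.1))
  expect_length(msgs2, 0)
  expect_warning(msgs3 <- check_sufficiency(ok, pathological_fraction = 0.35), "30")
  expect_length(msgs3, 1)
  # numeric vectors work too
  expect_warning(check_sufficiency(rnorm(100) + 10), "5,000")
})
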