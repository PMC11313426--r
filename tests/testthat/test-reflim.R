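test_that("pipeline recovers the limits of clean Gaussian data", {
  set.seed(31)
  est <- reflim(rnorm(10000, 100, 10))
  expect_identical(est$model, "gaussian")
  expect_equal(est$lower, 80.4, tolerance = 0.01)   # relative
  expect_equal(est$upper, 119.6, tolerance = 0.01)
  expect_true(est$ci_lower[1L] <= est$lower && est$lower <= est$ci_lower[2L])
  expect_true(est$ci_upper[1L] <= est$upper && est$upper <= est$ci_upper[2L])
  expect_lt(est$lower, est$upper)
})

test_that("pipeline is deterministic for a fixed input", {
  x <- gaussian_mixture(800, seed = 5)
  e1 <- reflim(x)
  e2 <- reflim(x)
  expect_identical(e1[c("lower", "upper", "n_used", "model")],
                   e2[c("lower", "upper", "n_used", "model")])
  expect_equal(e1, e2)
})

test_that("the three-Gaussian mixture yields the expected estimate", {
  est <- reflim(gaussian_mixture(1000, seed = 17), targets = c(80, 120))
  expect_identical(est$model, "gaussian")
  expect_equal(est$upper, 119.6, tolerance = 0.04)
  expect_gt(est$frac_nonpath, 0.82)
  expect_lt(est$frac_nonpath, 0.99)
  expect_s3_class(est$verification, "verification_report")
})

test_that("contamination below 25% moves limits less than the tolerance", {
  set.seed(41)
  n <- 5000
  healthy <- rnorm(n, 100, 10)
  k <- round(0.125 * n)
  mixed <- c(healthy[seq_len(n - 2 * k)], rnorm(k, 70, 15), rnorm(k, 130, 15))
  clean <- reflim(healthy)
  cont <- reflim(mixed)
  pu <- tolerance_range(clean$upper, c(clean$lower, clean$upper))$pu
  expect_lt(abs(cont$lower - clean$lower), pu * clean$lower)
  expect_lt(abs(cont$upper - clean$upper), pu * clean$upper)
})

test_that("input contracts and warnings behave as specified", {
  expect_error(reflim(rlnorm(39)), "insufficient|at least 40")
  expect_error(reflim(c(rnorm(100, 100, 5), -1)), "non-positive")
  set.seed(8)
  est <- reflim(rnorm(150, 100, 10))
  expect_true(any(grepl("inconspicuous", est$warnings)))
  expect_true(any(grepl("calibrated range", est$warnings)))  # n_used < 200
  big <- reflim(rnorm(10000, 100, 10))
  expect_true(any(grepl("calibrated range", big$warnings)))  # n_used > 2000
})

test_that("limits are rounded to a plausible number of digits", {
  expect_equal(unname(adjust_digits(c(80.4213, 119.5877))), c(80.4, 119.6), ignore_attr = TRUE)
  expect_equal(unname(adjust_digits(c(0.1412, 7.0993))), c(0.14, 7.10), ignore_attr = TRUE)
  expect_equal(unname(adjust_digits(c(41.2, 88.3), values = c(40, 61, 88))),
               c(41, 88), ignore_attr = TRUE)
  expect_identical(attr(adjust_digits(c(0.1412, 7.0993)), "digits"), 2L)
  # explicit override wins
  expect_equal(unname(adjust_digits(c(1.23456, 2.34567), digits = 3)),
               c(1.235, 2.346), ignore_attr = TRUE)
})

test_that("metadata from the analyte sample is carried through", {
  x <- analyte_sample(rlnorm(500, 4, 0.4), analyte = "GGT", unit = "U/L",
                      partition = "m")
  est <- reflim(x)
  expect_identical(est$analyte, "GGT")
  expect_identical(est$partition, "m")
  expect_identical(est$model, "lognormal")
})
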