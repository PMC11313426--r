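test_that("Bowley skewness matches closed forms", {
  expect_equal(bowley_skewness(1:5), 0)
  # population value for lognormal(4, 0.4) from exact quartiles
  expect_equal(bowley_pop(function(p) qlnorm(p, 4, 0.4)), 0.1341,
               tolerance = 1e-3)
  set.seed(42)
  b <- bowley_skewness(rlnorm(10000, 4, 0.4))
  expect_lt(abs(b - 0.134), 0.02)
})

test_that("Bowley skewness is location/scale invariant and antisymmetric", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- rlnorm(200, 1, 0.5)
    b <- bowley_skewness(x)
    expect_gte(b, -1); expect_lte(b, 1)
    expect_equal(bowley_skewness(3.7 * x + 11), b, tolerance = 1e-12)
    expect_equal(bowley_skewness(-x), -b, tolerance = 1e-12)
  }
})

test_that("degenerate and too-short samples are rejected", {
  expect_error(bowley_skewness(rep(5, 50)), "interquartile")
  expect_error(bowley_skewness(c(1, 2, 3)), "at least 4")
  expect_error(choose_model(c(rep(1, 39), -1)), "non-positive")
  expect_error(choose_model(rlnorm(39)), "insufficient data")
})

test_that("model choice follows the signed skewness delta", {
  set.seed(1)
  x_norm <- rnorm(1000, 100, 10)
  x_lnorm <- rlnorm(1000, 4, 0.4)
  d_norm <- choose_model(x_norm)
  d_lnorm <- choose_model(x_lnorm)
  expect_s3_class(d_norm, "distribution_decision")
  expect_identical(d_norm$model, "gaussian")
  expect_identical(d_lnorm$model, "lognormal")
  expect_equal(d_norm$delta, d_norm$bowley_raw - d_norm$bowley_log)
  expect_equal(d_lnorm$delta, d_lnorm$bowley_raw - d_lnorm$bowley_log)
  # boundary: delta exactly at the threshold stays gaussian (strict >)
  at_boundary <- choose_model(x_lnorm, threshold = d_lnorm$delta)
  expect_identical(at_boundary$model, "gaussian")
  # delta is scale-invariant (bowley is affine-invariant, log scaling only
  # shifts), so the decision does not depend on the measurement unit
  expect_equal(choose_model(17 * x_lnorm)$delta, d_lnorm$delta,
               tolerance = 1e-10)
  expect_identical(choose_model(0.01 * x_norm)$model, "gaussian")
})

test_that("delta converges to its population value at large n", {
  set.seed(7)
  d1 <- choose_model(rnorm(10000, 100, 10))$delta
  d2 <- choose_model(rlnorm(10000, 4, 0.4))$delta
  expect_equal(d1, delta_pop_normal(100, 10), tolerance = 0.02)
  expect_equal(d2, delta_pop_lognormal(4, 0.4), tolerance = 0.02)
  expect_equal(delta_pop_normal(100, 10), 0.034, tolerance = 0.01)
  expect_equal(delta_pop_lognormal(4, 0.4), 0.134, tolerance = 0.01)
})
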