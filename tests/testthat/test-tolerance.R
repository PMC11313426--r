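test_that("tolerance ranges follow the permissible-uncertainty rule", {
  tr <- tolerance_range(120, c(80, 120))
  s <- log(120 / 80) / 3.92
  expect_equal(tr$pu, 0.33 * (exp(s) - 1), tolerance = 1e-12)
  expect_equal(tr$lo, 115.7, tolerance = 1e-3)
  expect_equal(tr$hi, 124.3, tolerance = 1e-3)
  expect_true(tr$lo < tr$limit && tr$limit < tr$hi)
  # pU is exactly linear in the factor
  expect_equal(tolerance_range(120, c(80, 120), factor = 0.66)$pu, 2 * tr$pu)
  expect_error(tolerance_range(120, c(80, 120), factor = 0), "positive")
  expect_error(tolerance_range(-5, c(80, 120)), "positive")
  expect_error(tolerance_range(120, c(120, 80)), "lower < upper")
})

test_that("traffic-light geometry matches the green/yellow/red semantics", {
  interval <- c(80, 120)
  est <- tolerance_range(119.6, interval)
  # identity: estimate equals target
  expect_identical(interpret_limit(est, tolerance_range(119.6, interval),
                                   "upper")$color, "green")
  # target inside the estimate's zone
  v_green <- interpret_limit(est, tolerance_range(120, interval), "upper")
  expect_identical(v_green$color, "green")
  expect_identical(v_green$text, "within tolerance")
  # target outside the zone, but zones overlap
  just_out <- est$hi / (1 - est$pu) * 0.999
  v_yellow <- interpret_limit(est, tolerance_range(just_out, interval), "upper")
  expect_identical(v_yellow$color, "yellow")
  expect_identical(v_yellow$text, "slightly decreased")  # estimate < target
  # zones completely separated
  v_red <- interpret_limit(tolerance_range(170, interval), est, "upper")
  expect_identical(v_red$color, "red")
  expect_identical(v_red$text, "markedly increased")
  expect_identical(v_red$code, "r")
})

test_that("widening tolerance zones never pushes a verdict toward red", {
  rank <- c(green = 1L, yellow = 2L, red = 3L)
  set.seed(13)
  for (i in 1:50) {
    e_lim <- runif(1, 50, 150)
    t_lim <- runif(1, 50, 150)
    pu <- runif(1, 0.01, 0.3)
    v <- interpret_limit(tolerance_range(e_lim, pu = pu),
                         tolerance_range(t_lim, pu = pu), "upper")
    v_wide <- interpret_limit(tolerance_range(e_lim, pu = pu * 2),
                              tolerance_range(t_lim, pu = pu * 2), "upper")
    expect_lte(rank[[v_wide$color]], rank[[v$color]])
  }
})

test_that("direct quantiles use linear-interpolation percentiles", {
  expect_equal(unname(direct_quantiles(1:1000)), c(25.975, 975.025))
  expect_equal(unname(direct_quantiles(rep(7.5, 200))), c(7.5, 7.5))
  set.seed(19)
  q <- direct_quantiles(rnorm(100000))
  expect_equal(unname(q), c(-1.96, 1.96), tolerance = 0.02)
  expect_warning(direct_quantiles(rnorm(50)), "120")
  expect_warning(direct_quantiles(rnorm(30)), "40")
})

test_that("the 20-person guideline check rejects on more than two outliers", {
  inside <- seq(81, 119, 2)  # 20 values within (80, 120)
  expect_identical(as.character(guideline_check(inside, c(80, 120))), "accept")
  two_out <- c(inside[1:18], 60, 140)
  expect_identical(as.character(guideline_check(two_out, c(80, 120))), "accept")
  three_out <- c(inside[1:17], 60, 140, 150)
  res <- guideline_check(three_out, c(80, 120))
  expect_identical(as.character(res), "reject")
  expect_identical(attr(res, "n_outside"), 3L)
  expect_error(guideline_check(1:19, c(0, 100)), "exactly 20")
})

test_that("guideline null rejection rate matches the exact binomial tail", {
  p_exact <- pbinom(2, 20, 0.05, lower.tail = FALSE)
  expect_equal(p_exact, 0.0755, tolerance = 1e-3)
  set.seed(23)
  reps <- 4000
  rejections <- vapply(seq_len(reps), function(i) {
    identical(as.character(
      guideline_check(rnorm(20), c(qnorm(0.025), qnorm(0.975)))), "reject")
  }, logical(1L))
  se <- sqrt(p_exact * (1 - p_exact) / reps)
  expect_equal(mean(rejections), p_exact, tolerance = 3.5 * se / p_exact)
})
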