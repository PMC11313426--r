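test_that("generators are pure functions of parameters and seed", {
  expect_identical(gaussian_mixture(500, seed = 4), gaussian_mixture(500, seed = 4))
  expect_identical(lognormal_sample(500, 2, 0.3, seed = 4),
                   lognormal_sample(500, 2, 0.3, seed = 4))
  expect_identical(livertests_like(100, 30, seed = 4),
                   livertests_like(100, 30, seed = 4))
  expect_false(identical(gaussian_mixture(500, seed = 4),
                         gaussian_mixture(500, seed = 5)))
})

test_that("mixture components have the requested moments", {
  x <- gaussian_mixture(20000, weights = 1, means = 100, sds = 10, seed = 6)
  expect_equal(mean(x), 100, tolerance = 0.01)
  expect_equal(sd(x), 10, tolerance = 0.05)
  expect_error(gaussian_mixture(100, weights = c(0.5, 0.4),
                                means = c(0, 1), sds = c(1, 1)), "sum to 1")
  expect_error(gaussian_mixture(100, weights = c(1), means = 1, sds = -1))
})

test_that("lognormal samples match their population quantiles", {
  x <- lognormal_sample(20000, seed = 8)
  q <- quantile(x, c(0.025, 0.975), names = FALSE)
  expect_equal(q[1L], exp(-1.96), tolerance = 0.05)
  expect_equal(q[2L], exp(1.96), tolerance = 0.05)
  # degenerate spread collapses onto exp(meanlog)
  y <- lognormal_sample(100, meanlog = 2, sdlog = 1e-9, seed = 8)
  expect_equal(y, rep(exp(2), 100), tolerance = 1e-6)
  expect_equal(bowley_skewness(lognormal_sample(10000, 4, 0.4, seed = 8)),
               0.134, tolerance = 0.15)
})

test_that("the liver-panel table has the expected schema and mix", {
  tab <- livertests_like(seed = 12)
  expect_identical(names(tab),
                   c("category", "age", "sex", "ALB", "ALT", "AST", "BIL",
                     "CHE", "CREA", "GGT", "PROT"))
  expect_identical(nrow(tab), 612L)
  expect_equal(mean(tab$category == "patient"), 0.255, tolerance = 0.01)
  expect_true(all(tab$sex %in% c("f", "m")))
  analytes <- names(tab)[-(1:3)]
  expect_true(all(vapply(tab[analytes], function(v) all(v > 0), logical(1))))
})

test_that("healthy marginals recover their intended working model", {
  intended <- vapply(rivet:::.liver_models, `[[`, character(1L), "model")
  hits <- 0L; total <- 0L
  for (seed in 1:15) {
    tab <- livertests_like(800, 0, seed = 100 + seed)
    for (an in names(intended)) {
      for (s in c("f", "m")) {
        got <- choose_model(tab[[an]][tab$sex == s])$model
        hits <- hits + (got == intended[[an]])
        total <- total + 1L
      }
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("with no patients the indirect and direct estimates agree", {
  tab <- livertests_like(3000, 0, seed = 77)
  for (an in c("ALB", "GGT", "CREA", "PROT")) {
    for (s in c("f", "m")) {
      v <- tab[[an]][tab$sex == s]
      est <- reflim(v)
      direct <- direct_quantiles(v)
      pu <- tolerance_range(est$upper, c(est$lower, est$upper))$pu
      expect_lt(abs(est$lower - direct[1L]), pu * est$lower)
      expect_lt(abs(est$upper - direct[2L]), pu * est$upper)
    }
  }
})

test_that("simulated tables round-trip through CSV", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  tab <- livertests_like(60, 20, seed = 3)
  write_analyte_csv(tab, tmp)
  back <- utils::read.csv(tmp, stringsAsFactors = FALSE)
  expect_identical(names(back), names(tab))
  expect_equal(back$GGT, tab$GGT)
})
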