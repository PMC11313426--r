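#' Monte Carlo calibration of the limit estimator's sampling error
#'
#' The sampling standard deviation of each estimated reference limit (on the
#' standard-normal working scale) is measured by simulation: for each sample
#' size, clean standard-normal samples are pushed through the truncation and
#' Q-Q regression steps and the empirical sd of the lower- and upper-limit
#' estimates is recorded. A one-constant law \eqn{sd(n) = c / \sqrt{n}} is
#' then fitted per side by least squares. The constants feed the closed-form
#' 95% confidence intervals of \code{\link{ci95}}, so no per-dataset
#' simulation or bootstrap is ever needed at analysis time.
#'
#' The package ships constants from a seeded calibration run (2,000
#' replicates per sample size; see
#' \code{system.file("extdata", "ci_calibration.txt", package = "rivet")}).
#' Rerunning with larger \code{reps} sharpens the constants; the functional
#' form is unchanged.
#'
#' @param sample_sizes Integer vector of sample sizes to simulate.
#' @param reps Replicates per sample size (>= 500).
#' @param seed Integer seed; the calibration is a pure function of
#'   (\code{sample_sizes}, \code{reps}, \code{seed}).
#' @return An object of class \code{ci_calibration}: list with
#'   \code{sample_sizes}, \code{sd_lower}, \code{sd_upper} (empirical sds per
#'   size), \code{c_lower}, \code{c_upper} (fitted constants), \code{reps}
#'   and \code{seed}.
#' @examples
#' \donttest{
#' cal <- calibrate_ci95(c(200, 800), reps = 500, seed = 1)
#' cal$c_upper / sqrt(800)   # predicted sd of the upper limit at n = 800
#' }
#' @export
calibrate_ci95 <- function(sample_sizes = seq(200L, 2000L, by = 200L),
                           reps = 2000L, seed = 1L) {
  stopifnot(all(sample_sizes >= 40L), reps >= 500L)
  sample_sizes <- sort(as.integer(sample_sizes))
  set.seed(as.integer(seed))
  sd_lower <- sd_upper <- numeric(length(sample_sizes))
  for (i in seq_along(sample_sizes)) {
    n <- sample_sizes[i]
    lims <- vapply(seq_len(reps), function(r) {
      tr <- iboxplot_truncate(stats::rnorm(n))
      fit <- truncated_qq_fit(tr$kept)
      fit$mean_hat + c(-1.96, 1.96) * fit$sd_hat
    }, numeric(2L))
    sd_lower[i] <- stats::sd(lims[1L, ])
    sd_upper[i] <- stats::sd(lims[2L, ])
  }
  # least-squares c in sd(n) = c / sqrt(n)
  w <- 1 / sqrt(sample_sizes)
  structure(
    list(
      sample_sizes = sample_sizes,
      sd_lower = sd_lower,
      sd_upper = sd_upper,
      c_lower = sum(sd_lower * w) / sum(w^2),
      c_upper = sum(sd_upper * w) / sum(w^2),
      reps = as.integer(reps),
      seed = as.integer(seed)
    ),
    class = "ci_calibration"
  )
}

#' Closed-form 95% confidence intervals for the reference limits
#'
#' On the working (Gaussian) scale each limit estimate is treated as normal
#' with standard error \eqn{\hat\sigma \cdot c / \sqrt{n_{used}}}, where
#' \eqn{c} is the Monte Carlo calibrated constant for that side and
#' \eqn{n_{used}} the number of values surviving truncation. The 95% CI is
#' limit \eqn{\pm 1.96} standard errors; under the lognormal model both
#' bounds are exponentiated, so the CI is asymmetric in analyte units.
#'
#' @param fit A \code{\link{truncated_qq_fit}} result.
#' @param n_used Number of values the fit was computed from.
#' @param model "gaussian" or "lognormal".
#' @param calibration A \code{ci_calibration}; defaults to the shipped
#'   constants.
#' @return List with \code{ci_lower} and \code{ci_upper}, each
#'   \code{c(lo, hi)} in analyte units.
#' @examples
#' tr <- iboxplot_truncate(rnorm(1000, 100, 10))
#' ci95(truncated_qq_fit(tr$kept), length(tr$kept), "gaussian")
#' @export
ci95 <- function(fit, n_used, model = c("gaussian", "lognormal"),
                 calibration = ci_calibration()) {
  model <- match.arg(model)
  stopifnot(inherits(fit, "qq_fit"), inherits(calibration, "ci_calibration"),
            is.numeric(n_used), n_used >= 1)
  rng <- range(calibration$sample_sizes)
  if (n_used < rng[1L] || n_used > rng[2L]) {
    warning(sprintf(
      "n_used = %d outside the calibrated range [%d, %d]: CI is extrapolated",
      as.integer(n_used), rng[1L], rng[2L]), call. = FALSE)
  }
  se <- 1.96 * fit$sd_hat * c(calibration$c_lower, calibration$c_upper) /
    sqrt(n_used)
  lower_w <- fit$mean_hat - 1.96 * fit$sd_hat
  upper_w <- fit$mean_hat + 1.96 * fit$sd_hat
  ci_lower <- lower_w + c(-1, 1) * se[1L]
  ci_upper <- upper_w + c(-1, 1) * se[2L]
  if (model == "lognormal") {
    ci_lower <- exp(ci_lower)
    ci_upper <- exp(ci_upper)
  }
  list(ci_lower = ci_lower, ci_upper = ci_upper)
}

#' Shipped confidence-interval calibration constants
#'
#' Reads (and caches) the calibration constants distributed with the
#' package, produced by a seeded \code{\link{calibrate_ci95}} run recorded in
#' \code{inst/extdata/ci_calibration.txt}.
#'
#' @param path Optional path to an alternative calibration file.
#' @return A \code{ci_calibration} object.
#' @export
ci_calibration <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.rivet_cache$calibration)) return(.rivet_cache$calibration)
    path <- system.file("extdata", "ci_calibration.txt", package = "rivet")
    if (path == "") stop("shipped calibration file not found", call. = FALSE)
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(
    lapply(kv, function(p) as.numeric(strsplit(trimws(p[2L]), ",")[[1L]])),
    vapply(kv, function(p) trimws(p[1L]), character(1L))
  )
  cal <- structure(
    list(
      sample_sizes = as.integer(vals$sample_sizes),
      sd_lower = vals$sd_lower,
      sd_upper = vals$sd_upper,
      c_lower = vals$c_lower,
      c_upper = vals$c_upper,
      reps = as.integer(vals$reps),
      seed = as.integer(vals$seed)
    ),
    class = "ci_calibration"
  )
  if (cache) .rivet_cache$calibration <- cal
  cal
}

#' Write a calibration to the plain-text config format
#'
#' @param calibration A \code{ci_calibration} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_ci_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "ci_calibration"))
  num <- function(x) paste(format(x, digits = 15, scientific = FALSE,
                                  trim = TRUE), collapse = ",")
  writeLines(c(
    "# 95% CI calibration constants for the truncated Q-Q reference-limit pipeline",
    "# sd(limit estimate, working scale) = c_side / sqrt(n); see ?calibrate_ci95",
    "version=1",
    paste0("seed=", calibration$seed),
    paste0("reps=", calibration$reps),
    paste0("sample_sizes=", paste(calibration$sample_sizes, collapse = ",")),
    paste0("sd_lower=", num(calibration$sd_lower)),
    paste0("sd_upper=", num(calibration$sd_upper)),
    paste0("c_lower=", num(calibration$c_lower)),
    paste0("c_upper=", num(calibration$c_upper))
  ), path)
  invisible(path)
}

#' @export
print.ci_calibration <- function(x, ...) {
  cat(sprintf(
    "CI calibration: c_lower = %.3f, c_upper = %.3f (n = %d..%d, %d reps, seed %d)\n",
    x$c_lower, x$c_upper, min(x$sample_sizes), max(x$sample_sizes),
    x$reps, x$seed))
  invisible(x)
}

.rivet_cache <- new.env(parent = emptyenv())
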