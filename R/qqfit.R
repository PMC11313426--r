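#' Truncated normal quantile-quantile regression
#'
#' Estimates the mean and standard deviation of the uncontaminated parent
#' distribution from a truncated sample. 39 sample quantiles at equidistant
#' probabilities \eqn{k/40}, \eqn{k = 1, \dots, 39}, are regressed (ordinary
#' least squares) on the corresponding quantiles of a standard normal
#' restricted to its central 95%, i.e. standard-normal quantiles at
#' probabilities \eqn{0.025 + 0.95 k / 40}. Because the truncated sample
#' represents the parent's central 95%, the regression line has intercept =
#' parent mean and slope = parent sd.
#'
#' The squared correlation of the 39 quantile pairs is reported as a
#' linearity diagnostic: clear deviations from a straight line mean the
#' two-model (Gaussian/lognormal) assumption does not hold and a more
#' flexible method should be used. No hard cutoff is enforced; a soft warning
#' is emitted below \code{r2_warn}.
#'
#' @param truncated Numeric vector of truncated values (working scale),
#'   length >= 40.
#' @param r2_warn Warn when the Q-Q correlation r-squared falls below this
#'   value (default 0.95).
#' @return An object of class \code{qq_fit}: a list with \code{mean_hat},
#'   \code{sd_hat}, \code{intercept}, \code{slope}, \code{r_squared} and
#'   \code{pairs} (data frame of the 39 theoretical/sample quantile pairs).
#' @examples
#' tr <- iboxplot_truncate(rnorm(5000, 100, 10))
#' fit <- truncated_qq_fit(tr$kept)
#' c(fit$mean_hat, fit$sd_hat)   # close to (100, 10)
#' @export
truncated_qq_fit <- function(truncated, r2_warn = 0.95) {
  truncated <- as.numeric(truncated)
  if (anyNA(truncated)) stop("'truncated' contains missing values", call. = FALSE)
  if (length(truncated) < 40L) {
    stop("insufficient data: need at least 40 truncated values for the Q-Q fit",
         call. = FALSE)
  }
  k <- seq_len(39L)
  y <- stats::quantile(truncated, probs = k / 40, names = FALSE, type = 7)
  x <- stats::qnorm(0.025 + 0.95 * k / 40)
  fit <- stats::lm.fit(cbind(1, x), y)
  intercept <- unname(fit$coefficients[1L])
  slope <- unname(fit$coefficients[2L])
  if (!is.finite(slope) || slope <= 0) {
    stop("degenerate Q-Q fit: non-positive slope", call. = FALSE)
  }
  r2 <- stats::cor(x, y)^2
  if (is.finite(r2) && r2 < r2_warn) {
    warning(sprintf(
      "Q-Q plot r-squared %.3f < %.2f: distribution model may be inadequate",
      r2, r2_warn), call. = FALSE)
  }
  structure(
    list(
      mean_hat = intercept,
      sd_hat = slope,
      intercept = intercept,
      slope = slope,
      r_squared = r2,
      pairs = data.frame(theoretical = x, sample = y)
    ),
    class = "qq_fit"
  )
}

#' Reference limits from a Q-Q fit
#'
#' Extrapolates the 2.5th and 97.5th percentiles of the parent distribution
#' as \eqn{\hat\mu \pm 1.96 \hat\sigma} on the working scale. Under the
#' lognormal model the working scale is logarithmic and both limits are
#' exponentiated back to analyte units.
#'
#' @param fit A \code{qq_fit} object.
#' @param model "gaussian" or "lognormal".
#' @return Numeric vector \code{c(lower, upper)} in analyte units.
#' @examples
#' tr <- iboxplot_truncate(log(rlnorm(5000)))
#' limits_from_fit(truncated_qq_fit(tr$kept), "lognormal")  # ~ (0.14, 7.1)
#' @export
limits_from_fit <- function(fit, model = c("gaussian", "lognormal")) {
  model <- match.arg(model)
  stopifnot(inherits(fit, "qq_fit"))
  lim <- fit$mean_hat + c(-1.96, 1.96) * fit$sd_hat
  if (model == "lognormal") {
    lim <- exp(lim)
    if (!all(is.finite(lim))) {
      stop("lognormal back-transform overflowed the numeric range",
           call. = FALSE)
    }
  }
  names(lim) <- c("lower", "upper")
  lim
}

#' @export
print.qq_fit <- function(x, ...) {
  cat(sprintf(
    "Truncated Q-Q fit: mean %.4g, sd %.4g (39 quantile pairs, r2 = %.4f)\n",
    x$mean_hat, x$sd_hat, x$r_squared))
  invisible(x)
}
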