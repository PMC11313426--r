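#' Bowley's quartile skewness
#'
#' Robust skewness of the central 50% of a sample,
#' \eqn{(Q_3 + Q_1 - 2 Q_2) / (Q_3 - Q_1)}, bounded in \[-1, 1\]. Because it
#' only looks at the quartiles, it is insensitive to the pathological tails
#' that contaminate routine laboratory data.
#'
#' Quartiles are the linear-interpolation sample quantiles
#' (\code{\link[stats]{quantile}} type 7), used consistently throughout the
#' package.
#'
#' @param values Numeric vector, length >= 4.
#' @return A single number in \[-1, 1\].
#' @examples
#' bowley_skewness(c(1, 2, 3, 4, 5))        # 0: perfectly symmetric
#' bowley_skewness(rlnorm(1000, 4, 0.4))    # right-skewed, > 0
#' @export
bowley_skewness <- function(values) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("'values' contains missing values", call. = FALSE)
  if (length(values) < 4L) {
    stop("need at least 4 values for quartile skewness", call. = FALSE)
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3L] - q[1L]
  if (iqr <= 0) {
    stop("degenerate sample: zero interquartile range", call. = FALSE)
  }
  (q[3L] + q[1L] - 2 * q[2L]) / iqr
}

#' Choose a Gaussian or lognormal working model
#'
#' Computes Bowley's quartile skewness of the raw values and of their natural
#' logarithms. If the difference (raw minus log) exceeds a threshold the raw
#' distribution is markedly right-skewed relative to its log transform and the
#' lognormal model is selected; otherwise the Gaussian model is kept.
#'
#' The difference is signed: a left-skewed sample (negative delta) stays
#' Gaussian, since the lognormal alternative only accounts for right skew.
#' A delta exactly equal to the threshold stays Gaussian (strict inequality).
#'
#' @param values Numeric vector of strictly positive values, length >= 40.
#' @param threshold Decision threshold for the skewness difference
#'   (dimensionless, default 0.05).
#' @return An object of class \code{distribution_decision}: a list with
#'   elements \code{model} ("gaussian" or "lognormal"), \code{bowley_raw},
#'   \code{bowley_log}, \code{delta} and \code{threshold}.
#' @examples
#' choose_model(rnorm(1000, 100, 10))   # gaussian
#' choose_model(rlnorm(1000, 4, 0.4))   # lognormal
#' @export
choose_model <- function(values, threshold = 0.05) {
  values <- validate_positive(values, min_n = 40L)
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  b_raw <- bowley_skewness(values)
  b_log <- bowley_skewness(log(values))
  delta <- b_raw - b_log
  structure(
    list(
      model = if (delta > threshold) "lognormal" else "gaussian",
      bowley_raw = b_raw,
      bowley_log = b_log,
      delta = delta,
      threshold = threshold
    ),
    class = "distribution_decision"
  )
}

#' @export
print.distribution_decision <- function(x, ...) {
  cat("Distribution model: ", x$model, "\n", sep = "")
  cat(sprintf("  Bowley skewness  raw: %.3f  log: %.3f  delta: %.3f (threshold %g)\n",
              x$bowley_raw, x$bowley_log, x$delta, x$threshold))
  invisible(x)
}

# shared input guard: strictly positive, no NA, minimum length
validate_positive <- function(values, min_n = 40L, what = "values") {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  n_bad <- sum(values <= 0)
  if (n_bad > 0L) {
    stop(sprintf("%d non-positive %s found; laboratory results must be > 0",
                 n_bad, what), call. = FALSE)
  }
  if (length(values) < min_n) {
    stop(sprintf("insufficient data: %d %s, need at least %d",
                 length(values), what, min_n), call. = FALSE)
  }
  values
}
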