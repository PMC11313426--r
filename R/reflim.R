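#' Bundle analyte results with their metadata
#'
#' Light container for one analyte's worth of routine results: the positive
#' value vector plus labels used in reports (analyte name, unit, partition
#' such as sex). \code{\link{reflim}} accepts either this container or a
#' bare numeric vector.
#'
#' The container itself only requires positivity; model fitting
#' (\code{\link{reflim}}, \code{\link{choose_model}}) additionally requires
#' at least 40 values.
#'
#' @param values Numeric vector of strictly positive results.
#' @param analyte,unit,partition Labels carried through to reports.
#' @return An object of class \code{analyte_sample}.
#' @examples
#' analyte_sample(rlnorm(500, 4, 0.4), analyte = "GGT", unit = "U/L",
#'                partition = "m")
#' @export
analyte_sample <- function(values, analyte = "analyte", unit = "",
                           partition = "all") {
  values <- validate_positive(values, min_n = 1L)
  structure(
    list(values = values, analyte = analyte, unit = unit,
         partition = partition),
    class = "analyte_sample"
  )
}

#' @export
print.analyte_sample <- function(x, ...) {
  cat(sprintf("<analyte_sample> %s [%s], partition %s: n = %d, range %.4g-%.4g\n",
              x$analyte, x$unit, x$partition, length(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Indirect reference interval estimation
#'
#' Single-command estimation of the central-95% reference interval from
#' mixed routine results (healthy plus an unknown pathological fraction).
#' Three steps run consecutively:
#' \enumerate{
#'   \item model selection by Bowley's quartile skewness
#'     (\code{\link{choose_model}}); under the lognormal model all further
#'     work happens on the natural-log scale;
#'   \item iterative boxplot truncation to the central ~95% of inconspicuous
#'     values (\code{\link{iboxplot_truncate}});
#'   \item extrapolation of the limits from a truncated normal Q-Q
#'     regression (\code{\link{truncated_qq_fit}}), as mean +/- 1.96 sd,
#'     back-transformed for the lognormal model.
#' }
#' Limits are rounded to a plausible number of digits
#' (\code{\link{adjust_digits}}) and equipped with closed-form 95%
#' confidence intervals (\code{\link{ci95}}). A warning flag is attached
#' when fewer than 200 presumably inconspicuous values remain after
#' truncation; 40 values are the absolute minimum. The estimated
#' non-pathological fraction of the input is reported as
#' (n_used / 0.95) / n_input, since the surviving values represent the
#' central 95% of the inconspicuous population.
#'
#' When \code{targets} is supplied the estimate is additionally verified
#' against it: tolerance zones from the permissible uncertainty are placed
#' around both estimated and target limits and each side receives a
#' traffic-light verdict (see \code{\link{verify_limits}}).
#'
#' @param x An \code{\link{analyte_sample}} or a numeric vector of strictly
#'   positive results, n >= 40.
#' @param targets Optional numeric \code{c(lower, upper)} target reference
#'   interval to verify against.
#' @param threshold Skewness-delta threshold for model selection.
#' @param tolerance_factor Permissible-uncertainty factor for verification
#'   zones (see \code{\link{tolerance_range}}).
#' @param max_iter Truncation pass limit.
#' @param digits Decimal places for the reported limits; \code{NULL} (default)
#'   chooses them automatically from the interval width and data resolution.
#' @param n_warn Attach a small-sample warning when fewer values than this
#'   survive truncation (default 200).
#' @param r2_warn Soft warning threshold for Q-Q linearity.
#' @param calibration CI calibration constants (default: shipped).
#' @return An object of class \code{reflim_estimate}; a list whose main
#'   elements are \code{lower}, \code{upper} (rounded limits in analyte
#'   units), \code{ci_lower}, \code{ci_upper}, \code{model}, \code{decision},
#'   \code{truncation}, \code{fit}, \code{n_input}, \code{n_used},
#'   \code{frac_nonpath}, \code{warnings}, and \code{verification} (or
#'   \code{NULL}).
#' @examples
#' x <- gaussian_mixture(1000, seed = 7)
#' est <- reflim(x, targets = c(80, 120))
#' est
#' @export
reflim <- function(x, targets = NULL, threshold = 0.05,
                   tolerance_factor = 0.33, max_iter = 100L, digits = NULL,
                   n_warn = 200L, r2_warn = 0.95,
                   calibration = ci_calibration()) {
  sample <- if (inherits(x, "analyte_sample")) x else analyte_sample(x)
  values <- sample$values
  flags <- character()
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      flags <<- c(flags, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  decision <- choose_model(values, threshold = threshold)
  working <- if (decision$model == "lognormal") log(values) else values

  trunc <- collect(iboxplot_truncate(working, max_iter = max_iter))
  n_used <- length(trunc$kept)
  if (n_used < n_warn) {
    flags <- c(flags, sprintf(
      "only %d presumably inconspicuous values remain after truncation (< %d)",
      n_used, as.integer(n_warn)))
  }

  fit <- collect(truncated_qq_fit(trunc$kept, r2_warn = r2_warn))
  limits_raw <- limits_from_fit(fit, decision$model)
  ci <- collect(ci95(fit, n_used, decision$model, calibration = calibration))

  limits <- adjust_digits(limits_raw, values, digits = digits)
  d <- attr(limits, "digits")
  # keep the rounded limit inside its own (rounded) CI
  ci$ci_lower <- c(min(round(ci$ci_lower[1L], d), limits[1L]),
                   max(round(ci$ci_lower[2L], d), limits[1L]))
  ci$ci_upper <- c(min(round(ci$ci_upper[1L], d), limits[2L]),
                   max(round(ci$ci_upper[2L], d), limits[2L]))

  est <- structure(
    list(
      analyte = sample$analyte, unit = sample$unit,
      partition = sample$partition,
      model = decision$model, decision = decision, truncation = trunc,
      fit = fit,
      lower = unname(limits[1L]), upper = unname(limits[2L]),
      lower_raw = unname(limits_raw[1L]), upper_raw = unname(limits_raw[2L]),
      digits = d,
      ci_lower = ci$ci_lower, ci_upper = ci$ci_upper,
      n_input = length(values), n_used = n_used,
      frac_nonpath = min(1, (n_used / 0.95) / length(values)),
      warnings = flags,
      verification = NULL
    ),
    class = "reflim_estimate"
  )
  if (!is.null(targets)) {
    est$verification <- verify_limits(est, targets, factor = tolerance_factor)
  }
  est
}

#' Verify an estimate against target limits
#'
#' Places permissible-uncertainty tolerance zones around the estimated and
#' the target limits and produces one traffic-light verdict per side. Both
#' zones use the same relative permissible uncertainty, derived from the
#' target interval (the reference standard under verification).
#'
#' @param estimate A \code{reflim_estimate}.
#' @param targets Numeric \code{c(lower, upper)} target interval, both > 0.
#' @param factor Permissible-uncertainty factor (default 0.33).
#' @return An object of class \code{verification_report}: list with
#'   \code{targets}, \code{pu}, per-side tolerance ranges
#'   (\code{estimate_tr}, \code{target_tr}) and \code{verdicts}, plus
#'   \code{status} = the worst color observed.
#' @export
verify_limits <- function(estimate, targets, factor = 0.33) {
  stopifnot(inherits(estimate, "reflim_estimate"),
            is.numeric(targets), length(targets) == 2L)
  if (any(targets <= 0) || targets[1L] >= targets[2L]) {
    stop("'targets' must satisfy 0 < lower < upper", call. = FALSE)
  }
  pu <- tolerance_range(targets[2L], targets, factor = factor)$pu
  est_tr <- list(
    lower = tolerance_range(estimate$lower, pu = pu),
    upper = tolerance_range(estimate$upper, pu = pu)
  )
  tgt_tr <- list(
    lower = tolerance_range(targets[1L], pu = pu),
    upper = tolerance_range(targets[2L], pu = pu)
  )
  verdicts <- list(
    lower = interpret_limit(est_tr$lower, tgt_tr$lower, side = "lower"),
    upper = interpret_limit(est_tr$upper, tgt_tr$upper, side = "upper")
  )
  colors <- c(verdicts$lower$color, verdicts$upper$color)
  status <- if ("red" %in% colors) "red" else
    if ("yellow" %in% colors) "yellow" else "green"
  structure(
    list(targets = c(lower = targets[1L], upper = targets[2L]), pu = pu,
         estimate_tr = est_tr, target_tr = tgt_tr, verdicts = verdicts,
         status = status),
    class = "verification_report"
  )
}

#' Round reference limits to a plausible number of digits
#'
#' Chooses the decimal places d so that the interval width keeps roughly
#' three significant digits, d = max(0, 2 - floor(log10(upper - lower))),
#' and never rounds finer than the resolution actually observed in the data
#' (integer-resolution input yields integer limits).
#'
#' @param limits Numeric \code{c(lower, upper)}, lower < upper.
#' @param values Optional data vector whose observed resolution caps the
#'   decimals.
#' @param digits Override: fix the decimal places directly.
#' @return Rounded \code{c(lower, upper)} with attribute \code{digits}.
#' @examples
#' adjust_digits(c(80.4213, 119.5877))             # (80.4, 119.6)
#' adjust_digits(c(41.2, 88.3), values = c(40, 61, 88))  # (41, 88)
#' @export
adjust_digits <- function(limits, values = NULL, digits = NULL) {
  stopifnot(is.numeric(limits), length(limits) == 2L, limits[1L] < limits[2L])
  if (is.null(digits)) {
    digits <- max(0L, 2L - floor(log10(limits[2L] - limits[1L])))
    if (!is.null(values)) {
      digits <- min(digits, data_decimals(values))
    }
  }
  digits <- as.integer(digits)
  out <- round(limits, digits)
  attr(out, "digits") <- digits
  out
}

# finest number of decimal places observed in the data (capped at 8)
data_decimals <- function(values, cap = 8L) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) return(cap)
  values <- unique(values[seq_len(min(length(values), 1000L))])
  dec <- 0L
  for (d in 0:cap) {
    dec <- d
    if (all(abs(values - round(values, d)) < 1e-9 * pmax(1, abs(values)))) break
  }
  dec
}

#' @export
print.reflim_estimate <- function(x, ...) {
  fmt <- function(v) formatC(v, format = "f", digits = x$digits)
  cat(sprintf("Indirect reference interval for %s%s (%s)\n",
              x$analyte, if (nzchar(x$unit)) paste0(" [", x$unit, "]") else "",
              x$partition))
  cat(sprintf("  model: %s (skewness delta %.3f)\n", x$model,
              x$decision$delta))
  cat(sprintf("  limits: %s - %s   CI95 lower (%s to %s), upper (%s to %s)\n",
              fmt(x$lower), fmt(x$upper),
              fmt(x$ci_lower[1L]), fmt(x$ci_lower[2L]),
              fmt(x$ci_upper[1L]), fmt(x$ci_upper[2L])))
  cat(sprintf("  n = %d, n used = %d, estimated non-pathological fraction %.2f\n",
              x$n_input, x$n_used, x$frac_nonpath))
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  if (!is.null(x$verification)) {
    v <- x$verification
    cat(sprintf("  verification vs target %s - %s (pU = %.3f): %s\n",
                format(v$targets[1L]), format(v$targets[2L]), v$pu, v$status))
    cat(sprintf("    lower: %s (%s)   upper: %s (%s)\n",
                v$verdicts$lower$text, v$verdicts$lower$color,
                v$verdicts$upper$text, v$verdicts$upper$color))
  }
  invisible(x)
}
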