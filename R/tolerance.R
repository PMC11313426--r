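#' Tolerance zone from permissible uncertainty
#'
#' Builds an equivalence zone around a reference limit inside which
#' deviations are considered medically irrelevant. Unlike a confidence
#' interval, the zone does not shrink with sample size: it reflects the
#' permissible uncertainty of the measurand, not sampling noise.
#'
#' The default rule derives an empirical between-subject dispersion from the
#' reference interval itself on the log scale,
#' \eqn{s = (\ln U - \ln L) / 3.92}, sets the permissible relative
#' uncertainty to \eqn{pU = \mathrm{factor} \cdot (e^s - 1)}, and returns
#' \eqn{[\,\mathrm{limit}(1 - pU),\ \mathrm{limit}(1 + pU)\,]}. Wider or more
#' right-skewed intervals therefore get proportionally wider zones. The rule
#' and its factor are deliberately pluggable: any published permissible-
#' uncertainty specification can be substituted by supplying \code{pu}
#' directly.
#'
#' @param limit The reference limit (analyte units, > 0) around which the
#'   zone is built; normally one of the two interval bounds.
#' @param interval Numeric \code{c(lower, upper)} reference interval from
#'   which the dispersion is derived; both > 0, lower < upper.
#' @param factor Fraction of the empirical dispersion that is permissible
#'   (dimensionless, default 0.33, must be > 0).
#' @param pu Optional: supply the permissible relative uncertainty directly,
#'   bypassing the interval-based rule.
#' @return An object of class \code{tolerance_range}: list with
#'   \code{limit}, \code{lo}, \code{hi} and \code{pu}.
#' @examples
#' tolerance_range(120, c(80, 120))   # approx (115.7, 124.3)
#' @export
tolerance_range <- function(limit, interval, factor = 0.33, pu = NULL) {
  stopifnot(is.numeric(limit), length(limit) == 1L, is.finite(limit))
  if (limit <= 0) stop("'limit' must be positive", call. = FALSE)
  if (is.null(pu)) {
    stopifnot(is.numeric(interval), length(interval) == 2L)
    if (any(interval <= 0) || interval[1L] >= interval[2L]) {
      stop("'interval' must satisfy 0 < lower < upper", call. = FALSE)
    }
    if (!is.numeric(factor) || length(factor) != 1L || factor <= 0) {
      stop("'factor' must be a positive number", call. = FALSE)
    }
    s <- (log(interval[2L]) - log(interval[1L])) / 3.92
    pu <- factor * expm1(s)
  } else {
    stopifnot(is.numeric(pu), length(pu) == 1L, pu > 0)
  }
  lo <- max(limit * (1 - pu), limit * .Machine$double.eps)
  structure(
    list(limit = limit, lo = lo, hi = limit * (1 + pu), pu = pu),
    class = "tolerance_range"
  )
}

#' Traffic-light verdict for one reference limit
#'
#' Compares the tolerance zone of an estimated limit with that of a target
#' limit and returns the traffic-light verdict: green when the target limit
#' lies inside the estimate's tolerance zone, yellow when it lies outside but
#' the two zones still overlap, red when the zones are completely separated.
#' The direction (increased/decreased) is the sign of estimate minus target.
#'
#' @param estimate_tr Tolerance range around the estimated limit.
#' @param target_tr Tolerance range around the target limit.
#' @param side "lower" or "upper", carried through to the verdict.
#' @return An object of class \code{limit_verdict}: list with \code{color}
#'   ("green", "yellow" or "red"), \code{code} ("a", "c" or "r" for
#'   accept/check/reject), \code{text} and \code{side}.
#' @examples
#' est <- tolerance_range(119.6, c(80.4, 119.6))
#' interpret_limit(est, tolerance_range(120, c(80, 120)), "upper")  # green
#' interpret_limit(est, tolerance_range(140, c(80, 140)), "upper")  # red
#' @export
interpret_limit <- function(estimate_tr, target_tr,
                            side = c("upper", "lower")) {
  side <- match.arg(side)
  stopifnot(inherits(estimate_tr, "tolerance_range"),
            inherits(target_tr, "tolerance_range"))
  if (target_tr$limit >= estimate_tr$lo && target_tr$limit <= estimate_tr$hi) {
    color <- "green"
  } else if (estimate_tr$lo <= target_tr$hi && target_tr$lo <= estimate_tr$hi) {
    color <- "yellow"
  } else {
    color <- "red"
  }
  direction <- if (estimate_tr$limit >= target_tr$limit) "increased" else "decreased"
  text <- switch(color,
    green = "within tolerance",
    yellow = paste("slightly", direction),
    red = paste("markedly", direction)
  )
  structure(
    list(color = color,
         code = c(green = "a", yellow = "c", red = "r")[[color]],
         text = text, side = side),
    class = "limit_verdict"
  )
}

#' Direct nonparametric reference limits
#'
#' The guideline "gold standard" for data from healthy individuals: the
#' 2.5th and 97.5th sample percentiles, with no distributional assumptions
#' (linear-interpolation quantiles, type 7).
#'
#' @param values Numeric vector of results from reference individuals.
#' @return Numeric \code{c(lower, upper)}.
#' @examples
#' direct_quantiles(rnorm(5000, 100, 10))  # ~ (80.4, 119.6)
#' @export
direct_quantiles <- function(values) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  if (length(values) < 40L) {
    warning("fewer than 40 values: direct percentiles are unreliable",
            call. = FALSE)
  } else if (length(values) < 120L) {
    warning("fewer than 120 values: below the guideline minimum for direct estimation",
            call. = FALSE)
  }
  q <- stats::quantile(values, c(0.025, 0.975), names = FALSE, type = 7)
  names(q) <- c("lower", "upper")
  q
}

#' Simplified 20-person guideline verification
#'
#' The simplified guideline check: with exactly 20 values from healthy
#' individuals, a specified reference interval is rejected when more than
#' two of them fall outside its limits, and accepted otherwise.
#'
#' @param values20 Numeric vector of exactly 20 results from healthy
#'   individuals.
#' @param target Numeric \code{c(lower, upper)} reference interval under
#'   verification.
#' @return "accept" or "reject", with attribute \code{n_outside}.
#' @examples
#' guideline_check(seq(81, 119, 2), c(80, 120))  # accept
#' @export
guideline_check <- function(values20, target) {
  values20 <- as.numeric(values20)
  if (length(values20) != 20L || anyNA(values20)) {
    stop("the guideline check needs exactly 20 non-missing values",
         call. = FALSE)
  }
  stopifnot(is.numeric(target), length(target) == 2L, target[1L] < target[2L])
  k <- sum(values20 < target[1L] | values20 > target[2L])
  structure(if (k > 2L) "reject" else "accept", n_outside = k)
}

#' @export
print.tolerance_range <- function(x, ...) {
  cat(sprintf("Tolerance range: %.4g [%.4g, %.4g] (pU = %.3f)\n",
              x$limit, x$lo, x$hi, x$pu))
  invisible(x)
}

#' @export
print.limit_verdict <- function(x, ...) {
  cat(sprintf("%s limit: %s (%s)\n", x$side, x$text, x$color))
  invisible(x)
}
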