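#' Simulate a Gaussian mixture of healthy and pathological results
#'
#' Draws routine-data-like values from a mixture of Gaussian components.
#' The defaults reproduce the canonical evaluation scenario for indirect
#' methods: 80% normal values around 100 flanked by 10% low values around 70
#' and 10% high values around 125 (sds 10, 15, 15) — e.g. blood glucose in
#' mg/dL. Component counts are multinomial, so the realized mixing
#' proportions fluctuate as they would in real data.
#'
#' @param n Number of values.
#' @param weights Component probabilities (must sum to 1).
#' @param means,sds Component parameters (sds > 0).
#' @param seed Optional integer seed; identical seeds give identical samples.
#' @return Numeric vector of length \code{n}, in random order.
#' @examples
#' x <- gaussian_mixture(1000, seed = 1)
#' @export
gaussian_mixture <- function(n, weights = c(0.8, 0.1, 0.1),
                             means = c(100, 70, 125), sds = c(10, 15, 15),
                             seed = NULL) {
  stopifnot(length(weights) == length(means),
            length(means) == length(sds), all(sds > 0), n >= 1)
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("'weights' must sum to 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  counts <- stats::rmultinom(1L, n, weights)[, 1L]
  x <- unlist(lapply(seq_along(counts), function(i) {
    stats::rnorm(counts[i], means[i], sds[i])
  }), use.names = FALSE)
  sample(x)
}

#' Simulate lognormal laboratory values
#'
#' @param n Number of values.
#' @param meanlog,sdlog Parameters of the lognormal (sdlog > 0).
#' @param seed Optional integer seed.
#' @return Numeric vector of positive values.
#' @examples
#' x <- lognormal_sample(10000, meanlog = 4, sdlog = 0.4, seed = 1)
#' @export
lognormal_sample <- function(n, meanlog = 0, sdlog = 1, seed = NULL) {
  stopifnot(sdlog > 0, n >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  stats::rlnorm(n, meanlog, sdlog)
}

# Synthetic per-analyte, per-sex generating models for liver-panel-like data.
# Parameters are invented to mimic literature-style healthy intervals and the
# qualitative healthy/patient overlap of hepatology panels; they do not
# reproduce any real dataset. model: working distribution of healthy values;
# shift: patient displacement direction/magnitude (log-sd units for
# lognormal, sd units for gaussian); p_affect: chance a patient result is
# displaced at all (patients frequently have normal results).
.liver_models <- list(
  ALB  = list(model = "gaussian",  unit = "g/L",
              f = c(mean = 44, sd = 3),     m = c(mean = 46, sd = 3),
              shift = -2.5, p_affect = 0.6, round = 1),
  ALT  = list(model = "lognormal", unit = "U/L",
              f = c(mean = log(18.7), sd = 0.32),
              m = c(mean = log(22.4), sd = 0.41),
              shift = 1.5, p_affect = 0.7, round = 1),
  AST  = list(model = "lognormal", unit = "U/L",
              f = c(mean = log(18.7), sd = 0.32),
              m = c(mean = log(22.4), sd = 0.41),
              shift = 2.0, p_affect = 0.7, round = 1),
  BIL  = list(model = "lognormal", unit = "umol/L",
              f = c(mean = log(6.5), sd = 0.45),
              m = c(mean = log(7.5), sd = 0.45),
              shift = 2.5, p_affect = 0.6, round = 1),
  CHE  = list(model = "gaussian",  unit = "kU/L",
              f = c(mean = 7.3, sd = 0.9),  m = c(mean = 8.0, sd = 0.95),
              shift = -3.5, p_affect = 0.6, round = 2),
  CREA = list(model = "lognormal", unit = "umol/L",
              f = c(mean = log(64), sd = 0.22),
              m = c(mean = log(76), sd = 0.22),
              shift = 0.5, p_affect = 0.4, round = 1),
  GGT  = list(model = "lognormal", unit = "U/L",
              f = c(mean = log(15.5), sd = 0.47),
              m = c(mean = log(24.5), sd = 0.46),
              shift = 3.0, p_affect = 0.75, round = 1),
  PROT = list(model = "gaussian",  unit = "g/L",
              f = c(mean = 74.5, sd = 4.3), m = c(mean = 74.5, sd = 4.3),
              shift = -1.5, p_affect = 0.5, round = 1)
)

#' Simulate a liver-panel-like multi-analyte table (synthetic)
#'
#' Generates a table shaped like a routine hepatology study: a healthy
#' reference group and a patient group, eight analytes (ALB, ALT, AST, BIL,
#' CHE, CREA, GGT, PROT), sex-specific healthy distributions (Gaussian for
#' tightly regulated analytes, lognormal for enzymes and bilirubin) and
#' directional pathological shifts (enzymes/bilirubin up, albumin and
#' cholinesterase down), scaled by a per-patient severity so that many
#' patient results remain inconspicuous and the two groups overlap at the
#' decision boundary. All parameters are synthetic: they mimic the
#' qualitative geometry of such data, not any real cohort.
#'
#' The default group sizes give a 25.5% pathological fraction
#' (156 / 612).
#'
#' @param n_healthy,n_patient Group sizes (>= 0).
#' @param seed Optional integer seed.
#' @return Data frame with columns \code{category} ("reference"/"patient"),
#'   \code{age}, \code{sex} ("f"/"m") and the eight analyte columns.
#' @examples
#' head(livertests_like(50, 10, seed = 1))
#' @export
livertests_like <- function(n_healthy = 456L, n_patient = 156L, seed = NULL) {
  stopifnot(n_healthy >= 0, n_patient >= 0, n_healthy + n_patient > 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- n_healthy + n_patient
  category <- rep(c("reference", "patient"), c(n_healthy, n_patient))
  sex <- ifelse(stats::runif(n) < 0.39, "f", "m")
  age <- sample(19:77, n, replace = TRUE)
  severity <- ifelse(category == "patient", stats::runif(n), 0)
  out <- data.frame(category = category, age = age, sex = sex,
                    stringsAsFactors = FALSE)
  for (an in names(.liver_models)) {
    mod <- .liver_models[[an]]
    par <- rbind(mod$f, mod$m)[match(sex, c("f", "m")), , drop = FALSE]
    affected <- severity > 0 & stats::runif(n) < mod$p_affect
    loc <- par[, "mean"] +
      ifelse(affected, mod$shift * severity, 0) * par[, "sd"]
    z <- stats::rnorm(n, loc, par[, "sd"])
    v <- if (mod$model == "lognormal") exp(z) else pmax(z, par[, "sd"] / 10)
    out[[an]] <- round(v, mod$round)
  }
  out
}

#' Write a simulated analyte table to CSV
#'
#' @param table Data frame (e.g. from \code{\link{livertests_like}}).
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_analyte_csv <- function(table, path) {
  stopifnot(is.data.frame(table))
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
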