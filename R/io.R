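#' Read analyte values from a CSV file
#'
#' Reads one value column from a CSV with header, optionally filtering rows
#' on other columns (e.g. sex). Blank and non-numeric cells are dropped with
#' a message reporting the count; non-positive values raise an error, since
#' laboratory results must be strictly positive.
#'
#' @param path CSV file path.
#' @param column Name of the value column.
#' @param filters Optional named list; each element keeps only rows whose
#'   column equals the given value, e.g. \code{list(sex = "f")}.
#' @param unit Unit label carried into the returned sample.
#' @return An \code{\link{analyte_sample}}.
#' @export
read_values <- function(path, column, filters = NULL, unit = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("empty file: ", path, call. = FALSE)
  if (!column %in% names(tab)) {
    stop(sprintf("column '%s' not found in %s", column, path), call. = FALSE)
  }
  for (f in names(filters)) {
    if (!f %in% names(tab)) {
      stop(sprintf("filter column '%s' not found in %s", f, path),
           call. = FALSE)
    }
    tab <- tab[tab[[f]] %in% filters[[f]], , drop = FALSE]
  }
  raw <- tab[[column]]
  values <- suppressWarnings(as.numeric(raw))
  n_dropped <- sum(is.na(values))
  if (n_dropped > 0L) {
    message(sprintf("%s/%s: dropped %d blank or non-numeric cell(s)",
                    path, column, n_dropped))
    values <- values[!is.na(values)]
  }
  n_nonpos <- sum(values <= 0)
  if (n_nonpos > 0L) {
    stop(sprintf("%s/%s: %d non-positive value(s); results must be > 0",
                 path, column, n_nonpos), call. = FALSE)
  }
  partition <- if (length(filters)) {
    paste(unlist(filters), collapse = "/")
  } else "all"
  analyte_sample(values, analyte = column, unit = unit,
                 partition = partition)
}

#' Read a target-limit table from CSV
#'
#' Expects the four columns \code{analyte}, \code{partition}, \code{lower},
#' \code{upper}; every row must satisfy 0 < lower < upper.
#'
#' @param path CSV file path.
#' @return Validated data frame of targets.
#' @export
read_targets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("analyte", "partition", "lower", "upper")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("target table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab$lower <- as.numeric(tab$lower)
  tab$upper <- as.numeric(tab$upper)
  bad <- which(!is.finite(tab$lower) | !is.finite(tab$upper) |
                 tab$lower <= 0 | tab$lower >= tab$upper)
  if (length(bad)) {
    stop("invalid target limits (need 0 < lower < upper) in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tab[need]
}

#' Batch verification of reference intervals from CSV files
#'
#' Runs the full estimation and verification pipeline for every row of a
#' target table: the matching value column is extracted from the values CSV
#' (subset by partition when \code{partition_by} is given), the reference
#' interval is estimated indirectly, tolerance zones and traffic-light
#' verdicts against the target limits are computed, and — when the values
#' table has a \code{category} column with at least 20 "reference" rows —
#' the simplified 20-person guideline check is run alongside. A failure in
#' one analyte is logged and does not stop the others.
#'
#' Reports are written as JSON (machine-readable, schema version 1) and TSV
#' (human-readable) to \code{<out_prefix>.json} / \code{<out_prefix>.tsv}.
#'
#' @param values_csv CSV of results (one column per analyte, plus optional
#'   partition/category columns).
#' @param targets_csv CSV of target limits (see \code{\link{read_targets}}).
#' @param out_prefix Path prefix for the two report files; \code{NULL}
#'   writes no files.
#' @param partition_by Optional column name used to subset rows per target
#'   partition ("all" in the target table means no subsetting).
#' @param threshold,tolerance_factor,... Passed to \code{\link{reflim}}.
#' @return Invisibly, the report list; its \code{exit_code} element is 0 if
#'   all verdicts are green, 1 if any yellow, 2 if any red, 3 if any analyte
#'   failed.
#' @export
run_verify <- function(values_csv, targets_csv, out_prefix = NULL,
                       partition_by = NULL, threshold = 0.05,
                       tolerance_factor = 0.33, ...) {
  targets <- read_targets(targets_csv)
  tab <- utils::read.csv(values_csv, stringsAsFactors = FALSE)
  results <- vector("list", nrow(targets))
  for (i in seq_len(nrow(targets))) {
    tg <- targets[i, ]
    sub <- tab
    if (!is.null(partition_by) && tg$partition != "all") {
      sub <- sub[sub[[partition_by]] %in% tg$partition, , drop = FALSE]
    }
    entry <- list(analyte = tg$analyte, partition = tg$partition,
                  target_lower = tg$lower, target_upper = tg$upper)
    res <- tryCatch({
      if (!tg$analyte %in% names(sub)) {
        stop(sprintf("column '%s' not found", tg$analyte), call. = FALSE)
      }
      values <- suppressWarnings(as.numeric(sub[[tg$analyte]]))
      values <- values[!is.na(values)]
      est <- reflim(
        analyte_sample(values, analyte = tg$analyte,
                       partition = tg$partition),
        targets = c(tg$lower, tg$upper), threshold = threshold,
        tolerance_factor = tolerance_factor, ...)
      v <- est$verification
      guideline <- NA_character_
      if ("category" %in% names(sub)) {
        healthy <- suppressWarnings(
          as.numeric(sub[[tg$analyte]][sub$category == "reference"]))
        healthy <- healthy[!is.na(healthy)]
        if (length(healthy) >= 20L) {
          guideline <- as.character(
            guideline_check(healthy[seq_len(20L)], c(tg$lower, tg$upper)))
        }
      }
      c(entry, list(
        status = v$status,
        code = c(green = "a", yellow = "c", red = "r")[[v$status]],
        n = est$n_input, n_used = est$n_used, model = est$model,
        lower = est$lower, upper = est$upper,
        ci_lower = est$ci_lower, ci_upper = est$ci_upper,
        pu = v$pu,
        tolerance_lower = c(v$estimate_tr$lower$lo, v$estimate_tr$lower$hi),
        tolerance_upper = c(v$estimate_tr$upper$lo, v$estimate_tr$upper$hi),
        verdict_lower = v$verdicts$lower[c("color", "code", "text")],
        verdict_upper = v$verdicts$upper[c("color", "code", "text")],
        frac_nonpath = est$frac_nonpath,
        guideline = guideline,
        warnings = est$warnings
      ))
    }, error = function(e) {
      message(sprintf("verification failed for %s (%s): %s",
                      tg$analyte, tg$partition, conditionMessage(e)))
      c(entry, list(status = "failed", error = conditionMessage(e)))
    })
    results[[i]] <- res
  }
  statuses <- vapply(results, `[[`, character(1L), "status")
  exit_code <- if (any(statuses == "failed")) 3L else
    if (any(statuses == "red")) 2L else
      if (any(statuses == "yellow")) 1L else 0L
  report <- list(schema_version = 1L, exit_code = exit_code,
                 results = results)
  if (!is.null(out_prefix)) {
    jsonlite::write_json(report, paste0(out_prefix, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
    utils::write.table(report_to_table(report), paste0(out_prefix, ".tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(report)
}

# flatten a verification report for the TSV rendering
report_to_table <- function(report) {
  rows <- lapply(report$results, function(r) {
    ok <- r$status != "failed"
    data.frame(
      analyte = r$analyte, partition = r$partition,
      status = r$status, code = if (ok) r$code else "",
      n = if (ok) r$n else NA_integer_,
      n_used = if (ok) r$n_used else NA_integer_,
      model = if (ok) r$model else "",
      lower = if (ok) r$lower else NA_real_,
      upper = if (ok) r$upper else NA_real_,
      target_lower = r$target_lower, target_upper = r$target_upper,
      verdict_lower = if (ok) r$verdict_lower$text else "",
      verdict_upper = if (ok) r$verdict_upper$text else "",
      frac_nonpath = if (ok) round(r$frac_nonpath, 3) else NA_real_,
      guideline = if (ok) r$guideline else "",
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
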