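# Aggregation of per-plane evaluation records into study-style summary
# statistics: mean, SD, 95% Student-t confidence interval and labelled
# extremes, with display rounding to 0.1 mm (half away from zero) and full
# precision retained in JSON.

#' 95% confidence interval of the mean (Student t)
#'
#' `mean +/- t(0.975, n-1) * sd / sqrt(n)` with the sample SD (n-1
#' denominator). With the small per-plane samples of a clinical series the
#' t interval is materially wider than the normal one.
#'
#' @param values numeric vector, length >= 2.
#' @return Named vector `c(low, high)` (mm).
#' @export
ci95 <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("need at least 2 values for a confidence interval",
                   call. = FALSE)
  m <- mean(values)
  half <- stats::qt(0.975, n - 1L) * stats::sd(values) / sqrt(n)
  c(low = m - half, high = m + half)
}

#' Summary statistics of a metric over evaluation records
#'
#' Mean, SD, 95% t-CI, and extremes (with the plane labels attaining them)
#' over the non-missing values of one metric column.
#'
#' @param records an `evaluation_records` data frame (or any data frame
#'   with `plane_label` and the metric column).
#' @param metric one of `"esm"`, `"l"`, `"sm"` (columns `esm_mm`, `l_mm`,
#'   `sm_mm`).
#' @return A list of class `summary_stats`: `metric`, `n`, `mean`, `sd`,
#'   `ci95_low`, `ci95_high` (NA when n < 2), `min`, `max`, `min_label`,
#'   `max_label`.
#' @export
summarize_metric <- function(records, metric = c("esm", "l", "sm")) {
  metric <- match.arg(metric)
  col <- paste0(metric, "_mm")
  if (!col %in% names(records)) stop("records lack column ", col, call. = FALSE)
  ok <- !is.na(records[[col]])
  if (!any(ok)) stop("no values available for metric '", metric, "'",
                     call. = FALSE)
  v <- records[[col]][ok]
  lab <- as.character(records$plane_label[ok])
  ci <- if (length(v) >= 2L) ci95(v) else c(low = NA_real_, high = NA_real_)
  structure(list(metric = metric, n = length(v), mean = mean(v),
                 sd = if (length(v) >= 2L) stats::sd(v) else NA_real_,
                 ci95_low = unname(ci["low"]), ci95_high = unname(ci["high"]),
                 min = min(v), max = max(v),
                 min_label = lab[which.min(v)], max_label = lab[which.max(v)]),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("%s (n = %d): mean %.1f mm (95%% CI %.1f to %.1f), min %.1f (%s), max %.1f (%s)\n",
              toupper(x$metric), x$n, round_half_up(x$mean),
              round_half_up(x$ci95_low), round_half_up(x$ci95_high),
              round_half_up(x$min), x$min_label,
              round_half_up(x$max), x$max_label))
  invisible(x)
}

#' Render the per-plane report
#'
#' Writes the per-plane records as a CSV (columns `plane_label`,
#' `desired_margin_mm`, `SM_mm`, `ESM_mm`, `L_mm`, values display-rounded
#' to 0.1 mm, missing margins blank) and a JSON report keeping full
#' precision plus the summary statistics of every metric with data.
#'
#' @param records an `evaluation_records` data frame.
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with the file paths and the summaries.
#' @export
render_report <- function(records, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.1f", round_half_up(x)))
  csv <- data.frame(plane_label = records$plane_label,
                    desired_margin_mm = fmt(records$desired_margin_mm),
                    SM_mm = fmt(records$sm_mm),
                    ESM_mm = fmt(records$esm_mm),
                    L_mm = fmt(records$l_mm),
                    stringsAsFactors = FALSE)
  csv_path <- file.path(dir, "records.csv")
  utils::write.csv(csv, csv_path, row.names = FALSE, quote = FALSE)

  summaries <- list()
  for (m in c("sm", "esm", "l")) {
    s <- tryCatch(summarize_metric(records, m), error = function(e) NULL)
    if (!is.null(s)) summaries[[m]] <- unclass(s)
  }
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(list(records = as.data.frame(records),
                            summary = summaries),
                       json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(list(csv = csv_path, json = json_path, summary = summaries))
}

#' Per-plane accuracy measurements of the reference clinical series
#'
#' Loads the packaged per-plane table of a published 11-patient series of
#' guided pelvic bone tumor resections: for each of the nine evaluable cut
#' planes, the desired safe margin, the achieved surgical margin SM and the
#' location accuracy L (mm). ESM is recomputed as `SM - desired margin`,
#' never stored.
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return An `evaluation_records`-compatible data frame with columns
#'   `plane_label`, `patient`, `desired_margin_mm`, `sm_mm`, `esm_mm`,
#'   `l_mm`.
#' @export
read_series_cuts <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pelvis_series_cuts.csv",
                        package = "pelvicut", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("plane_label", "desired_margin_mm", "sm_mm", "l_mm") %in%
                  names(df)))
  df$plane_label <- as.character(df$plane_label)
  df$esm_mm <- error_in_safe_margin(df$sm_mm, df$desired_margin_mm)
  class(df) <- c("evaluation_records", class(df))
  df
}
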