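#' Read a trace file
#'
#' One trace per file: a two-column CSV `data_point_index,intensity` with a
#' header line. Indices are 1-based and must be consecutive.
#'
#' @param path file path.
#' @param sample_id,locus_id identifiers (defaults derived from the file
#'   name).
#' @param is_reference reference flag.
#' @return a [new_trace()].
#' @export
read_trace <- function(path, sample_id = NULL, locus_id = "locus",
                       is_reference = FALSE) {
  if (!file.exists(path))
    ms_stop("methscreen_io_failure", "trace file not found: %s", path)
  df <- utils::read.csv(path)
  if (ncol(df) < 2L)
    ms_stop("methscreen_io_failure",
            "trace file must have columns data_point_index, intensity: %s", path)
  df <- df[order(df[[1L]]), ]
  if (is.null(sample_id))
    sample_id <- sub("\\.csv$", "", basename(path))
  new_trace(df[[2L]], sample_id = sample_id, locus_id = locus_id,
            is_reference = is_reference)
}

#' Write a trace file
#' @param trace a [new_trace()].
#' @param path output CSV path.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "meth_trace"))
  utils::write.csv(
    data.frame(data_point_index = seq_along(trace$intensities),
               intensity = trace$intensities),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table
#'
#' One row per patient. Required columns: `patient_id`, `set` (pilot /
#' training / validation), `time_months`, `event`; clinical covariates and
#' one `score_<locus>` column per locus are optional. Cells in numeric
#' columns that do not parse become missing, with a warning giving the
#' count. Supplementary spreadsheets must be exported to TSV or CSV first;
#' the `xls` dialect is recognized only to produce a clear error.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return validated cohort data frame.
#' @export
read_cohort_table <- function(path, dialect = c("tsv", "csv", "xls")) {
  dialect <- match.arg(dialect)
  if (dialect == "xls")
    ms_stop("methscreen_io_failure",
            "no XLS reader is available; export the spreadsheet to TSV or CSV")
  if (!file.exists(path))
    ms_stop("methscreen_io_failure", "cohort file not found: %s", path)
  df <- if (dialect == "tsv")
    utils::read.delim(path, na.strings = c("NA", ""), stringsAsFactors = FALSE)
  else utils::read.csv(path, na.strings = c("NA", ""), stringsAsFactors = FALSE)
  if (!nrow(df)) ms_stop("methscreen_empty_table", "cohort table is empty")
  required <- c("patient_id", "set", "time_months", "event")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    ms_stop("methscreen_missing_required_column",
            "cohort table lacks required column(s): %s",
            paste(missing_cols, collapse = ", "))
  numeric_cols <- c("time_months", "event", score_columns(df))
  bad <- 0L
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- bad + sum(is.na(v) & !is.na(df[[col]]))
    df[[col]] <- v
  }
  if (bad > 0L)
    warning(sprintf("%d unparseable numeric cell(s) set to missing", bad))
  df
}

#' Write a cohort table as TSV
#' @param cohort cohort data frame.
#' @param path output path.
#' @export
write_cohort_table <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

report_rows <- function(x) {
  if (inherits(x, "screen_report")) {
    s2 <- x$stage2
    s2$stage <- "training"
    s2$adjusted_p <- NA_real_
    s2$validated <- NA
    s3 <- x$stage3
    if (nrow(s3)) {
      s3$stage <- "validation"
      s3$candidate <- TRUE
      s3$reason <- "stage-2 candidate"
    }
    cols <- c("stage", "locus", "n_used", "cutpoint", "logrank_p", "auc",
              "candidate", "adjusted_p", "validated", "reason")
    rows <- rbind(s2[intersect(cols, names(s2))],
                  if (nrow(s3)) s3[intersect(cols, names(s3))])
    rows[, intersect(cols, names(rows)), drop = FALSE]
  } else if (inherits(x, "cox_fit")) {
    data.frame(term = names(x$coef), coef = unname(x$coef),
               se = unname(x$se), hr = unname(x$hr),
               ci_lower = unname(x$ci_lower), ci_upper = unname(x$ci_upper),
               wald_p = unname(x$wald_p), lrt_p = x$lrt_p, n_used = x$n_used,
               stringsAsFactors = FALSE)
  } else if (inherits(x, "td_roc")) {
    data.frame(cutpoint = x$cutpoints, sens = x$sens, spec = x$spec,
               fpr = x$fpr, auc = x$auc, horizon = x$horizon,
               stringsAsFactors = FALSE)
  } else if (inherits(x, "km_curve")) {
    data.frame(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
               surv = x$surv, stringsAsFactors = FALSE)
  } else ms_stop("methscreen_io_failure", "unsupported report object")
}

#' Write an analysis report as TSV and JSON
#'
#' TSV columns are formatted for reading (p-values to 4 decimals, hazard
#' ratios and AUCs to 2); the JSON file keeps full precision, so reading
#' it back reproduces the computed values exactly.
#'
#' @param x a `screen_report`, `cox_fit`, `td_roc` or `km_curve`.
#' @param path_prefix output path without extension; `<prefix>.tsv` and
#'   `<prefix>.json` are written.
#' @return the two paths, invisibly.
#' @export
write_report <- function(x, path_prefix) {
  rows <- report_rows(x)
  fmt <- rows
  for (col in intersect(c("logrank_p", "adjusted_p", "wald_p", "lrt_p"),
                        names(fmt)))
    fmt[[col]] <- ifelse(is.na(fmt[[col]]), NA, fmt_p(fmt[[col]]))
  for (col in intersect(c("hr", "ci_lower", "ci_upper", "auc"), names(fmt)))
    fmt[[col]] <- ifelse(is.na(fmt[[col]]), NA, fmt_est(fmt[[col]]))
  tsv <- paste0(path_prefix, ".tsv")
  json <- paste0(path_prefix, ".json")
  utils::write.table(fmt, tsv, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NA")
  payload <- if (inherits(x, "screen_report"))
    list(counts = as.list(x$counts), stage1 = x$stage1, stage2 = x$stage2,
         stage3 = x$stage3, config = unclass(x$config))
  else rows
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(tsv = tsv, json = json))
}
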