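#' Configuration for the marker screening cascade
#'
#' @param horizon td-ROC evaluation time, months. Median follow-up in the
#'   emulated study design is well above 60 months in the training arm, so
#'   a 60-month horizon is supported by the data in both arms.
#' @param alpha log-rank significance threshold (strict `<`).
#' @param auc_threshold minimum td-ROC AUC (strict `>`).
#' @param theta stage-1 dispersion threshold on the normalized score scale
#'   (inclusive `>=`); the pilot filter has no quantitative definition in
#'   the assay literature, so this is flagged in every report.
#' @param stage1_stat dispersion statistic: `"range"` (default) or `"sd"`.
#' @param estimator td-ROC estimator variant, `"km"` or `"nne"`.
#' @param ties Cox tie handling.
#' @return a `screen_config` list.
#' @export
screen_config <- function(horizon = 60, alpha = 0.05, auc_threshold = 0.6,
                          theta = 0.2, stage1_stat = c("range", "sd"),
                          estimator = c("km", "nne"),
                          ties = c("efron", "breslow")) {
  stopifnot(horizon > 0, alpha > 0, alpha < 1,
            auc_threshold >= 0, auc_threshold <= 1, theta >= 0)
  structure(list(horizon = horizon, alpha = alpha,
                 auc_threshold = auc_threshold, theta = theta,
                 stage1_stat = match.arg(stage1_stat),
                 estimator = match.arg(estimator), ties = match.arg(ties)),
            class = "screen_config")
}

score_columns <- function(cohort) grep("^score_", names(cohort), value = TRUE)

#' Stage 1: pilot differential-methylation filter
#'
#' Loci whose scores barely vary across the small pilot sample set cannot
#' separate outcome groups and are dropped before any survival testing.
#' A locus passes when its dispersion statistic (range of scores by
#' default) is at least `theta`; the boundary is inclusive.
#'
#' @param pilot_scores data frame or matrix of pilot-sample scores, one
#'   column per locus.
#' @param theta dispersion threshold.
#' @param stat `"range"` or `"sd"`.
#' @return data frame with `locus`, `dispersion`, `pass`.
#' @export
stage1_differential_filter <- function(pilot_scores, theta = 0.2,
                                       stat = c("range", "sd")) {
  stat <- match.arg(stat)
  pilot_scores <- as.data.frame(pilot_scores)
  disp <- vapply(pilot_scores, function(s) {
    s <- s[!is.na(s)]
    if (length(s) < 2L)
      ms_stop("methscreen_insufficient_pilot_data",
              "a locus has fewer than 2 non-missing pilot scores")
    if (stat == "range") diff(range(s)) else stats::sd(s)
  }, numeric(1))
  data.frame(locus = names(pilot_scores), dispersion = unname(disp),
             pass = unname(disp >= theta), stringsAsFactors = FALSE)
}

#' Stage 2: training-set screen
#'
#' For every locus surviving stage 1: dichotomize the training cohort at
#' its own median score and test the two groups by log-rank; compute the
#' td-ROC AUC of the continuous score at the configured horizon. A locus is
#' a candidate when `p < alpha` and `AUC > auc_threshold`, both strict.
#' The continuous score (not the dichotomized group) enters the AUC, since
#' a single cutpoint yields a degenerate one-point ROC.
#'
#' @param training cohort data frame (training rows only) with
#'   `time_months`, `event` and `score_<locus>` columns.
#' @param loci character vector of locus names (without the `score_`
#'   prefix) to test.
#' @param config a [screen_config()].
#' @return data frame with per-locus `n_used`, `cutpoint`, `logrank_p`,
#'   `auc`, `candidate`, `reason`.
#' @export
stage2_training_screen <- function(training, loci, config = screen_config()) {
  if (sum(training$event, na.rm = TRUE) < 1)
    ms_stop("methscreen_degenerate_groups", "training cohort has no events")
  rows <- lapply(loci, function(locus) {
    sc <- training[[paste0("score_", locus)]]
    ok <- stats::complete.cases(training$time_months, training$event, sc)
    out <- data.frame(locus = locus, n_used = sum(ok), cutpoint = NA_real_,
                      logrank_p = NA_real_, auc = NA_real_, candidate = FALSE,
                      reason = "", stringsAsFactors = FALSE)
    res <- tryCatch({
      dich <- dichotomize_at_median(sc[ok])
      lr <- logrank_test(training$time_months[ok], training$event[ok], dich$group)
      roc <- td_roc(training$time_months[ok], training$event[ok], sc[ok],
                    config$horizon, estimator = config$estimator)
      out$cutpoint <- dich$cutpoint
      out$logrank_p <- lr$p.value
      out$auc <- roc$auc
      out$candidate <- lr$p.value < config$alpha & roc$auc > config$auc_threshold
      out$reason <- if (out$candidate) "candidate" else "below thresholds"
      out
    }, methscreen_error = function(e) {
      out$reason <- conditionMessage(e)
      out
    })
    res
  })
  do.call(rbind, rows)
}

#' Bonferroni adjustment
#'
#' Family-wise error control by multiplying the raw p-value by the number
#' of tests, capped at 1.
#'
#' @param p raw p-value(s) in \[0, 1\].
#' @param m number of tests (>= 1).
#' @return adjusted p-value(s), `min(1, m * p)`.
#' @export
bonferroni_adjust <- function(p, m) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    ms_stop("methscreen_invalid_p", "p-values must lie in [0, 1]")
  if (m < 1) ms_stop("methscreen_invalid_p", "number of tests must be >= 1")
  pmin(1, m * p)
}

#' Stage 3: independent validation with Bonferroni correction
#'
#' Each stage-2 candidate is re-tested in the validation cohort:
#' median-dichotomized log-rank using the validation cohort's own median,
#' td-ROC AUC at the same horizon, and a Bonferroni adjustment with `m` the
#' number of candidates carried into validation. The final call is an
#' adjusted p below `alpha`.
#'
#' @param validation validation-cohort data frame.
#' @param candidates character vector of candidate locus names.
#' @param config a [screen_config()].
#' @param training_ids patient ids of the training cohort, used to enforce
#'   disjointness of the two sets.
#' @return data frame with per-candidate validation statistics and calls.
#' @export
stage3_validate <- function(validation, candidates, config = screen_config(),
                            training_ids = NULL) {
  if (!is.null(training_ids)) {
    overlap <- intersect(training_ids, validation$patient_id)
    if (length(overlap))
      ms_stop("methscreen_cohort_overlap",
              "%d patient(s) appear in both training and validation sets",
              length(overlap))
  }
  if (!length(candidates))
    return(data.frame(locus = character(0), n_used = integer(0),
                      cutpoint = numeric(0), logrank_p = numeric(0),
                      auc = numeric(0), adjusted_p = numeric(0),
                      validated = logical(0), stringsAsFactors = FALSE))
  m <- length(candidates)
  rows <- lapply(candidates, function(locus) {
    sc <- validation[[paste0("score_", locus)]]
    ok <- stats::complete.cases(validation$time_months, validation$event, sc)
    dich <- dichotomize_at_median(sc[ok])
    lr <- logrank_test(validation$time_months[ok], validation$event[ok], dich$group)
    roc <- td_roc(validation$time_months[ok], validation$event[ok], sc[ok],
                  config$horizon, estimator = config$estimator)
    adj <- bonferroni_adjust(lr$p.value, m)
    data.frame(locus = locus, n_used = sum(ok), cutpoint = dich$cutpoint,
               logrank_p = lr$p.value, auc = roc$auc, adjusted_p = adj,
               validated = adj < config$alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full three-stage screening cascade
#'
#' Stage 1 filters loci for apparent differential methylation among the
#' pilot samples; stage 2 screens the survivors in the training cohort
#' (which contains the pilot samples by design); stage 3 validates the
#' stage-2 candidates in the independent validation cohort with a
#' Bonferroni correction over the candidate count. Deterministic given the
#' cohort and configuration.
#'
#' @param cohort a cohort data frame with a `set` column partitioning
#'   patients into `pilot`, `training`, `validation` (the training cohort
#'   is `pilot` + `training` rows).
#' @param config a [screen_config()].
#' @return object of class `screen_report` with elements `stage1`,
#'   `stage2`, `stage3`, `counts`, `config`.
#' @export
run_screen <- function(cohort, config = screen_config()) {
  if (!all(c("patient_id", "set", "time_months", "event") %in% names(cohort)))
    ms_stop("methscreen_missing_required_column",
            "cohort needs patient_id, set, time_months, event columns")
  loci_cols <- score_columns(cohort)
  if (!length(loci_cols))
    ms_stop("methscreen_empty_table", "cohort has no score_<locus> columns")
  pilot <- cohort[cohort$set == "pilot", , drop = FALSE]
  training <- cohort[cohort$set %in% c("pilot", "training"), , drop = FALSE]
  validation <- cohort[cohort$set == "validation", , drop = FALSE]
  s1 <- stage1_differential_filter(pilot[loci_cols], theta = config$theta,
                                   stat = config$stage1_stat)
  s1$locus <- sub("^score_", "", s1$locus)
  passed <- s1$locus[s1$pass]
  s2 <- stage2_training_screen(training, passed, config)
  candidates <- s2$locus[s2$candidate]
  s3 <- stage3_validate(validation, candidates, config,
                        training_ids = training$patient_id)
  structure(list(
    stage1 = s1, stage2 = s2, stage3 = s3,
    counts = c(loci = length(loci_cols), stage1_pass = length(passed),
               stage2_candidates = length(candidates),
               validated = sum(s3$validated)),
    config = config,
    note = "stage-1 dispersion threshold theta is an analysis choice, not an assay constant"),
    class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>\n")
  cat(sprintf("  loci tested: %d -> stage 1 pass: %d -> stage 2 candidates: %d -> validated: %d\n",
              x$counts["loci"], x$counts["stage1_pass"],
              x$counts["stage2_candidates"], x$counts["validated"]))
  if (nrow(x$stage3)) {
    cat("  validation results:\n")
    for (i in seq_len(nrow(x$stage3)))
      cat(sprintf("    %s: log-rank p = %s, AUC = %s, Bonferroni p = %s%s\n",
                  x$stage3$locus[i], fmt_p(x$stage3$logrank_p[i]),
                  fmt_est(x$stage3$auc[i]), fmt_p(x$stage3$adjusted_p[i]),
                  if (x$stage3$validated[i]) " *" else ""))
  }
  invisible(x)
}
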