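#' Kaplan-Meier product-limit estimator
#'
#' Estimates the metastasis-free survival function from right-censored
#' follow-up times. Subjects censored at an event time are counted as at
#' risk through that time, the usual convention.
#'
#' @param time positive follow-up times (months to distant metastasis or
#'   last follow-up).
#' @param event event indicator: 1 = distant metastasis observed,
#'   0 = censored.
#' @return object of class `km_curve` with the distinct event times, at-risk
#'   and event counts, and survival estimates.
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1L) ms_stop("methscreen_empty_cohort", "no records supplied")
  stopifnot(length(time) == length(event))
  if (any(!is.finite(time)) || any(time <= 0))
    ms_stop("methscreen_invalid_record", "times must be positive and finite")
  if (!all(event %in% c(0, 1)))
    ms_stop("methscreen_invalid_record", "event indicator must be 0 or 1")
  tt <- sort(unique(time[event == 1]))
  n_risk <- vapply(tt, function(s) sum(time >= s), numeric(1))
  n_event <- vapply(tt, function(s) sum(time == s & event == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(time = tt, n_risk = n_risk, n_event = n_event, surv = surv,
                 n = length(time), n_events = sum(event)),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve
#'
#' Step-function evaluation of `Shat(t)`, right-continuous: the product runs
#' over event times `<= t`. `Shat(0) = 1`.
#'
#' @param km a [km_estimate()] result.
#' @param t evaluation times (vectorized).
#' @return survival probabilities at `t`.
#' @export
km_surv_at <- function(km, t) {
  stopifnot(inherits(km, "km_curve"))
  idx <- findInterval(t, km$time)
  c(1, km$surv)[idx + 1L]
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, events = %d, %d distinct event times\n",
              x$n, x$n_events, length(x$time)))
  invisible(x)
}

# Fast scalar KM survival at a single horizon; used heavily by td_roc where
# a subgroup KM is needed per cutpoint.
km_at_fast <- function(time, event, t) {
  keep <- time <= t & event == 1
  if (!any(keep)) return(1)
  tt <- time[keep]
  u <- sort(unique(tt))
  d <- tabulate(factor(tt, levels = u))
  sorted <- sort(time)
  n_risk <- length(time) - findInterval(u, sorted, left.open = TRUE)
  prod(1 - d / n_risk)
}

# KM survival at `horizon` within the marker-defined subgroup {X > c}
# (direction "gt") or {X <= c} ("le"), for every cutpoint at once. Subjects
# enter the subgroup incrementally as the cutpoint moves, so death and
# at-risk counts on the shared event-time grid are updated rather than
# recomputed, one O(k) pass per cutpoint.
km_subgroup_scan <- function(time, event, marker, horizon, cuts,
                             direction = c("gt", "le")) {
  direction <- match.arg(direction)
  u <- sort(unique(time[event == 1 & time <= horizon]))
  k <- length(u)
  n <- length(time)
  fi <- findInterval(time, u)              # number of grid times <= time_i
  is_death <- event == 1 & time <= horizon # then u[fi] == time_i
  ord <- if (direction == "gt") order(marker, decreasing = TRUE) else order(marker)
  iter <- if (direction == "gt") rev(seq_along(cuts)) else seq_along(cuts)
  inside <- function(x, c0) if (direction == "gt") x > c0 else x <= c0
  d <- numeric(k)     # subgroup deaths at each grid time
  a <- numeric(k)     # a[j]: subgroup members with time strictly below u[j+?]
  added <- 0L
  ptr <- 1L
  surv <- numeric(length(cuts))
  for (i in iter) {
    while (ptr <= n && inside(marker[ord[ptr]], cuts[i])) {
      s <- ord[ptr]
      if (is_death[s]) d[fi[s]] <- d[fi[s]] + 1
      if (fi[s] < k) a[fi[s] + 1L] <- a[fi[s] + 1L] + 1
      added <- added + 1L
      ptr <- ptr + 1L
    }
    if (added == 0L || k == 0L) { surv[i] <- 1; next }
    n_risk <- added - cumsum(a)            # at risk at each grid time
    j <- d > 0
    surv[i] <- prod(1 - d[j] / n_risk[j])
  }
  surv
}

#' Two-sample log-rank test
#'
#' Compares survival between two groups by summing, over the distinct event
#' times, the observed minus hypergeometric-expected events in one group and
#' standardizing by the summed hypergeometric variances; the squared
#' standardized sum is chi-square with 1 degree of freedom under the null.
#'
#' @inheritParams km_estimate
#' @param group two-level grouping (factor, character or logical).
#' @return object of class `logrank_test`: `statistic`, `p.value`,
#'   `observed` and `expected` per group.
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  g <- factor(group)
  if (nlevels(g) != 2L || any(table(g) == 0L))
    ms_stop("methscreen_degenerate_groups",
            "log-rank test needs two non-empty groups (got %d)", nlevels(g))
  if (sum(event) < 1)
    ms_stop("methscreen_degenerate_groups", "no events in either group")
  tt <- sort(unique(time[event == 1]))
  a <- g == levels(g)[1L]
  oa <- ea <- v <- numeric(length(tt))
  for (j in seq_along(tt)) {
    s <- tt[j]
    at_risk <- time >= s
    n_j <- sum(at_risk)
    n_aj <- sum(at_risk & a)
    d_j <- sum(time == s & event == 1)
    oa[j] <- sum(time == s & event == 1 & a)
    ea[j] <- d_j * n_aj / n_j
    v[j] <- if (n_j > 1)
      d_j * (n_aj / n_j) * (1 - n_aj / n_j) * (n_j - d_j) / (n_j - 1) else 0
  }
  vsum <- sum(v)
  stat <- if (vsum > 0) (sum(oa) - sum(ea))^2 / vsum else 0
  structure(list(statistic = stat,
                 p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 observed = c(sum(oa), sum(event) - sum(oa)),
                 expected = c(sum(ea), sum(event) - sum(ea)),
                 groups = levels(g)),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("<logrank_test> chi-square = %.4f (1 df), p = %s\n",
              x$statistic, fmt_p(x$p.value)))
  invisible(x)
}

#' Dichotomize a continuous marker at a cohort median
#'
#' The median methylation score of a designated cohort is the cut point;
#' scores at or below it are "low", above it "high". Ties at the cut point
#' go to the low group, which is deterministic and order independent. Using
#' the training cohort's own median when analyzing training data, and the
#' validation cohort's when validating, mirrors the study design.
#'
#' @param scores marker values to assign to groups.
#' @param cutpoint_scores values whose median defines the cut point;
#'   defaults to `scores` itself.
#' @return list with `cutpoint` and `group` (factor, levels low/high).
#' @export
dichotomize_at_median <- function(scores, cutpoint_scores = scores) {
  cs <- cutpoint_scores[!is.na(cutpoint_scores)]
  if (length(unique(cs)) < 2L)
    ms_stop("methscreen_degenerate_cutpoint",
            "cut-point cohort needs at least two distinct values")
  cut <- stats::median(cs)
  grp <- factor(ifelse(scores > cut, "high", "low"), levels = c("low", "high"))
  if (all(grp[!is.na(grp)] == "low") || all(grp[!is.na(grp)] == "high"))
    ms_stop("methscreen_degenerate_cutpoint",
            "all scores fall on one side of the median cut point")
  list(cutpoint = cut, group = grp)
}

# ---- Cox proportional hazards -----------------------------------------------

# Efron-approximated log partial likelihood, score vector and information
# matrix at beta, for sorted inputs. Breslow is the d = 0 weighting.
cox_loglik <- function(beta, time, event, x, ties = "efron") {
  eta <- drop(x %*% beta)
  w <- exp(eta)
  p <- ncol(x)
  utimes <- sort(unique(time[event == 1]))
  ll <- 0
  grad <- numeric(p)
  info <- matrix(0, p, p)
  for (s in utimes) {
    risk <- time >= s
    dead <- time == s & event == 1
    d <- sum(dead)
    s0 <- sum(w[risk])
    s1 <- colSums(x[risk, , drop = FALSE] * w[risk])
    s2 <- crossprod(x[risk, , drop = FALSE] * sqrt(w[risk]))
    ll <- ll + sum(eta[dead])
    grad <- grad + colSums(x[dead, , drop = FALSE])
    if (ties == "efron" && d > 1) {
      s0d <- sum(w[dead])
      s1d <- colSums(x[dead, , drop = FALSE] * w[dead])
      s2d <- crossprod(x[dead, , drop = FALSE] * sqrt(w[dead]))
      for (l in 0:(d - 1)) {
        f <- l / d
        s0l <- s0 - f * s0d
        s1l <- s1 - f * s1d
        s2l <- s2 - f * s2d
        ll <- ll - log(s0l)
        grad <- grad - s1l / s0l
        info <- info + s2l / s0l - tcrossprod(s1l) / s0l^2
      }
    } else {
      ll <- ll - d * log(s0)
      grad <- grad - d * s1 / s0
      info <- info + d * (s2 / s0 - tcrossprod(s1) / s0^2)
    }
  }
  list(loglik = ll, grad = grad, info = info)
}

#' Cox proportional hazards model
#'
#' Maximizes the Cox partial likelihood by Newton-Raphson with step-halving,
#' using the Efron approximation for tied event times by default. Reports,
#' per term, the hazard ratio `exp(beta)` with a Wald 95% confidence
#' interval `exp(beta +/- 1.96 SE)`, and the likelihood-ratio test of the
#' fitted model against the null. Rows with a missing value in the time,
#' event or any requested covariate are dropped (complete-case analysis per
#' model), and the number of rows actually used is reported.
#'
#' @inheritParams km_estimate
#' @param x numeric covariate matrix or data frame (one column per term);
#'   continuous markers enter per unit of the raw score, binary clinical
#'   factors as 0/1 codes (see [encode_covariates()]).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param tol convergence tolerance on the change in log partial likelihood.
#' @param max_iter maximum Newton-Raphson iterations.
#' @return object of class `cox_fit`.
#' @export
cox_fit <- function(time, event, x, ties = c("efron", "breslow"),
                    tol = 1e-9, max_iter = 100L) {
  ties <- match.arg(ties)
  x <- as.matrix(as.data.frame(x))
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n_input <- length(time)
  cc <- stats::complete.cases(time, event, x)
  time <- time[cc]; event <- event[cc]; x <- x[cc, , drop = FALSE]
  if (sum(event) < 1)
    ms_stop("methscreen_non_identifiable", "no events among complete cases")
  if (any(apply(x, 2, function(col) length(unique(col)) < 2L)))
    ms_stop("methscreen_non_identifiable",
            "a covariate is constant across complete cases")
  p <- ncol(x)
  beta <- numeric(p)
  cur <- cox_loglik(beta, time, event, x, ties)
  ll0 <- cur$loglik
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(cur$info, cur$grad), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)))
      ms_stop("methscreen_non_convergence",
              "singular information matrix at iteration %d", iter)
    # step-halving if the proposed update decreases the partial likelihood
    for (h in 0:20) {
      cand <- beta + step / 2^h
      new <- cox_loglik(cand, time, event, x, ties)
      if (is.finite(new$loglik) && new$loglik >= cur$loglik - 1e-12) break
    }
    delta <- new$loglik - cur$loglik
    beta <- cand
    cur <- new
    if (abs(delta) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    ms_stop("methscreen_non_convergence",
            "Newton-Raphson did not converge in %d iterations", max_iter)
  se <- sqrt(diag(solve(cur$info)))
  z <- stats::qnorm(0.975)
  lrt <- 2 * (cur$loglik - ll0)
  structure(list(
    coef = stats::setNames(drop(beta), colnames(x)),
    se = stats::setNames(se, colnames(x)),
    hr = exp(drop(beta)),
    ci_lower = exp(drop(beta) - z * se),
    ci_upper = exp(drop(beta) + z * se),
    wald_p = 2 * stats::pnorm(-abs(drop(beta) / se)),
    loglik = c(null = ll0, final = cur$loglik),
    lrt_stat = lrt,
    lrt_p = stats::pchisq(lrt, df = p, lower.tail = FALSE),
    n_used = length(time), n_input = n_input, n_events = sum(event),
    ties = ties, iter = iter, converged = converged),
    class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d (of %d), events = %d, ties = %s\n",
              x$n_used, x$n_input, x$n_events, x$ties))
  for (i in seq_along(x$coef))
    cat(sprintf("  %s: HR = %s (95%% CI %s - %s), Wald p = %s\n",
                names(x$coef)[i], fmt_est(x$hr[i]), fmt_est(x$ci_lower[i]),
                fmt_est(x$ci_upper[i]), fmt_p(x$wald_p[i])))
  cat(sprintf("  LRT = %.4f (%d df), p = %s\n", x$lrt_stat, length(x$coef),
              fmt_p(x$lrt_p)))
  invisible(x)
}

# ---- Time-dependent ROC ------------------------------------------------------

# Nearest-neighbour conditional survival S(t | X = x_i) for every subject,
# from a symmetric rank neighbourhood containing a fraction `span` of the
# cohort on each side; used by the smoothed (NNE) estimator variant.
nne_cond_surv <- function(time, event, marker, t, span) {
  n <- length(time)
  r <- rank(marker, ties.method = "first")
  k <- max(1L, floor(span * n))
  vapply(seq_len(n), function(i) {
    nb <- abs(r - r[i]) <= k
    km_at_fast(time[nb], event[nb], t)
  }, numeric(1))
}

#' Time-dependent ROC curve for censored survival data
#'
#' Cumulative/dynamic ROC at horizon `t`: cases are subjects with an event
#' by `t`, controls those event-free beyond `t`. Because case/control status
#' is unknown for subjects censored before `t`, sensitivity and specificity
#' are estimated with Kaplan-Meier plug-ins: with `Shat` the overall KM
#' curve and `Shat_{X>c}` the KM curve within the subgroup above cutpoint
#' `c`,
#' `sens(c, t) = (1 - Shat_{X>c}(t)) P(X>c) / (1 - Shat(t))` and
#' `spec(c, t) = Shat_{X<=c}(t) P(X<=c) / Shat(t)`.
#' The plug-in can leave \[0, 1\]; estimates are clipped. The smoothed
#' nearest-neighbour variant (`estimator = "nne"`) replaces the subgroup KM
#' curves by rank-neighbourhood conditional survival estimates, which
#' guarantees a monotone ROC at the cost of a smoothing span choice.
#'
#' @inheritParams km_estimate
#' @param marker continuous marker (methylation score); higher values are
#'   taken to indicate higher risk.
#' @param horizon evaluation time `t`, in the units of `time` (months).
#' @param estimator `"km"` (default) or `"nne"`.
#' @param span neighbourhood half-fraction for the NNE variant.
#' @return object of class `td_roc`: cutpoints, `sens`, `spec`, `fpr`,
#'   `auc`, `horizon`, `estimator`.
#' @export
td_roc <- function(time, event, marker, horizon, estimator = c("km", "nne"),
                   span = 0.05) {
  estimator <- match.arg(estimator)
  stopifnot(length(time) == length(event), length(time) == length(marker))
  cc <- stats::complete.cases(time, event, marker)
  time <- time[cc]; event <- event[cc]; marker <- marker[cc]
  if (horizon <= 0 || horizon > max(time))
    ms_stop("methscreen_invalid_horizon",
            "horizon must lie in (0, max observed time]")
  if (!any(time <= horizon & event == 1))
    ms_stop("methscreen_no_events_by_horizon", "no events observed by the horizon")
  s_all <- km_at_fast(time, event, horizon)
  if (s_all <= 0)
    ms_stop("methscreen_undefined_survival",
            "overall survival estimate is zero at the horizon")
  cuts <- sort(unique(marker))
  n <- length(time)
  if (estimator == "km") {
    p_hi <- 1 - findInterval(cuts, sort(marker)) / n
    s_hi <- km_subgroup_scan(time, event, marker, horizon, cuts, "gt")
    s_lo <- km_subgroup_scan(time, event, marker, horizon, cuts, "le")
    sens <- (1 - s_hi) * p_hi / (1 - s_all)
    spec <- s_lo * (1 - p_hi) / s_all
  } else {
    cond <- nne_cond_surv(time, event, marker, horizon, span)
    s_smooth <- mean(cond)
    sens <- spec <- numeric(length(cuts))
    for (i in seq_along(cuts)) {
      hi <- marker > cuts[i]
      joint_hi <- sum(cond[hi]) / n            # P(X > c, T > t)
      sens[i] <- (mean(hi) - joint_hi) / (1 - s_smooth)
      spec[i] <- (sum(cond[!hi]) / n) / s_smooth
    }
  }
  sens <- pmin(pmax(sens, 0), 1)
  spec <- pmin(pmax(spec, 0), 1)
  obj <- structure(list(horizon = horizon, cutpoints = cuts, sens = sens,
                        spec = spec, fpr = 1 - spec, estimator = estimator,
                        n = n, n_events_by_horizon = sum(time <= horizon & event == 1)),
                   class = "td_roc")
  obj$auc <- auc_at_horizon(obj)
  obj
}

#' Area under a time-dependent ROC curve
#'
#' Trapezoidal integration over the ROC points sorted by false-positive
#' rate, with the (0,0) and (1,1) corners included.
#'
#' @param tdroc a [td_roc()] result.
#' @return AUC in \[0, 1\].
#' @export
auc_at_horizon <- function(tdroc) {
  stopifnot(inherits(tdroc, "td_roc"))
  fpr <- c(0, tdroc$fpr, 1)
  tpr <- c(0, tdroc$sens, 1)
  # order on rounded coordinates so that float jitter of ~1e-16 in the KM
  # plug-in cannot scramble vertically stacked ROC points
  o <- order(round(fpr, 12), round(tpr, 12))
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' @export
print.td_roc <- function(x, ...) {
  cat(sprintf("<td_roc> horizon = %g, AUC = %s (%s estimator, n = %d, %d events by t)\n",
              x$horizon, fmt_est(x$auc), x$estimator, x$n, x$n_events_by_horizon))
  invisible(x)
}

#' AUC at several horizons
#'
#' Convenience scan reported alongside any single-horizon AUC, since the
#' choice of horizon is a tunable of the analysis.
#'
#' @inheritParams td_roc
#' @param horizons evaluation times (months).
#' @return data frame with `horizon`, `auc`, `n_events_by_horizon`.
#' @export
auc_horizon_scan <- function(time, event, marker,
                             horizons = c(36, 48, 60, 80, 96), ...) {
  horizons <- horizons[horizons <= max(time, na.rm = TRUE)]
  rows <- lapply(horizons, function(h) {
    r <- td_roc(time, event, marker, h, ...)
    data.frame(horizon = h, auc = r$auc,
               n_events_by_horizon = r$n_events_by_horizon)
  })
  do.call(rbind, rows)
}

#' Code clinical covariates as Cox model terms
#'
#' Produces the 0/1 contrasts used in the univariate and pairwise
#' multivariate models: age at surgery (>50 vs <=50 years), tumor stage
#' (T2,T3 vs T1), progesterone receptor status (positive vs negative),
#' endocrine treatment (no vs yes), tumor grade (3 vs 1,2). Missing values
#' propagate as `NA` and are dropped per model by [cox_fit()].
#'
#' @param cohort a cohort data frame (see [read_cohort_table()]) with
#'   columns `age_group`, `t_stage`, `pr_status`, `endocrine`, `grade`.
#' @return data frame of numeric 0/1 columns `age_gt50`, `stage_t2plus`,
#'   `pr_positive`, `endocrine_no`, `grade3`.
#' @export
encode_covariates <- function(cohort) {
  bin <- function(x, one) ifelse(is.na(x), NA_real_, as.numeric(x %in% one))
  data.frame(
    age_gt50 = bin(cohort$age_group, "gt50"),
    stage_t2plus = bin(cohort$t_stage, "T2T3"),
    pr_positive = bin(cohort$pr_status, "positive"),
    endocrine_no = bin(cohort$endocrine, "no"),
    grade3 = bin(cohort$grade, "G3"))
}
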