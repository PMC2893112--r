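test_that("Kaplan-Meier matches the hand product-limit computation", {
  # all events
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # middle time censored: S(1) = 2/3, then only 1 at risk at t = 3
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$time, c(1, 3))
  expect_equal(km2$surv, c(2 / 3, 0))
  expect_equal(km_surv_at(km2, c(0.5, 1, 2.5, 3)), c(1, 2 / 3, 2 / 3, 0))
  # no events: survival stays at 1
  km3 <- km_estimate(c(4, 5, 6), c(0, 0, 0))
  expect_identical(length(km3$time), 0L)
  expect_equal(km_surv_at(km3, c(1, 100)), c(1, 1))
  expect_error(km_estimate(numeric(0), numeric(0)),
               class = "methscreen_empty_cohort")
})

test_that("Kaplan-Meier equals the oracle and survfit on random censored data", {
  skip_if_not_installed("survival")
  set.seed(3)
  for (r in 1:20) {
    n <- sample(10:80, 1)
    time <- round(rexp(n, 0.1), 1) + 0.1  # provoke ties
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) event[1] <- 1
    km <- km_estimate(time, event)
    ora <- oracle_km(time, event)
    expect_equal(km$time, ora$time)
    expect_equal(km$surv, ora$surv)
    sf <- survival::survfit(survival::Surv(time, event) ~ 1)
    expect_equal(km_surv_at(km, sf$time), sf$surv, tolerance = 1e-12)
  }
})

test_that("without censoring Kaplan-Meier is 1 minus the ECDF at event times", {
  set.seed(4)
  time <- rexp(50)
  km <- km_estimate(time, rep(1, 50))
  expect_equal(km_surv_at(km, km$time), 1 - stats::ecdf(time)(km$time))
})

test_that("log-rank statistic matches the hypergeometric-moment oracle", {
  time <- c(1, 2, 3, 4)
  event <- c(1, 1, 1, 1)
  group <- c("A", "A", "B", "B")
  lr <- logrank_test(time, event, group)
  # brute force per event time: E and V from the 2xK hypergeometric moments
  oa <- ea <- v <- 0
  for (s in time) {
    at <- time >= s
    n <- sum(at); na <- sum(at & group == "A"); d <- 1
    oa <- oa + as.numeric(group[time == s] == "A")
    ea <- ea + d * na / n
    if (n > 1) v <- v + d * (na / n) * (1 - na / n) * (n - d) / (n - 1)
  }
  expect_equal(lr$statistic, (oa - ea)^2 / v)

  # identical records in both groups: no separation at any event time
  t2 <- rep(c(2, 5, 9), 2)
  e2 <- rep(c(1, 0, 1), 2)
  g2 <- rep(c("A", "B"), each = 3)
  lr2 <- logrank_test(t2, e2, g2)
  expect_equal(lr2$statistic, 0)
  expect_equal(lr2$p.value, 1)

  expect_error(logrank_test(c(1, 2), c(1, 1), c("A", "A")),
               class = "methscreen_degenerate_groups")
  expect_error(logrank_test(c(1, 2), c(0, 0), c("A", "B")),
               class = "methscreen_degenerate_groups")
})

test_that("log-rank is label-invariant and matches survdiff", {
  skip_if_not_installed("survival")
  set.seed(8)
  for (r in 1:10) {
    n <- sample(20:80, 1)
    time <- round(rexp(n, 0.1), 1) + 0.1
    event <- rbinom(n, 1, 0.7)
    group <- sample(c("A", "B"), n, replace = TRUE)
    if (sum(event) == 0 || length(unique(group)) < 2) next
    lr <- logrank_test(time, event, group)
    swapped <- logrank_test(time, event, ifelse(group == "A", "B", "A"))
    expect_equal(lr$statistic, swapped$statistic)
    sd <- survival::survdiff(survival::Surv(time, event) ~ group)
    expect_equal(lr$statistic, sd$chisq, tolerance = 1e-10)
  }
})

test_that("median dichotomization splits at the cohort median, ties to low", {
  d <- dichotomize_at_median(c(1, 2, 3, 4))
  expect_equal(d$cutpoint, 2.5)
  expect_equal(as.character(d$group), c("low", "low", "high", "high"))
  # score exactly at the cut point goes to the low group
  d2 <- dichotomize_at_median(c(1, 2, 3), cutpoint_scores = c(0, 2, 10, 2))
  expect_equal(d2$cutpoint, 2)
  expect_equal(as.character(d2$group), c("low", "low", "high"))
  expect_error(dichotomize_at_median(rep(0.5, 6)),
               class = "methscreen_degenerate_cutpoint")
})

test_that("td-ROC equals the direct-counting estimator without censoring", {
  set.seed(9)
  n <- 40
  time <- rexp(n, 0.1)
  marker <- runif(n)
  horizon <- stats::median(time)
  roc <- td_roc(time, rep(1, n), marker, horizon)
  for (i in seq_along(roc$cutpoints)) {
    c0 <- roc$cutpoints[i]
    expect_equal(roc$sens[i],
                 sum(marker > c0 & time <= horizon) / sum(time <= horizon))
    expect_equal(roc$spec[i],
                 sum(marker <= c0 & time > horizon) / sum(time > horizon))
  }
})

test_that("a perfectly ranking marker gives AUC 1", {
  set.seed(10)
  time <- sort(rexp(30, 0.1))
  horizon <- (time[15] + time[16]) / 2
  roc <- td_roc(time, rep(1, 30), -time, horizon)
  expect_equal(roc$auc, 1)
})

test_that("sensitivity and specificity stay in [0, 1] under censoring", {
  set.seed(12)
  for (r in 1:25) {
    n <- sample(30:100, 1)
    time <- rexp(n, 0.05)
    event <- rbinom(n, 1, 0.5)
    marker <- runif(n)
    horizon <- stats::quantile(time, 0.6)
    roc <- tryCatch(td_roc(time, event, marker, horizon),
                    methscreen_error = function(e) NULL)
    if (is.null(roc)) next
    expect_true(all(roc$sens >= 0 & roc$sens <= 1))
    expect_true(all(roc$spec >= 0 & roc$spec <= 1))
    expect_true(roc$auc >= 0 && roc$auc <= 1)
  }
})

test_that("td-ROC guards degenerate horizons", {
  time <- c(5, 10, 15)
  expect_error(td_roc(time, c(1, 1, 1), 1:3, 100),
               class = "methscreen_invalid_horizon")
  expect_error(td_roc(time, c(0, 1, 1), 1:3, 4),
               class = "methscreen_no_events_by_horizon")
})

test_that("NNE variant agrees with KM variant on uncensored data", {
  set.seed(13)
  n <- 80
  time <- rexp(n, 0.1)
  marker <- runif(n) + 0.5 * (time < stats::median(time))
  horizon <- stats::median(time)
  km <- td_roc(time, rep(1, n), marker, horizon, estimator = "km")
  nne <- td_roc(time, rep(1, n), marker, horizon, estimator = "nne", span = 0.1)
  expect_true(abs(km$auc - nne$auc) < 0.1)
  expect_true(all(nne$sens >= 0 & nne$sens <= 1))
})

test_that("trapezoid AUC matches hand integration", {
  mk_roc <- function(fpr, sens) {
    structure(list(fpr = fpr, spec = 1 - fpr, sens = sens), class = "td_roc")
  }
  expect_equal(auc_at_horizon(mk_roc(c(0.25, 0.5, 0.75), c(0.25, 0.5, 0.75))), 0.5)
  expect_equal(auc_at_horizon(mk_roc(0, 1)), 1)
  # 5-cutpoint staircase, integrated by hand over the 6 trapezoids
  fpr <- c(0.1, 0.2, 0.4, 0.7, 0.9)
  sens <- c(0.3, 0.5, 0.6, 0.8, 0.95)
  f <- c(0, fpr, 1)
  s <- c(0, sens, 1)
  hand <- sum(diff(f) * (s[-1] + s[-length(s)]) / 2)
  expect_equal(auc_at_horizon(mk_roc(fpr, sens)), hand)
})

test_that("horizon scan reports an AUC per requested horizon", {
  co <- make_toy_cohort(n = 120, beta = 1.5, seed = 21)
  scan <- auc_horizon_scan(co$time, co$event, co$x, horizons = c(10, 20, 30))
  expect_identical(nrow(scan), 3L)
  expect_true(all(scan$auc > 0 & scan$auc < 1))
})
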