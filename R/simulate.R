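#' Parameters for simulating an electropherogram trace
#'
#' The simulated trace is a sum of unit-height Gaussian CpG peaks scaled by
#' per-site methylation levels, plus the constant normalization-tag peak
#' group, all multiplied by a global amplitude factor, with additive
#' Gaussian noise truncated at zero and an optional positional shift. This
#' emulates the structure the scoring pipeline assumes: methylation
#' modulates CpG peak heights, the tag is methylation independent, and
#' amplitude and mobility vary between runs.
#'
#' @param n_cpg_sites number of CpG sites.
#' @param methylation per-site methylation levels in \[0, 1\]; recycled to
#'   `n_cpg_sites`.
#' @param peak_spacing distance between adjacent CpG peaks, data points.
#' @param peak_width Gaussian peak standard deviation, data points.
#' @param cpg_start data-point position of the first CpG peak.
#' @param tag_position centre of the tag peak group.
#' @param tag_amplitude tag peak height before global scaling.
#' @param tag_peak_count number of tag peaks.
#' @param amplitude global amplitude factor `k > 0` (template amount,
#'   injection efficiency).
#' @param noise_sd additive Gaussian noise standard deviation, in the same
#'   arbitrary units as the unscaled signal.
#' @param shift positional shift in data points (mobility offset).
#' @param length trace length in data points.
#' @param seed optional RNG seed for the noise.
#' @return a `trace_sim_params` list.
#' @export
trace_sim_params <- function(n_cpg_sites = 5L, methylation = 1,
                             peak_spacing = 12L, peak_width = 3,
                             cpg_start = 100L, tag_position = 450L,
                             tag_amplitude = 1, tag_peak_count = 3L,
                             amplitude = 1, noise_sd = 0.01, shift = 0L,
                             length = 600L, seed = NULL) {
  methylation <- rep_len(methylation, n_cpg_sites)
  if (any(methylation < 0 | methylation > 1))
    ms_stop("methscreen_invalid_params", "methylation levels must lie in [0, 1]")
  if (amplitude <= 0) ms_stop("methscreen_invalid_params", "amplitude must be > 0")
  last_cpg <- cpg_start + (n_cpg_sites - 1L) * peak_spacing
  if (length < last_cpg + 31L || length < tag_position + 2L * peak_spacing)
    ms_stop("methscreen_invalid_params",
            "trace length must accommodate the tag and all CpG windows")
  structure(list(n_cpg_sites = as.integer(n_cpg_sites),
                 methylation = methylation,
                 peak_spacing = as.integer(peak_spacing), peak_width = peak_width,
                 cpg_start = as.integer(cpg_start),
                 tag_position = as.integer(tag_position),
                 tag_amplitude = tag_amplitude,
                 tag_peak_count = as.integer(tag_peak_count),
                 amplitude = amplitude, noise_sd = noise_sd,
                 shift = as.integer(shift), length = as.integer(length),
                 seed = seed),
            class = "trace_sim_params")
}

#' CpG peak positions programmed into a simulated trace
#' @param params a [trace_sim_params()].
#' @return integer positions (before any shift).
#' @export
sim_cpg_positions <- function(params) {
  params$cpg_start + (seq_len(params$n_cpg_sites) - 1L) * params$peak_spacing
}

#' The amplicon spec matching a trace simulation
#' @param params a [trace_sim_params()].
#' @param locus_id locus identifier.
#' @return an [amplicon_spec()].
#' @export
sim_amplicon_spec <- function(params, locus_id = "locus") {
  amplicon_spec(locus_id, params$n_cpg_sites,
                expected_tag_position = params$tag_position,
                tag_peak_count = params$tag_peak_count,
                peak_spacing = params$peak_spacing,
                peak_width = params$peak_width)
}

#' Simulate an electropherogram trace
#'
#' @param params a [trace_sim_params()].
#' @param sample_id,locus_id identifiers.
#' @param is_reference reference flag passed through to the trace.
#' @return a [new_trace()] object.
#' @export
simulate_trace <- function(params, sample_id = "sim", locus_id = "locus",
                           is_reference = FALSE) {
  stopifnot(inherits(params, "trace_sim_params"))
  x <- seq_len(params$length)
  signal <- numeric(params$length)
  for (i in seq_len(params$n_cpg_sites))
    signal <- signal + params$methylation[i] *
      gauss_peak(x, params$cpg_start + (i - 1L) * params$peak_spacing,
                 params$peak_width)
  span <- (params$tag_peak_count - 1L) * params$peak_spacing
  tag_centres <- params$tag_position + seq(-span / 2, span / 2,
                                           length.out = params$tag_peak_count)
  for (c0 in tag_centres)
    signal <- signal + params$tag_amplitude * gauss_peak(x, c0, params$peak_width)
  y <- params$amplitude * signal
  if (params$noise_sd > 0)
    y <- y + with_seed(params$seed, stats::rnorm(params$length, 0, params$noise_sd))
  y <- pmax(y, 0)
  if (params$shift != 0L) {
    z <- numeric(params$length)
    s <- params$shift
    if (s > 0L) z[(1L + s):params$length] <- y[1L:(params$length - s)]
    else z[1L:(params$length + s)] <- y[(1L - s):params$length]
    y <- z
  }
  new_trace(y, sample_id = sample_id, locus_id = locus_id,
            is_reference = is_reference)
}

#' Simulate the fully methylated reference trace
#'
#' The in-silico analogue of artificially methylated control DNA: every
#' CpG site at methylation level 1, no noise, no shift.
#'
#' @inheritParams simulate_trace
#' @return a reference [new_trace()].
#' @export
simulate_reference_trace <- function(params, sample_id = "reference",
                                     locus_id = "locus") {
  p <- params
  p$methylation <- rep(1, p$n_cpg_sites)
  p$noise_sd <- 0
  p$shift <- 0L
  simulate_trace(p, sample_id = sample_id, locus_id = locus_id,
                 is_reference = TRUE)
}

#' Parameters for simulating a patient cohort
#'
#' The cohort emulates the structure of the study population: methylation
#' scores drawn per locus from Beta distributions, event times from an
#' exponential proportional-hazards model whose log hazard is linear in the
#' locus scores and in 0/1 clinical covariates, independent uniform
#' censoring (administrative follow-up truncation), and covariate
#' prevalences and missingness matching the published patient
#' characteristics of an ER+/LNP anthracycline-treated cohort.
#'
#' @param n_pilot,n_training,n_validation set sizes; the pilot samples are
#'   part of the training cohort (`n_training` includes `n_pilot`).
#' @param n_loci number of loci.
#' @param beta per-locus log hazard ratios per unit score; default one
#'   informative locus at `log(3.7)` among nulls.
#' @param shape1,shape2 Beta shape parameters for the score marginals,
#'   recycled per locus. The default is strongly bimodal: tumors tend to
#'   either methylate a differentially methylated promoter or leave it
#'   unmethylated, and a bimodal marginal is the regime in which a
#'   continuous-score hazard ratio near 3.7 per unit coexists with a
#'   time-dependent AUC near 0.7.
#' @param h0 baseline hazard per month.
#' @param c_max censoring horizon: censoring times are uniform on
#'   `[0, c_max]` months.
#' @param covariate_prev named prevalences of the 0/1 clinical covariates.
#' @param gamma named log hazard ratios of the clinical covariates.
#' @param missingness named missingness rates for clinical covariates.
#' @param seed RNG seed.
#' @return a `cohort_sim_params` list.
#' @export
cohort_sim_params <- function(n_pilot = 12L, n_training = 84L,
                              n_validation = 78L, n_loci = 37L,
                              beta = c(log(3.7), rep(0, n_loci - 1L)),
                              shape1 = 0.25, shape2 = 0.30,
                              h0 = 0.0045, c_max = 144,
                              covariate_prev = c(age_gt50 = 0.51,
                                                 stage_t2plus = 0.73,
                                                 pr_positive = 0.815,
                                                 endocrine_yes = 0.37,
                                                 grade3 = 0.56),
                              gamma = c(age_gt50 = 0, stage_t2plus = 0,
                                        pr_positive = 0, endocrine_yes = 0,
                                        grade3 = 0),
                              missingness = c(t_stage = 0.019, grade = 0.17,
                                              endocrine = 0.012),
                              seed = NULL) {
  if (n_training < n_pilot)
    ms_stop("methscreen_invalid_params", "n_training must include the pilot samples")
  if (length(beta) != n_loci)
    ms_stop("methscreen_invalid_params", "beta must have one entry per locus")
  if (h0 <= 0 || c_max <= 0)
    ms_stop("methscreen_invalid_params", "h0 and c_max must be positive")
  if (any(covariate_prev < 0 | covariate_prev > 1) ||
      any(missingness < 0 | missingness > 1))
    ms_stop("methscreen_invalid_params", "probabilities must lie in [0, 1]")
  structure(list(n_pilot = as.integer(n_pilot),
                 n_training = as.integer(n_training),
                 n_validation = as.integer(n_validation),
                 n_loci = as.integer(n_loci), beta = beta,
                 shape1 = rep_len(shape1, n_loci),
                 shape2 = rep_len(shape2, n_loci),
                 h0 = h0, c_max = c_max, covariate_prev = covariate_prev,
                 gamma = gamma, missingness = missingness, seed = seed),
            class = "cohort_sim_params")
}

#' Simulate a patient cohort with known ground truth
#'
#' Draws scores, covariates, proportional-hazards event times and
#' independent censoring per [cohort_sim_params()], assigns set labels
#' (`pilot`, `training`, `validation`), and returns the generating
#' parameters alongside the table so recovery can be tested.
#'
#' @param params a [cohort_sim_params()].
#' @param locus_names optional locus names; default `locus_01`, ...
#' @return list with `cohort` (data frame) and `truth`.
#' @export
simulate_cohort <- function(params, locus_names = NULL) {
  stopifnot(inherits(params, "cohort_sim_params"))
  n <- params$n_training + params$n_validation
  if (is.null(locus_names))
    locus_names <- sprintf("locus_%02d", seq_len(params$n_loci))
  with_seed(params$seed, {
    scores <- vapply(seq_len(params$n_loci), function(g)
      stats::rbeta(n, params$shape1[g], params$shape2[g]), numeric(n))
    colnames(scores) <- locus_names
    pv <- params$covariate_prev
    z <- cbind(age_gt50 = stats::rbinom(n, 1, pv["age_gt50"]),
               stage_t2plus = stats::rbinom(n, 1, pv["stage_t2plus"]),
               pr_positive = stats::rbinom(n, 1, pv["pr_positive"]),
               endocrine_yes = stats::rbinom(n, 1, pv["endocrine_yes"]),
               grade3 = stats::rbinom(n, 1, pv["grade3"]))
    eta <- drop(scores %*% params$beta) +
      drop(z %*% params$gamma[colnames(z)])
    t_event <- stats::rexp(n, rate = params$h0 * exp(eta))
    t_cens <- stats::runif(n, 0, params$c_max)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    miss <- function(x, rate) {
      x[stats::runif(n) < rate] <- NA
      x
    }
    cohort <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      set = c(rep("pilot", params$n_pilot),
              rep("training", params$n_training - params$n_pilot),
              rep("validation", params$n_validation)),
      time_months = time, event = event,
      age_group = ifelse(z[, "age_gt50"] == 1, "gt50", "le50"),
      t_stage = miss(ifelse(z[, "stage_t2plus"] == 1, "T2T3", "T1"),
                     params$missingness["t_stage"]),
      pr_status = ifelse(z[, "pr_positive"] == 1, "positive", "negative"),
      grade = miss(ifelse(z[, "grade3"] == 1, "G3",
                          sample(c("G1", "G2"), n, replace = TRUE,
                                 prob = c(0.1, 0.9))),
                   params$missingness["grade"]),
      endocrine = miss(ifelse(z[, "endocrine_yes"] == 1, "yes", "no"),
                       params$missingness["endocrine"]),
      stringsAsFactors = FALSE)
    sc <- as.data.frame(scores)
    names(sc) <- paste0("score_", locus_names)
    cohort <- cbind(cohort, sc)
    list(cohort = cohort,
         truth = list(beta = stats::setNames(params$beta, locus_names),
                      gamma = params$gamma, h0 = params$h0,
                      c_max = params$c_max))
  })
}

#' Expected censoring fraction of the cohort generative model
#'
#' With event time exponential at rate `lambda = h0 exp(beta X)` and
#' censoring uniform on `[0, c_max]`, the censoring probability given
#' `lambda` is `(1 - exp(-lambda c_max)) / (lambda c_max)`; this integrates
#' it over the Beta score distribution. Quadrature is used for at most one
#' informative locus (the default design); with several, a large fixed-seed
#' Monte Carlo approximation is returned.
#'
#' @param params a [cohort_sim_params()].
#' @return expected fraction of censored subjects (clinical covariate
#'   effects `gamma` assumed zero or included via Monte Carlo).
#' @export
expected_censoring_fraction <- function(params) {
  stopifnot(inherits(params, "cohort_sim_params"))
  pcens <- function(lambda) (1 - exp(-lambda * params$c_max)) / (lambda * params$c_max)
  inf <- which(params$beta != 0)
  if (any(params$gamma != 0) || length(inf) > 1L) {
    lam <- with_seed(986527L, {
      nmc <- 2e5
      sc <- vapply(seq_len(params$n_loci), function(g)
        stats::rbeta(nmc, params$shape1[g], params$shape2[g]), numeric(nmc))
      zeta <- rowSums(vapply(seq_along(params$gamma), function(j)
        stats::rbinom(nmc, 1, params$covariate_prev[j]) * params$gamma[j],
        numeric(nmc)))
      params$h0 * exp(drop(sc %*% params$beta) + zeta)
    })
    return(mean(pcens(lam)))
  }
  if (!length(inf)) return(pcens(params$h0))
  g <- inf[1L]
  stats::integrate(function(x)
    pcens(params$h0 * exp(params$beta[g] * x)) *
      stats::dbeta(x, params$shape1[g], params$shape2[g]),
    0, 1, rel.tol = 1e-8)$value
}
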