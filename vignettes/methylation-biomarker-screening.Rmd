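---
title: "Methods: trace-based methylation scoring and survival-based marker screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trace-based methylation scoring and survival-based marker screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methscreen)
```

## What the package computes

`methscreen` implements a complete pipeline for identifying DNA methylation
biomarkers of distant-metastasis risk from quantitative bisulfite
sequencing:

1. **Trace scoring** — converting single-channel Sanger electropherograms of
   bisulfite-converted DNA into a per-sample, per-locus methylation score;
2. **Survival statistics** — Kaplan-Meier curves, the log-rank test, Cox
   proportional-hazards regression and time-dependent ROC/AUC for censored
   time-to-event outcomes, all implemented from primitives;
3. **A three-stage screening cascade** — a pilot differential-methylation
   filter, a training-set screen, and Bonferroni-corrected validation in an
   independent patient set;
4. **A synthetic-data generator** for both traces and cohorts, so that every
   stage is testable end to end with known ground truth.

## Trace scoring model

After bisulfite conversion, only methylated cytosines remain cytosines, so
in the extracted analysis channel the peak height at each CpG position
scales with the methylation fraction of the template molecules. Each
amplicon additionally carries a constant tag (`CGTCGTCG` at the reverse
primer's 5' end) whose signal is methylation independent. The pipeline per
trace is:

1. **Tag detection.** A matched filter built from the expected tag peak
   pattern (Gaussian peaks at the assay's nominal spacing) is slid over a
   window of ±100 data points around the expected tag position; the
   best-responding index is the tag position. Matched filtering was chosen
   because it is robust to noise and directly verifiable against an
   exhaustive scan.
2. **Alignment.** The trace is shifted so its tag lands on the locus's
   common target position; vacated points are zero-filled (windows near the
   edges are clipped anyway, so padding content never enters a score).
3. **Normalization.** The tag signal is integrated over a fixed-width
   window (default three peak spacings, covering the whole tag region;
   a single-peak window is available via `integration_width`) and every
   data point is divided by this area. Because the tag is constant, this
   cancels template amount and injection efficiency: scores are invariant
   under global rescaling of the trace.
4. **CpG localization.** Peak positions are read off the fully methylated
   reference trace — the in-silico analogue of artificially methylated
   control DNA — by local-maximum detection with a floor of 5% of the trace
   maximum and a minimum spacing of 8 data points. These defaults resolve
   the assay's nominal 12-point peak spacing with 3-point peak width; both
   are configurable.
5. **Quantification.** Each site's value is the maximum of the normalized
   sample trace within ±30 data points of the reference peak (a closed
   window, clipped at the trace bounds), absorbing residual alignment
   error. The methylation score is the arithmetic mean over the amplicon's
   CpG sites.

Scores are left on the raw normalized-intensity scale; no clipping or
calibration to percent methylation is performed, because all downstream
analyses use medians, ranks, or the score as a linear Cox covariate, none
of which require a bounded scale.

Indices are 1-based throughout, the R convention; all windows are closed
intervals.

On noiseless simulated traces these choices give three exact properties
that the test suite asserts: invariance under amplitude scaling (to 1e-9),
exact invariance under integer shifts within the search range, and strict
linearity of the score in a common per-site methylation level.

## Survival statistics

The endpoint is time to distant metastasis in months, right-censored at
last follow-up.

* **Kaplan-Meier / log-rank.** Standard product-limit estimator; censored
  subjects tied with an event time count as at risk through that time. The
  two-sample log-rank statistic uses the hypergeometric moments per event
  time and is compared against chi-square with 1 df.
* **Median dichotomization.** The cut point is the median score of the
  designated cohort — the training cohort's own median for training
  analyses, the validation cohort's for validation. Scores exactly at the
  cut point go to the low group (deterministic and order independent).
* **Cox proportional hazards.** Newton-Raphson on the partial likelihood
  with the Efron tie approximation by default (Breslow available),
  step-halving on any decrease, convergence at 1e-9 on the log partial
  likelihood, at most 100 iterations. Hazard ratios are reported per unit
  of the raw methylation score with Wald 95% intervals
  `exp(beta ± 1.96 SE)`, plus the likelihood-ratio test against the null
  model. Rows with missing values in any requested term are dropped per
  model (complete-case), and `n_used` is reported so that the varying
  denominators of covariate analyses remain visible. Clinical covariates
  enter as 0/1 contrasts: age >50 vs ≤50 years at surgery, T2+T3 vs T1,
  PR positive vs negative, no endocrine treatment vs yes, grade 3 vs 1–2.
  Age is binary by default (continuous age can be supplied as a term
  directly).
* **Time-dependent ROC.** Cumulative cases / dynamic controls at horizon
  `t`: cases have events by `t`, controls are event-free beyond `t`.
  Because censoring hides case status, sensitivity and specificity use
  Kaplan-Meier plug-ins: with `S` the overall KM curve and `S_{X>c}` the
  subgroup KM above cutpoint `c`,

  sens(c,t) = (1 − S_{X>c}(t))·P(X>c) / (1 − S(t)),
  spec(c,t) = S_{X≤c}(t)·P(X≤c) / S(t).

  The plug-in can leave [0,1]; values are clipped, which the tests assert.
  AUC is the trapezoid over ROC points with the (0,0) and (1,1) corners.
  ROC points are ordered on coordinates rounded to 12 decimals so that
  floating-point jitter of order 1e-16 in the KM products cannot scramble
  vertically stacked points; without censoring the estimator then equals
  direct case/control counting exactly, and the AUC equals the
  Mann-Whitney statistic. A smoothed nearest-neighbour variant
  (`estimator = "nne"`, rank-neighbourhood conditional survival, default
  span 0.05) is provided for users who need a monotone ROC; the KM variant
  is the default because it is assumption-free and oracle-verifiable.
* **Horizon.** The AUC horizon is a genuine tunable with no single correct
  value; the default is 60 months, which is well inside the follow-up of
  both emulated cohorts, and `auc_horizon_scan()` reports 36/48/60/80/96
  months alongside any single-horizon value.

## The screening cascade

Stage 1 drops loci without apparent differential methylation across the
pilot samples. "Apparent differential methylation" has no assay-defined
quantitative form, so the filter is a dispersion threshold: range of pilot
scores ≥ θ, default θ = 0.2 on the normalized score scale (an SD-based
alternative is available). θ is an analysis choice, and every report
carries a note saying so. The boundary is inclusive.

Stage 2 tests each surviving locus in the training cohort — which includes
the pilot samples by design — by median-dichotomized log-rank and by the
td-ROC AUC of the continuous score (a single cut point would give a
degenerate one-point ROC). Candidates must satisfy `p < 0.05` and
`AUC > 0.6`, both strict.

Stage 3 re-tests candidates in the disjoint validation cohort using the
validation cohort's own median, adjusts the log-rank p by Bonferroni with
`m` equal to the number of stage-2 candidates, and calls a marker validated
at adjusted `p < 0.05` (the stage-2 threshold, reused for symmetry). The
cascade is monotone by construction — validated ⊆ candidates ⊆ stage-1
passes — and deterministic given the cohort and configuration.

## What the synthetic data emulate

`simulate_trace()` builds `k·[Σ_i m_i G(pos_i, σ) + tag] + noise`,
truncated at zero and optionally shifted: Gaussian CpG peaks whose heights
scale with per-site methylation `m_i ∈ [0,1]`, a constant tag group, a
global amplitude factor, additive Gaussian noise (default SD 0.01 against
unit peak height, i.e. ~1% of a fully methylated peak), and a mobility
offset. The reference trace is the same construction with all `m_i = 1`
and no noise.

`simulate_cohort()` draws per-locus scores from Beta distributions, event
times from an exponential proportional-hazards model with log hazard
linear in the scores (and optionally in the clinical covariates), and
independent uniform censoring on [0, 144] months — administrative
follow-up truncation. Defaults emulate the cohort structure the package
targets: 12 pilot samples inside an 84-patient training set plus 78
validation patients, 37 loci with one informative locus at hazard ratio
3.7 per unit score, covariate prevalences of roughly 51% age >50, 73%
T2+T3, 82% PR positive, 37% endocrine-treated, 56% grade 3 among graded
tumors, with realistic missingness for stage, grade and endocrine therapy.

Two generator defaults deserve justification:

* **Score marginals are bimodal**, Beta(0.25, 0.30). Tumors tend either to
  methylate a differentially methylated promoter or to leave it
  unmethylated, so a U-shaped marginal is the biologically realistic
  shape. It is also the only regime in which the emulation is internally
  consistent: a hazard ratio near 3.7 per unit of a [0,1]-bounded score
  can only produce a time-dependent AUC near 0.7 when the score mass sits
  near the ends of the interval; a unimodal marginal with the same
  per-unit effect yields a much weaker marker.
* **Baseline hazard 0.0045/month** with the 144-month uniform censoring
  window, giving an expected event fraction near 0.40, matching the
  target cohort's event rate. `expected_censoring_fraction()` computes the
  analytic censoring probability of any parameterization by quadrature
  over the score distribution, and the simulator is tested against it.

The generator does **not** emulate: four-channel chromatograms or base
calling, mobility-dependent peak-width drift, inter-centre batch effects,
assay-specific dropout, correlated loci, or dependent censoring. Passing
tests therefore demonstrate correctness of the algorithms under the
stated generative model, not robustness to every artefact of real
capillary data.

## Degenerate inputs and edge policies

* A flat or signal-free trace raises a classed error
  (`methscreen_no_normalization_signal`) rather than returning a score.
* A shift that would discard the tag, a zero tag area, fewer detectable
  reference peaks than CpG sites, and an empty measurement set each raise
  their own classed error; `score_sample()` re-raises with sample and
  locus context attached.
* A locus whose scores are constant in a cohort cannot be median-split;
  inside the cascade this is recorded as a stage-2 failure with a reason
  instead of aborting the screen.
* Cox fits refuse constant covariates and event-free data
  (`methscreen_non_identifiable`) rather than returning divergent
  estimates.
* td-ROC requires at least one event by the horizon and positive overall
  survival at the horizon.

## Problem sizes used by the checks

The package's own verification uses sizes chosen to make Monte-Carlo error
small relative to each assertion: 1,000 random windows for the
quantification oracle; 200 simulated cohorts of n = 150 (true HR 3.7,
~35% censoring) for Wald coverage, which must land in [90%, 98%]; n =
2,000 for the null AUC check (0.5 ± 0.03); 100 replicates of a 10-locus
null screen for stage-2 false-positive calibration; and 400 replicates of
the full 162-patient, 37-locus cascade for validation power. The last
property sits genuinely near its boundary — the informative locus survives
Bonferroni-corrected validation in roughly 53% of replicates under the
default design — which is why the replicate count is large: median
dichotomization and the two-stage filter discard real information, and a
marker with a per-unit hazard ratio of 3.7 is only just strong enough to
clear them at these sample sizes.

## Known limitations

* The trace model assumes a single extracted channel; raw four-channel
  AB1 ingestion is out of scope.
* The Cox implementation covers unstratified, time-fixed covariates only;
  no proportionality diagnostics, competing risks, or imputation of
  missing covariates.
* The KM-based td-ROC is not guaranteed monotone; the NNE option trades
  that for a smoothing-span choice.
* Bonferroni is the only multiplicity correction wired into stage 3 by
  design; other corrections can be applied to the reported raw p-values.
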