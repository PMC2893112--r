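#' Construct an electropherogram trace
#'
#' A trace is the single extracted channel of a capillary-sequencing
#' electropherogram for one sample at one locus: an ordered series of
#' non-negative fluorescence intensities, one per data point. After bisulfite
#' conversion only methylated cytosines remain as C, so the intensity of the
#' C-channel peak at each CpG position carries the methylation signal.
#'
#' @param intensities numeric vector of non-negative, finite intensities
#'   (arbitrary fluorescence units), indexed by data point (1-based).
#' @param sample_id,locus_id identifiers carried through to the score.
#' @param is_reference flag for the fully methylated control trace used to
#'   define CpG peak positions.
#' @return an object of class `meth_trace`.
#' @export
new_trace <- function(intensities, sample_id = "sample", locus_id = "locus",
                      is_reference = FALSE) {
  intensities <- as.numeric(intensities)
  if (length(intensities) < 1L)
    ms_stop("methscreen_invalid_trace", "trace must contain at least one data point")
  if (any(!is.finite(intensities)) || any(intensities < 0))
    ms_stop("methscreen_invalid_trace",
            "trace intensities must be finite and non-negative")
  structure(
    list(sample_id = as.character(sample_id), locus_id = as.character(locus_id),
         intensities = intensities, is_reference = isTRUE(is_reference)),
    class = "meth_trace")
}

#' @export
print.meth_trace <- function(x, ...) {
  cat(sprintf("<meth_trace> %s / %s: %d data points%s, max intensity %.4g\n",
              x$sample_id, x$locus_id, length(x$intensities),
              if (x$is_reference) " (reference)" else "", max(x$intensities)))
  invisible(x)
}

#' Describe the amplicon analyzed at one locus
#'
#' Each reverse primer carries the constant tag sequence CGTCGTCG at its 5'
#' end, so every amplicon ends in a methylation-independent run of peaks that
#' serves as the normalization signal. The spec records how many CpG sites
#' the fragment contains, where the tag signal is expected in the trace, and
#' the peak geometry used to build the matched-filter template.
#'
#' @param locus_id locus identifier.
#' @param n_cpg_sites number of CpG sites in the PCR fragment (>= 1).
#' @param expected_tag_position data-point index hint for the centre of the
#'   tag peak group.
#' @param tag_peak_count number of peaks the tag produces in the analysis
#'   channel (default 3, the three CG dinucleotides of CGTCGTCG).
#' @param peak_spacing nominal distance between adjacent peaks, data points.
#' @param peak_width Gaussian peak standard deviation, data points.
#' @param tag_sequence the tag sequence; fixed by the assay design.
#' @return an object of class `amplicon_spec`.
#' @export
amplicon_spec <- function(locus_id, n_cpg_sites, expected_tag_position,
                          tag_peak_count = 3L, peak_spacing = 12L,
                          peak_width = 3, tag_sequence = "CGTCGTCG") {
  if (n_cpg_sites < 1L) ms_stop("methscreen_invalid_spec", "n_cpg_sites must be >= 1")
  if (tag_peak_count < 1L) ms_stop("methscreen_invalid_spec", "tag_peak_count must be >= 1")
  structure(
    list(locus_id = as.character(locus_id), n_cpg_sites = as.integer(n_cpg_sites),
         expected_tag_position = as.integer(expected_tag_position),
         tag_peak_count = as.integer(tag_peak_count),
         peak_spacing = as.integer(peak_spacing), peak_width = peak_width,
         tag_sequence = tag_sequence),
    class = "amplicon_spec")
}

# Unit-height Gaussian peak shape on integer offsets.
gauss_peak <- function(x, centre, sigma) exp(-((x - centre)^2) / (2 * sigma^2))

# Matched-filter template for the tag peak group, returned as a list of
# integer offsets (relative to the group centre) and template values.
tag_template <- function(spec) {
  span <- (spec$tag_peak_count - 1L) * spec$peak_spacing
  pad <- ceiling(3 * spec$peak_width)
  off <- seq.int(-(span / 2 + pad), span / 2 + pad)
  centres <- seq(-span / 2, span / 2, length.out = spec$tag_peak_count)
  vals <- rowSums(vapply(centres, function(c0) gauss_peak(off, c0, spec$peak_width),
                         numeric(length(off))))
  list(offsets = round(off), values = vals)
}

# Trace value at (possibly out-of-range) indices, zero outside.
trace_at <- function(intensities, idx) {
  out <- numeric(length(idx))
  ok <- idx >= 1L & idx <= length(intensities)
  out[ok] <- intensities[idx[ok]]
  out
}

#' Locate and integrate the normalization signal
#'
#' Slides a matched filter built from the expected tag peak pattern over a
#' search window around the expected tag position and returns the data-point
#' index with the strongest response, together with the integrated intensity
#' over the tag region. Every trace of a locus is later divided by this area,
#' which cancels sample-to-sample amplitude differences (template amount,
#' injection efficiency) because the tag signal is methylation independent.
#'
#' @param trace a [new_trace()] object.
#' @param spec an [amplicon_spec()].
#' @param search_halfwidth half-width of the search window around
#'   `expected_tag_position`, data points.
#' @param signal_floor minimum matched-filter response; below it the trace is
#'   declared to have no usable normalization signal.
#' @param integration_width width of the integration window centred on the
#'   detected tag position; default `3 * peak_spacing`, covering the whole
#'   tag region. Set to `peak_spacing` to integrate a single central peak.
#' @return a `norm_info` list: `tag_position`, `tag_area`, `shift_applied`
#'   (0 until [align_trace()] is used), `response`.
#' @export
find_normalization_signal <- function(trace, spec, search_halfwidth = 100L,
                                      signal_floor = 1e-8,
                                      integration_width = NULL) {
  stopifnot(inherits(trace, "meth_trace"), inherits(spec, "amplicon_spec"))
  if (is.null(integration_width)) integration_width <- 3L * spec$peak_spacing
  tmpl <- tag_template(spec)
  n <- length(trace$intensities)
  cand <- seq.int(max(1L, spec$expected_tag_position - search_halfwidth),
                  min(n, spec$expected_tag_position + search_halfwidth))
  resp <- vapply(cand, function(p)
    sum(trace_at(trace$intensities, p + tmpl$offsets) * tmpl$values), numeric(1))
  best <- which.max(resp)
  if (!length(best) || resp[best] < signal_floor)
    ms_stop("methscreen_no_normalization_signal",
            "no normalization signal: best matched-filter response %.3g below floor %.3g",
            if (length(best)) resp[best] else 0, signal_floor)
  pos <- cand[best]
  half <- floor(integration_width / 2)
  win <- seq.int(max(1L, pos - half), min(n, pos + half))
  area <- sum(trace$intensities[win])
  if (area <= 0)
    ms_stop("methscreen_no_normalization_signal",
            "integrated tag area is zero at detected position %d", pos)
  structure(list(tag_position = pos, tag_area = area, shift_applied = 0L,
                 response = resp[best]),
            class = "norm_info")
}

#' Shift a trace so its normalization signal sits at a common position
#'
#' Electropherograms of different samples are offset against each other by
#' run-to-run mobility differences; shifting each until its tag signal sits
#' at the same data point puts all CpG windows of a locus onto a shared
#' coordinate frame. Vacated positions are zero-filled.
#'
#' @param trace a [new_trace()] object.
#' @param norm the trace's [find_normalization_signal()] result.
#' @param target_position data-point index the tag should land on.
#' @return the shifted trace, with attribute `shift_applied`.
#' @export
align_trace <- function(trace, norm, target_position) {
  stopifnot(inherits(trace, "meth_trace"), inherits(norm, "norm_info"))
  n <- length(trace$intensities)
  shift <- as.integer(target_position) - norm$tag_position
  if (abs(shift) >= n || target_position < 1L || target_position > n)
    ms_stop("methscreen_shift_out_of_range",
            "shift of %d data points discards the tag on a trace of length %d",
            shift, n)
  y <- numeric(n)
  if (shift >= 0L) y[(1L + shift):n] <- trace$intensities[1L:(n - shift)]
  else y[1L:(n + shift)] <- trace$intensities[(1L - shift):n]
  out <- trace
  out$intensities <- y
  attr(out, "shift_applied") <- shift
  out
}

#' Normalize a trace by its integrated tag area
#'
#' Divides every data point by the integrated normalization signal, making
#' intensities comparable across samples of a locus.
#'
#' @inheritParams align_trace
#' @return the normalized trace.
#' @export
normalize_trace <- function(trace, norm) {
  stopifnot(inherits(trace, "meth_trace"), inherits(norm, "norm_info"))
  if (norm$tag_area <= 0)
    ms_stop("methscreen_zero_normalization", "tag area must be positive")
  out <- trace
  out$intensities <- trace$intensities / norm$tag_area
  out
}

# Indices of local maxima: rising (or flat) on the left, strictly falling on
# the right, so noiseless integer-sampled Gaussian peaks give one index each.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[x[i] >= x[i - 1L] & x[i] > x[i + 1L]]
}

#' Identify CpG peak positions from the fully methylated reference
#'
#' On the aligned, normalized reference trace every CpG site shows its
#' maximal possible signal, so its peaks mark where patient-sample CpG
#' signals must be read. Peaks inside the tag region are excluded, the rest
#' filtered by a detection floor and a minimum spacing, and the
#' `n_cpg_sites` tallest are returned in ascending position order.
#'
#' @param reference the processed (aligned, normalized) reference trace.
#' @param spec an [amplicon_spec()].
#' @param detection_floor minimum peak height as a fraction of the trace
#'   maximum (default 0.05).
#' @param min_spacing minimum distance between accepted peaks, data points.
#' @param tag_window optional integer range of data points to mask out
#'   (the tag region) before peak finding.
#' @return integer vector of `n_cpg_sites` peak positions, ascending.
#' @export
locate_cpg_positions <- function(reference, spec, detection_floor = 0.05,
                                 min_spacing = 8L, tag_window = NULL) {
  stopifnot(inherits(reference, "meth_trace"), inherits(spec, "amplicon_spec"))
  if (!reference$is_reference)
    ms_stop("methscreen_invalid_trace", "CpG positions must come from a reference trace")
  y <- reference$intensities
  if (!is.null(tag_window)) y[tag_window[tag_window >= 1L & tag_window <= length(y)]] <- 0
  floor_abs <- detection_floor * max(y)
  cand <- local_maxima(y)
  cand <- cand[y[cand] > floor_abs]
  # Greedy selection from the tallest down, enforcing the minimum spacing.
  cand <- cand[order(y[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in cand) {
    if (!length(kept) || all(abs(kept - p) >= min_spacing)) kept <- c(kept, p)
  }
  if (length(kept) < spec$n_cpg_sites)
    ms_stop("methscreen_peak_count_mismatch",
            "found %d peaks above the detection floor, but %d CpG sites expected",
            length(kept), spec$n_cpg_sites)
  sort(kept[seq_len(spec$n_cpg_sites)])
}

#' Quantify one CpG site in a normalized trace
#'
#' The site's intensity is the maximum of the normalized trace within +/- 30
#' data points (configurable) of the corresponding peak in the reference
#' trace, a closed window clipped to the trace bounds. The tolerance absorbs
#' residual alignment error between sample and reference.
#'
#' @param norm_trace the aligned, normalized sample trace.
#' @param ref_position reference peak position, data-point index.
#' @param half_width window half-width, data points (default 30).
#' @return non-negative real: the site's normalized intensity.
#' @export
quantify_cpg_site <- function(norm_trace, ref_position, half_width = 30L) {
  stopifnot(inherits(norm_trace, "meth_trace"))
  n <- length(norm_trace$intensities)
  if (ref_position < 1L || ref_position > n)
    ms_stop("methscreen_invalid_position",
            "reference position %d outside trace bounds [1, %d]", ref_position, n)
  lo <- max(1L, ref_position - half_width)
  hi <- min(n, ref_position + half_width)
  max(norm_trace$intensities[lo:hi])
}

#' Average per-site intensities into a methylation score
#'
#' The methylation score of a sample at a locus is the arithmetic mean of
#' the normalized CpG intensities across all sites of the PCR fragment.
#' Scores are left on the raw normalized-intensity scale (no clipping to
#' \[0, 1\]); downstream analyses use medians and ranks, which are invariant
#' to that choice.
#'
#' @param intensities numeric vector of per-site normalized intensities.
#' @param sample_id,locus_id identifiers.
#' @return a `methylation_score` list with `score` and `n_sites_used`.
#' @export
compute_methylation_score <- function(intensities, sample_id = "sample",
                                      locus_id = "locus") {
  if (length(intensities) < 1L)
    ms_stop("methscreen_empty_measurement_set",
            "at least one CpG measurement is required")
  if (any(!is.finite(intensities)) || any(intensities < 0))
    ms_stop("methscreen_invalid_trace", "CpG intensities must be finite and >= 0")
  structure(list(sample_id = sample_id, locus_id = locus_id,
                 score = mean(intensities),
                 n_sites_used = length(intensities)),
            class = "methylation_score")
}

#' @export
print.methylation_score <- function(x, ...) {
  cat(sprintf("<methylation_score> %s / %s: %.4f over %d CpG sites\n",
              x$sample_id, x$locus_id, x$score, x$n_sites_used))
  invisible(x)
}

#' Process the fully methylated reference trace of a locus
#'
#' Fixes the shared coordinate frame for the locus: detects the reference's
#' tag, aligns it to the expected tag position, normalizes, and reads off
#' the CpG peak positions that all patient samples of the locus are
#' quantified against.
#'
#' @inheritParams find_normalization_signal
#' @param target_position data point the tag is aligned to for all samples
#'   of the locus; defaults to `spec$expected_tag_position`.
#' @param ... passed on to [locate_cpg_positions()].
#' @return a `reference_frame` list: `target_position`, `cpg_positions`,
#'   `trace` (the processed reference), `norm`.
#' @export
process_reference <- function(reference, spec,
                              target_position = spec$expected_tag_position,
                              search_halfwidth = 100L, signal_floor = 1e-8,
                              integration_width = NULL, ...) {
  norm <- find_normalization_signal(reference, spec, search_halfwidth,
                                    signal_floor, integration_width)
  aligned <- align_trace(reference, norm, target_position)
  norm$shift_applied <- attr(aligned, "shift_applied")
  processed <- normalize_trace(aligned, norm)
  iw <- if (is.null(integration_width)) 3L * spec$peak_spacing else integration_width
  tag_win <- seq.int(target_position - iw, target_position + iw)
  cpg <- locate_cpg_positions(processed, spec, tag_window = tag_win, ...)
  structure(list(target_position = as.integer(target_position),
                 cpg_positions = cpg, trace = processed, norm = norm),
            class = "reference_frame")
}

#' Score one sample trace against its locus reference
#'
#' Runs the full per-trace pipeline in order: detect the normalization
#' signal, shift the trace so the tag sits at the locus's common position,
#' divide by the integrated tag area, take the windowed maximum at every
#' reference CpG position, and average the sites into the methylation score.
#'
#' @param trace the sample trace.
#' @param reference either the locus's reference trace or a pre-computed
#'   [process_reference()] frame (cheaper when scoring many samples).
#' @param spec an [amplicon_spec()].
#' @param half_width CpG quantification window half-width (default 30).
#' @param ... passed to [find_normalization_signal()] / [process_reference()].
#' @return a `methylation_score` with additional fields `shift_applied` and
#'   `tag_area`.
#' @export
score_sample <- function(trace, reference, spec, half_width = 30L, ...) {
  frame <- if (inherits(reference, "reference_frame")) reference
           else process_reference(reference, spec, ...)
  res <- tryCatch({
    norm <- find_normalization_signal(trace, spec, ...)
    aligned <- align_trace(trace, norm, frame$target_position)
    norm$shift_applied <- attr(aligned, "shift_applied")
    normed <- normalize_trace(aligned, norm)
    vals <- vapply(frame$cpg_positions,
                   function(p) quantify_cpg_site(normed, p, half_width),
                   numeric(1))
    sc <- compute_methylation_score(vals, trace$sample_id, trace$locus_id)
    sc$shift_applied <- norm$shift_applied
    sc$tag_area <- norm$tag_area
    sc
  }, methscreen_error = function(e) {
    ms_stop(class(e)[1L], "sample %s, locus %s: %s",
            trace$sample_id, trace$locus_id, conditionMessage(e))
  })
  res
}

#' Score a batch of traces listed in a manifest
#'
#' @param manifest data frame with columns `sample_id`, `locus_id`,
#'   `trace_path`, `reference_path`.
#' @param specs named list of [amplicon_spec()] objects, one per locus.
#' @param ... passed to [score_sample()].
#' @return data frame with one row per trace: `sample_id`, `locus_id`,
#'   `score`, `n_sites_used`, `shift_applied`, `tag_area`.
#' @export
score_traces <- function(manifest, specs, ...) {
  needed <- c("sample_id", "locus_id", "trace_path", "reference_path")
  if (!all(needed %in% names(manifest)))
    ms_stop("methscreen_missing_required_column",
            "manifest must contain columns: %s", paste(needed, collapse = ", "))
  frames <- new.env(parent = emptyenv())
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    locus <- manifest$locus_id[i]
    spec <- specs[[locus]]
    if (is.null(spec))
      ms_stop("methscreen_invalid_spec", "no amplicon spec for locus %s", locus)
    key <- manifest$reference_path[i]
    if (is.null(frames[[key]])) {
      ref <- read_trace(key, is_reference = TRUE, locus_id = locus)
      frames[[key]] <- process_reference(ref, spec, ...)
    }
    tr <- read_trace(manifest$trace_path[i], sample_id = manifest$sample_id[i],
                     locus_id = locus)
    sc <- score_sample(tr, frames[[key]], spec, ...)
    data.frame(sample_id = sc$sample_id, locus_id = sc$locus_id,
               score = sc$score, n_sites_used = sc$n_sites_used,
               shift_applied = sc$shift_applied, tag_area = sc$tag_area,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
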