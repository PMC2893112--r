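test_that("normalization signal is found where the tag was injected", {
  # single-peak tag, otherwise empty trace: the only nonzero region
  spec1 <- amplicon_spec("L", n_cpg_sites = 1, expected_tag_position = 200,
                         tag_peak_count = 1)
  y <- numeric(400)
  y[180:220] <- methscreen:::gauss_peak(180:220, 200, 3)
  tr <- new_trace(y)
  norm <- find_normalization_signal(tr, spec1)
  expect_identical(norm$tag_position, 200L)
  expect_gt(norm$tag_area, 0)

  # tag amid CpG peaks and noise: verified against an exhaustive scan of the
  # matched-filter response over every admissible index
  p <- trace_sim_params(n_cpg_sites = 4, methylation = 0.8, tag_position = 350,
                        noise_sd = 0.02, length = 500, seed = 5)
  spec <- sim_amplicon_spec(p)
  tr2 <- simulate_trace(p)
  norm2 <- find_normalization_signal(tr2, spec)
  tmpl <- methscreen:::tag_template(spec)
  resp <- vapply(seq_along(tr2$intensities), function(pos)
    sum(methscreen:::trace_at(tr2$intensities, pos + tmpl$offsets) * tmpl$values),
    numeric(1))
  expect_identical(norm2$tag_position, which.max(resp))
  expect_identical(norm2$tag_position, 350L)
})

test_that("a flat trace has no normalization signal", {
  spec <- amplicon_spec("L", 1, expected_tag_position = 100)
  expect_error(find_normalization_signal(new_trace(numeric(300)), spec),
               class = "methscreen_no_normalization_signal")
})

test_that("alignment moves the tag to the target position", {
  p <- trace_sim_params(n_cpg_sites = 3, noise_sd = 0, tag_position = 210,
                        length = 400, cpg_start = 60)
  spec <- sim_amplicon_spec(p)
  tr <- simulate_trace(p)
  norm <- find_normalization_signal(tr, spec)

  same <- align_trace(tr, norm, 210)
  expect_identical(same$intensities, tr$intensities)
  expect_identical(attr(same, "shift_applied"), 0L)

  moved <- align_trace(tr, norm, 200)
  spec200 <- sim_amplicon_spec(p)
  spec200$expected_tag_position <- 200L
  redetect <- find_normalization_signal(moved, spec200)
  expect_identical(redetect$tag_position, 200L)

  expect_error(align_trace(tr, norm, 10000),
               class = "methscreen_shift_out_of_range")
})

test_that("normalization divides every point by the tag area", {
  tr <- new_trace(c(10, 5, 0, 20))
  norm <- structure(list(tag_position = 1L, tag_area = 5, shift_applied = 0L),
                    class = "norm_info")
  expect_equal(normalize_trace(tr, norm)$intensities, c(2, 1, 0, 4))
  norm$tag_area <- 0
  expect_error(normalize_trace(tr, norm),
               class = "methscreen_zero_normalization")
})

test_that("CpG positions are recovered from a noiseless reference", {
  # three Gaussian peaks at known centres, no tag masking needed
  y <- numeric(300)
  for (c0 in c(100, 112, 124)) y <- y + methscreen:::gauss_peak(1:300, c0, 3)
  ref <- new_trace(y, is_reference = TRUE)
  spec <- amplicon_spec("L", 3, expected_tag_position = 250)
  pos <- locate_cpg_positions(ref, spec)
  # oracle: argmax within each programmed region
  oracle <- vapply(c(100, 112, 124), function(c0) {
    w <- (c0 - 5):(c0 + 5)
    w[which.max(y[w])]
  }, numeric(1))
  expect_identical(as.numeric(pos), oracle)

  spec8 <- amplicon_spec("L", 8, expected_tag_position = 250)
  expect_error(locate_cpg_positions(ref, spec8),
               class = "methscreen_peak_count_mismatch")

  y1 <- methscreen:::gauss_peak(1:300, 150, 3)
  ref1 <- new_trace(y1, is_reference = TRUE)
  spec1 <- amplicon_spec("L", 1, expected_tag_position = 250)
  expect_identical(locate_cpg_positions(ref1, spec1), which.max(y1))
})

test_that("CpG quantification is the windowed maximum, clipped at bounds", {
  # local max 0.8 sitting 20 points right of the reference position
  y <- numeric(200)
  y[120] <- 0.8
  tr <- new_trace(y)
  expect_equal(quantify_cpg_site(tr, 100, half_width = 30), 0.8)
  expect_equal(quantify_cpg_site(tr, 100, half_width = 10), 0)

  const <- new_trace(rep(0.3, 50))
  expect_equal(quantify_cpg_site(const, 25), 0.3)

  edge <- new_trace(c(rep(0, 39), 5, rep(0, 60)))
  expect_equal(quantify_cpg_site(edge, 10), 5) # window [1, 40] includes index 40
  expect_error(quantify_cpg_site(edge, 500),
               class = "methscreen_invalid_position")
})

test_that("windowed maximum equals brute-force enumeration on random cases", {
  set.seed(42)
  for (i in 1:1000) {
    n <- sample(50:150, 1)
    tr <- new_trace(runif(n))
    pos <- sample(n, 1)
    hw <- sample(0:40, 1)
    idx <- max(1, pos - hw):min(n, pos + hw)
    expect_identical(quantify_cpg_site(tr, pos, hw), max(tr$intensities[idx]))
  }
})

test_that("methylation score is the mean of site intensities", {
  expect_equal(compute_methylation_score(c(0.2, 0.4, 0.6))$score, 0.4)
  sc <- compute_methylation_score(0.7)
  expect_equal(sc$score, 0.7)
  expect_identical(sc$n_sites_used, 1L)
  expect_error(compute_methylation_score(numeric(0)),
               class = "methscreen_empty_measurement_set")
  # score times n_sites_used recovers the sum exactly
  v <- c(0.11, 0.27, 0.53, 0.08)
  sc4 <- compute_methylation_score(v)
  expect_identical(sc4$score * sc4$n_sites_used, sum(v))
})

test_that("noiseless scores are linear in the common methylation level", {
  su <- make_noiseless_setup(methylation = 1)
  ref_score <- score_sample(su$ref, su$frame, su$spec)$score
  for (alpha in c(0, 0.25, 0.5, 0.8, 1)) {
    p <- su$params
    p$methylation <- rep(alpha, p$n_cpg_sites)
    sc <- score_sample(simulate_trace(p), su$frame, su$spec)$score
    expect_equal(sc, alpha * ref_score, tolerance = 1e-12)
  }
  # strict monotonicity across increasing levels
  scores <- vapply(seq(0.1, 0.9, by = 0.2), function(a) {
    p <- su$params
    p$methylation <- rep(a, p$n_cpg_sites)
    score_sample(simulate_trace(p), su$frame, su$spec)$score
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("scores are invariant to amplitude scaling and positional shift", {
  su <- make_noiseless_setup(methylation = c(0.2, 0.9, 0.5, 0.1, 0.7))
  base <- score_sample(simulate_trace(su$params), su$frame, su$spec)$score
  for (k in c(0.5, 3, 10)) {
    p <- su$params
    p$amplitude <- k
    expect_equal(score_sample(simulate_trace(p), su$frame, su$spec)$score,
                 base, tolerance = 1e-9)
  }
  for (d in c(-40L, -15L, 15L, 40L)) {
    p <- su$params
    p$shift <- d
    sc <- score_sample(simulate_trace(p), su$frame, su$spec)
    expect_identical(sc$score, base)
    expect_identical(sc$shift_applied, -d)
  }
  # combined scale + shift
  p <- su$params
  p$amplitude <- 3
  p$shift <- 15L
  expect_equal(score_sample(simulate_trace(p), su$frame, su$spec)$score,
               base, tolerance = 1e-9)
})

test_that("the reference scored against itself averages its own peak maxima", {
  su <- make_noiseless_setup()
  sc <- score_sample(su$ref, su$frame, su$spec)
  manual <- mean(vapply(su$frame$cpg_positions, function(p)
    quantify_cpg_site(su$frame$trace, p), numeric(1)))
  expect_equal(sc$score, manual)
  expect_identical(sc$n_sites_used, su$spec$n_cpg_sites)
})

test_that("step errors carry sample and locus context", {
  su <- make_noiseless_setup()
  flat <- new_trace(numeric(600), sample_id = "S77", locus_id = "CDO1")
  err <- tryCatch(score_sample(flat, su$frame, su$spec), error = identity)
  expect_s3_class(err, "methscreen_no_normalization_signal")
  expect_match(conditionMessage(err), "S77")
  expect_match(conditionMessage(err), "CDO1")
})
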