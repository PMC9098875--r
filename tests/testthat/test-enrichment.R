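make_det_matrix <- function(n_detected, n_cond = 10) {
  # one transcript detected in n_detected of n_cond condensates, plus an
  # anchor transcript detected everywhere so columns are never empty
  counts <- rbind(t1 = c(rep(50, n_detected), rep(0, n_cond - n_detected)),
                  anchor = rep(50, n_cond))
  colnames(counts) <- paste0("c", seq_len(n_cond))
  cm <- toy_matrix(counts, c(t1 = 1000, anchor = 1000))
  suppressWarnings(compute_tpm(cm))
}

test_that("detection frequency and bins follow the detected share", {
  d3 <- detection_frequency(make_det_matrix(3))
  expect_equal(d3$detect_freq[d3$transcript_id == "t1"], 30)
  expect_equal(as.character(d3$bin[d3$transcript_id == "t1"]), "mid")
  d0 <- detection_frequency(make_det_matrix(0))
  expect_equal(d0$detect_freq[d0$transcript_id == "t1"], 0)
  expect_equal(as.character(d0$bin[d0$transcript_id == "t1"]), "not_detected")
  d10 <- detection_frequency(make_det_matrix(10))
  expect_equal(d10$detect_freq[d10$transcript_id == "t1"], 100)
  expect_equal(as.character(d10$bin[d10$transcript_id == "t1"]), "gt90")
  dlow <- detection_frequency(make_det_matrix(1, n_cond = 20))
  expect_equal(as.character(dlow$bin[dlow$transcript_id == "t1"]), "lt10")
})

test_that("control wells are excluded from the detection denominator", {
  cm <- make_det_matrix(3)
  cm$meta$is_control[1] <- TRUE  # a detected well becomes a control
  d <- detection_frequency(cm)
  expect_equal(d$n_condensates[1], 9)
  expect_equal(d$detect_freq[d$transcript_id == "t1"], 100 * 2 / 9)
})

test_that("the smoother reproduces constants and needs informative input", {
  set.seed(701)
  tpm <- rlnorm(50, 5, 1)
  fitted <- fit_frequency_smoother(tpm, rep(40, 50))
  expect_equal(fitted, rep(40, 50), tolerance = 1e-6)
  expect_error(fit_frequency_smoother(tpm[1:2], c(10, 20)), "at least 20")
  expect_error(fit_frequency_smoother(rep(100, 50), rnorm(50, 40)),
               "degenerate")
})

test_that("a displaced transcript is flagged by spline and loess alike", {
  set.seed(702)
  n <- 120
  tpm <- exp(seq(log(5), log(5e4), length.out = n))
  freq <- 100 / (1 + exp(-(log10(tpm) - 2.8) * 2)) + rnorm(n, 0, 2)
  freq <- pmin(pmax(freq, 0), 100)
  shift_idx <- 30
  freq[shift_idx] <- min(freq[shift_idx] + 40, 100)
  for (sm in c("spline", "loess")) {
    fitted <- fit_frequency_smoother(tpm, freq, smoother = sm)
    resid <- freq - fitted
    expect_true(call_enriched(resid)[shift_idx], label = sm)
    expect_gte(resid[shift_idx], 30)
    expect_lte(resid[shift_idx], 50)
    expect_equal(which(call_enriched(resid)), shift_idx)
  }
})

test_that("least-squares residuals are centred near zero", {
  pool <- generate_pool(400, frac_enriched = 0, seed = 71)
  cm <- simulate_condensates(pool, uptake_model(), 64, seed = 72)
  et <- enrichment_table(detection_frequency(filter_matrix(compute_tpm(cm))$matrix),
                         pool$info)
  expect_lt(abs(mean(et$residual, na.rm = TRUE)), 1)
})

test_that("enriched calls use a strict residual threshold", {
  expect_equal(call_enriched(c(31, 30, -5)), c(TRUE, FALSE, FALSE))
  expect_equal(call_enriched(c(NA, 45)), c(FALSE, TRUE))
  # monotone: raising the threshold never adds calls
  set.seed(703)
  r <- rnorm(200, 0, 20)
  counts <- vapply(seq(0, 60, by = 5), function(th)
    sum(call_enriched(r, th)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("length-residual correlation is binned by input abundance", {
  pool <- generate_pool(600, frac_enriched = 0, seed = 81)
  cm <- simulate_condensates(pool, uptake_model(beta_length = 1.2), 64, seed = 82)
  et <- enrichment_table(detection_frequency(filter_matrix(compute_tpm(cm))$matrix),
                         pool$info)
  bl <- binned_length_correlation(et, n_bins = 10)
  expect_equal(nrow(bl), 10)
  expect_gt(mean(bl$r > 0, na.rm = TRUE), 0.5)  # length preference shows up
  expect_error(binned_length_correlation(et, n_bins = 1), "at least 2")
})

test_that("without a length effect binned correlations centre on zero", {
  rs <- vapply(1:20, function(rep) {
    pool <- generate_pool(200, frac_enriched = 0, seed = 900 + rep)
    cm <- simulate_condensates(pool, uptake_model(beta_length = 0), 32,
                               seed = 950 + rep)
    et <- enrichment_table(
      detection_frequency(suppressWarnings(compute_tpm(cm))), pool$info)
    bl <- binned_length_correlation(et, n_bins = 4)
    mean(bl$r, na.rm = TRUE)
  }, numeric(1))
  expect_lt(mean(abs(rs)), 0.15)
})

test_that("input-absent transcripts are excluded from the fit", {
  pool <- generate_pool(100, seed = 91)
  cm <- simulate_condensates(pool, uptake_model(), 24, seed = 92)
  det <- detection_frequency(filter_matrix(compute_tpm(cm))$matrix)
  info <- pool$info
  info$input_tpm[1:3] <- 0
  et <- enrichment_table(det, info)
  absent <- et$transcript_id %in% info$transcript_id[1:3]
  expect_true(all(is.na(et$fitted_freq[absent])))
  expect_false(any(et$enriched[absent]))
})
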