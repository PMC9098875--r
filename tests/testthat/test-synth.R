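test_that("generated pools satisfy their invariants", {
  pool <- generate_pool(100, frac_enriched = 0.1, spacing = 70, seed = 1)
  expect_equal(sum(pool$info$input_tpm), 1e6, tolerance = 1e-9)
  expect_true(all(pool$info$length >= 200))
  expect_equal(unname(nchar(pool$sequences)), pool$info$length)
  expect_equal(sum(pool$info$truth_enriched), 10)
  # planted occurrences are verbatim at the stated 0-based starts, 70 apart
  for (i in seq_len(nrow(pool$planted))) {
    p <- pool$planted[i, ]
    mot <- pool$motif_pair[ifelse(p$motif_id == "motif1", 1, 2)]
    expect_equal(substr(pool$sequences[[p$transcript_id]], p$start + 1,
                        p$start + nchar(mot)), mot)
  }
  by_tx <- split(pool$planted, pool$planted$transcript_id)
  expect_true(all(vapply(by_tx, function(d)
    diff(sort(d$start)) == 70, logical(1))))
})

test_that("pools honour frac_enriched = 0 and are seed-deterministic", {
  p0 <- generate_pool(50, frac_enriched = 0, seed = 3)
  expect_false(any(p0$info$truth_enriched))
  expect_equal(nrow(p0$planted), 0)
  expect_identical(generate_pool(50, frac_enriched = 0.2, seed = 7),
                   generate_pool(50, frac_enriched = 0.2, seed = 7))
  expect_false(identical(generate_pool(50, seed = 7)$sequences,
                         generate_pool(50, seed = 8)$sequences))
})

test_that("pool generation rejects impossible motif placements", {
  expect_error(generate_pool(20, motif_pair = c("ACGTACGTACGT", "ACGTACGTACGT"),
                             spacing = 195), "minimum transcript length")
  expect_error(generate_pool(20, motif_pair = c("ACGTXCGT", revcomp("ACGTACGT"))),
               "alphabet")
  expect_error(generate_pool(20, motif_pair = c("ACGT", "ACGT")), "\\[6, 50\\]")
})

test_that("condensate counts conserve the drawn depths", {
  pool <- generate_pool(60, seed = 11)
  cm <- simulate_condensates(pool, uptake_model(), 30, seed = 12)
  expect_equal(unname(colSums(cm$counts)), cm$meta$depth)
  expect_true(all(cm$counts == floor(cm$counts)))
  expect_identical(cm$counts,
                   simulate_condensates(pool, uptake_model(), 30, seed = 12)$counts)
})

test_that("pure ambient capture follows input proportions", {
  pool <- generate_pool(40, frac_enriched = 0.2, seed = 21)
  m <- uptake_model(ambient_fraction = 1, beta_motif = 5, depth_scale = 5e4)
  cm <- simulate_condensates(pool, m, 24, seed = 22)
  tot <- rowSums(cm$counts)
  expect_gt(cor(tot / sum(tot), pool$info$input_tpm / 1e6), 0.99)
})

test_that("without a motif effect planted transcripts behave like controls", {
  pool <- generate_pool(400, frac_enriched = 0.1, seed = 11)
  cm <- simulate_condensates(pool, uptake_model(beta_motif = 0), 192, seed = 11)
  cm <- filter_matrix(compute_tpm(cm))$matrix
  det <- detection_frequency(cm)
  # abundance-matched controls: nearest non-planted neighbour in input TPM
  enr <- which(pool$info$truth_enriched)
  ctrl <- vapply(enr, function(i) {
    cand <- which(!pool$info$truth_enriched)
    cand[which.min(abs(log(pool$info$input_tpm[cand]) -
                         log(pool$info$input_tpm[i])))]
  }, integer(1))
  n <- det$n_condensates[1]
  pt <- suppressWarnings(stats::prop.test(
    c(sum(det$n_detected[enr]), sum(det$n_detected[ctrl])),
    c(n * length(enr), n * length(ctrl))))
  expect_gt(pt$p.value, 0.01)
})

test_that("motif boost monotonically raises planted detection frequency", {
  means <- vapply(c(0, 1, 2), function(bm) {
    mean(vapply(1:20, function(rep) {
      pool <- generate_pool(150, frac_enriched = 0.1, seed = 500 + rep)
      cm <- simulate_condensates(pool, uptake_model(beta_motif = bm,
                                                    depth_scale = 400),
                                 32, seed = 600 + rep)
      cm <- suppressWarnings(compute_tpm(cm))
      det <- detection_frequency(cm)
      mean(det$detect_freq[pool$info$truth_enriched])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("larger condensates carry more distinct transcripts", {
  pool <- generate_pool(500, seed = 31)
  cm <- simulate_condensates(pool, uptake_model(), 96, seed = 32)
  cm <- filter_matrix(compute_tpm(cm))$matrix
  rho <- cor(cm$meta$fsc, colSums(cm$tpm >= 1), method = "spearman")
  expect_gt(rho, 0)
})

test_that("fixtures round-trip and regenerate byte-identically", {
  pool <- generate_pool(30, frac_enriched = 0.1, seed = 41)
  cm <- simulate_condensates(pool, uptake_model(), 10, seed = 42)
  d1 <- withr::local_tempdir()
  paths <- write_fixture(pool, cm, d1)
  fx <- read_fixture(d1)
  expect_equal(unname(fx$matrix$counts), unname(cm$counts))
  expect_equal(rownames(fx$matrix$counts), rownames(cm$counts))
  expect_identical(fx$sequences, pool$sequences)
  expect_equal(fx$matrix$meta$pseudoalign_frac, cm$meta$pseudoalign_frac)
  # MatrixMarket triplet agrees with the dense TSV route
  mm <- read_count_matrix(d1)
  expect_equal(unname(mm$counts), unname(cm$counts))
  d2 <- withr::local_tempdir()
  regenerate_fixture(file.path(d1, "manifest.yaml"), d2)
  for (f in c("transcripts.fasta", "matrix.tsv", "truth.tsv", "metadata.csv"))
    expect_identical(readLines(file.path(d2, f)), readLines(file.path(d1, f)))
})

test_that("empty pools are rejected before anything is written", {
  pool <- generate_pool(30, seed = 41)
  cm <- simulate_condensates(pool, uptake_model(), 10, seed = 42)
  pool$info <- pool$info[0, ]
  d <- withr::local_tempdir()
  expect_error(write_fixture(pool, cm, file.path(d, "x")), "empty")
  expect_false(file.exists(file.path(d, "x", "transcripts.fasta")))
})
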