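test_that("local alignment scores match hand-checked cases", {
  # 7 matches + 1 internal mismatch beats splitting into two blocks
  expect_equal(sw_score("ACGTACGT", "ACGTTCGT", "trans")$score, 13)
  expect_equal(sw_score("AAAA", "CCCC", "trans")$score, 0)
  s <- "ACGGTTACGGTTACGGTTAC"
  expect_equal(sw_score(s, s, "trans")$score, 2 * nchar(s))
  expect_equal(sw_score("", "ACGT")$score, 0)
  expect_error(sw_score("ACGX", "ACGT"), "alphabet")
  # N is a mismatch against everything, including N
  expect_equal(sw_score("NNNN", "NNNN", "trans")$score, 0)
})

test_that("scoring scheme presets carry the published parameters", {
  tr <- scoring_scheme("trans")
  expect_equal(c(tr$match, tr$mismatch, tr$gap_open, tr$gap_extend),
               c(2, -1, 30, 0.05))
  si <- scoring_scheme("sine")
  expect_equal(c(si$match, si$mismatch, si$gap_open, si$gap_extend),
               c(2, -1, 10, 0))
  expect_error(scoring_scheme("nope"), "unknown scheme")
})

test_that("scores agree with a naive quadratic DP oracle on random pairs", {
  set.seed(401)
  pairs <- cbind(random_dna(150), random_dna(150))
  for (nm in c("trans", "sine")) {
    sch <- scoring_scheme(nm)
    for (k in seq_len(nrow(pairs))) {
      expect_equal(sw_score(pairs[k, 1], pairs[k, 2], sch)$score,
                   naive_sw(pairs[k, 1], pairs[k, 2], sch$match, sch$mismatch,
                            sch$gap_open, sch$gap_extend),
                   tolerance = 1e-9)
    }
  }
})

test_that("scores agree with Biostrings pairwiseAlignment", {
  set.seed(402)
  a <- random_dna(25, 10, 60); b <- random_dna(25, 10, 60)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                                  baseOnly = TRUE)
  for (k in seq_along(a)) {
    ref <- Biostrings::pairwiseAlignment(a[k], b[k], substitutionMatrix = mat,
                                         gapOpening = 30, gapExtension = 0.05,
                                         type = "local", scoreOnly = TRUE)
    expect_equal(sw_score(a[k], b[k], "trans")$score, as.numeric(ref))
  }
})

test_that("score bounds and gap-free optimality for short sequences hold", {
  set.seed(403)
  for (k in 1:200) {
    a <- random_dna(1, 4, 8); b <- random_dna(1, 4, 8)
    sc <- sw_score(a, b, "trans")$score
    expect_gte(sc, 0)
    expect_lte(sc, 2 * min(nchar(a), nchar(b)))
    # any gap costs >= 30.05, more than two 15-nt blocks could recoup, so
    # optimal alignments of short sequences are gap-free
    expect_equal(sc, gapfree_best(a, b))
  }
})

test_that("traceback spans are consistent with the score", {
  r <- sw_score("TTTACGTACGTTT", "GGACGTACGGG", "trans", spans = TRUE)
  a_sub <- substr("TTTACGTACGTTT", r$a_span[1] + 1, r$a_span[2])
  b_sub <- substr("GGACGTACGGG", r$b_span[1] + 1, r$b_span[2])
  expect_equal(r$score, 2 * nchar(a_sub))  # perfect gap-free match here
  expect_equal(a_sub, b_sub)
})

test_that("complementarity scoring is a symmetric revcomp alignment", {
  expect_equal(complementarity_score("AAACCC", "GGGTTT")$score, 12)
  set.seed(404)
  for (k in 1:25) {
    a <- random_dna(1, 10, 40); b <- random_dna(1, 10, 40)
    expect_equal(complementarity_score(a, b)$score,
                 complementarity_score(b, a)$score)
  }
  a <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
  expect_equal(complementarity_score(a, revcomp(a))$score, 40)
  # direct mode scores similarity, not complementarity
  expect_equal(complementarity_score("AAAA", "AAAA", mode = "direct")$score, 8)
})

test_that("pool complementarity handles degenerate pools and combinatorics", {
  set.seed(405)
  seqs <- setNames(random_dna(6, 50, 60), paste0("s", 1:6))
  pc <- pool_complementarity(seqs, seqs, match_lengths = FALSE)
  expect_equal(unname(pc$class_max["enriched_x_enriched"]),
               unname(pc$class_max["background_x_background"]))
  expect_false(pc$exceeds)  # identical pools cannot separate
  pc2 <- pool_complementarity(seqs[1:2], seqs[3:4], match_lengths = FALSE)
  tab <- table(pc2$scores$class)
  expect_equal(as.integer(tab[c("enriched_x_enriched", "background_x_background")]),
               c(1L, 1L))
  expect_equal(as.integer(tab["enriched_x_background"]), 4L)
  expect_error(pool_complementarity(seqs[1], seqs), "at least 2")
})

test_that("planted complementary pairs separate enriched pools", {
  pool <- generate_pool(120, frac_enriched = 0.15, seed = 406,
                        len_median = 800, len_sdlog = 0.3)
  enr <- pool$sequences[pool$info$truth_enriched]
  bg <- pool$sequences[!pool$info$truth_enriched]
  pc <- pool_complementarity(enr, bg, seed = 406)
  expect_true(pc$exceeds)
  expect_gt(pc$class_max["enriched_x_enriched"], pc$outside_max)
})

test_that("SINE homology averages top hits and spots verbatim matches", {
  set.seed(407)
  ref <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  other <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  hit <- substr(ref, 31, 50)  # verbatim 20-mer of ref
  m <- sine_homology(list(m1 = hit), c(alu = ref, mir = other))
  expect_equal(unname(m["m1", "alu"]), 40)
  expect_equal(colnames(m)[which.max(m["m1", ])], "alu")
  # five identical hits average to the single-hit score
  m5 <- sine_homology(list(m1 = rep(hit, 5)), c(alu = ref))
  expect_equal(unname(m5["m1", "alu"]), 40)
  expect_equal(sine_homology(list(m1 = "AAAAAAAA"), c(r = "GCGCGCGCGC"))[1, 1],
               0)
  expect_warning(sine_homology(list(m1 = hit, m2 = character(0)),
                               c(alu = ref)), "no hits")
})
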