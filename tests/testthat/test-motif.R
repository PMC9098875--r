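uniform_bg <- rep(0.25, 4)

test_that("scanning finds consensus occurrences with strand and coordinates", {
  hits <- scan_motifs(c(t1 = "TTACGTTT"), list(motif("m1", "ACGT")),
                      background = uniform_bg)
  plus <- hits[hits$strand == "+", ]
  expect_equal(nrow(plus), 1)
  expect_equal(c(plus$start, plus$end), c(2, 6))
  # non-palindromic motif on the minus strand, transcript coordinates
  hits2 <- scan_motifs(c(t1 = "TTTAGGTTT"), list(motif("m2", "ACCT")),
                       background = uniform_bg)
  expect_equal(hits2$strand, "-")
  expect_equal(c(hits2$start, hits2$end), c(3, 7))  # AGGT = revcomp(ACCT)
  # a single mismatch fails a threshold of 1
  expect_equal(nrow(scan_motifs(c(t1 = "TTACGATT"),
                                list(motif("m1", "ACGTT")),
                                threshold_frac = 1, background = uniform_bg)), 0)
  # transcripts shorter than the motif yield no hits and no error
  expect_equal(nrow(scan_motifs(c(t1 = "ACG"), list(motif("m1", "ACGTACGT")),
                                background = uniform_bg)), 0)
})

test_that("scanning a reverse-complemented sequence mirrors the hits", {
  set.seed(301)
  seq <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  # plant one occurrence per strand so hits are guaranteed
  substr(seq, 41, 50) <- "ACGGTTCAGA"
  substr(seq, 201, 210) <- revcomp("ACGGTTCAGA")
  m <- list(motif("m", "ACGGTTCAGA"))
  fwd <- scan_motifs(setNames(seq, "t"), m, threshold_frac = 0.8,
                     background = uniform_bg)
  rev <- scan_motifs(setNames(revcomp(seq), "t"), m, threshold_frac = 0.8,
                     background = uniform_bg)
  expect_gte(nrow(fwd), 2)
  expect_equal(nrow(rev), nrow(fwd))
  mapped <- data.frame(start = 300 - rev$end, end = 300 - rev$start,
                       strand = ifelse(rev$strand == "+", "-", "+"))
  mapped <- mapped[order(mapped$start), ]
  expect_equal(mapped$start, fwd$start)
  expect_equal(mapped$end, fwd$end)
  expect_equal(mapped$strand, fwd$strand)
})

test_that("overlapping same-motif hits keep the better (then leftmost) one", {
  hits <- scan_motifs(c(t1 = "AAAAAA"), list(motif("m", "AAAA")),
                      background = uniform_bg)
  plus <- hits[hits$strand == "+", ]
  expect_equal(nrow(plus), 1)
  expect_equal(plus$start, 0)  # ties broken leftmost
})

test_that("cis co-occurrence classifies transcripts and joins frequencies", {
  hits <- data.frame(transcript_id = c("t1", "t1", "t2", "t3"),
                     motif_id = c("m1", "m2", "m1", "m2"),
                     start = c(0, 70, 5, 9), end = c(10, 80, 15, 19),
                     strand = "+", score = 10, stringsAsFactors = FALSE)
  cc <- cis_cooccurrence(hits, "m1", "m2", transcripts = paste0("t", 1:4))
  expect_equal(as.character(cc$classes),
               c("both", "a_only", "b_only", "none"))
  expect_error(cis_cooccurrence(hits, "m1", "nope"), "unknown motif")
  df <- setNames(c(80, 40, 30, 10), paste0("t", 1:4))
  cc2 <- cis_cooccurrence(hits, "m1", "m2", detect_freq = df)
  expect_equal(cc2$summary$mean_detect_freq,
               c(80, 40, 30, 10))
  none <- cis_cooccurrence(hits[0, ], "m1", "m2",
                           transcripts = paste0("t", 1:3))
  expect_true(all(cc2$summary$n == 1))
  expect_true(all(as.character(none$classes) == "none"))
})

test_that("transcripts with both planted motifs are detected most often", {
  pool <- generate_pool(500, frac_enriched = 0.08, seed = 311)
  cm <- simulate_condensates(pool, uptake_model(beta_motif = 2), 96, seed = 312)
  cm <- filter_matrix(compute_tpm(cm))$matrix
  det <- detection_frequency(cm)
  hits <- scan_motifs(pool$sequences,
                      list(motif("m1", pool$motif_pair[1]),
                           motif("m2", pool$motif_pair[2])))
  cc <- cis_cooccurrence(hits, "m1", "m2",
                         detect_freq = setNames(det$detect_freq,
                                                det$transcript_id))
  s <- cc$summary
  both <- s$mean_detect_freq[s$class == "both"]
  expect_gt(both, max(0, s$mean_detect_freq[s$class == "none"], na.rm = TRUE))
})

test_that("nearest 5'-neighbour distances are start-to-start", {
  hits <- data.frame(transcript_id = "t1", motif_id = "m1",
                     start = c(10, 80, 150), end = c(20, 90, 160),
                     strand = "+", score = 1, stringsAsFactors = FALSE)
  nd <- neighbor_distances(hits)
  expect_equal(nd$distances$distance, c(70, 70))
  expect_equal(nd$medians$median_distance, 70)
  single <- neighbor_distances(hits[1, , drop = FALSE])
  expect_equal(nrow(single$distances), 0)
  # invariant to row order
  shuffled <- neighbor_distances(hits[c(3, 1, 2), ])
  expect_equal(shuffled$distances, nd$distances)
})

test_that("planted spacing is recovered exactly from scanned hits", {
  pool <- generate_pool(200, frac_enriched = 0.1, spacing = 70, seed = 321)
  hits <- scan_motifs(pool$sequences,
                      list(motif("m1", pool$motif_pair[1]),
                           motif("m2", pool$motif_pair[2])))
  nd <- neighbor_distances(hits)
  med <- nd$medians
  pair <- med[med$motif_id != med$neighbor_motif, ]
  expect_true(all(pair$median_distance == 70))
})

test_that("k-mer discovery recovers a planted 12-mer and controls the null", {
  set.seed(331)
  planted <- "ACGGTCATTGCA"
  mk <- function(n, with_motif) vapply(seq_len(n), function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    if (with_motif) substr(s, 101, 112) <- planted
    s
  }, character(1))
  enr <- mk(50, TRUE)
  bg <- c(mk(2, TRUE), mk(48, FALSE))
  res <- discover_kmers(enr, bg, k = 8)
  expect_gt(nrow(res$kmers), 0)
  # the best merged motif reconstructs (part of) the planted word on one strand
  top <- res$merged$consensus[which.min(res$merged$min_p_adj)]
  overlaps <- function(a, b) grepl(a, b, fixed = TRUE) || grepl(b, a, fixed = TRUE)
  expect_true(overlaps(top, planted) || overlaps(top, revcomp(planted)))
  # identical generative process: nothing significant
  null <- discover_kmers(mk(30, FALSE), mk(30, FALSE), k = 8)
  expect_equal(nrow(null$kmers), 0)
  expect_error(discover_kmers(enr, character(0)), "background pool is empty")
  expect_error(discover_kmers(enr, bg, k = 13), "\\[4, 12\\]")
})
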