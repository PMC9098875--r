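# Independent reference implementations used as test oracles. These are
# deliberately naive and written without reference to the package internals.

# Naive quadratic Smith-Waterman with affine gaps (Gotoh recurrences,
# full matrices, plain loops). A gap of length L costs open + L * ext.
naive_sw <- function(a, b, match = 2, mismatch = -1, open = 30, ext = 0.05) {
  x <- strsplit(toupper(a), "")[[1]]
  y <- strsplit(toupper(b), "")[[1]]
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0) return(0)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      s <- if (x[i] == y[j] && x[i] != "N") match else mismatch
      E[i + 1, j + 1] <- max(H[i + 1, j] - open - ext, E[i + 1, j] - ext)
      F[i + 1, j + 1] <- max(H[i, j + 1] - open - ext, F[i, j + 1] - ext)
      H[i + 1, j + 1] <- max(0, H[i, j] + s, E[i + 1, j + 1], F[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# Brute-force best gap-free local alignment score: maximum over all
# diagonal offsets and all contiguous windows.
gapfree_best <- function(a, b, match = 2, mismatch = -1) {
  x <- strsplit(toupper(a), "")[[1]]
  y <- strsplit(toupper(b), "")[[1]]
  best <- 0
  for (i in seq_along(x)) {
    for (j in seq_along(y)) {
      # extend a diagonal starting at (i, j), keeping the best prefix sum
      run <- 0
      k <- 0
      while (i + k <= length(x) && j + k <= length(y)) {
        run <- run + if (x[i + k] == y[j + k] && x[i + k] != "N") match else mismatch
        if (run > best) best <- run
        if (run < 0) break
        k <- k + 1
      }
    }
  }
  best
}

random_dna <- function(n, min_len = 5, max_len = 40) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), sample(min_len:max_len, 1),
                 replace = TRUE), collapse = ""), character(1))
}

# Adjusted Rand index between two labelings (closed-form from the
# contingency table).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# Toy condensate matrix built directly from a counts matrix
toy_matrix <- function(counts, lengths, fsc = NULL, pseudoalign = NULL,
                       type = "CM-Dex:PDDA", experiment = "exp1") {
  meta <- data.frame(condensate_id = colnames(counts),
                     fsc = if (is.null(fsc)) rep(1e4, ncol(counts)) else fsc,
                     condensate_type = type, experiment = experiment,
                     is_control = FALSE,
                     pseudoalign_frac = if (is.null(pseudoalign))
                       rep(0.8, ncol(counts)) else pseudoalign,
                     stringsAsFactors = FALSE)
  condensate_matrix(counts, lengths, meta)
}
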