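#' Sequence motif objects
#'
#' A motif is a 4 x width probability matrix (rows A, C, G, T; columns sum
#' to 1) with an id and a consensus string. Constructed from a consensus
#' (each column puts probability 1 on the consensus base) or from a matrix
#' (consensus = per-column argmax, alphabetical tie-break A < C < G < T).
#'
#' @param motif_id identifier.
#' @param consensus consensus string over A/C/G/T (used when `matrix` is
#'   `NULL`).
#' @param matrix 4 x width numeric probability matrix, rows in A, C, G, T
#'   order.
#' @return object of class `motif` with fields `motif_id`, `width`,
#'   `matrix`, `consensus`.
#' @examples
#' motif("m1", "ACGT")
#' @export
motif <- function(motif_id, consensus = NULL, matrix = NULL) {
  bases <- c("A", "C", "G", "T")
  if (is.null(matrix)) {
    if (is.null(consensus)) stop("supply a consensus or a probability matrix")
    consensus <- .check_dna(consensus, allow_n = FALSE, what = "motif consensus")
    w <- nchar(consensus)
    matrix <- base::matrix(0, 4, w, dimnames = list(bases, NULL))
    matrix[cbind(match(strsplit(consensus, "")[[1]], bases), seq_len(w))] <- 1
  } else {
    matrix <- as.matrix(matrix)
    if (nrow(matrix) != 4) stop("probability matrix must have 4 rows (A,C,G,T)")
    rownames(matrix) <- bases
    w <- ncol(matrix)
    csums <- colSums(matrix)
    if (any(abs(csums - 1) > 1e-6))
      stop("motif '", motif_id, "': probability columns must sum to 1")
    consensus <- paste(bases[apply(matrix, 2, which.max)], collapse = "")
  }
  if (w < 4 || w > 100) stop("motif width must lie in [4, 100]")
  structure(list(motif_id = motif_id, width = w, matrix = matrix,
                 consensus = consensus), class = "motif")
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("motif '%s' (width %d): %s\n", x$motif_id, x$width, x$consensus))
  invisible(x)
}

# log-odds matrix (log2) against a background composition, with a small
# pseudocount so consensus-derived zero probabilities stay finite; a 5th
# row holds the N score (the column minimum, so N never helps a hit)
.log_odds <- function(m, background, pseudo = 0.01) {
  p <- sweep(m$matrix * (1 - pseudo), 1, pseudo * background, `+`)
  lom <- log2(sweep(p, 1, background, `/`))
  rbind(lom, N = apply(lom, 2, min))
}

# reverse complement of a 4(+N)-row matrix: reverse columns, swap A/T, C/G
.revcomp_matrix <- function(lom) {
  out <- lom[c("T", "G", "C", "A", "N")[seq_len(nrow(lom))], rev(seq_len(ncol(lom))), drop = FALSE]
  rownames(out) <- rownames(lom)
  out
}

.scan_one_strand <- function(code, lom, w) {
  L <- length(code)
  if (L < w) return(list(start = integer(0), score = numeric(0)))
  npos <- L - w + 1L
  sc <- numeric(npos)
  for (k in seq_len(w)) sc <- sc + lom[code[seq_len(npos) + k - 1L], k]
  list(start = seq_len(npos) - 1L, score = sc)
}

# greedy overlap resolution: keep the higher score, ties leftmost
.resolve_overlaps <- function(df, w) {
  if (nrow(df) <= 1) return(df)
  df <- df[order(-df$score, df$start), ]
  kept <- logical(nrow(df))
  ends <- df$start + w
  for (i in seq_len(nrow(df))) {
    ov <- kept & df$start < ends[i] & ends > df$start[i]
    if (!any(ov)) kept[i] <- TRUE
  }
  out <- df[kept, ]
  out[order(out$start), ]
}

#' Scan transcripts for motif occurrences
#'
#' Slides each motif's log-odds matrix (log2, against a background base
#' composition) over both strands of every transcript and reports windows
#' scoring at least `threshold_frac` of the motif's maximum attainable
#' score. Coordinates are 0-based half-open on the transcript's forward
#' strand; a minus-strand hit means the motif occurs on the reverse
#' complement at those positions. Overlapping hits of the same motif on the
#' same strand are resolved by keeping the higher score (ties: leftmost).
#' Transcripts shorter than a motif simply yield no hits for it. This
#' max-score-fraction threshold is a deliberate simplification of
#' MAST-style E-value significance, which depends on a sequence-composition
#' model; the fraction is configurable.
#'
#' @param transcripts named character vector of transcript sequences.
#' @param motifs list of [motif()] objects (bare consensus strings are
#'   accepted and converted).
#' @param threshold_frac fraction of the maximum attainable log-odds score
#'   required for a hit, in (0, 1\] (default 0.85).
#' @param background numeric length-4 background base composition (A,C,G,T);
#'   default: empirical mononucleotide frequencies of `transcripts`.
#' @return data.frame of hits: `transcript_id`, `motif_id`, `start`, `end`
#'   (0-based half-open), `strand` (`"+"`/`"-"`), `score`.
#' @examples
#' scan_motifs(c(t1 = "TTACGTTT"), list(motif("m1", "ACGT")),
#'             background = rep(0.25, 4))
#' @export
scan_motifs <- function(transcripts, motifs, threshold_frac = 0.85,
                        background = NULL) {
  if (threshold_frac <= 0 || threshold_frac > 1)
    stop("threshold_frac must lie in (0, 1]")
  if (is.null(names(transcripts)))
    names(transcripts) <- paste0("tx", seq_along(transcripts))
  motifs <- lapply(motifs, function(m)
    if (inherits(m, "motif")) m else motif(m, consensus = m))
  transcripts <- vapply(transcripts, .check_dna, character(1))
  if (is.null(background)) {
    tab <- table(factor(unlist(strsplit(transcripts, ""), use.names = FALSE),
                        levels = c("A", "C", "G", "T", "N")))[1:4]
    background <- as.numeric(tab / sum(tab))
  }
  stopifnot(length(background) == 4, all(background > 0))
  bases <- c("A", "C", "G", "T", "N")
  codes <- lapply(strsplit(transcripts, ""), function(s) match(s, bases))

  res <- list()
  for (m in motifs) {
    lom <- .log_odds(m, background)
    lom_rc <- .revcomp_matrix(lom)
    max_score <- sum(apply(lom[1:4, , drop = FALSE], 2, max))
    thr <- threshold_frac * max_score
    for (tx in names(codes)) {
      code <- codes[[tx]]
      for (strand in c("+", "-")) {
        sc <- .scan_one_strand(code, if (strand == "+") lom else lom_rc, m$width)
        hit <- which(sc$score >= thr)
        if (!length(hit)) next
        df <- data.frame(transcript_id = tx, motif_id = m$motif_id,
                         start = sc$start[hit], end = sc$start[hit] + m$width,
                         strand = strand, score = sc$score[hit],
                         stringsAsFactors = FALSE)
        res[[length(res) + 1]] <- .resolve_overlaps(df, m$width)
      }
    }
  }
  if (!length(res))
    return(data.frame(transcript_id = character(0), motif_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$transcript_id, out$start, out$motif_id), ]
}

#' Classify transcripts by cis co-occurrence of two motifs
#'
#' Labels every transcript by whether it carries hits of motif A, motif B,
#' both (cis complementarity when B is A's reverse complement) or neither,
#' and, when detection frequencies are supplied, summarises the mean
#' detection frequency per class.
#'
#' @param hits hit table from [scan_motifs()].
#' @param motif_a,motif_b motif ids present in `hits`' provenance.
#' @param transcripts character vector of all transcript ids (the
#'   classification universe); defaults to the names of `detect_freq`, or to
#'   the transcripts appearing in `hits`.
#' @param detect_freq optional named numeric vector of detection frequencies
#'   (percent) per transcript.
#' @return list with `classes` (named factor per transcript with levels
#'   `both`, `a_only`, `b_only`, `none`) and, if `detect_freq` given,
#'   `summary` (data.frame `class`, `n`, `mean_detect_freq`).
#' @export
cis_cooccurrence <- function(hits, motif_a, motif_b, transcripts = NULL,
                             detect_freq = NULL) {
  known <- unique(hits$motif_id)
  for (m in c(motif_a, motif_b))
    if (nrow(hits) > 0 && !m %in% known)
      stop("unknown motif id '", m, "' (no hits of it in the table)")
  if (is.null(transcripts))
    transcripts <- if (!is.null(detect_freq)) names(detect_freq) else
      unique(hits$transcript_id)
  has_a <- transcripts %in% hits$transcript_id[hits$motif_id == motif_a]
  has_b <- transcripts %in% hits$transcript_id[hits$motif_id == motif_b]
  cls <- factor(ifelse(has_a & has_b, "both",
                ifelse(has_a, "a_only",
                ifelse(has_b, "b_only", "none"))),
                levels = c("both", "a_only", "b_only", "none"))
  names(cls) <- transcripts
  out <- list(classes = cls)
  if (!is.null(detect_freq)) {
    df <- detect_freq[transcripts]
    out$summary <- data.frame(
      class = levels(cls),
      n = as.integer(table(cls)),
      mean_detect_freq = as.numeric(tapply(df, cls, mean)),
      row.names = NULL)
  }
  out
}

#' Nearest 5'-neighbour distances between motif hits
#'
#' For every hit, the start-to-start distance to the nearest hit (of any
#' motif) with a strictly smaller start on the same transcript. Distances
#' are grouped by (motif of the hit, motif of the neighbour) and summarised
#' by the group median. Transcripts with a single hit contribute nothing;
#' ties in neighbour position are broken by motif id. The result is
#' invariant to the input row order.
#'
#' @param hits hit table from [scan_motifs()].
#' @return list with `distances` (data.frame `transcript_id`, `motif_id`,
#'   `neighbor_motif`, `distance`) and `medians` (data.frame `motif_id`,
#'   `neighbor_motif`, `n`, `median_distance`).
#' @export
neighbor_distances <- function(hits) {
  empty <- data.frame(transcript_id = character(0), motif_id = character(0),
                      neighbor_motif = character(0), distance = integer(0))
  if (nrow(hits) < 2)
    return(list(distances = empty, medians = empty[, -1]))
  hits <- hits[order(hits$transcript_id, hits$start, hits$motif_id), ]
  res <- lapply(split(hits, hits$transcript_id), function(h) {
    if (nrow(h) < 2) return(NULL)
    rows <- lapply(seq_len(nrow(h)), function(i) {
      smaller <- which(h$start < h$start[i])
      if (!length(smaller)) return(NULL)
      # nearest strictly-5' start; ties broken by motif id (alphabetical)
      cand <- smaller[h$start[smaller] == max(h$start[smaller])]
      nb <- cand[order(h$motif_id[cand])][1]
      data.frame(transcript_id = h$transcript_id[i], motif_id = h$motif_id[i],
                 neighbor_motif = h$motif_id[nb],
                 distance = h$start[i] - h$start[nb],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  d <- do.call(rbind, res)
  if (is.null(d)) return(list(distances = empty, medians = empty[, -1]))
  rownames(d) <- NULL
  agg <- aggregate(distance ~ motif_id + neighbor_motif, d,
                   function(x) c(n = length(x), med = median(x)))
  medians <- data.frame(motif_id = agg$motif_id,
                        neighbor_motif = agg$neighbor_motif,
                        n = as.integer(agg$distance[, "n"]),
                        median_distance = agg$distance[, "med"])
  list(distances = d, medians = medians)
}

# unique k-mers present in a sequence on either strand
.kmer_set <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  fwd <- substring(seq, 1:(L - k + 1), k:L)
  rev <- substring(revcomp(seq), 1:(L - k + 1), k:L)
  u <- unique(c(fwd, rev))
  u[!grepl("N", u, fixed = TRUE)]
}

#' Discover enriched k-mers between transcript pools
#'
#' A discovery-lite alternative to full de novo motif discovery: counts the
#' transcripts containing each k-mer (on either strand) in the enriched and
#' background pools, tests one-sided enrichment with the hypergeometric
#' distribution, Bonferroni-corrects over all 4^k k-mers, and greedily
#' merges significant k-mers that overlap by k-1 with consistent offsets
#' into longer consensus strings. No claim of equivalence to full
#' EM/PWM-based discovery is made.
#'
#' @param enriched,background character vectors of transcript sequences.
#' @param k k-mer size in \[4, 12\] (memory guard; default 8).
#' @param alpha significance level on Bonferroni-adjusted p-values.
#' @return list with `kmers` (data.frame `kmer`, `n_enriched`,
#'   `n_background`, `p`, `p_adj`, ranked by p; significant k-mers only) and
#'   `merged` (data.frame `consensus`, `width`, `n_members`, `min_p_adj`).
#' @export
discover_kmers <- function(enriched, background, k = 8L, alpha = 0.05) {
  if (k < 4 || k > 12) stop("k must lie in [4, 12]")
  if (length(enriched) == 0) stop("enriched pool is empty")
  if (length(background) == 0) stop("background pool is empty")
  enriched <- vapply(enriched, .check_dna, character(1), USE.NAMES = FALSE)
  background <- vapply(background, .check_dna, character(1), USE.NAMES = FALSE)
  n_e <- length(enriched); n_b <- length(background)
  ce <- table(unlist(lapply(enriched, .kmer_set, k = k), use.names = FALSE))
  cb <- table(unlist(lapply(background, .kmer_set, k = k), use.names = FALSE))
  kmers <- union(names(ce), names(cb))
  xe <- as.integer(ce[kmers]); xe[is.na(xe)] <- 0L
  xb <- as.integer(cb[kmers]); xb[is.na(xb)] <- 0L
  p <- phyper(xe - 1, xe + xb, n_e + n_b - xe - xb, n_e, lower.tail = FALSE)
  p_adj <- pmin(1, p * 4^k)  # Bonferroni over the whole k-mer space
  ord <- order(p)
  sig <- ord[p_adj[ord] < alpha]
  kdf <- data.frame(kmer = kmers[sig], n_enriched = xe[sig],
                    n_background = xb[sig], p = p[sig], p_adj = p_adj[sig],
                    stringsAsFactors = FALSE)
  # greedy merge: attach a k-mer to a growing consensus when it overlaps an
  # end by k-1 characters
  merged <- list()
  for (km in kdf$kmer) {
    placed <- FALSE
    for (i in seq_along(merged)) {
      cons <- merged[[i]]$consensus
      if (substr(km, 1, k - 1) == substr(cons, nchar(cons) - k + 2, nchar(cons))) {
        merged[[i]]$consensus <- paste0(cons, substr(km, k, k))
        merged[[i]]$members <- c(merged[[i]]$members, km); placed <- TRUE; break
      }
      if (substr(km, 2, k) == substr(cons, 1, k - 1)) {
        merged[[i]]$consensus <- paste0(substr(km, 1, 1), cons)
        merged[[i]]$members <- c(merged[[i]]$members, km); placed <- TRUE; break
      }
      if (grepl(km, cons, fixed = TRUE)) {
        merged[[i]]$members <- c(merged[[i]]$members, km); placed <- TRUE; break
      }
    }
    if (!placed) merged[[length(merged) + 1]] <- list(consensus = km, members = km)
  }
  mdf <- if (length(merged)) data.frame(
    consensus = vapply(merged, `[[`, character(1), "consensus"),
    width = vapply(merged, function(m) nchar(m$consensus), integer(1)),
    n_members = vapply(merged, function(m) length(m$members), integer(1)),
    min_p_adj = vapply(merged, function(m)
      min(kdf$p_adj[kdf$kmer %in% m$members]), numeric(1)),
    stringsAsFactors = FALSE)
  else data.frame(consensus = character(0), width = integer(0),
                  n_members = integer(0), min_p_adj = numeric(0))
  list(kmers = kdf, merged = mdf)
}
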