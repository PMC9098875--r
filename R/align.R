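#' Alignment scoring schemes
#'
#' Construct a Smith-Waterman scoring scheme with affine gap penalties. A gap
#' of length L costs `gap_open + L * gap_extend`: the opening penalty is
#' charged once per gap and the extension penalty once per gapped position
#' (the convention of `Biostrings::pairwiseAlignment`, whose affine model
#' differs from tools that charge opening for the first gapped position only).
#'
#' Two named presets are provided, matching the parameter sets used for
#' trans-complementarity scoring between transcripts and for motif-vs-SINE
#' homology scoring respectively:
#'
#' * `"trans"`: match 2, mismatch -1, gap open 30, gap extend 0.05. The heavy
#'   opening cost makes short optimal alignments effectively gap-free.
#' * `"sine"`: match 2, mismatch -1, gap open 10, gap extend 0.
#'
#' @param name preset name (`"trans"` or `"sine"`), or any label when the
#'   numeric parameters are given explicitly.
#' @param match match score (positive).
#' @param mismatch mismatch score (typically negative).
#' @param gap_open non-negative gap opening cost.
#' @param gap_extend non-negative per-position gap extension cost.
#' @return an object of class `scoring_scheme`.
#' @examples
#' scoring_scheme("trans")
#' scoring_scheme("custom", match = 1, mismatch = -2, gap_open = 5, gap_extend = 1)
#' @export
scoring_scheme <- function(name = "trans", match = NULL, mismatch = NULL,
                           gap_open = NULL, gap_extend = NULL) {
  presets <- list(
    trans = list(match = 2, mismatch = -1, gap_open = 30, gap_extend = 0.05),
    sine  = list(match = 2, mismatch = -1, gap_open = 10, gap_extend = 0)
  )
  p <- presets[[name]]
  if (is.null(p)) {
    if (is.null(match) || is.null(mismatch) || is.null(gap_open) || is.null(gap_extend))
      stop("unknown scheme '", name, "'; supply match/mismatch/gap_open/gap_extend")
    p <- list(match = match, mismatch = mismatch,
              gap_open = gap_open, gap_extend = gap_extend)
  } else {
    if (!is.null(match)) p$match <- match
    if (!is.null(mismatch)) p$mismatch <- mismatch
    if (!is.null(gap_open)) p$gap_open <- gap_open
    if (!is.null(gap_extend)) p$gap_extend <- gap_extend
  }
  stopifnot(p$gap_open >= 0, p$gap_extend >= 0)
  structure(c(list(name = name), p), class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("scoring_scheme '%s': match %g, mismatch %g, gap %g + %g per position\n",
              x$name, x$match, x$mismatch, x$gap_open, x$gap_extend))
  invisible(x)
}

.as_scheme <- function(scheme) {
  if (inherits(scheme, "scoring_scheme")) scheme else scoring_scheme(scheme)
}

#' Smith-Waterman local alignment score
#'
#' Optimal local alignment score of two nucleotide sequences under affine gap
#' penalties (a gap of length L costs `gap_open + L * gap_extend`). N scores
#' as a mismatch against every base including N. The score is 0 when no
#' positive-scoring local alignment exists; an empty sequence scores 0.
#'
#' @param a,b nucleotide strings over A/C/G/T/N (case-insensitive).
#' @param scheme a [scoring_scheme()] or preset name.
#' @param spans if `TRUE`, also compute the aligned spans (0-based half-open
#'   coordinates on each sequence) by full-matrix traceback with ties broken
#'   diagonal, then up, then left. Quadratic memory; off by default.
#' @return a list of class `alignment_score` with elements `score`, `scheme`,
#'   and, when `spans = TRUE`, `a_span` and `b_span` (integer length-2,
#'   0-based half-open).
#' @examples
#' sw_score("ACGTACGT", "ACGTTCGT")$score        # 13: 7 matches + 1 mismatch
#' sw_score("AAAA", "CCCC")$score                # 0
#' @export
sw_score <- function(a, b, scheme = "trans", spans = FALSE) {
  sch <- .as_scheme(scheme)
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  a <- .check_dna(a); b <- .check_dna(b)
  if (spans) {
    r <- sw_align_cpp(a, b, sch$match, sch$mismatch, sch$gap_open, sch$gap_extend)
    out <- list(score = r$score, scheme = sch$name,
                a_span = c(r$a_start, r$a_end), b_span = c(r$b_start, r$b_end))
  } else {
    out <- list(score = sw_score_cpp(a, b, sch$match, sch$mismatch,
                                     sch$gap_open, sch$gap_extend),
                scheme = sch$name)
  }
  class(out) <- "alignment_score"
  out
}

#' @export
print.alignment_score <- function(x, ...) {
  cat(sprintf("local alignment score %g (scheme '%s')\n", x$score, x$scheme))
  if (!is.null(x$a_span))
    cat(sprintf("  a[%d,%d) ~ b[%d,%d)\n", x$a_span[1], x$a_span[2],
                x$b_span[1], x$b_span[2]))
  invisible(x)
}

#' Trans-complementarity score between two transcripts
#'
#' Scores the potential of two transcripts to base-pair in trans by locally
#' aligning `a` against the reverse complement of `b`. Because
#' revcomp is an involution that preserves local alignment scores, the
#' measure is symmetric in its arguments. Set `mode = "direct"` for plain
#' similarity of `a` vs `b` without strand flipping.
#'
#' @inheritParams sw_score
#' @param mode `"revcomp"` (default; complementarity) or `"direct"`
#'   (sequence similarity).
#' @return an `alignment_score`.
#' @examples
#' complementarity_score("AAACCC", "GGGTTT")$score  # 12: revcomp(b) == a
#' @export
complementarity_score <- function(a, b, scheme = "trans",
                                  mode = c("revcomp", "direct")) {
  mode <- match.arg(mode)
  if (mode == "revcomp") b <- revcomp(b)
  sw_score(a, b, scheme)
}

# stratified sampler: pick size(target) sequences from candidates matching the
# target length distribution by quantile strata
.length_matched_sample <- function(target_lengths, candidate_lengths, n_strata = 10) {
  n <- length(target_lengths)
  if (length(candidate_lengths) < n)
    stop("background candidate pool smaller than the enriched pool")
  qs <- quantile(candidate_lengths, probs = seq(0, 1, length.out = n_strata + 1))
  qs[1] <- -Inf; qs[n_strata + 1] <- Inf
  strat_target <- cut(target_lengths, qs, labels = FALSE)
  strat_cand <- cut(candidate_lengths, qs, labels = FALSE)
  picked <- integer(0)
  avail <- rep(TRUE, length(candidate_lengths))
  for (s in seq_len(n_strata)) {
    need <- sum(strat_target == s)
    if (need == 0) next
    pool <- which(avail & strat_cand == s)
    if (length(pool) < need) pool <- which(avail)  # stratum exhausted: fall back
    take <- if (length(pool) == 1) pool else sample(pool, min(need, length(pool)))
    picked <- c(picked, take)
    avail[take] <- FALSE
  }
  # top up if strata rounding left us short
  while (length(picked) < n) {
    pool <- which(avail)
    take <- if (length(pool) == 1) pool else sample(pool, 1)
    picked <- c(picked, take)
    avail[take] <- FALSE
  }
  picked[seq_len(n)]
}

#' Pairwise complementarity distributions between transcript pools
#'
#' Computes all unordered pairwise trans-complementarity scores within the
#' enriched pool, between the enriched pool and a length-matched background
#' pool, and within the background pool. The background is subsampled from
#' the candidates to match the enriched pool's length distribution by
#' quantile strata (10 strata, seeded). Self-pairs are excluded. The summary
#' reports each class's maximum and whether the enriched-vs-enriched maximum
#' strictly exceeds the maximum seen in either other class (the "dotted
#' line" criterion: the highest score observed outside enriched-vs-enriched
#' comparisons).
#'
#' @param enriched named character vector of enriched transcript sequences.
#' @param background named character vector of candidate background
#'   (non-enriched) sequences; subsampled to `length(enriched)` sequences
#'   with a matched length distribution unless `match_lengths = FALSE`.
#' @param scheme scoring scheme (default `"trans"`).
#' @param mode passed to [complementarity_score()].
#' @param match_lengths perform length-matched background subsampling.
#' @param seed integer seed for the background sampler.
#' @return list of class `pool_complementarity` with `scores` (a data.frame
#'   `query_id`, `target_id`, `class`, `score`), `class_max` (named numeric),
#'   `exceeds` (logical: enriched x enriched max strictly above both other
#'   maxima), and `background_ids`.
#' @export
pool_complementarity <- function(enriched, background, scheme = "trans",
                                 mode = "revcomp", match_lengths = TRUE,
                                 seed = 1L) {
  if (length(enriched) < 2 || length(background) < 2)
    stop("each pool needs at least 2 sequences")
  if (is.null(names(enriched))) names(enriched) <- paste0("enr", seq_along(enriched))
  if (is.null(names(background))) names(background) <- paste0("bg", seq_along(background))
  sch <- .as_scheme(scheme)
  if (match_lengths && length(background) >= length(enriched)) {
    idx <- withr::with_seed(seed, .length_matched_sample(nchar(enriched), nchar(background)))
    background <- background[idx]
  }
  pair_scores <- function(p1, p2, cls) {
    if (identical(names(p1), names(p2))) {
      cmb <- utils::combn(length(p1), 2)
      data.frame(query_id = names(p1)[cmb[1, ]], target_id = names(p2)[cmb[2, ]],
                 class = cls,
                 score = vapply(seq_len(ncol(cmb)), function(k)
                   complementarity_score(p1[[cmb[1, k]]], p2[[cmb[2, k]]],
                                         sch, mode)$score, numeric(1)),
                 stringsAsFactors = FALSE)
    } else {
      grid <- expand.grid(i = seq_along(p1), j = seq_along(p2))
      data.frame(query_id = names(p1)[grid$i], target_id = names(p2)[grid$j],
                 class = cls,
                 score = vapply(seq_len(nrow(grid)), function(k)
                   complementarity_score(p1[[grid$i[k]]], p2[[grid$j[k]]],
                                         sch, mode)$score, numeric(1)),
                 stringsAsFactors = FALSE)
    }
  }
  sc <- rbind(pair_scores(enriched, enriched, "enriched_x_enriched"),
              pair_scores(enriched, background, "enriched_x_background"),
              pair_scores(background, background, "background_x_background"))
  class_max <- tapply(sc$score, sc$class, max)
  outside_max <- max(class_max[c("enriched_x_background", "background_x_background")])
  structure(list(scores = sc,
                 class_max = c(class_max),
                 outside_max = outside_max,
                 exceeds = unname(class_max["enriched_x_enriched"] > outside_max),
                 background_ids = names(background)),
            class = "pool_complementarity")
}

#' @export
print.pool_complementarity <- function(x, ...) {
  cat("pairwise complementarity score distributions\n")
  for (cls in names(x$class_max)) {
    s <- x$scores$score[x$scores$class == cls]
    cat(sprintf("  %-24s n=%4d  median %6.1f  max %6.1f\n",
                cls, length(s), median(s), max(s)))
  }
  cat(sprintf("  enriched x enriched max %s the maximum outside (%.1f)\n",
              if (x$exceeds) "exceeds" else "does not exceed", x$outside_max))
  invisible(x)
}

#' Motif-to-SINE homology score matrix
#'
#' For each consensus motif, aligns its top-scoring hit sequences (at most 5)
#' against every SINE reference and averages the local alignment score over
#' the hits, giving one row per motif and one column per reference. Uses the
#' `"sine"` scheme (match 2, mismatch -1, gap open 10, extend 0) by default.
#'
#' @param motif_hits named list: motif id -> character vector of hit
#'   sequences, ordered best first; only the first 5 are used. Fewer than 5
#'   hits are averaged over what is available (with a message); zero hits
#'   drop the row with a warning.
#' @param sine_refs named character vector of SINE reference sequences (e.g.
#'   read from FASTA with [read_fasta()]).
#' @param scheme scoring scheme (default `"sine"`).
#' @return numeric matrix, motifs x references, of mean alignment scores.
#' @export
sine_homology <- function(motif_hits, sine_refs, scheme = "sine") {
  if (length(sine_refs) == 0) stop("no SINE reference sequences supplied")
  if (is.null(names(sine_refs))) names(sine_refs) <- paste0("SINE", seq_along(sine_refs))
  sch <- .as_scheme(scheme)
  rows <- list()
  for (m in names(motif_hits)) {
    hits <- motif_hits[[m]]
    if (length(hits) == 0) {
      warning("motif '", m, "' has no hits; row omitted")
      next
    }
    if (length(hits) > 5) hits <- hits[1:5]
    if (length(hits) < 5)
      message("motif '", m, "': averaging over ", length(hits), " hit(s)")
    rows[[m]] <- vapply(sine_refs, function(ref)
      mean(vapply(hits, function(h) sw_score(h, ref, sch)$score, numeric(1))),
      numeric(1))
  }
  if (length(rows) == 0) stop("no motif had any hits")
  out <- do.call(rbind, rows)
  colnames(out) <- names(sine_refs)
  out
}
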