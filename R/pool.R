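#' Default planted complementary motif pair
#'
#' A fixed 24-nt consensus and its reverse complement, used as the default
#' cis-complementary pair planted by [generate_pool()]. 24 nt sits inside
#' the 11-50 nt range typical of enriched condensate motifs and is long
#' enough that a planted occurrence is unambiguous against the random
#' sequence background.
#'
#' @return character vector of length 2: the motif and its reverse complement.
#' @export
default_motif_pair <- function() {
  m1 <- "ATCGTTAGGCATCCGATTACGGAC"
  c(m1, revcomp(m1))
}

#' Generate a synthetic input transcript pool
#'
#' Builds a pool of random transcripts emulating a total-RNA input pool:
#' log-normal lengths (median `len_median` nt, floor 200 nt), i.i.d. random
#' sequence at GC content `gc`, and heavy-tailed input abundances (log-normal
#' with `sigma = tpm_sdlog` before normalisation to TPM summing to 1e6).
#' A fraction `frac_enriched` of transcripts (chosen uniformly at random)
#' carries a planted cis-complementary motif pair: both motifs on the plus
#' strand, `spacing` nt apart start-to-start, and `truth_enriched = TRUE`.
#' These labels are the ground truth for enrichment parameter-recovery tests.
#'
#' @param n_transcripts number of transcripts (>= 10).
#' @param motif_pair character vector of two consensus motifs (6-50 nt,
#'   A/C/G/T); by default a 24-mer and its reverse complement
#'   ([default_motif_pair()]).
#' @param frac_enriched fraction of transcripts carrying the planted pair,
#'   in \[0, 0.5\].
#' @param spacing start-to-start distance in nt between the two planted
#'   motifs (default 70).
#' @param seed integer seed; the pool is fully deterministic given the seed.
#' @param len_median,len_sdlog log-normal length distribution parameters
#'   (median nt and sdlog).
#' @param tpm_sdlog sdlog of the heavy-tailed input abundance distribution.
#' @param gc GC content of the random sequence background.
#' @return object of class `transcript_pool`: a list with `info` (data.frame
#'   `transcript_id`, `length`, `input_tpm`, `truth_enriched`), `sequences`
#'   (named character vector), `planted` (data.frame `transcript_id`,
#'   `motif_id`, `start` (0-based), `strand`), `motif_pair`, and `params`.
#' @examples
#' pool <- generate_pool(50, frac_enriched = 0.1, seed = 1)
#' sum(pool$info$truth_enriched)  # 5
#' @export
generate_pool <- function(n_transcripts,
                          motif_pair = default_motif_pair(),
                          frac_enriched = 0.05,
                          spacing = 70L,
                          seed = 1L,
                          len_median = 2000,
                          len_sdlog = 0.6,
                          tpm_sdlog = 1.5,
                          gc = 0.45) {
  stopifnot(n_transcripts >= 10, frac_enriched >= 0, frac_enriched <= 0.5,
            length(motif_pair) == 2, spacing >= 0)
  motif_pair <- vapply(motif_pair, .check_dna, character(1), allow_n = FALSE,
                       what = "motif consensus")
  w <- nchar(motif_pair)
  if (any(w < 6 | w > 50)) stop("motif consensus length must be in [6, 50]")
  min_len <- 200L
  if (spacing + max(w) > min_len)
    stop("spacing + motif length (", spacing + max(w),
         ") exceeds the minimum transcript length (", min_len, ")")

  withr::with_seed(as.integer(seed), {
    lens <- pmax(min_len, round(rlnorm(n_transcripts, log(len_median), len_sdlog)))
    base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(lens, function(L)
      paste(sample(names(base_probs), L, replace = TRUE, prob = base_probs),
            collapse = ""), character(1))
    tpm_raw <- rlnorm(n_transcripts, meanlog = 0, sdlog = tpm_sdlog)
    tpm <- tpm_raw / sum(tpm_raw) * 1e6

    n_enr <- round(frac_enriched * n_transcripts)
    enriched_idx <- if (n_enr > 0) sample(n_transcripts, n_enr) else integer(0)
    planted <- list()
    for (i in enriched_idx) {
      # plant motif 1 at s and motif 2 at s + spacing (start-to-start)
      max_start <- lens[i] - (spacing + w[2])
      s <- sample.int(max_start + 1, 1) - 1L  # 0-based
      substr(seqs[i], s + 1, s + w[1]) <- motif_pair[1]
      substr(seqs[i], s + spacing + 1, s + spacing + w[2]) <- motif_pair[2]
      planted[[length(planted) + 1]] <- data.frame(
        transcript_id = sprintf("tx%04d", i),
        motif_id = c("motif1", "motif2"),
        start = c(s, s + spacing),
        strand = "+", stringsAsFactors = FALSE)
    }
    ids <- sprintf("tx%04d", seq_len(n_transcripts))
    names(seqs) <- ids
    pool <- list(
      info = data.frame(transcript_id = ids, length = as.integer(lens),
                        input_tpm = tpm,
                        truth_enriched = seq_len(n_transcripts) %in% enriched_idx,
                        stringsAsFactors = FALSE),
      sequences = seqs,
      planted = if (length(planted)) do.call(rbind, planted) else
        data.frame(transcript_id = character(0), motif_id = character(0),
                   start = integer(0), strand = character(0)),
      motif_pair = unname(motif_pair),
      params = list(n_transcripts = n_transcripts, motif_pair = unname(motif_pair),
                    frac_enriched = frac_enriched, spacing = as.integer(spacing),
                    seed = as.integer(seed), len_median = len_median,
                    len_sdlog = len_sdlog, tpm_sdlog = tpm_sdlog, gc = gc))
    class(pool) <- "transcript_pool"
    pool
  })
}

#' @export
print.transcript_pool <- function(x, ...) {
  cat(sprintf("transcript_pool: %d transcripts, median length %d nt, %d with planted motif pair\n",
              nrow(x$info), as.integer(median(x$info$length)),
              sum(x$info$truth_enriched)))
  invisible(x)
}

#' Uptake model for condensate simulation
#'
#' Parameterises how transcripts partition into condensates. The unnormalised
#' uptake weight of transcript t in a condensate of type k is
#' `input_tpm_t^beta_abundance * exp(beta_length * log(length_t) +
#' beta_motif * truth_enriched_t + type_weights[[k]][t])`.
#' The expected number of captured molecules of a condensate with forward
#' scatter `fsc` is `depth_scale * (fsc / fsc_ref)^capacity_exponent`
#' (volume scaling for the default exponent 3), and its counts are a
#' multinomial draw from the uptake weights mixed with ambient input-pool
#' proportions at `ambient_fraction`.
#'
#' @param beta_abundance exponent on input abundance. The default 0.6 makes
#'   capture sub-proportional to input frequency, reflecting competition of
#'   transcripts for finite droplet capacity: uptake rises strongly with
#'   input abundance but saturates at the top of a heavy-tailed pool.
#' @param beta_length coefficient on log transcript length (0 = no length
#'   preference).
#' @param beta_motif log-weight boost for transcripts carrying the planted
#'   complementary motif pair.
#' @param type_weights optional named list: condensate type -> per-transcript
#'   log-weight offset vector (recycled if length 1).
#' @param capacity_exponent exponent linking FSC (size) to capture depth.
#' @param ambient_fraction fraction of each condensate's molecules drawn from
#'   the surrounding (input-pool) RNA rather than its uptake weights, in
#'   \[0, 1\].
#' @param depth_scale expected molecule count of a condensate at the
#'   reference size `fsc_ref`.
#' @param fsc_ref reference FSC for the depth scaling.
#' @return object of class `uptake_model`.
#' @export
uptake_model <- function(beta_abundance = 0.6, beta_length = 0, beta_motif = 0,
                         type_weights = NULL, capacity_exponent = 3,
                         ambient_fraction = 0.05, depth_scale = 1200,
                         fsc_ref = 2e4) {
  if (ambient_fraction < 0 || ambient_fraction > 1)
    stop("ambient_fraction must be in [0, 1]")
  if (depth_scale <= 0) stop("depth_scale must be positive")
  structure(list(beta_abundance = beta_abundance, beta_length = beta_length,
                 beta_motif = beta_motif, type_weights = type_weights,
                 capacity_exponent = capacity_exponent,
                 ambient_fraction = ambient_fraction,
                 depth_scale = depth_scale, fsc_ref = fsc_ref),
            class = "uptake_model")
}

#' @export
print.uptake_model <- function(x, ...) {
  cat(sprintf(paste0("uptake_model: beta_abundance %g, beta_length %g, beta_motif %g,\n",
                     "  capacity exponent %g, ambient %.2f, depth %g at FSC %g\n"),
              x$beta_abundance, x$beta_length, x$beta_motif,
              x$capacity_exponent, x$ambient_fraction, x$depth_scale, x$fsc_ref))
  invisible(x)
}
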