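#' Pipeline configuration
#'
#' Central parameter set for the analysis stages. The defaults are the
#' thresholds the pipeline is designed around: TPM detection threshold 1,
#' 20% read-coverage filter (applied when the dataset's mean
#' pseudoalignment falls below 40%), condensate removal at <5%
#' pseudoalignment for FSC > 2e4, enrichment residual threshold 30
#' percentage points, motif-scan score fraction 0.85, 5 principal
#' components, and Bonferroni alpha 0.01 for differential tests.
#'
#' @param tpm_min detection / filtering threshold on TPM.
#' @param coverage_min minimum per-transcript read-coverage fraction.
#' @param pseudoalign_min minimum condensate pseudoalignment fraction (the
#'   filter applies only above `fsc_cut`).
#' @param fsc_cut FSC above which the pseudoalignment filter applies.
#' @param mean_pseudoalign_cut dataset mean pseudoalignment below which the
#'   coverage filter is applied.
#' @param residual_threshold enriched-call threshold in percentage points.
#' @param smoother `"spline"` or `"loess"`.
#' @param scan_threshold_frac motif-scan max-score fraction.
#' @param kmer_k,kmer_alpha k-mer discovery parameters.
#' @param trans_scheme,sine_scheme scoring scheme names.
#' @param n_components,cluster_k embedding parameters (`cluster_k = NULL`
#'   selects k by silhouette).
#' @param de_alpha Bonferroni-adjusted significance threshold.
#' @param n_bins abundance bins for the length correlation.
#' @param seed pipeline seed.
#' @param ... unknown keys are rejected.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(tpm_min = 1, coverage_min = 0.2,
                            pseudoalign_min = 0.05, fsc_cut = 2e4,
                            mean_pseudoalign_cut = 0.4,
                            residual_threshold = 30, smoother = "spline",
                            scan_threshold_frac = 0.85,
                            kmer_k = 8L, kmer_alpha = 0.05,
                            trans_scheme = "trans", sine_scheme = "sine",
                            n_components = 5L, cluster_k = NULL,
                            de_alpha = 0.01, n_bins = 10L, seed = 1L, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(names(extra), collapse = ", "))
  structure(list(tpm_min = tpm_min, coverage_min = coverage_min,
                 pseudoalign_min = pseudoalign_min, fsc_cut = fsc_cut,
                 mean_pseudoalign_cut = mean_pseudoalign_cut,
                 residual_threshold = residual_threshold, smoother = smoother,
                 scan_threshold_frac = scan_threshold_frac,
                 kmer_k = kmer_k, kmer_alpha = kmer_alpha,
                 trans_scheme = trans_scheme, sine_scheme = sine_scheme,
                 n_components = n_components, cluster_k = cluster_k,
                 de_alpha = de_alpha, n_bins = n_bins, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full single-condensate analysis pipeline
#'
#' Chains the stages on a fixture directory (as written by
#' [write_fixture()] or assembled externally in the same layout): QC
#' filtering, detection-frequency enrichment calling, motif scanning of the
#' enriched transcripts, pairwise pool complementarity, optional SINE
#' homology scoring, and (when several condensate types are present)
#' cross-type correlation. Per-stage entity counts are logged; any stage
#' failure aborts with the stage name. Reruns on identical inputs and seed
#' give identical reports.
#'
#' @param input_dir fixture directory containing the count matrix,
#'   `lengths.tsv`, `metadata.csv`, `transcripts.fasta` and (for input
#'   abundances) `truth.tsv` or an `input_tpm.tsv` with columns
#'   `transcript_id`, `input_tpm`.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for per-stage TSV outputs.
#' @param sine_refs optional named character vector of SINE reference
#'   sequences.
#' @param logfile optional path appended with one log line per stage.
#' @return list of class `condenseq_report` with components `qc`,
#'   `enrichment`, `hits`, `kmers`, `complementarity`, `sine`,
#'   `type_correlations` (when applicable) and `summary`.
#' @export
run_pipeline <- function(input_dir, config = pipeline_config(),
                         out_dir = NULL, sine_refs = NULL, logfile = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  fx <- stage("read", read_fixture(input_dir))
  cm <- fx$matrix
  if (is.null(fx$pool_info) || !"input_tpm" %in% names(fx$pool_info)) {
    it_path <- file.path(input_dir, "input_tpm.tsv")
    if (!file.exists(it_path))
      stop("pipeline stage 'read' failed: no input-pool abundances (truth.tsv or input_tpm.tsv)")
    fx$pool_info <- read.delim(it_path, stringsAsFactors = FALSE)
  }
  if (!"length" %in% names(fx$pool_info))
    fx$pool_info$length <- unname(cm$lengths[fx$pool_info$transcript_id])

  qc <- stage("qc", filter_matrix(cm, config))
  .log_stage("qc", ncol(cm$counts), ncol(qc$matrix$counts), logfile)

  detfreq <- stage("enrichment", detection_frequency(qc$matrix, config$tpm_min))
  et <- stage("enrichment",
              enrichment_table(detfreq, fx$pool_info,
                               threshold = config$residual_threshold,
                               smoother = config$smoother))
  .log_stage("enrichment", nrow(et), sum(et$enriched), logfile)

  enriched_ids <- et$transcript_id[et$enriched]
  seqs <- fx$sequences
  hits <- NULL; kmers <- NULL; comp <- NULL; sine <- NULL
  if (!is.null(seqs) && length(enriched_ids) >= 2) {
    bg_ids <- et$transcript_id[!et$enriched & !is.na(et$residual)]
    kmers <- stage("discover", discover_kmers(
      seqs[enriched_ids],
      seqs[withr::with_seed(config$seed,
                            sample(bg_ids, min(length(bg_ids),
                                               length(enriched_ids))))],
      k = config$kmer_k, alpha = config$kmer_alpha))
    .log_stage("discover", length(enriched_ids), nrow(kmers$merged), logfile)

    scan_motif_set <- if (nrow(kmers$merged) >= 1)
      lapply(seq_len(min(10, nrow(kmers$merged))), function(i)
        motif(sprintf("motif%d", i), consensus = kmers$merged$consensus[i]))
    else list()
    if (length(scan_motif_set)) {
      hits <- stage("scan", scan_motifs(seqs, scan_motif_set,
                                        threshold_frac = config$scan_threshold_frac))
      .log_stage("scan", length(seqs), nrow(hits), logfile)
    }
    comp <- stage("complement", pool_complementarity(
      seqs[enriched_ids], seqs[bg_ids], scheme = config$trans_scheme,
      seed = config$seed))
    .log_stage("complement", length(enriched_ids), nrow(comp$scores), logfile)
    if (!is.null(sine_refs) && !is.null(hits) && nrow(hits) > 0) {
      enr_hits <- hits[hits$transcript_id %in% enriched_ids, ]
      hit_seqs <- split(enr_hits, enr_hits$motif_id)
      motif_hits <- lapply(hit_seqs, function(h) {
        h <- h[order(-h$score), ][seq_len(min(5, nrow(h))), ]
        substring(seqs[h$transcript_id], h$start + 1, h$end)
      })
      sine <- stage("sine", sine_homology(motif_hits, sine_refs,
                                          scheme = config$sine_scheme))
      .log_stage("sine", length(motif_hits), nrow(sine), logfile)
    }
  }
  tc <- NULL
  if ("condensate_type" %in% names(qc$matrix$meta) &&
      length(unique(qc$matrix$meta$condensate_type)) >= 2) {
    tc <- stage("compare", type_correlations(type_frequency_matrix(
      qc$matrix, config$tpm_min)))
    .log_stage("compare", ncol(tc), ncol(tc), logfile)
  }
  report <- list(qc = qc, enrichment = et, hits = hits, kmers = kmers,
                 complementarity = comp, sine = sine, type_correlations = tc,
                 summary = list(
                   n_condensates_in = ncol(cm$counts),
                   n_condensates_pass = ncol(qc$matrix$counts),
                   n_transcripts = nrow(et),
                   n_enriched = sum(et$enriched),
                   config = unclass(config)))
  class(report) <- "condenseq_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(qc$report, file.path(out_dir, "qc_report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(et), file.path(out_dir, "enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(hits))
      write.table(hits, file.path(out_dir, "motif_hits.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    if (!is.null(comp))
      write.table(comp$scores, file.path(out_dir, "complementarity.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(sine))
      write.table(data.frame(motif_id = rownames(sine), sine),
                  file.path(out_dir, "sine_scores.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }
  report
}

#' @export
print.condenseq_report <- function(x, ...) {
  s <- x$summary
  cat("condenseq pipeline report\n")
  cat(sprintf("  condensates: %d in, %d passing QC\n",
              s$n_condensates_in, s$n_condensates_pass))
  cat(sprintf("  transcripts: %d analysed, %d enriched\n",
              s$n_transcripts, s$n_enriched))
  if (!is.null(x$kmers))
    cat(sprintf("  discovered merged k-mer motifs: %d\n", nrow(x$kmers$merged)))
  if (!is.null(x$complementarity))
    cat(sprintf("  enriched x enriched complementarity max %s maximum outside (%.1f)\n",
                if (x$complementarity$exceeds) "exceeds" else "does not exceed",
                x$complementarity$outside_max))
  invisible(x)
}
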