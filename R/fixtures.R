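#' Write a simulated dataset to disk
#'
#' Emits a complete on-disk fixture for a simulated pool and condensate
#' population: transcript FASTA, the count matrix (dense TSV and
#' MatrixMarket triplet), transcript lengths, condensate metadata CSV,
#' ground-truth labels TSV and a YAML manifest recording every generator
#' parameter and seed, so the dataset can be regenerated byte-identically
#' with [regenerate_fixture()].
#'
#' @param pool a [generate_pool()] result (must be non-empty).
#' @param cm the matching [simulate_condensates()] result.
#' @param out_dir output directory (created).
#' @return named character vector of written paths (the manifest first),
#'   invisibly.
#' @export
write_fixture <- function(pool, cm, out_dir) {
  stopifnot(inherits(pool, "transcript_pool"), inherits(cm, "condensate_matrix"))
  if (nrow(pool$info) == 0) stop("empty transcript pool; nothing written")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(manifest = file.path(out_dir, "manifest.yaml"),
             fasta = file.path(out_dir, "transcripts.fasta"),
             truth = file.path(out_dir, "truth.tsv"))
  ok <- tryCatch({
    write_fasta(pool$sequences, paths["fasta"])
    mp <- write_count_matrix(cm, out_dir)
    write.table(pool$info, paths["truth"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    # precision 17 so double-valued parameters survive the YAML round trip
    yaml::write_yaml(list(generator = "condenseq",
                          pool = pool$params, simulation = cm$params),
                     paths["manifest"], precision = 17)
    c(paths, mp)
  }, error = function(e) stop("fixture write failed for ", out_dir, ": ",
                              conditionMessage(e), call. = FALSE))
  invisible(ok)
}

#' Read a fixture directory back into memory
#'
#' @param dir directory written by [write_fixture()].
#' @return list with `pool_info` (truth table), `sequences` and `matrix`
#'   (a `condensate_matrix`).
#' @export
read_fixture <- function(dir) {
  cm <- read_count_matrix(dir)
  truth_path <- file.path(dir, "truth.tsv")
  fasta_path <- file.path(dir, "transcripts.fasta")
  list(pool_info = if (file.exists(truth_path))
    read.delim(truth_path, stringsAsFactors = FALSE) else NULL,
    sequences = if (file.exists(fasta_path)) read_fasta(fasta_path) else NULL,
    matrix = cm)
}

#' Regenerate a fixture from its manifest
#'
#' Re-runs the generator with the parameters and seeds recorded in a
#' fixture manifest; with an unchanged package version the regenerated
#' files are byte-identical to the originals.
#'
#' @param manifest path to a `manifest.yaml` written by [write_fixture()].
#' @param out_dir output directory for the regenerated fixture.
#' @return the written paths, invisibly.
#' @export
regenerate_fixture <- function(manifest, out_dir) {
  mf <- yaml::read_yaml(manifest)
  pp <- mf$pool
  pool <- generate_pool(n_transcripts = pp$n_transcripts,
                        motif_pair = unlist(pp$motif_pair),
                        frac_enriched = pp$frac_enriched, spacing = pp$spacing,
                        seed = pp$seed, len_median = pp$len_median,
                        len_sdlog = pp$len_sdlog, tpm_sdlog = pp$tpm_sdlog,
                        gc = pp$gc)
  sp <- mf$simulation
  model <- do.call(uptake_model, sp$model[setdiff(names(sp$model), "type_weights")])
  if (!is.null(sp$model$type_weights)) model$type_weights <- sp$model$type_weights
  cm <- simulate_condensates(pool, model, n_condensates = sp$n_condensates,
                             types = unlist(sp$types), seed = sp$seed,
                             fsc_meanlog = sp$fsc_meanlog,
                             fsc_sdlog = sp$fsc_sdlog,
                             experiment = sp$experiment)
  write_fixture(pool, cm, out_dir)
}
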