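#' Read and write FASTA sequence files
#'
#' Thin wrappers around `Biostrings` returning plain named character vectors,
#' the sequence representation used throughout the package.
#'
#' @param path file path.
#' @param x named character vector of sequences.
#' @return `read_fasta`: named character vector. `write_fasta`: `path`,
#'   invisibly.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  if (is.null(names(x))) stop("sequences must be named")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
  invisible(path)
}

#' Read a transcript-by-condensate count matrix
#'
#' Accepts either a dense TSV (header row of condensate ids, first column
#' transcript ids) or a MatrixMarket triplet directory containing
#' `matrix.mtx`, `features.tsv` (transcript ids) and `barcodes.tsv`
#' (condensate ids). Identifier duplicates, negative entries and dimension
#' mismatches between the triplet and its id lists are rejected.
#'
#' @param path TSV file, or directory holding the MatrixMarket triplet.
#' @param lengths named integer vector of transcript lengths; if `NULL`, a
#'   `lengths.tsv` (columns `transcript_id`, `length`) is looked up next to
#'   the matrix.
#' @param meta optional metadata data.frame (see [condensate_matrix()]); if
#'   `NULL`, a `metadata.csv` next to the matrix is used when present.
#' @return a `condensate_matrix`.
#' @export
read_count_matrix <- function(path, lengths = NULL, meta = NULL) {
  if (dir.exists(path)) {
    mtx_path <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx_path)) stop("no matrix.mtx in directory ", path)
    m <- as.matrix(Matrix::readMM(mtx_path))
    feats <- readLines(file.path(path, "features.tsv"))
    bcs <- readLines(file.path(path, "barcodes.tsv"))
    if (length(feats) != nrow(m))
      stop("features.tsv has ", length(feats), " ids but matrix has ",
           nrow(m), " rows")
    if (length(bcs) != ncol(m))
      stop("barcodes.tsv has ", length(bcs), " ids but matrix has ",
           ncol(m), " columns")
    dimnames(m) <- list(feats, bcs)
    base_dir <- path
  } else {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    storage.mode(m) <- "double"
    if (anyNA(m)) stop("missing values in count matrix ", path)
    base_dir <- dirname(path)
  }
  if (any(m < 0)) stop("negative values in count matrix")
  if (is.null(lengths)) {
    lp <- file.path(base_dir, "lengths.tsv")
    if (!file.exists(lp)) stop("no transcript lengths supplied and no ", lp)
    ldf <- read.delim(lp, stringsAsFactors = FALSE)
    lengths <- setNames(as.integer(ldf$length), ldf$transcript_id)
  }
  if (is.null(meta)) {
    mp <- file.path(base_dir, "metadata.csv")
    if (file.exists(mp)) meta <- read.csv(mp, stringsAsFactors = FALSE)
  }
  condensate_matrix(m, lengths, meta)
}

#' Write a condensate matrix to disk
#'
#' Emits the dense TSV, the MatrixMarket triplet (`matrix.mtx`,
#' `features.tsv`, `barcodes.tsv`), `lengths.tsv` and `metadata.csv` into a
#' directory, the layout [read_count_matrix()] reads back losslessly.
#'
#' @param cm a `condensate_matrix`.
#' @param out_dir output directory (created if absent).
#' @return named character vector of the written paths, invisibly.
#' @export
write_count_matrix <- function(cm, out_dir) {
  stopifnot(inherits(cm, "condensate_matrix"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(tsv = file.path(out_dir, "matrix.tsv"),
             mtx = file.path(out_dir, "matrix.mtx"),
             features = file.path(out_dir, "features.tsv"),
             barcodes = file.path(out_dir, "barcodes.tsv"),
             lengths = file.path(out_dir, "lengths.tsv"),
             meta = file.path(out_dir, "metadata.csv"))
  df <- data.frame(transcript_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, paths["tsv"], sep = "\t", quote = FALSE, row.names = FALSE)
  Matrix::writeMM(Matrix::Matrix(cm$counts, sparse = TRUE), paths["mtx"])
  writeLines(rownames(cm$counts), paths["features"])
  writeLines(colnames(cm$counts), paths["barcodes"])
  write.table(data.frame(transcript_id = names(cm$lengths),
                         length = unname(cm$lengths)),
              paths["lengths"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.csv(cm$meta, paths["meta"], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Read motifs from a minimal MEME-style text file
#'
#' Parses a minimal motif text format: each motif starts with a line
#' `MOTIF <id>`, followed either by a
#' `letter-probability matrix: alength= 4 w= <width>` header and `<width>`
#' rows of four probabilities (A C G T order), or by a single consensus
#' line of A/C/G/T letters. Probability columns must sum to 1 (tolerance
#' 1e-6) and widths lie in \[4, 100\]. The consensus of a matrix motif is
#' the per-column argmax with alphabetical tie-break A < C < G < T.
#'
#' @param path motif file.
#' @return list of [motif()] objects; empty list (with a warning) for an
#'   empty file.
#' @export
read_motifs <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^MOTIF\\b", lines)
  if (length(starts) == 0) {
    warning("no motifs found in ", path)
    return(list())
  }
  ends <- c(starts[-1] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    id <- sub("^MOTIF\\s+", "", lines[starts[k]])
    id <- strsplit(id, "\\s+")[[1]][1]
    block <- lines[seq(starts[k] + 1L, ends[k])]
    hdr <- grep("^letter-probability matrix", block)
    if (length(hdr)) {
      w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", block[hdr[1]]))
      rows <- block[seq(hdr[1] + 1L, hdr[1] + w)]
      pm <- t(vapply(strsplit(rows, "\\s+"),
                     function(r) as.numeric(r[1:4]), numeric(4)))
      out[[k]] <- motif(id, matrix = t(pm))  # 4 x width
    } else {
      cons <- block[grepl("^[ACGTacgt]+$", block)][1]
      if (is.na(cons)) stop("motif '", id, "': no matrix and no consensus line")
      out[[k]] <- motif(id, consensus = cons)
    }
  }
  out
}

#' Write motifs in the minimal MEME-style text format
#'
#' @param motifs list of [motif()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_motifs <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat("MEME-minimal motif set\n\n", file = con)
  for (m in motifs) {
    cat(sprintf("MOTIF %s\nletter-probability matrix: alength= 4 w= %d\n",
                m$motif_id, m$width), file = con)
    write.table(format(t(m$matrix), digits = 6), con, quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    cat("\n", file = con)
  }
  invisible(path)
}

#' Read and write key-value pipeline configuration files
#'
#' Configurations are YAML key-value files; [pipeline_config()] validates
#' and fills defaults.
#'
#' @param path file path.
#' @param config a list / `pipeline_config`.
#' @return `read_config`: a validated `pipeline_config`.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
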