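#' Detection-frequency matrix per condensate type
#'
#' Detection frequency (percent) of every transcript within each condensate
#' type, with per-type passing-condensate counts.
#'
#' @param cm a filtered `condensate_matrix` with TPM and a
#'   `condensate_type` metadata column.
#' @param tpm_min detection threshold (default 1).
#' @return list with `freq` (matrix transcripts x types, percent) and `n`
#'   (named condensate counts).
#' @export
type_frequency_matrix <- function(cm, tpm_min = 1) {
  stopifnot(inherits(cm, "condensate_matrix"),
            "condensate_type" %in% names(cm$meta))
  if (is.null(cm$tpm)) stop("compute TPM first")
  keep <- if ("is_control" %in% names(cm$meta)) !cm$meta$is_control else
    rep(TRUE, ncol(cm$tpm))
  types <- unique(cm$meta$condensate_type[keep])
  freq <- vapply(types, function(ty) {
    cols <- keep & cm$meta$condensate_type == ty
    100 * rowMeans(cm$tpm[, cols, drop = FALSE] >= tpm_min)
  }, numeric(nrow(cm$tpm)))
  list(freq = freq,
       n = vapply(types, function(ty)
         sum(keep & cm$meta$condensate_type == ty), integer(1)))
}

#' Pairwise Pearson correlation of detection frequencies between types
#'
#' Correlates per-transcript detection frequencies between condensate types
#' over the transcripts detected in at least one type. Types with zero
#' variance yield `NA` entries with a warning; the diagonal is 1.
#'
#' @param freq matrix transcripts x types (e.g. `type_frequency_matrix()$freq`),
#'   or the list returned by [type_frequency_matrix()].
#' @return symmetric correlation matrix with unit diagonal.
#' @export
type_correlations <- function(freq) {
  if (is.list(freq) && !is.data.frame(freq)) freq <- freq$freq
  freq <- as.matrix(freq)
  if (ncol(freq) < 2) stop("need at least 2 condensate types")
  shared <- rowSums(freq > 0) > 0
  f <- freq[shared, , drop = FALSE]
  novar <- apply(f, 2, sd) == 0
  if (any(novar))
    warning("type(s) with zero detection-frequency variance: ",
            paste(colnames(f)[novar], collapse = ", "))
  r <- suppressWarnings(cor(f))
  diag(r) <- 1
  r
}

#' Input-normalised profiles of enriched transcripts
#'
#' Builds the condensate-by-transcript profile matrix used for embedding:
#' restricted to the union of per-type enriched transcripts, each entry is
#' `log((condensate TPM + 1) / (input TPM + 1))`, then centred and
#' unit-scaled per transcript within each experiment batch. Transcripts
#' absent from the input pool are excluded with a message; rows with zero
#' variance within a batch scale to 0.
#'
#' @param cm a filtered `condensate_matrix` with TPM.
#' @param enriched_ids character vector: union of enriched transcript ids
#'   across condensate types (e.g. from [enrichment_table()] per type).
#' @param input_tpm named input-pool TPM vector.
#' @return matrix condensates x transcripts of scaled log-ratios, with
#'   condensate metadata in `attr(, "meta")`.
#' @export
build_profiles <- function(cm, enriched_ids, input_tpm) {
  stopifnot(inherits(cm, "condensate_matrix"))
  if (is.null(cm$tpm)) stop("compute TPM first")
  enriched_ids <- intersect(enriched_ids, rownames(cm$tpm))
  if (length(enriched_ids) == 0) stop("no enriched transcripts in the matrix")
  absent <- enriched_ids[is.na(input_tpm[enriched_ids]) |
                           input_tpm[enriched_ids] <= 0]
  if (length(absent)) {
    message(length(absent), " enriched transcript(s) absent from the input pool excluded")
    enriched_ids <- setdiff(enriched_ids, absent)
  }
  ratio <- log((t(cm$tpm[enriched_ids, , drop = FALSE]) + 1) /
                 rep(input_tpm[enriched_ids] + 1, each = ncol(cm$tpm)))
  batch <- if ("experiment" %in% names(cm$meta)) cm$meta$experiment else
    rep("all", nrow(ratio))
  for (b in unique(batch)) {
    rows <- batch == b
    mu <- colMeans(ratio[rows, , drop = FALSE])
    sdv <- apply(ratio[rows, , drop = FALSE], 2, sd)
    sdv[sdv == 0] <- 1
    ratio[rows, ] <- sweep(sweep(ratio[rows, , drop = FALSE], 2, mu), 2, sdv, `/`)
  }
  attr(ratio, "meta") <- cm$meta
  ratio
}

#' PCA embedding and clustering of single condensates
#'
#' Projects condensate profiles onto the first `n_components` principal
#' components (5 by default) and clusters them with seeded k-means. When
#' `k = NULL` the cluster number is chosen in 2..6 by the mean silhouette
#' width. Degenerate inputs (all profiles identical) are flagged and return
#' no labels.
#'
#' @param profiles condensates x transcripts matrix from [build_profiles()].
#' @param n_components number of principal components (default 5).
#' @param k number of clusters, or `NULL` for silhouette selection.
#' @param seed integer seed for k-means initialisation.
#' @return object of class `condensate_embedding`: list with `coords`
#'   (condensates x PCs), `cluster` (integer labels or `NULL` when
#'   degenerate), `k`, `degenerate`, `cluster_mean_fsc` (when FSC metadata
#'   is present) and `meta`.
#' @export
embed_and_cluster <- function(profiles, n_components = 5, k = NULL, seed = 0L) {
  meta <- attr(profiles, "meta")
  n <- nrow(profiles)
  if (!is.null(k) && k > n) stop("k exceeds the number of condensates")
  if (!is.null(k) && n < 2 * k) stop("need at least 2*k condensates")
  if (all(apply(profiles, 2, sd) == 0)) {
    warning("all condensate profiles identical; clustering is degenerate")
    return(structure(list(coords = NULL, cluster = NULL, k = NA_integer_,
                          degenerate = TRUE, meta = meta),
                     class = "condensate_embedding"))
  }
  pc <- prcomp(profiles, center = TRUE, scale. = FALSE)
  ncomp <- min(n_components, ncol(pc$x))
  coords <- pc$x[, seq_len(ncomp), drop = FALSE]
  km_at <- function(kk) withr::with_seed(as.integer(seed),
                                         kmeans(coords, centers = kk, nstart = 25))
  if (is.null(k)) {
    ks <- 2:min(6, n - 1)
    sil <- vapply(ks, function(kk) {
      cl <- km_at(kk)$cluster
      mean(cluster::silhouette(cl, dist(coords))[, "sil_width"])
    }, numeric(1))
    k <- ks[which.max(sil)]
  }
  km <- km_at(k)
  out <- list(coords = coords, cluster = km$cluster, k = k, degenerate = FALSE,
              meta = meta)
  if (!is.null(meta) && "fsc" %in% names(meta))
    out$cluster_mean_fsc <- tapply(meta$fsc, km$cluster, mean)
  structure(out, class = "condensate_embedding")
}

#' @export
print.condensate_embedding <- function(x, ...) {
  if (x$degenerate) {
    cat("condensate_embedding: degenerate (identical profiles), no labels\n")
  } else {
    cat(sprintf("condensate_embedding: %d condensates, %d PCs, k = %d clusters (sizes %s)\n",
                nrow(x$coords), ncol(x$coords), x$k,
                paste(table(x$cluster), collapse = "/")))
    if (!is.null(x$cluster_mean_fsc))
      cat("  mean FSC per cluster:",
          paste(sprintf("%.0f", x$cluster_mean_fsc), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Differential transcripts between two condensate groups
#'
#' Two-sided Wilcoxon rank-sum test on log2(TPM + 1) per transcript between
#' two groups of condensates, Bonferroni-corrected over the tested
#' transcripts. Transcripts that are all-zero in both groups are excluded
#' (with a message). Groups must each contain at least 3 condensates.
#'
#' @param cm a filtered `condensate_matrix` with TPM.
#' @param labels vector of two group labels, one per condensate (order of
#'   `cm` columns).
#' @param alpha significance threshold on adjusted p-values (default 0.01).
#' @return data.frame: `transcript_id`, `statistic` (rank-sum W),
#'   `log2fc` (mean log2(TPM+1) difference, group 1 minus group 2), `p`,
#'   `p_adj`, `significant`.
#' @export
differential_transcripts <- function(cm, labels, alpha = 0.01) {
  stopifnot(inherits(cm, "condensate_matrix"))
  if (is.null(cm$tpm)) stop("compute TPM first")
  labels <- as.character(labels)
  if (length(labels) != ncol(cm$tpm))
    stop("one label per condensate required")
  grp <- unique(labels)
  if (length(grp) != 2) stop("exactly two label groups required")
  g1 <- labels == grp[1]; g2 <- labels == grp[2]
  if (sum(g1) < 3 || sum(g2) < 3) stop("each group needs at least 3 condensates")
  lt <- log2(cm$tpm + 1)
  tested <- rowSums(lt) > 0
  if (any(!tested))
    message(sum(!tested), " all-zero transcript(s) excluded from testing")
  ids <- rownames(lt)[tested]
  res <- t(vapply(ids, function(tx) {
    x <- lt[tx, g1]; y <- lt[tx, g2]
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
    c(stat = unname(wt$statistic), p = wt$p.value,
      lfc = mean(x) - mean(y))
  }, numeric(3)))
  p_adj <- p.adjust(res[, "p"], method = "bonferroni")
  data.frame(transcript_id = ids, statistic = res[, "stat"],
             log2fc = res[, "lfc"], p = res[, "p"], p_adj = p_adj,
             significant = p_adj < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}
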