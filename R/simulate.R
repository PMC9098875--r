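#' Simulate a population of sequenced condensates
#'
#' Draws a condensate population (log-normal FSC sizes) and, for each
#' condensate, a captured-molecule depth `D ~ Poisson(depth_scale *
#' (fsc/fsc_ref)^capacity_exponent)` followed by a multinomial draw of D
#' molecules over the transcripts. The multinomial probabilities mix the
#' model's uptake weights with ambient input-pool proportions at
#' `ambient_fraction`, emulating RNA from the liquid surrounding a sorted
#' droplet. Per-condensate metadata (FSC, SSC, type, experiment, well,
#' simulated pseudoalignment fraction) is attached. Fully deterministic
#' given the seed.
#'
#' @param pool a [generate_pool()] result.
#' @param model an [uptake_model()].
#' @param n_condensates number of condensates to simulate (>= 2).
#' @param types character vector of condensate types, assigned round-robin
#'   (default a single `"CM-Dex:PDDA"` population).
#' @param seed integer seed.
#' @param fsc_meanlog,fsc_sdlog log-normal FSC distribution (defaults centre
#'   the population on the reference size `fsc_ref = 2e4`).
#' @param experiment experiment label stored in the metadata.
#' @return object of class `condensate_matrix`: list with `counts` (integer
#'   matrix, transcripts x condensates), `tpm` (initially `NULL`; see
#'   [compute_tpm()]), `lengths` (named integer), `meta` (data.frame with
#'   `condensate_id`, `fsc`, `ssc`, `condensate_type`, `experiment`, `well`,
#'   `is_control`, `pseudoalign_frac`, and the drawn molecule `depth`, which
#'   every column of `counts` sums to exactly), and `params`.
#' @examples
#' pool <- generate_pool(50, seed = 1)
#' cm <- simulate_condensates(pool, uptake_model(), n_condensates = 12, seed = 1)
#' colSums(cm$counts)  # one drawn depth per condensate
#' @export
simulate_condensates <- function(pool, model = uptake_model(),
                                 n_condensates, types = "CM-Dex:PDDA",
                                 seed = 1L,
                                 fsc_meanlog = log(2e4), fsc_sdlog = 0.35,
                                 experiment = "sim1") {
  stopifnot(inherits(pool, "transcript_pool"), inherits(model, "uptake_model"),
            n_condensates >= 2)
  info <- pool$info
  n_tx <- nrow(info)

  base_logw <- model$beta_abundance * log(info$input_tpm) +
    model$beta_length * log(info$length) +
    model$beta_motif * as.numeric(info$truth_enriched)
  ambient <- info$input_tpm / sum(info$input_tpm)

  withr::with_seed(as.integer(seed), {
    fsc <- rlnorm(n_condensates, fsc_meanlog, fsc_sdlog)
    ssc <- fsc * rlnorm(n_condensates, 0, 0.2)
    type <- rep_len(types, n_condensates)
    depth_mean <- model$depth_scale * (fsc / model$fsc_ref)^model$capacity_exponent
    depth <- rpois(n_condensates, depth_mean)

    counts <- matrix(0L, nrow = n_tx, ncol = n_condensates,
                     dimnames = list(info$transcript_id,
                                     sprintf("cond%04d", seq_len(n_condensates))))
    for (j in seq_len(n_condensates)) {
      logw <- base_logw
      if (!is.null(model$type_weights) && !is.null(model$type_weights[[type[j]]]))
        logw <- logw + rep_len(model$type_weights[[type[j]]], n_tx)
      w <- exp(logw - max(logw))
      if (!any(w > 0) || !all(is.finite(w)))
        stop("all-zero or non-finite uptake weight vector for condensate ", j)
      p <- (1 - model$ambient_fraction) * w / sum(w) +
        model$ambient_fraction * ambient
      if (depth[j] > 0)
        counts[, j] <- as.integer(rmultinom(1, size = depth[j], prob = p))
    }
    meta <- data.frame(
      condensate_id = colnames(counts),
      fsc = fsc, ssc = ssc,
      condensate_type = type,
      experiment = experiment,
      well = sprintf("%s%02d", LETTERS[(seq_len(n_condensates) - 1) %/% 12 %% 8 + 1],
                     (seq_len(n_condensates) - 1) %% 12 + 1),
      is_control = FALSE,
      pseudoalign_frac = rbeta(n_condensates, 16, 4),  # realistic high fractions
      depth = depth,
      stringsAsFactors = FALSE)
    cm <- list(counts = counts, tpm = NULL,
               lengths = setNames(info$length, info$transcript_id),
               meta = meta,
               params = list(n_condensates = n_condensates, types = types,
                             seed = as.integer(seed), fsc_meanlog = fsc_meanlog,
                             fsc_sdlog = fsc_sdlog, experiment = experiment,
                             model = unclass(model)))
    class(cm) <- "condensate_matrix"
    cm
  })
}

#' Construct a condensate matrix from components
#'
#' Assembles a `condensate_matrix` from a counts (or TPM) matrix, transcript
#' lengths and per-condensate metadata, validating identifiers. Used by the
#' readers and available for assembling matrices from external
#' quantifications.
#'
#' @param counts non-negative numeric matrix, transcripts x condensates, with
#'   dimnames.
#' @param lengths named integer vector of transcript lengths (nt).
#' @param meta data.frame with at least `condensate_id`; typically also
#'   `fsc`, `condensate_type`, `experiment`, `pseudoalign_frac`, `is_control`.
#' @param coverage optional named per-transcript read-coverage fraction in
#'   \[0, 1\].
#' @return a `condensate_matrix`.
#' @export
condensate_matrix <- function(counts, lengths, meta = NULL, coverage = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have transcript rownames and condensate colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate transcript identifiers")
  if (anyDuplicated(colnames(counts))) stop("duplicate condensate identifiers")
  if (any(counts < 0)) stop("negative values in count matrix")
  if (!all(rownames(counts) %in% names(lengths)))
    stop("lengths missing for some transcripts")
  lengths <- lengths[rownames(counts)]
  if (any(lengths <= 0)) stop("transcript lengths must be positive")
  if (is.null(meta)) {
    meta <- data.frame(condensate_id = colnames(counts), stringsAsFactors = FALSE)
  } else {
    if (!"condensate_id" %in% names(meta)) stop("meta needs a condensate_id column")
    if (!setequal(meta$condensate_id, colnames(counts)))
      stop("metadata condensate ids do not match matrix columns")
    meta <- meta[match(colnames(counts), meta$condensate_id), , drop = FALSE]
    rownames(meta) <- NULL
    if ("pseudoalign_frac" %in% names(meta) &&
        any(meta$pseudoalign_frac < 0 | meta$pseudoalign_frac > 1, na.rm = TRUE))
      stop("pseudoalign_frac must lie in [0, 1]")
  }
  if (!is.null(coverage)) {
    if (any(coverage < 0 | coverage > 1, na.rm = TRUE))
      stop("coverage fractions must lie in [0, 1]")
    coverage <- coverage[rownames(counts)]
  }
  structure(list(counts = counts, tpm = NULL, lengths = lengths, meta = meta,
                 coverage = coverage, params = list()),
            class = "condensate_matrix")
}

#' @export
print.condensate_matrix <- function(x, ...) {
  cat(sprintf("condensate_matrix: %d transcripts x %d condensates (%s TPM)\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$tpm)) "no" else "with"))
  if (nrow(x$meta) && "condensate_type" %in% names(x$meta)) {
    tb <- table(x$meta$condensate_type)
    cat("  types:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.condensate_matrix <- function(x) dim(x$counts)
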