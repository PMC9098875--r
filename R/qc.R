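#' Transcripts-per-million quantification
#'
#' Per condensate (column): `rate_t = count_t / length_t`, then
#' `tpm_t = rate_t / sum(rate) * 1e6`, so every column with any signal sums
#' to 1e6. All-zero columns stay all-zero with a warning.
#'
#' @param x a `condensate_matrix`, or a bare counts matrix.
#' @param lengths named transcript lengths (ignored when `x` is a
#'   `condensate_matrix`).
#' @return the `condensate_matrix` with its `tpm` slot filled, or (for a
#'   bare matrix input) the TPM matrix.
#' @examples
#' compute_tpm(matrix(c(10, 90), 2, 1, dimnames = list(c("A", "B"), "c1")),
#'             lengths = c(A = 1000, B = 3000))
#' @export
compute_tpm <- function(x, lengths = NULL) {
  if (inherits(x, "condensate_matrix")) {
    counts <- x$counts
    lengths <- x$lengths
  } else {
    counts <- as.matrix(x)
    if (is.null(lengths)) stop("supply transcript lengths")
    lengths <- lengths[rownames(counts)]
  }
  if (any(lengths <= 0) || anyNA(lengths)) stop("transcript lengths must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  rate <- counts / lengths
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warning(sum(zero), " condensate column(s) have no counts; TPM left at zero")
    tot[zero] <- 1
  }
  tpm <- sweep(rate, 2, tot, `/`) * 1e6
  if (inherits(x, "condensate_matrix")) {
    x$tpm <- tpm
    x
  } else tpm
}

#' Quality-control filtering of a condensate matrix
#'
#' Applies, in fixed order:
#' 1. **Condensate filter**: remove condensates with pseudoalignment
#'    fraction below `pseudoalign_min` *and* FSC above `fsc_cut` (large
#'    droplets should capture plenty of RNA, so a low aligned fraction
#'    there flags a failed library). Conjunctive: small condensates with
#'    low pseudoalignment are kept.
#' 2. **Coverage filter**: when the dataset's mean pseudoalignment is below
#'    `mean_pseudoalign_cut` and per-transcript coverage fractions are
#'    available, remove transcripts with read coverage below
#'    `coverage_min`.
#' 3. **Detection filter**: set TPM entries below `tpm_min` to zero (the
#'    transcript counts as not detected in that condensate), then recompute
#'    TPM on the surviving transcript set so columns renormalise to 1e6.
#'
#' The operation is idempotent: zeroing sub-threshold entries only
#' increases the surviving entries' renormalised TPM, so a second
#' application changes nothing.
#'
#' @param cm a `condensate_matrix`; TPM is computed if absent.
#' @param config a [pipeline_config()] or list overriding the thresholds
#'   `tpm_min` (1), `coverage_min` (0.2), `pseudoalign_min` (0.05),
#'   `fsc_cut` (2e4), `mean_pseudoalign_cut` (0.4).
#' @param renormalize recompute TPM after transcript removal/zeroing
#'   (default `TRUE`; set `FALSE` to keep the original column scale).
#' @return list of class `qc_result`: `matrix` (filtered
#'   `condensate_matrix` with counts zeroed/subset and TPM recomputed) and
#'   `report` (data.frame `entity`, `id`, `reason`, `value`, `threshold`)
#'   plus `counts_in`/`counts_out` bookkeeping.
#' @export
filter_matrix <- function(cm, config = pipeline_config(), renormalize = TRUE) {
  stopifnot(inherits(cm, "condensate_matrix"))
  cfg <- config
  if (is.null(cm$tpm)) cm <- suppressWarnings(compute_tpm(cm))
  report <- list()
  n_cond_in <- ncol(cm$counts); n_tx_in <- nrow(cm$counts)

  # 1. condensate filter (needs pseudoalign_frac when enabled)
  if (!is.null(cfg$pseudoalign_min)) {
    if (!"pseudoalign_frac" %in% names(cm$meta))
      stop("condensate filter enabled but metadata has no pseudoalign_frac")
    drop <- cm$meta$pseudoalign_frac < cfg$pseudoalign_min &
      cm$meta$fsc > cfg$fsc_cut
    if (any(drop)) {
      report[[length(report) + 1]] <- data.frame(
        entity = "condensate", id = cm$meta$condensate_id[drop],
        reason = "low_pseudoalignment_large_fsc",
        value = cm$meta$pseudoalign_frac[drop],
        threshold = cfg$pseudoalign_min, stringsAsFactors = FALSE)
      keep <- !drop
      cm$counts <- cm$counts[, keep, drop = FALSE]
      cm$tpm <- cm$tpm[, keep, drop = FALSE]
      cm$meta <- cm$meta[keep, , drop = FALSE]
      rownames(cm$meta) <- NULL
    }
  }

  # 2. low-coverage transcript filter, only for low-pseudoalignment datasets
  if (!is.null(cm$coverage) && !is.null(cfg$coverage_min) &&
      "pseudoalign_frac" %in% names(cm$meta) &&
      mean(cm$meta$pseudoalign_frac) < cfg$mean_pseudoalign_cut) {
    drop_tx <- !is.na(cm$coverage) & cm$coverage < cfg$coverage_min
    if (any(drop_tx)) {
      report[[length(report) + 1]] <- data.frame(
        entity = "transcript", id = rownames(cm$counts)[drop_tx],
        reason = "low_read_coverage", value = cm$coverage[drop_tx],
        threshold = cfg$coverage_min, stringsAsFactors = FALSE)
      cm$counts <- cm$counts[!drop_tx, , drop = FALSE]
      cm$tpm <- cm$tpm[!drop_tx, , drop = FALSE]
      cm$lengths <- cm$lengths[!drop_tx]
      cm$coverage <- cm$coverage[!drop_tx]
    }
  }

  # 3. sub-threshold TPM entries -> not detected
  low <- cm$tpm < cfg$tpm_min & cm$tpm > 0
  if (any(low)) {
    cm$counts[low] <- 0
    n_zeroed <- sum(low)
    report[[length(report) + 1]] <- data.frame(
      entity = "entry", id = sprintf("%d entries", n_zeroed),
      reason = "tpm_below_min", value = NA_real_,
      threshold = cfg$tpm_min, stringsAsFactors = FALSE)
  }
  if (renormalize) cm <- suppressWarnings(compute_tpm(cm))

  report <- if (length(report)) do.call(rbind, report) else
    data.frame(entity = character(0), id = character(0), reason = character(0),
               value = numeric(0), threshold = numeric(0))
  structure(list(matrix = cm, report = report,
                 counts_in = c(transcripts = n_tx_in, condensates = n_cond_in),
                 counts_out = c(transcripts = nrow(cm$counts),
                                condensates = ncol(cm$counts))),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("qc_result: %d/%d condensates and %d/%d transcripts retained; %d report rows\n",
              x$counts_out["condensates"], x$counts_in["condensates"],
              x$counts_out["transcripts"], x$counts_in["transcripts"],
              nrow(x$report)))
  invisible(x)
}

#' Partition coefficient from fluorescence intensities
#'
#' The partition coefficient K of a droplet is the ratio of RNA
#' concentration inside the droplet to the surrounding supernatant,
#' estimated from mean fluorescence intensities: `K_i = droplet_i /
#' supernatant`. Returns the mean and sample standard deviation (n-1
#' denominator; 0 when a single droplet is measured).
#'
#' @param droplets positive numeric vector of per-droplet mean intensities.
#' @param supernatant positive scalar supernatant mean intensity.
#' @return list with `k` (per-droplet coefficients), `mean`, `sd`, `n`.
#' @examples
#' partition_coefficient(c(80, 120), 10)  # mean 10, sd ~2.83
#' @export
partition_coefficient <- function(droplets, supernatant) {
  if (length(droplets) < 1) stop("need at least one droplet intensity")
  if (!is.numeric(supernatant) || length(supernatant) != 1 || supernatant <= 0)
    stop("supernatant intensity must be a positive scalar")
  k <- droplets / supernatant
  list(k = k, mean = mean(k), sd = if (length(k) > 1) sd(k) else 0,
       n = length(k))
}
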