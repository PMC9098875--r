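#' Per-transcript detection frequency across condensates
#'
#' The percentage of QC-passing, non-control condensates in which each
#' transcript is detected (post-filter TPM at or above `tpm_min`). Also
#' returns the frequency category used for descriptive summaries:
#' `not_detected` (0), `lt10` (0-10), `mid` (10-90, inclusive) and `gt90`
#' (above 90).
#'
#' @param cm a filtered `condensate_matrix` with TPM computed (see
#'   [filter_matrix()]).
#' @param tpm_min detection threshold on TPM (default 1, matching the QC
#'   filter so "detected" and "retained" coincide).
#' @return data.frame: `transcript_id`, `n_detected`, `n_condensates`,
#'   `detect_freq` (percent), `bin`.
#' @export
detection_frequency <- function(cm, tpm_min = 1) {
  stopifnot(inherits(cm, "condensate_matrix"))
  if (is.null(cm$tpm)) stop("compute TPM (or run filter_matrix) first")
  keep <- if ("is_control" %in% names(cm$meta)) !cm$meta$is_control else
    rep(TRUE, ncol(cm$tpm))
  n <- sum(keep)
  if (n == 0) stop("zero passing condensates")
  det <- rowSums(cm$tpm[, keep, drop = FALSE] >= tpm_min)
  freq <- 100 * det / n
  bin <- ifelse(det == 0, "not_detected",
         ifelse(freq < 10, "lt10",
         ifelse(freq <= 90, "mid", "gt90")))
  data.frame(transcript_id = rownames(cm$tpm), n_detected = as.integer(det),
             n_condensates = n, detect_freq = freq,
             bin = factor(bin, levels = c("not_detected", "lt10", "mid", "gt90")),
             stringsAsFactors = FALSE)
}

#' Smoothed detection-frequency expectation from input abundance
#'
#' Fits detection frequency (percent) as a smooth function of
#' `log10(input_tpm + 1)` and returns predictions at the observed
#' abscissae. The default smoother is a penalized cubic smoothing spline
#' with the smoothing parameter chosen by generalized cross-validation
#' (`stats::smooth.spline`); a local-linear LOESS fit is available as an
#' independent alternative. Transcripts absent from the input
#' (`input_tpm = 0`) should be excluded before fitting (see
#' [enrichment_table()]).
#'
#' @param input_tpm positive input abundances (TPM).
#' @param detect_freq detection frequencies in percent.
#' @param smoother `"spline"` (default) or `"loess"`.
#' @param spar optional fixed smoothing parameter for the spline (otherwise
#'   GCV); `span` for LOESS (default 0.75).
#' @param span LOESS span.
#' @return numeric vector of fitted frequencies at the input order.
#' @export
fit_frequency_smoother <- function(input_tpm, detect_freq,
                                   smoother = c("spline", "loess"),
                                   spar = NULL, span = 0.75) {
  smoother <- match.arg(smoother)
  stopifnot(length(input_tpm) == length(detect_freq))
  if (length(input_tpm) < 20)
    stop("need at least 20 transcripts to fit the smoother")
  x <- log10(input_tpm + 1)
  if (diff(range(x)) == 0) stop("degenerate abscissa: all input TPM equal")
  if (smoother == "spline") {
    fit <- if (is.null(spar)) smooth.spline(x, detect_freq, cv = FALSE)
    else smooth.spline(x, detect_freq, spar = spar)
    as.numeric(predict(fit, x)$y)
  } else {
    fit <- loess(detect_freq ~ x, degree = 1, span = span,
                 family = "gaussian",
                 control = stats::loess.control(surface = "direct"))
    as.numeric(predict(fit, data.frame(x = x)))
  }
}

#' Enrichment table: observed vs expected detection frequency
#'
#' Combines input abundance and detection frequency, fits the abundance
#' smoother, computes residuals (observed minus fitted, in percentage
#' points) and flags enriched transcripts. Transcripts with zero input TPM
#' are excluded from the fit and reported separately with `NA` residuals
#' (they have no abundance expectation to deviate from).
#'
#' @param detfreq result of [detection_frequency()].
#' @param pool_info data.frame with `transcript_id`, `input_tpm`, `length`
#'   (e.g. the `info` component of a [generate_pool()] result, or assembled
#'   from an input-pool quantification).
#' @param threshold residual threshold in percentage points for the
#'   enriched call (default 30, strict `>`).
#' @param smoother,spar,span passed to [fit_frequency_smoother()].
#' @return object of class `enrichment_table`: data.frame `transcript_id`,
#'   `input_tpm`, `length`, `detect_freq`, `fitted_freq`, `residual`,
#'   `enriched`, `bin`, with the fit settings in attributes.
#' @export
enrichment_table <- function(detfreq, pool_info, threshold = 30,
                             smoother = "spline", spar = NULL, span = 0.75) {
  df <- merge(detfreq, pool_info[, c("transcript_id", "input_tpm", "length")],
              by = "transcript_id", sort = FALSE)
  fit_set <- df$input_tpm > 0
  df$fitted_freq <- NA_real_
  df$fitted_freq[fit_set] <- fit_frequency_smoother(
    df$input_tpm[fit_set], df$detect_freq[fit_set], smoother = smoother,
    spar = spar, span = span)
  df$residual <- df$detect_freq - df$fitted_freq
  df$enriched <- call_enriched(df$residual, threshold)
  out <- df[, c("transcript_id", "input_tpm", "length", "detect_freq",
                "fitted_freq", "residual", "enriched", "bin")]
  attr(out, "threshold") <- threshold
  attr(out, "smoother") <- smoother
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Enriched-transcript call from residuals
#'
#' A transcript is enriched when its residual (observed minus
#' abundance-expected detection frequency) strictly exceeds the threshold,
#' 30 percentage points by default. `NA` residuals (input-absent
#' transcripts) yield `FALSE`.
#'
#' @param residual numeric residuals in percentage points.
#' @param threshold strict threshold (default 30).
#' @return logical vector.
#' @examples
#' call_enriched(c(31, 30, -5))  # TRUE FALSE FALSE
#' @export
call_enriched <- function(residual, threshold = 30) {
  out <- residual > threshold
  out[is.na(out)] <- FALSE
  out
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("enrichment_table: %d transcripts, %d enriched (residual > %g, %s smoother)\n",
              nrow(x), sum(x$enriched), attr(x, "threshold"), attr(x, "smoother")))
  invisible(x)
}

#' @export
summary.enrichment_table <- function(object, ...) {
  cat(sprintf("%d transcripts; detection frequency bins:\n", nrow(object)))
  print(table(object$bin))
  cat(sprintf("enriched (residual > %g): %d\n", attr(object, "threshold"),
              sum(object$enriched)))
  invisible(object)
}

#' Plot detection frequency against input abundance
#'
#' The diagnostic scatter of detection frequency vs log10 input TPM with
#' the fitted smoother and enriched transcripts highlighted.
#'
#' @param x an `enrichment_table`.
#' @param ... passed to `plot`.
#' @export
plot.enrichment_table <- function(x, ...) {
  lx <- log10(x$input_tpm + 1)
  plot(lx, x$detect_freq, pch = 16, cex = 0.5,
       col = ifelse(x$enriched, "red", grDevices::grey(0.4, 0.5)),
       xlab = "log10(input TPM + 1)", ylab = "detection frequency (%)", ...)
  ok <- !is.na(x$fitted_freq)
  o <- order(lx[ok])
  graphics::lines(lx[ok][o], x$fitted_freq[ok][o], col = "blue", lwd = 2)
  invisible(x)
}

#' Length-residual correlation within input-abundance bins
#'
#' Splits transcripts into near-equal quantile bins of input TPM
#' (log-spaced) and reports the Pearson correlation of transcript length
#' with enrichment residual inside each bin, isolating the length effect
#' from the dominant abundance effect. Bins with fewer than 5 transcripts
#' are reported as `NA`.
#'
#' @param et an [enrichment_table()].
#' @param n_bins number of abundance bins (>= 2; default 10).
#' @return data.frame: `bin`, `n`, `tpm_lo`, `tpm_hi`, `r`.
#' @export
binned_length_correlation <- function(et, n_bins = 10) {
  if (n_bins < 2) stop("n_bins must be at least 2")
  df <- et[et$input_tpm > 0 & !is.na(et$residual), ]
  if (nrow(df) < 5 * n_bins)
    stop("need at least ", 5 * n_bins, " transcripts for ", n_bins, " bins")
  br <- quantile(log10(df$input_tpm), probs = seq(0, 1, length.out = n_bins + 1))
  br[1] <- -Inf; br[n_bins + 1] <- Inf
  bin <- cut(log10(df$input_tpm), br, labels = FALSE)
  res <- lapply(seq_len(n_bins), function(b) {
    sub <- df[bin == b, ]
    r <- if (nrow(sub) < 5 || sd(sub$length) == 0 || sd(sub$residual) == 0)
      NA_real_ else cor(sub$length, sub$residual)
    data.frame(bin = b, n = nrow(sub),
               tpm_lo = min(sub$input_tpm), tpm_hi = max(sub$input_tpm), r = r)
  })
  do.call(rbind, res)
}
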