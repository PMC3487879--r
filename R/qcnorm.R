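# Probe-level QC by detection P-value and quantile normalization of log2
# intensities.

#' Filter probes by detection P-value
#'
#' A probe is excluded when its detection P-value exceeds `alpha` in at
#' least `fail_fraction` of the samples (i.e. it is retained iff the number
#' of failing samples is strictly below `fail_fraction * n_samples`). The
#' default mirrors the common Illumina rule: drop probes not detected
#' (P > 0.05) in >= 25% of samples. Setting `fail_fraction = 0.75` instead
#' keeps every probe detected in at least 25% of samples, the laxer reading
#' sometimes used for "expressed above background" filters.
#'
#' @param expr an [expression_matrix()] carrying detection P-values.
#' @param alpha detection threshold in (0, 1); a sample "fails" a probe when
#'   detection P > alpha.
#' @param fail_fraction fraction of samples in (0, 1] at which a probe is
#'   excluded.
#' @return the filtered [expression_matrix()]; sample set unchanged, probe
#'   order preserved. Emits a message with probes in/out.
#' @export
detection_filter <- function(expr, alpha = 0.05, fail_fraction = 0.25) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (is.null(expr$detection_p))
    stop_val(paste("no detection P-values present; supply them or skip QC",
                   "(--no-qc in the command-line pipeline)"))
  check_number(alpha, "alpha", 0, 1, closed_lower = FALSE,
               closed_upper = FALSE)
  check_number(fail_fraction, "fail_fraction", 0, 1, closed_lower = FALSE)
  n <- ncol(expr$intensities)
  fails <- rowSums(expr$detection_p > alpha)
  keep <- fails < fail_fraction * n
  message(sprintf(
    "detection_filter: %d of %d probes retained (excluded if detection P > %g in >= %g%% of %d samples)",
    sum(keep), length(keep), alpha, 100 * fail_fraction, n))
  out <- expr
  out$intensities <- expr$intensities[keep, , drop = FALSE]
  out$detection_p <- expr$detection_p[keep, , drop = FALSE]
  out
}

#' Quantile-normalize log2 intensities
#'
#' Raw intensities are log2-transformed first (shifted by `log_offset` when
#' any value is <= 0, as background-subtracted Illumina data can be), then
#' every sample's value distribution is forced to the common rank-wise mean
#' distribution. Ties receive the average of the tied ranks' means. The
#' rank-to-mean mapping is delegated to [limma::normalizeQuantiles()].
#'
#' @param expr an [expression_matrix()] on the `raw` or `log2` scale.
#' @param log_offset offset added before log2 when non-positive raw
#'   intensities are present (default 1).
#' @return the normalized [expression_matrix()] with scale flag
#'   `"log2-quantile-normalized"`; within-sample rank order is preserved.
#' @export
quantile_normalize <- function(expr, log_offset = 1) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (nrow(expr$intensities) < 2L)
    stop_val("quantile normalization needs at least 2 probes (got %d)",
             nrow(expr$intensities))
  x <- expr$intensities
  if (expr$scale == SCALE_RAW) {
    if (any(x <= 0)) {
      message(sprintf(
        "quantile_normalize: non-positive intensities present; using log2(x + %g)",
        log_offset))
      x <- x + log_offset
      if (any(x <= 0))
        stop_val("intensities remain non-positive after offset %g", log_offset)
    }
    x <- log2(x)
  }
  dn <- dimnames(x)
  x <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(x) <- dn
  out <- expr
  out$intensities <- x
  out$scale <- SCALE_LOG2_QN
  out
}
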