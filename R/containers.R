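# Light S3 containers for the pipeline's data. Matrices are kept probe x
# sample (expression/residuals) and sample x SNP (genotypes), mirroring the
# layouts of Matrix-eQTL-style scans.

SCALE_RAW <- "raw"
SCALE_LOG2 <- "log2"
SCALE_LOG2_QN <- "log2-quantile-normalized"

#' Expression matrix container
#'
#' Probe x sample intensity matrix with an optional same-shape detection
#' P-value matrix (Illumina-style per-probe, per-sample detection statistic)
#' and a scale flag tracking the normalization state. The flag only moves
#' forward: `raw` -> `log2` -> `log2-quantile-normalized`.
#'
#' @param intensities numeric matrix, probes in rows, samples in columns;
#'   dimnames give probe and sample identifiers.
#' @param detection_p optional numeric matrix in `[0, 1]`, same shape as
#'   `intensities`.
#' @param scale one of `"raw"`, `"log2"`, `"log2-quantile-normalized"`.
#' @return an `expression_matrix` object.
#' @export
expression_matrix <- function(intensities, detection_p = NULL,
                              scale = c("raw", "log2",
                                        "log2-quantile-normalized")) {
  scale <- match.arg(scale)
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop_val("'intensities' must be a numeric matrix")
  if (is.null(rownames(intensities)))
    rownames(intensities) <- paste0("probe_", seq_len(nrow(intensities)))
  if (is.null(colnames(intensities)))
    colnames(intensities) <- paste0("sample_", seq_len(ncol(intensities)))
  if (anyDuplicated(rownames(intensities)))
    stop_val("duplicate probe IDs: %s",
             paste(unique(rownames(intensities)[duplicated(rownames(intensities))]),
                   collapse = ", "))
  if (anyDuplicated(colnames(intensities)))
    stop_val("duplicate sample IDs: %s",
             paste(unique(colnames(intensities)[duplicated(colnames(intensities))]),
                   collapse = ", "))
  if (!is.null(detection_p)) {
    if (!is.matrix(detection_p) || !identical(dim(detection_p), dim(intensities)))
      stop_val("detection-P matrix shape (%s) does not match intensities (%s)",
               paste(dim(detection_p), collapse = " x "),
               paste(dim(intensities), collapse = " x "))
    if (any(detection_p < 0 | detection_p > 1, na.rm = TRUE))
      stop_val("detection P-values must lie in [0, 1]")
    dimnames(detection_p) <- dimnames(intensities)
  }
  structure(list(intensities = intensities, detection_p = detection_p,
                 scale = scale),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d probes x %d samples [%s]%s\n",
              nrow(x$intensities), ncol(x$intensities), x$scale,
              if (is.null(x$detection_p)) "" else " + detection-P"))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$intensities)

probe_ids <- function(x) rownames(x$intensities)
sample_ids <- function(x) UseMethod("sample_ids")
#' @export
sample_ids.expression_matrix <- function(x) colnames(x$intensities)
#' @export
sample_ids.genotype_table <- function(x) rownames(x$codes)
#' @export
sample_ids.covariate_table <- function(x) x$sample_id
#' @export
sample_ids.residual_matrix <- function(x) colnames(x$residuals)

#' Genotype table container
#'
#' Sample x SNP matrix of additive minor-allele dosage codes {0, 1, 2} with
#' `NA` for missing genotypes, optional allele labels, and the observed
#' minor-allele frequency (MAF) computed from the non-missing codes.
#'
#' @param codes numeric matrix, samples in rows, SNPs in columns; entries in
#'   `{0, 1, 2, NA}`.
#' @param alleles optional data.frame with columns `snp_id`, `major`, `minor`.
#' @return a `genotype_table` with an observed `maf` vector per SNP.
#' @export
genotype_table <- function(codes, alleles = NULL) {
  if (!is.matrix(codes) || !is.numeric(codes))
    stop_val("'codes' must be a numeric matrix (samples x SNPs)")
  bad <- !(codes %in% c(0, 1, 2)) & !is.na(codes)
  if (any(bad))
    stop_val("genotype codes must be 0, 1, 2 or missing; found %s",
             paste(unique(codes[bad]), collapse = ", "))
  if (is.null(rownames(codes)))
    rownames(codes) <- paste0("sample_", seq_len(nrow(codes)))
  if (is.null(colnames(codes)))
    colnames(codes) <- paste0("snp_", seq_len(ncol(codes)))
  if (anyDuplicated(rownames(codes)) || anyDuplicated(colnames(codes)))
    stop_val("duplicate sample or SNP IDs in genotype table")
  maf <- apply(codes, 2L, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    f <- mean(g) / 2
    min(f, 1 - f)
  })
  structure(list(codes = codes, alleles = alleles, maf = maf),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d samples x %d SNPs\n",
              nrow(x$codes), ncol(x$codes)))
  cat("observed MAF:\n")
  print(round(x$maf, 4))
  invisible(x)
}

snp_ids <- function(x) colnames(x$codes)

#' Covariate table container
#'
#' Per-sample age (years) and case/control status. Missing ages or statuses
#' are rejected rather than imputed.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param age numeric vector of ages in years (positive).
#' @param status character or factor with levels `case`/`control`
#'   (case-insensitive).
#' @return a `covariate_table` (a data.frame subclass).
#' @export
covariate_table <- function(sample_id, age, status) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop_val("duplicate sample IDs: %s",
             paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  if (length(age) != length(sample_id) || length(status) != length(sample_id))
    stop_val("sample_id, age and status must have equal length")
  if (any(is.na(age)) || any(!is.finite(age)) || any(age <= 0))
    stop_val("ages must be positive and non-missing")
  status <- tolower(as.character(status))
  if (any(is.na(status)) || !all(status %in% c("case", "control")))
    stop_val("status must be 'case' or 'control' for every sample")
  structure(data.frame(sample_id = sample_id, age = as.numeric(age),
                       status = status, stringsAsFactors = FALSE),
            class = c("covariate_table", "data.frame"))
}

#' Residual matrix container
#'
#' Probe x sample residual phenotypes after covariate adjustment; each
#' probe's residuals have mean ~0 by construction.
#'
#' @param residuals numeric matrix, probes x samples, with dimnames.
#' @return a `residual_matrix` object.
#' @export
residual_matrix <- function(residuals) {
  if (!is.matrix(residuals) || !is.numeric(residuals))
    stop_val("'residuals' must be a numeric matrix")
  structure(list(residuals = residuals), class = "residual_matrix")
}

#' @export
print.residual_matrix <- function(x, ...) {
  cat(sprintf("residual_matrix: %d probes x %d samples\n",
              nrow(x$residuals), ncol(x$residuals)))
  invisible(x)
}
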