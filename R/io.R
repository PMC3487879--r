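# Readers and writers for the pipeline's tabular formats. TSV is the
# native dialect (UTF-8, "." as missing token); BED input goes through
# rtracklayer, VCF genotype input through VariantAnnotation when available.

.MISSING_TOKEN <- "."

.read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = .MISSING_TOKEN, ...)
}

.require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_val("'%s' is missing required column(s): %s", path,
             paste(missing, collapse = ", "))
}

.read_matrix_tsv <- function(path, what) {
  df <- .read_tsv(path)
  if (ncol(df) < 2L)
    stop_val("'%s' must have an ID column plus at least one sample column",
             path)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1L], is.numeric, logical(1)))
    first_col <- names(df)[-1L][bad[1L]]
    bad_row <- which(is.na(suppressWarnings(as.numeric(df[[bad[1L] + 1L]]))) &
                       !is.na(df[[bad[1L] + 1L]]))[1L]
    stop_val("non-numeric %s value in '%s' at probe '%s', sample column '%s'",
             what, path, ids[if (is.na(bad_row)) 1L else bad_row], first_col)
  }
  rownames(m) <- ids
  m
}

#' Read an expression matrix (and optional detection P-values) from TSV
#'
#' Expected layout: first column = probe ID, header row = sample IDs,
#' numeric cells. The detection file must have exactly the same shape and
#' IDs.
#'
#' @param path intensity TSV path.
#' @param detection_path optional detection-P TSV path.
#' @param scale the scale the stored intensities are on (default `"raw"`).
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, detection_path = NULL,
                                   scale = c("raw", "log2",
                                             "log2-quantile-normalized")) {
  scale <- match.arg(scale)
  m <- .read_matrix_tsv(path, "intensity")
  det <- NULL
  if (!is.null(detection_path)) {
    det <- .read_matrix_tsv(detection_path, "detection-P")
    if (!identical(dim(det), dim(m)))
      stop_val("detection file shape (%s) does not match intensity file shape (%s)",
               paste(dim(det), collapse = " x "),
               paste(dim(m), collapse = " x "))
    if (!identical(rownames(det), rownames(m)) ||
        !identical(colnames(det), colnames(m)))
      stop_val("detection file probe/sample IDs do not match the intensity file")
  }
  expression_matrix(m, detection_p = det, scale = scale)
}

.write_matrix_tsv <- function(m, path, id_col) {
  df <- data.frame(rownames(m), format(m, digits = 17, trim = TRUE,
                                       scientific = NA),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_col, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

#' Write an expression matrix (and optional detection P-values) to TSV
#'
#' @param expr an [expression_matrix()].
#' @param path intensity TSV destination.
#' @param detection_path optional destination for the detection-P matrix.
#' @return invisibly, `path`.
#' @export
write_expression_matrix <- function(expr, path, detection_path = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  .write_matrix_tsv(expr$intensities, path, "probe_id")
  if (!is.null(detection_path)) {
    if (is.null(expr$detection_p))
      stop_val("no detection P-values to write")
    .write_matrix_tsv(expr$detection_p, path = detection_path, "probe_id")
  }
  invisible(path)
}

#' Read genotypes from long TSV or VCF
#'
#' TSV layout is long format with columns `sample_id`, `snp_id`, `code`
#' (0/1/2, `.` for missing). VCF input parses the GT field (`0/0` -> 0,
#' `0/1` -> 1, `1/1` -> 2, `./.` -> missing; phased `|` separators
#' accepted) via the VariantAnnotation package.
#'
#' @param path input file path.
#' @param format `"tsv"` or `"vcf"`.
#' @return a [genotype_table()]; observed per-SNP MAFs are reported via a
#'   message.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  gt <- if (format == "tsv") .read_genotypes_tsv(path) else
    .read_genotypes_vcf(path)
  message(sprintf("read_genotypes: %d samples x %d SNPs; observed MAF: %s",
                  nrow(gt$codes), ncol(gt$codes),
                  paste(sprintf("%s=%.3f", snp_ids(gt), gt$maf),
                        collapse = ", ")))
  gt
}

.read_genotypes_tsv <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("sample_id", "snp_id", "code"), path)
  code <- suppressWarnings(as.numeric(df$code))
  bad <- which(!is.na(df$code) & (is.na(code) | !(code %in% c(0, 1, 2))))
  if (length(bad))
    stop_val("invalid genotype code '%s' in '%s' at data line %d (must be 0, 1, 2 or '.')",
             df$code[bad[1L]], path, bad[1L])
  if (anyDuplicated(df[c("sample_id", "snp_id")])) {
    d <- which(duplicated(df[c("sample_id", "snp_id")]))[1L]
    stop_val("duplicate (sample, SNP) pair in '%s': (%s, %s) at data line %d",
             path, df$sample_id[d], df$snp_id[d], d)
  }
  samples <- unique(df$sample_id)
  snps <- unique(df$snp_id)
  codes <- matrix(NA_real_, length(samples), length(snps),
                  dimnames = list(samples, snps))
  codes[cbind(match(df$sample_id, samples), match(df$snp_id, snps))] <- code
  genotype_table(codes)
}

.read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop_val("VCF input requires the VariantAnnotation package; use the TSV format instead")
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop_val("VCF '%s' has no GT genotype field", path)
  code_one <- function(x) {
    alleles <- strsplit(x, "[/|]")[[1L]]
    if (any(alleles == ".") || !length(alleles)) return(NA_real_)
    sum(alleles != "0")
  }
  codes <- t(apply(gt, c(1L, 2L), code_one))
  bad <- !(codes %in% c(0, 1, 2)) & !is.na(codes)
  if (any(bad))
    stop_val("VCF '%s' contains genotypes outside the biallelic 0/1/2 coding",
             path)
  genotype_table(codes)
}

#' Write genotypes as long TSV
#'
#' @param genotypes a [genotype_table()].
#' @param path destination TSV.
#' @return invisibly, `path`.
#' @export
write_genotypes <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_table"))
  codes <- genotypes$codes
  df <- data.frame(sample_id = rep(rownames(codes), times = ncol(codes)),
                   snp_id = rep(colnames(codes), each = nrow(codes)),
                   code = ifelse(is.na(as.vector(codes)), .MISSING_TOKEN,
                                 as.character(as.vector(codes))),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a covariate table from TSV
#'
#' Columns: `sample_id`, `age` (years), `status` (`case`/`control`,
#' case-insensitive). Missing ages or statuses are rejected.
#'
#' @param path TSV path.
#' @return a [covariate_table()].
#' @export
read_covariates <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("sample_id", "age", "status"), path)
  if (anyNA(df$age) || anyNA(df$status)) {
    bad <- which(is.na(df$age) | is.na(df$status))[1L]
    stop_val("missing age or status in '%s' at data line %d (sample '%s')",
             path, bad, df$sample_id[bad])
  }
  covariate_table(df$sample_id, df$age, df$status)
}

#' Write a covariate table to TSV
#' @param cov a [covariate_table()].
#' @param path destination TSV.
#' @return invisibly, `path`.
#' @export
write_covariates <- function(cov, path) {
  utils::write.table(as.data.frame(cov), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read SNP point positions from TSV
#'
#' Columns: `chrom`, `pos` (1-based), `snp_id`.
#'
#' @param path TSV path.
#' @return data.frame `snp_id`, `chrom`, `pos`.
#' @export
read_snp_loci <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("chrom", "pos", "snp_id"), path)
  if (!is.numeric(df$pos) || anyNA(df$pos))
    stop_val("non-numeric or missing SNP position in '%s'", path)
  data.frame(snp_id = as.character(df$snp_id),
             chrom = as.character(df$chrom), pos = as.numeric(df$pos),
             stringsAsFactors = FALSE)
}

#' Read gene intervals from BED
#'
#' BED is 0-based half-open; intervals are converted to the package's
#' 1-based inclusive convention on load (start + 1, end unchanged). The BED
#' `name` field carries the gene/probe identifier.
#'
#' @param path BED file path.
#' @return data.frame `gene_id`, `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @export
read_gene_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  if (is.null(nm) || any(is.na(nm)))
    stop_val("BED file '%s' must carry gene identifiers in the name field",
             path)
  # rtracklayer already converts BED to 1-based inclusive GRanges
  data.frame(gene_id = as.character(nm),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' Format a permutation P-value the way result tables print it
#'
#' Zero stays `"0"`; anything else is rendered in scientific notation with
#' two decimals (e.g. `1e-04` -> `"1.00E-04"`).
#'
#' @param p numeric vector of permutation P-values.
#' @return character vector.
#' @export
format_perm_p <- function(p) {
  ifelse(is.na(p), .MISSING_TOKEN,
         ifelse(p == 0, "0", toupper(formatC(p, format = "e", digits = 2))))
}

#' Write association records to TSV
#'
#' Fixed column order (`snp_id`, `probe_id`, `n_used`, `coding`, `beta`,
#' `t_stat`, `nominal_p`, `r2`, `adj_r2`, `perm_p`, `perm_p_display`,
#' `cis_trans`, `degenerate`), snp-major row order, floats at full
#' precision plus a human-readable `perm_p_display` column at 1/B
#' resolution.
#'
#' @param records association records data.frame (non-empty).
#' @param path destination TSV.
#' @return invisibly, `path`.
#' @export
write_association_table <- function(records, path) {
  if (!nrow(records)) stop_val("no association records to write")
  records <- records[order(records$snp_id, records$probe_id), , drop = FALSE]
  num <- function(x) ifelse(is.na(x), .MISSING_TOKEN,
                            sprintf("%.17g", x))
  out <- data.frame(snp_id = records$snp_id, probe_id = records$probe_id,
                    n_used = records$n_used, coding = records$coding,
                    beta = num(records$beta), t_stat = num(records$t_stat),
                    nominal_p = num(records$nominal_p),
                    r2 = num(records$r2), adj_r2 = num(records$adj_r2),
                    perm_p = num(records$perm_p),
                    perm_p_display = format_perm_p(records$perm_p),
                    cis_trans = ifelse(is.na(records$cis_trans),
                                       .MISSING_TOKEN, records$cis_trans),
                    degenerate = records$degenerate,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read association records written by [write_association_table()]
#'
#' @param path results TSV path.
#' @return association records data.frame.
#' @export
read_association_table <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("snp_id", "probe_id", "n_used", "coding", "beta",
                         "t_stat", "nominal_p", "r2", "adj_r2", "perm_p",
                         "cis_trans", "degenerate"), path)
  df$perm_p_display <- NULL
  for (col in c("beta", "t_stat", "nominal_p", "r2", "adj_r2", "perm_p"))
    df[[col]] <- as.numeric(df[[col]])
  df$degenerate <- as.logical(df$degenerate)
  df
}
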