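# Genomic annotation of scan results: cis/trans classification against a
# distance window, per-SNP significance counts at permutation thresholds,
# and cross-SNP overlap summaries. Coordinates are 1-based inclusive
# internally; the BED reader converts from BED's 0-based half-open
# convention on load.

#' Classify one SNP-gene pair as cis or trans
#'
#' A pair is `cis` when both loci sit on the same chromosome and the
#' distance from the SNP point to the gene interval is at most `window`
#' (closed boundary: exactly `window` base pairs is still cis); `trans`
#' otherwise; `unknown` when either locus lacks coordinates.
#'
#' @param snp list or one-row data.frame with `chrom` and `pos` (1-based).
#' @param gene list or one-row data.frame with `chrom`, `start`, `end`
#'   (1-based inclusive interval).
#' @param window distance window in base pairs (default 1 Mb).
#' @param anchor `"edge"` (distance to the nearest interval edge, 0 inside
#'   the gene) or `"start"` (distance to the interval start).
#' @return `"cis"`, `"trans"` or `"unknown"`.
#' @export
classify_cis_trans <- function(snp, gene, window = 1e6,
                               anchor = c("edge", "start")) {
  anchor <- match.arg(anchor)
  check_number(window, "window", lower = 0)
  if (is.null(snp$chrom) || is.na(snp$chrom) || is.null(snp$pos) ||
      is.na(snp$pos) || is.null(gene$chrom) || is.na(gene$chrom) ||
      is.null(gene$start) || is.na(gene$start))
    return("unknown")
  if (as.character(snp$chrom) != as.character(gene$chrom)) return("trans")
  d <- snp_gene_distance(snp$pos, gene$start, gene$end, anchor)
  if (d <= window) "cis" else "trans"
}

#' Distance from a SNP point to a gene interval
#'
#' @param pos SNP position (1-based).
#' @param start,end gene interval (1-based inclusive).
#' @param anchor `"edge"` or `"start"`, see [classify_cis_trans()].
#' @return distance in base pairs (0 inside the interval for
#'   `anchor = "edge"`). Vectorized.
#' @export
snp_gene_distance <- function(pos, start, end, anchor = c("edge", "start")) {
  anchor <- match.arg(anchor)
  if (anchor == "start") return(abs(pos - start))
  pmax(start - pos, pos - end, 0)
}

#' Annotate association records with cis/trans calls
#'
#' Joins SNP point positions and probe-target gene intervals onto the scan
#' records and fills the `cis_trans` column. Probes without a gene interval,
#' or SNPs without a position, are called `unknown`.
#'
#' @param records association records from [scan_all()] or
#'   [permutation_scan()].
#' @param snp_loci data.frame `snp_id`, `chrom`, `pos` (1-based), e.g. from
#'   [read_snp_loci()].
#' @param gene_loci data.frame `gene_id`, `chrom`, `start`, `end` (1-based
#'   inclusive) keyed by the probe's target gene, e.g. from
#'   [read_gene_bed()]; `gene_id` is matched against `probe_id`.
#' @param window,anchor see [classify_cis_trans()].
#' @return `records` with `cis_trans` filled.
#' @export
annotate_cis_trans <- function(records, snp_loci, gene_loci, window = 1e6,
                               anchor = c("edge", "start")) {
  anchor <- match.arg(anchor)
  check_number(window, "window", lower = 0)
  si <- match(records$snp_id, snp_loci$snp_id)
  gi <- match(records$probe_id, gene_loci$gene_id)
  schrom <- snp_loci$chrom[si]
  spos <- snp_loci$pos[si]
  gchrom <- gene_loci$chrom[gi]
  gstart <- gene_loci$start[gi]
  gend <- gene_loci$end[gi]
  known <- !is.na(schrom) & !is.na(spos) & !is.na(gchrom) & !is.na(gstart)
  call <- rep("unknown", nrow(records))
  same <- known & as.character(schrom) == as.character(gchrom)
  call[known & !same] <- "trans"
  d <- snp_gene_distance(spos[same], gstart[same], gend[same], anchor)
  call[same] <- ifelse(d <= window, "cis", "trans")
  records$cis_trans <- call
  records
}

#' Per-SNP counts of significant associations
#'
#' Counts records with permutation-adjusted P strictly below each threshold
#' (matching "P < 0.05"-style table headers), per SNP.
#'
#' @param records association records with `perm_p` filled.
#' @param thresholds numeric thresholds, default `c(0.05, 0.01, 0.001)`.
#' @return data.frame with one row per threshold and one column per SNP,
#'   plus a `threshold` column.
#' @export
threshold_counts <- function(records, thresholds = c(0.05, 0.01, 0.001)) {
  if (!"perm_p" %in% names(records) ||
      (nrow(records) > 0L && all(is.na(records$perm_p))))
    stop_val("records are missing the 'perm_p' field; run permutation_scan first")
  thresholds <- sort(thresholds, decreasing = TRUE)
  snps <- unique(records$snp_id)
  counts <- vapply(snps, function(s) {
    p <- records$perm_p[records$snp_id == s]
    vapply(thresholds, function(t) sum(p < t, na.rm = TRUE), numeric(1))
  }, numeric(length(thresholds)))
  counts <- matrix(counts, nrow = length(thresholds),
                   dimnames = list(NULL, snps))
  out <- data.frame(threshold = thresholds, counts, check.names = FALSE)
  rownames(out) <- sprintf("P<%g", thresholds)
  out
}

#' Extract per-SNP significant probe sets
#'
#' @param records association records with `perm_p` filled.
#' @param threshold strict significance threshold on `perm_p`.
#' @return named list: SNP id -> character vector of significant probe IDs.
#' @export
significant_sets <- function(records, threshold = 0.05) {
  if (!"perm_p" %in% names(records) ||
      (nrow(records) > 0L && all(is.na(records$perm_p))))
    stop_val("records are missing the 'perm_p' field; run permutation_scan first")
  split(records$probe_id[records$perm_p < threshold],
        factor(records$snp_id[records$perm_p < threshold],
               levels = unique(records$snp_id)))
}

#' Cross-SNP overlap of significant probe sets
#'
#' Reports the size of the intersection of all sets, the percentage of each
#' SNP's set contained in that common intersection (rounded to the nearest
#' integer percent, ties away from zero), and all pairwise intersection
#' sizes. An empty input set yields an `NA` percentage (undefined, not 0)
#' and is flagged.
#'
#' @param sig_sets named list of probe-ID sets (>= 2), e.g. from
#'   [significant_sets()].
#' @return list with `n_common`, `set_sizes`, `percent_of_set`,
#'   `pairwise` (matrix of pairwise intersection sizes), `empty_sets`.
#' @export
overlap_summary <- function(sig_sets) {
  if (length(sig_sets) < 2L)
    stop_val("need at least 2 sets to summarize overlap (got %d)",
             length(sig_sets))
  sig_sets <- lapply(sig_sets, unique)
  sizes <- vapply(sig_sets, length, integer(1))
  common <- Reduce(intersect, sig_sets)
  pct <- ifelse(sizes == 0, NA_real_,
                round_half_away(100 * length(common) / sizes))
  k <- length(sig_sets)
  pairwise <- matrix(0L, k, k, dimnames = list(names(sig_sets),
                                               names(sig_sets)))
  for (i in seq_len(k)) for (j in seq_len(k))
    pairwise[i, j] <- length(intersect(sig_sets[[i]], sig_sets[[j]]))
  if (any(sizes == 0))
    warning(sprintf("empty significant set(s): %s",
                    paste(names(sig_sets)[sizes == 0], collapse = ", ")),
            call. = FALSE)
  list(n_common = length(common), set_sizes = sizes, percent_of_set = pct,
       pairwise = pairwise, empty_sets = names(sig_sets)[sizes == 0])
}
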