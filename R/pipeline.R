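# End-to-end pipeline: one configuration object chaining QC, normalization,
# residualization, the association scan, permutation adjustment, genomic
# annotation, summary reports and (optionally) gene-set enrichment.

#' Pipeline configuration
#'
#' Collects input paths and stage parameters. Defaults mirror the standard
#' analysis settings: detection alpha 0.05, exclusion at 25% failing
#' samples, 10,000 permutations, a 1 Mb cis window, and reporting
#' thresholds 0.05 / 0.01 / 0.001.
#'
#' @param expression,detection,genotypes,covariates input TSV paths
#'   (`detection` may be `NULL` to skip QC).
#' @param snp_loci,gene_bed optional annotation paths (SNP TSV, gene BED);
#'   both required for cis/trans calls.
#' @param gmt optional GMT path enabling enrichment of the significant
#'   gene list.
#' @param qc_alpha,qc_fail_fraction,log_offset QC/normalization parameters,
#'   see [detection_filter()] and [quantile_normalize()].
#' @param coding genotype coding for the scan.
#' @param B,seed,scheme,pseudocount permutation parameters, see
#'   [permutation_scan()].
#' @param window_bp,distance_anchor cis window parameters, see
#'   [annotate_cis_trans()].
#' @param thresholds reporting thresholds (sorted descending).
#' @param enrich_method `"fisher"` or `"ease"`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(expression, genotypes, covariates,
                            detection = NULL, snp_loci = NULL,
                            gene_bed = NULL, gmt = NULL,
                            qc_alpha = 0.05, qc_fail_fraction = 0.25,
                            log_offset = 1,
                            coding = c("additive", "dominant"),
                            B = 10000L, seed = 1L,
                            scheme = c("joint", "per_pair"),
                            pseudocount = c("none", "add_one"),
                            window_bp = 1e6,
                            distance_anchor = c("edge", "start"),
                            thresholds = c(0.05, 0.01, 0.001),
                            enrich_method = c("fisher", "ease")) {
  cfg <- list(expression = expression, detection = detection,
              genotypes = genotypes, covariates = covariates,
              snp_loci = snp_loci, gene_bed = gene_bed, gmt = gmt,
              qc_alpha = qc_alpha, qc_fail_fraction = qc_fail_fraction,
              log_offset = log_offset, coding = match.arg(coding),
              B = check_count(B, "B", 1L), seed = check_count(seed, "seed"),
              scheme = match.arg(scheme),
              pseudocount = match.arg(pseudocount), window_bp = window_bp,
              distance_anchor = match.arg(distance_anchor),
              thresholds = sort(thresholds, decreasing = TRUE),
              enrich_method = match.arg(enrich_method))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (k in c("expression", "detection", "genotypes", "covariates",
              "snp_loci", "gene_bed", "gmt")) {
    if (!is.null(raw[[k]]) && !grepl("^/", raw[[k]]))
      raw[[k]] <- file.path(base, raw[[k]])
  }
  do.call(pipeline_config, raw)
}

#' Run the full eQTL pipeline
#'
#' Executes, in order: detection-P QC (when detection data are present),
#' quantile normalization, covariate residualization, the all-pairs
#' association scan, permutation adjustment, cis/trans annotation (when
#' loci are supplied), threshold-count and overlap summaries, and gene-set
#' enrichment of the significant genes (when a GMT is supplied). Each stage
#' logs probe/sample counts so the bookkeeping is inspectable.
#'
#' @param config a `pipeline_config` from [pipeline_config()] or
#'   [read_pipeline_config()].
#' @param out_dir optional directory; when given, the result tables are
#'   written there as TSV.
#' @return list with `records`, `counts`, `overlap` (or NULL if < 2 SNPs
#'   reach significance machinery), `enrichment` (or NULL), plus the
#'   intermediate `expression`, `residuals`, `genotypes`, `covariates`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  expr <- read_expression_matrix(config$expression,
                                 detection_path = config$detection,
                                 scale = "raw")
  message(sprintf("loaded %d probes x %d samples", nrow(expr$intensities),
                  ncol(expr$intensities)))
  if (!is.null(config$detection))
    expr <- detection_filter(expr, alpha = config$qc_alpha,
                             fail_fraction = config$qc_fail_fraction)
  expr <- quantile_normalize(expr, log_offset = config$log_offset)
  cov <- read_covariates(config$covariates)
  genotypes <- read_genotypes(config$genotypes)
  resid <- residualize(expr, cov)
  records <- scan_all(resid, genotypes, coding = config$coding)
  message(sprintf("scanned %d probe x SNP pairs", nrow(records)))
  records <- permutation_scan(resid, genotypes, records, B = config$B,
                              seed = config$seed, scheme = config$scheme,
                              pseudocount = config$pseudocount)
  if (!is.null(config$snp_loci) && !is.null(config$gene_bed)) {
    records <- annotate_cis_trans(records, read_snp_loci(config$snp_loci),
                                  read_gene_bed(config$gene_bed),
                                  window = config$window_bp,
                                  anchor = config$distance_anchor)
  }
  counts <- threshold_counts(records, thresholds = config$thresholds)
  sig <- significant_sets(records, threshold = config$thresholds[1L])
  overlap <- if (length(sig) >= 2L) overlap_summary(sig) else NULL
  enrichment <- NULL
  if (!is.null(config$gmt)) {
    query <- unique(unlist(sig, use.names = FALSE))
    universe <- unique(records$probe_id)
    if (length(query))
      enrichment <- enrichment_test(query, universe, read_gmt(config$gmt),
                                    method = config$enrich_method)
    else message("no significant genes; skipping enrichment")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_association_table(records, file.path(out_dir, "associations.tsv"))
    utils::write.table(counts, file.path(out_dir, "threshold_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(overlap)) {
      ov <- data.frame(snp_id = names(overlap$set_sizes),
                       n_significant = as.integer(overlap$set_sizes),
                       n_common_all = overlap$n_common,
                       percent_in_common = overlap$percent_of_set)
      utils::write.table(ov, file.path(out_dir, "overlap_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(enrichment))
      utils::write.table(enrichment, file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(records = records, counts = counts, overlap = overlap,
       enrichment = enrichment, expression = expr, residuals = resid,
       genotypes = genotypes, covariates = cov)
}

#' Write a simulated cohort in the pipeline's input formats
#'
#' Emits expression + detection TSVs (intensities are written on the raw
#' scale, `2^log2`, so the written files exercise the real readers and the
#' log2 step of normalization), genotype long TSV and covariate TSV.
#'
#' @param cohort list from [simulate_cohort()].
#' @param out_dir destination directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_simulated_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  expr <- cohort$expression
  raw <- expr
  raw$intensities <- 2^expr$intensities
  raw$scale <- "raw"
  paths <- c(expression = file.path(out_dir, "expression.tsv"),
             detection = file.path(out_dir, "detection.tsv"),
             genotypes = file.path(out_dir, "genotypes.tsv"),
             covariates = file.path(out_dir, "covariates.tsv"))
  write_expression_matrix(raw, paths[["expression"]],
                          detection_path = paths[["detection"]])
  write_genotypes(cohort$genotypes, paths[["genotypes"]])
  write_covariates(cohort$covariates, paths[["covariates"]])
  invisible(paths)
}
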