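# Association scan: simple linear regression of residual expression on
# genotype, one SNP-probe pair at a time (regress_pair) or vectorized over
# all pairs (scan_all). Statistics come from the correlation algebra of the
# one-predictor model: t = r * sqrt(n-2) / sqrt(1-r^2), P two-sided from the
# t distribution on n-2 df, adjusted r^2 = 1 - (1-r^2)(n-1)/(n-2).

.apply_coding <- function(g, coding) {
  switch(coding,
         additive = g,
         dominant = as.numeric(g >= 1),
         stop_val("unknown genotype coding '%s'", coding))
}

.assoc_record <- function(snp_id, probe_id, n_used, coding, beta, t_stat,
                          nominal_p, r2, adj_r2, degenerate) {
  data.frame(snp_id = snp_id, probe_id = probe_id, n_used = n_used,
             coding = coding, beta = beta, t_stat = t_stat,
             nominal_p = nominal_p, r2 = r2, adj_r2 = adj_r2,
             perm_p = NA_real_, cis_trans = NA_character_,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Regress one probe's residuals on one SNP
#'
#' Samples with missing genotype are dropped pairwise (`n_used` records the
#' remainder). A genotype that is constant after missing-data removal, or
#' fewer than 3 complete pairs, yields a degenerate record with `beta = 0`
#' and `nominal_p = 1` rather than an error, so whole-scan bookkeeping stays
#' rectangular.
#'
#' @param residuals_for_probe numeric vector of residual phenotypes.
#' @param codes_for_snp numeric vector of genotype codes `{0, 1, 2, NA}`,
#'   same length.
#' @param coding `"additive"` (0/1/2 minor-allele dosage) or `"dominant"`
#'   (0 vs >= 1 minor allele, i.e. carrier status).
#' @param snp_id,probe_id identifiers carried into the record.
#' @return a one-row data.frame association record with columns `snp_id`,
#'   `probe_id`, `n_used`, `coding`, `beta`, `t_stat`, `nominal_p`, `r2`,
#'   `adj_r2`, `perm_p` (NA here), `cis_trans` (NA here), `degenerate`.
#' @export
regress_pair <- function(residuals_for_probe, codes_for_snp,
                         coding = c("additive", "dominant"),
                         snp_id = "snp", probe_id = "probe") {
  coding <- match.arg(coding)
  y <- as.numeric(residuals_for_probe)
  g <- as.numeric(codes_for_snp)
  if (length(y) != length(g))
    stop_val("residual and genotype vectors differ in length (%d vs %d)",
             length(y), length(g))
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]
  g <- .apply_coding(g[ok], coding)
  n <- length(y)
  if (n < 3L || stats::var(g) == 0 || stats::var(y) == 0)
    return(.assoc_record(snp_id, probe_id, n, coding, beta = 0, t_stat = 0,
                         nominal_p = 1, r2 = 0, adj_r2 = 0,
                         degenerate = TRUE))
  sxx <- sum((g - mean(g))^2)
  sxy <- sum((g - mean(g)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  beta <- sxy / sxx
  r2 <- sxy^2 / (sxx * syy)
  r2 <- min(r2, 1)
  df <- n - 2L
  if (r2 >= 1) {
    t_stat <- sign(beta) * Inf
    p <- 0
  } else {
    t_stat <- (beta / sqrt((syy - beta * sxy) / df)) * sqrt(sxx)
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - 2)
  .assoc_record(snp_id, probe_id, n, coding, beta, t_stat, p, r2, adj_r2,
                degenerate = FALSE)
}

# Row-standardize a probe x sample matrix over a column subset: returns the
# centered matrix plus row sums of squares (used by the vectorized scan and
# the permutation engine).
.center_rows <- function(y) {
  mu <- rowMeans(y)
  yc <- y - mu
  list(yc = yc, ss = rowSums(yc^2))
}

#' Scan all SNP-probe pairs
#'
#' Vectorized equivalent of calling [regress_pair()] on every probe x SNP
#' combination; output is snp-major (SNPs in genotype-table order, probes in
#' residual-matrix order within each SNP).
#'
#' @param residuals a [residual_matrix()].
#' @param genotypes a [genotype_table()] over the same samples.
#' @param coding genotype coding, as in [regress_pair()].
#' @return data.frame of `n_probes * n_snps` association records.
#' @export
scan_all <- function(residuals, genotypes,
                     coding = c("additive", "dominant")) {
  coding <- match.arg(coding)
  stopifnot(inherits(residuals, "residual_matrix"),
            inherits(genotypes, "genotype_table"))
  if (!setequal(sample_ids(residuals), sample_ids(genotypes)))
    stop_val("sample mismatch between residuals and genotypes; only in residuals: %s; only in genotypes: %s",
             paste(setdiff(sample_ids(residuals), sample_ids(genotypes)),
                   collapse = ", "),
             paste(setdiff(sample_ids(genotypes), sample_ids(residuals)),
                   collapse = ", "))
  y_all <- residuals$residuals
  codes <- genotypes$codes[match(colnames(y_all), rownames(genotypes$codes)),
                           , drop = FALSE]
  out <- vector("list", ncol(codes))
  for (s in seq_len(ncol(codes))) {
    g_raw <- codes[, s]
    idx <- which(!is.na(g_raw))
    g <- .apply_coding(g_raw[idx], coding)
    y <- y_all[, idx, drop = FALSE]
    n <- length(idx)
    probe <- rownames(y_all)
    if (n < 3L || stats::var(g) == 0) {
      out[[s]] <- .assoc_record(colnames(codes)[s], probe, n, coding,
                                beta = 0, t_stat = 0, nominal_p = 1,
                                r2 = 0, adj_r2 = 0, degenerate = TRUE)
      next
    }
    gc <- g - mean(g)
    sxx <- sum(gc^2)
    cy <- .center_rows(y)
    sxy <- drop(cy$yc %*% gc)
    syy <- cy$ss
    degen <- syy == 0
    syy_safe <- ifelse(degen, 1, syy)
    beta <- sxy / sxx
    r2 <- pmin(sxy^2 / (sxx * syy_safe), 1)
    df <- n - 2L
    denom <- pmax(syy_safe - beta * sxy, 0)
    t_stat <- ifelse(denom == 0, sign(beta) * Inf,
                     beta * sqrt(sxx) / sqrt(denom / df))
    p <- 2 * stats::pt(-abs(t_stat), df)
    adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - 2)
    rec <- .assoc_record(colnames(codes)[s], probe, n, coding, beta, t_stat,
                         p, r2, adj_r2, degenerate = FALSE)
    if (any(degen)) {
      rec$beta[degen] <- 0
      rec$t_stat[degen] <- 0
      rec$nominal_p[degen] <- 1
      rec$r2[degen] <- 0
      rec$adj_r2[degen] <- 0
      rec$degenerate[degen] <- TRUE
    }
    out[[s]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
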