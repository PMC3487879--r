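# Permutation engine for adjusted ("permutated") P-values: the fraction of
# phenotype relabelings whose nominal P ties or beats the observed one.
# Within one SNP the degrees of freedom are fixed across relabelings, so
# comparing nominal P-values is equivalent to comparing squared
# correlations; the engine works on r^2 and computes all pair statistics
# for one relabeling in a single matrix product.

# Tolerance when comparing permuted r^2 against observed r^2: relabelings
# that reproduce the observed grouping give algebraically identical
# statistics but can differ in the last float ulp; ties must count against
# the observed value.
.PERM_TOL <- 1e-12

#' Permutation-adjusted P-values for an association scan
#'
#' For each SNP-probe pair, `perm_p` is the fraction of `B` random sample
#' relabelings of the residual matrix whose nominal P is less than or equal
#' to the observed one (ties count). With `pseudocount = "none"`,
#' `perm_p = count / B`, so 0 is reportable and the smallest positive value
#' is `1/B`; `"add_one"` gives `(count + 1) / (B + 1)`.
#'
#' Under `scheme = "joint"` (default) one relabeling of the whole residual
#' matrix per iteration is shared across every pair, preserving
#' transcript-transcript correlation and costing O(B) relabelings;
#' `"per_pair"` draws independent relabelings for every pair.
#'
#' @param residuals a [residual_matrix()].
#' @param genotypes a [genotype_table()] over the same samples.
#' @param records association records from [scan_all()] on the same inputs.
#' @param B number of permutations (the study-scale default is 10,000).
#' @param seed integer seed for the relabelings.
#' @param scheme `"joint"` or `"per_pair"`.
#' @param pseudocount `"none"` or `"add_one"`.
#' @return `records` with the `perm_p` column filled in (degenerate records
#'   get `perm_p = 1`).
#' @export
permutation_scan <- function(residuals, genotypes, records, B = 10000L,
                             seed = 1L, scheme = c("joint", "per_pair"),
                             pseudocount = c("none", "add_one")) {
  scheme <- match.arg(scheme)
  pseudocount <- match.arg(pseudocount)
  stopifnot(inherits(residuals, "residual_matrix"),
            inherits(genotypes, "genotype_table"))
  B <- check_count(B, "B", min = 1L)
  coding <- unique(records$coding)
  if (length(coding) != 1L)
    stop_val("records mix genotype codings: %s", paste(coding, collapse = ", "))
  y_all <- residuals$residuals
  codes <- genotypes$codes[match(colnames(y_all), rownames(genotypes$codes)),
                           , drop = FALSE]
  n <- ncol(y_all)
  snps <- colnames(codes)
  probes <- rownames(y_all)
  key <- function(s, p) paste(s, p, sep = "\r")
  rec_pos <- match(key(rep(snps, each = length(probes)),
                       rep(probes, times = length(snps))),
                   key(records$snp_id, records$probe_id))
  if (anyNA(rec_pos))
    stop_val("records do not cover the full SNP x probe grid of the inputs")

  set.seed(seed)
  counts <- if (scheme == "joint") {
    .perm_counts_joint(y_all, codes, coding, B)
  } else {
    .perm_counts_per_pair(y_all, codes, coding, B)
  }
  perm_p <- if (pseudocount == "none") counts / B else (counts + 1) / (B + 1)
  records$perm_p[rec_pos] <- as.vector(perm_p)
  records$perm_p[records$degenerate] <- 1
  records
}

# Per-SNP preparation: non-missing index, centered coded genotype, its sum
# of squares, and the observed r^2 for every probe (same algebra as
# scan_all). Returns NULL for degenerate SNPs.
.perm_prep_snp <- function(y_all, g_raw, coding) {
  idx <- which(!is.na(g_raw))
  if (length(idx) < 3L) return(NULL)
  g <- .apply_coding(g_raw[idx], coding)
  if (stats::var(g) == 0) return(NULL)
  gc <- g - mean(g)
  sxx <- sum(gc^2)
  y <- y_all[, idx, drop = FALSE]
  cy <- .center_rows(y)
  ss <- ifelse(cy$ss == 0, Inf, cy$ss)  # zero-variance probes can never hit
  obs_r2 <- drop(cy$yc %*% gc)^2 / (sxx * ss)
  list(idx = idx, gc = gc, sxx = sxx, obs_r2 = obs_r2,
       complete = length(idx) == ncol(y_all))
}

# Joint scheme: one relabeling per iteration shared by all SNPs and probes.
# For SNP s with non-missing subset idx, the statistic of relabeling pi is
# cor(Y[probe, pi(idx)], g[idx]); scattering the centered genotype into an
# n-vector at positions pi(idx) turns all probes' numerators into one
# matrix product. Denominators are constant when the SNP has no missing
# genotypes, otherwise recovered from subset row sums of Y and Y^2.
.perm_counts_joint <- function(y_all, codes, coding, B, chunk = 512L) {
  n <- ncol(y_all)
  preps <- lapply(seq_len(ncol(codes)), function(s)
    .perm_prep_snp(y_all, codes[, s], coding))
  y2_all <- y_all^2
  counts <- matrix(0, nrow(y_all), ncol(codes))
  done <- 0L
  while (done < B) {
    nb <- min(chunk, B - done)
    perms <- vapply(seq_len(nb), function(b) sample.int(n), integer(n))
    for (s in seq_along(preps)) {
      pr <- preps[[s]]
      if (is.null(pr)) next
      m <- length(pr$idx)
      w <- matrix(0, n, nb)
      w[perms[pr$idx, , drop = FALSE] + n * rep(seq_len(nb) - 1L, each = m)] <-
        pr$gc
      num <- y_all %*% w
      if (pr$complete) {
        ss <- .center_rows(y_all)$ss
        ss <- ifelse(ss == 0, Inf, ss)
        r2 <- num^2 / (pr$sxx * ss)
      } else {
        ind <- matrix(0, n, nb)
        ind[perms[pr$idx, , drop = FALSE] + n * rep(seq_len(nb) - 1L, each = m)] <- 1
        s1 <- y_all %*% ind
        s2 <- y2_all %*% ind
        ss <- s2 - s1^2 / m
        ss[ss <= 0] <- Inf
        r2 <- num^2 / (pr$sxx * ss)
      }
      counts[, s] <- counts[, s] + rowSums(r2 >= pr$obs_r2 - .PERM_TOL)
    }
    done <- done + nb
  }
  for (s in seq_along(preps)) if (is.null(preps[[s]])) counts[, s] <- B
  counts
}

# Per-pair scheme: independent relabelings for every pair. Permuting the
# phenotype within the non-missing subset leaves its multiset (hence mean
# and variance) unchanged, so only numerators vary.
.perm_counts_per_pair <- function(y_all, codes, coding, B, chunk = 2048L) {
  counts <- matrix(0, nrow(y_all), ncol(codes))
  for (s in seq_len(ncol(codes))) {
    pr <- .perm_prep_snp(y_all, codes[, s], coding)
    if (is.null(pr)) {
      counts[, s] <- B
      next
    }
    m <- length(pr$idx)
    for (p in seq_len(nrow(y_all))) {
      y <- y_all[p, pr$idx]
      yc <- y - mean(y)
      ss <- sum(yc^2)
      if (ss == 0) {
        counts[p, s] <- 0
        next
      }
      hits <- 0
      done <- 0L
      while (done < B) {
        nb <- min(chunk, B - done)
        yp <- vapply(seq_len(nb), function(b) yc[sample.int(m)], numeric(m))
        r2 <- drop(crossprod(yp, pr$gc))^2 / (pr$sxx * ss)
        hits <- hits + sum(r2 >= pr$obs_r2[p] - .PERM_TOL)
        done <- done + nb
      }
      counts[p, s] <- hits
    }
  }
  counts
}

#' Exact permutation P by full enumeration
#'
#' Enumerates all `n!` relabelings of the phenotype vector (n <= 8) and
#' returns the exact fraction whose squared correlation with the genotype
#' ties or beats the observed one. Includes the identity relabeling, so the
#' result is at least `1/n!`. This is the ground-truth oracle against which
#' the Monte-Carlo engine is validated.
#'
#' @param residual_vector numeric phenotype vector, length n <= 8.
#' @param genotype_vector numeric genotype codes, same length, no missing.
#' @return the exact permutation P-value.
#' @export
exact_permutation_oracle <- function(residual_vector, genotype_vector) {
  y <- as.numeric(residual_vector)
  g <- as.numeric(genotype_vector)
  if (length(y) != length(g))
    stop_val("vectors differ in length (%d vs %d)", length(y), length(g))
  if (anyNA(y) || anyNA(g))
    stop_val("the exact oracle requires complete data")
  n <- length(y)
  if (n > 8L)
    stop_val("exact enumeration limited to n <= 8 (got %d)", n)
  if (stats::var(y) == 0 || stats::var(g) == 0) return(1)
  gc <- g - mean(g)
  sxx <- sum(gc^2)
  yc <- y - mean(y)
  ss <- sum(yc^2)
  obs_r2 <- sum(yc * gc)^2 / (sxx * ss)
  perms <- all_permutations(n)
  num <- (matrix(yc[perms], nrow(perms)) %*% gc)^2 / (sxx * ss)
  mean(num >= obs_r2 - .PERM_TOL)
}
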