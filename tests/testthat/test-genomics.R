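# cis/trans classification, threshold counts and cross-SNP overlaps.

test_that("SNPs within the 1 Mb window are called cis", {
  # 806 kb and 697 kb upstream of a gene: both inside the default window
  gene <- list(chrom = "8", start = 128748315, end = 128753680)
  snp_806 <- list(chrom = "8", pos = gene$end + 806000)
  snp_697 <- list(chrom = "8", pos = gene$start - 697000)
  expect_equal(classify_cis_trans(snp_806, gene), "cis")
  expect_equal(classify_cis_trans(snp_697, gene), "cis")
  expect_equal(snp_gene_distance(snp_806$pos, gene$start, gene$end), 806000)
})

test_that("cis window boundary is closed and chromosomes must match", {
  gene <- list(chrom = "2", start = 5e6, end = 6e6)
  at_window <- list(chrom = "2", pos = 6e6 + 1e6)
  beyond <- list(chrom = "2", pos = 6e6 + 1e6 + 1)
  other_chrom <- list(chrom = "3", pos = 6e6)
  inside <- list(chrom = "2", pos = 5.5e6)
  expect_equal(classify_cis_trans(at_window, gene), "cis")
  expect_equal(classify_cis_trans(beyond, gene), "trans")
  expect_equal(classify_cis_trans(other_chrom, gene), "trans")
  expect_equal(classify_cis_trans(inside, gene), "cis")
  expect_equal(snp_gene_distance(inside$pos, gene$start, gene$end), 0)
})

test_that("missing coordinates give unknown; negative window errors", {
  gene <- list(chrom = "2", start = 5e6, end = 6e6)
  expect_equal(classify_cis_trans(list(chrom = NA, pos = NA), gene),
               "unknown")
  expect_error(classify_cis_trans(list(chrom = "2", pos = 1), gene,
                                  window = -5), "window")
})

test_that("start anchor measures to the interval start", {
  gene <- list(chrom = "1", start = 100, end = 200)
  snp <- list(chrom = "1", pos = 150)
  expect_equal(snp_gene_distance(snp$pos, gene$start, gene$end, "start"), 50)
  expect_equal(snp_gene_distance(snp$pos, gene$start, gene$end, "edge"), 0)
})

test_that("annotate_cis_trans fills calls across a record table", {
  records <- data.frame(
    snp_id = c("rsA", "rsA", "rsB", "rsB"),
    probe_id = c("G1", "G2", "G1", "G3"),
    perm_p = c(0.01, 0.2, 0.3, 0.4))
  snp_loci <- data.frame(snp_id = c("rsA", "rsB"), chrom = c("1", "2"),
                         pos = c(1.2e6, 5e6))
  gene_loci <- data.frame(gene_id = c("G1", "G2"), chrom = c("1", "1"),
                          start = c(1e5, 9e6), end = c(2e5, 9.1e6))
  out <- annotate_cis_trans(records, snp_loci, gene_loci)
  expect_equal(out$cis_trans, c("cis", "trans", "trans", "unknown"))
})

test_that("threshold counts use strict inequality per SNP", {
  records <- data.frame(snp_id = "rsX",
                        probe_id = paste0("p", 1:4),
                        perm_p = c(0.04, 0.009, 0.0005, 0.05))
  counts <- threshold_counts(records)
  expect_equal(unname(unlist(counts[, "rsX"])), c(3, 2, 1))
  # perm_p exactly 0.05 is not counted at the 0.05 threshold
  expect_equal(counts["P<0.05", "rsX"], 3)
})

test_that("threshold counts are monotone and require perm_p", {
  cfg <- null_config(seed = 44, n_probes = 40)
  coh <- make_residual_cohort(cfg)
  rec <- scan_all(coh$residuals, coh$genotypes)
  expect_error(threshold_counts(rec), "perm_p")
  rec <- permutation_scan(coh$residuals, coh$genotypes, rec, B = 200,
                          seed = 1)
  counts <- threshold_counts(rec, thresholds = c(0.2, 0.1, 0.05, 0.01))
  for (s in unique(rec$snp_id))
    expect_true(all(diff(counts[[s]]) <= 0))
  expect_equal(nrow(threshold_counts(rec[0, ])), 3)
})

test_that("overlap summary reproduces printed three-way percentages", {
  # set sizes 959 / 821 / 618 sharing exactly 312 probes
  common <- sprintf("shared_%03d", 1:312)
  sets <- list(
    rs10098821 = c(common, sprintf("a_%03d", 1:(959 - 312))),
    rs10088218 = c(common, sprintf("b_%03d", 1:(821 - 312))),
    rs1516982 = c(common, sprintf("c_%03d", 1:(618 - 312))))
  ov <- overlap_summary(sets)
  expect_equal(ov$n_common, 312)
  expect_equal(unname(ov$percent_of_set), c(33, 38, 50))
  expect_equal(unname(diag(ov$pairwise)), c(959, 821, 618))
  expect_true(all(ov$pairwise >= 312))
})

test_that("overlap edge cases: disjoint, identical and empty sets", {
  disjoint <- list(a = c("x", "y"), b = c("z", "w"))
  ov <- overlap_summary(disjoint)
  expect_equal(ov$n_common, 0)
  expect_equal(unname(ov$percent_of_set), c(0, 0))

  identical_sets <- list(a = c("x", "y"), b = c("y", "x"))
  ov2 <- overlap_summary(identical_sets)
  expect_equal(unname(ov2$percent_of_set), c(100, 100))

  expect_warning(ov3 <- overlap_summary(list(a = character(), b = "x")),
                 "empty")
  expect_true(is.na(ov3$percent_of_set[["a"]]))
  expect_equal(ov3$empty_sets, "a")
})

test_that("overlap invariants hold on random set families", {
  set.seed(10)
  for (i in 1:5) {
    sets <- lapply(1:3, function(j)
      sample(sprintf("g%02d", 1:30), sample(5:25, 1)))
    names(sets) <- paste0("s", 1:3)
    ov <- overlap_summary(sets)
    expect_lte(ov$n_common, min(ov$pairwise[upper.tri(ov$pairwise)]))
    expect_lte(min(ov$pairwise[upper.tri(ov$pairwise)]), min(ov$set_sizes))
  }
})

test_that("percent rounding is nearest with ties away from zero", {
  ov <- overlap_summary(list(a = sprintf("c%d", 1:200),
                             b = c(sprintf("c%d", 1:3), "b1", "b2", "b3",
                                   "b4", "b5")))
  # 3/8 = 37.5% rounds to 38, not 37 (and not banker's 38? -> away from 0)
  expect_equal(unname(ov$percent_of_set[["b"]]), 38)
})
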