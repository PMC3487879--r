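# Synthetic cohort generator: Hardy-Weinberg genotypes, cohort covariates,
# effect-size conversion and the planted-effect expression model.

test_that("genotypes follow Hardy-Weinberg frequencies at the given MAF", {
  cfg <- simulation_config(n_cases = 50000, n_controls = 50000,
                           snp_mafs = c(s1 = 0.127, s2 = 0.5, s3 = 0),
                           planted_effects = data.frame(),
                           n_probes = 1, seed = 9)
  g <- simulate_genotypes(cfg)$codes
  n <- nrow(g)

  # MAF 0: no minor allele anywhere
  expect_true(all(g[, "s3"] == 0))

  # MAF 0.5: mean dosage 1 within 3 SE of Binomial(2, 0.5)
  se_mean <- sqrt(2 * 0.5 * 0.5 / n)
  expect_lt(abs(mean(g[, "s2"]) - 1), 3 * se_mean)

  # MAF 0.127: heterozygote fraction 2pq = 0.221742 within 3 SE
  p_het <- 2 * 0.127 * (1 - 0.127)
  se_het <- sqrt(p_het * (1 - p_het) / n)
  expect_lt(abs(mean(g[, "s1"] == 1) - p_het), 3 * se_het)

  # all three genotype classes near p^2, 2pq, q^2
  q <- 0.127
  freqs <- c(mean(g[, "s1"] == 0), mean(g[, "s1"] == 1), mean(g[, "s1"] == 2))
  expected <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  expect_true(all(abs(freqs - expected) <
                    3 * sqrt(expected * (1 - expected) / n)))
})

test_that("invalid MAFs are rejected naming the SNP", {
  expect_error(simulation_config(snp_mafs = c(good = 0.2, bad = 0.7),
                                 planted_effects = data.frame()),
               "bad")
  expect_error(simulation_config(snp_mafs = c(neg = -0.1),
                                 planted_effects = data.frame()),
               "neg")
})

test_that("covariates match configured group sizes and age ranges", {
  cfg <- simulation_config(seed = 3, n_probes = 1,
                           planted_effects = data.frame())
  cov <- simulate_covariates(cfg)
  expect_equal(nrow(cov), 121)
  expect_equal(sum(cov$status == "case"), 74)
  expect_equal(sum(cov$status == "control"), 47)
  expect_true(all(cov$age[cov$status == "case"] >= 21 &
                    cov$age[cov$status == "case"] <= 85))
  expect_true(all(cov$age[cov$status == "control"] >= 26 &
                    cov$age[cov$status == "control"] <= 89))
})

test_that("empty groups are rejected", {
  cfg <- simulation_config(n_cases = 0, n_controls = 5,
                           planted_effects = data.frame())
  expect_error(simulate_covariates(cfg), "non-empty")
})

test_that("effect_size_to_beta matches its closed form and edge cases", {
  expect_equal(effect_size_to_beta(0, 0.3, 1), 0)
  # f = 0.5, p = 0.5: beta = sqrt(0.5 / (0.5 * 2 * 0.25)) = sqrt(2)
  expect_equal(effect_size_to_beta(0.5, 0.5, 1), sqrt(2))
  expect_error(effect_size_to_beta(0.1, 0, 1), "no genotype variance")
  expect_error(effect_size_to_beta(1, 0.3, 1), "variance_fraction")
})

test_that("planted slope explains the target variance fraction at large n", {
  # f = 0.13 at the rs10098821 case MAF; large-n R^2 must converge to f
  set.seed(123)
  n <- 1e6
  p <- 0.127
  beta <- effect_size_to_beta(0.13, p, 1)
  g <- rbinom(n, 2, p)
  y <- beta * g + rnorm(n)
  r2 <- cor(y, g)^2
  expect_lt(abs(r2 - 0.13), 0.005)
})

test_that("expression model is deterministic and respects the config", {
  cfg <- simulation_config(seed = 21, n_probes = 30)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$expression$intensities, b$expression$intensities)
  expect_identical(a$genotypes$codes, b$genotypes$codes)
  expect_identical(a$covariates$age, b$covariates$age)

  expect_equal(dim(a$expression$intensities), c(30L, 121L))
  # detection_miss_rate = 0 -> every detection P passes QC
  cfg0 <- simulation_config(seed = 21, n_probes = 10,
                            detection_miss_rate = 0)
  expect_true(all(simulate_cohort(cfg0)$expression$detection_p == 0.01))
})

test_that("planted probe index outside the matrix is rejected", {
  cfg <- simulation_config(
    seed = 5, n_probes = 3,
    planted_effects = data.frame(snp_id = "rs10098821", probe = 10L,
                                 variance_fraction = 0.1))
  g <- simulate_genotypes(cfg)
  cov <- simulate_covariates(cfg)
  expect_error(simulate_expression(g, cov, cfg), "n_probes")
})

test_that("probes without planted effects behave as nulls", {
  # with zero covariate betas and no planted effects, columns are i.i.d.
  # noise around the probe baseline: genotype regression is null-calibrated
  cfg <- null_config(seed = 77, n_probes = 200,
                     covariate_betas = c(age = 0, status = 0))
  coh <- simulate_cohort(cfg)
  res <- residual_matrix(coh$expression$intensities -
                           rowMeans(coh$expression$intensities))
  rec <- scan_all(res, coh$genotypes)
  expect_gt(mean(rec$nominal_p < 0.05), 0.05 - 3 * sqrt(0.05 * 0.95 / 400))
  expect_lt(mean(rec$nominal_p < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("optional LD knob induces the requested genotype correlation", {
  # r = 0.8 is feasible at equal MAFs (|D| stays inside the allele-frequency
  # bounds); genotype correlation equals the haplotype correlation under
  # random union of gametes
  cfg <- simulation_config(
    n_cases = 20000, n_controls = 20000,
    snp_mafs = c(a = 0.3, b = 0.3), planted_effects = data.frame(),
    ld_pairs = data.frame(snp_a = "a", snp_b = "b", r = 0.8),
    n_probes = 1, seed = 13)
  g <- simulate_genotypes(cfg)$codes
  expect_lt(abs(cor(g[, "a"], g[, "b"]) - 0.8), 0.01)
  expect_true(all(g %in% 0:2))

  # an infeasible request is clamped to the tightest attainable linkage
  cfg2 <- simulation_config(
    n_cases = 20000, n_controls = 20000,
    snp_mafs = c(a = 0.3, b = 0.2), planted_effects = data.frame(),
    ld_pairs = data.frame(snp_a = "a", snp_b = "b", r = 1),
    n_probes = 1, seed = 14)
  g2 <- simulate_genotypes(cfg2)$codes
  r_max <- min(0.3 * 0.8, 0.7 * 0.2) / sqrt(0.3 * 0.7 * 0.2 * 0.8)
  expect_lt(abs(cor(g2[, "a"], g2[, "b"]) - r_max), 0.01)
})
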