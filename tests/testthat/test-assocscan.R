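# Simple-regression association statistics, pairwise and vectorized.

test_that("regress_pair matches the closed-form OLS oracle on a toy", {
  y <- c(1.0, 0.8, 2.1, 1.9, 3.2, 2.9)
  g <- c(0, 0, 1, 1, 2, 2)
  rec <- regress_pair(y, g)

  # independent closed-form oracle
  n <- 6
  sxx <- sum((g - mean(g))^2)
  sxy <- sum((g - mean(g)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  beta <- sxy / sxx
  sigma2 <- (syy - beta * sxy) / (n - 2)
  t_stat <- beta / sqrt(sigma2 / sxx)
  p <- 2 * pt(-abs(t_stat), n - 2)
  r2 <- sxy^2 / (sxx * syy)

  expect_equal(rec$beta, beta, tolerance = 1e-10)
  expect_equal(rec$t_stat, t_stat, tolerance = 1e-10)
  expect_equal(rec$nominal_p, p, tolerance = 1e-10)
  expect_equal(rec$r2, r2, tolerance = 1e-10)
  expect_equal(rec$adj_r2, 1 - (1 - r2) * (n - 1) / (n - 2),
               tolerance = 1e-10)
  expect_equal(rec$n_used, 6L)
})

test_that("regress_pair agrees with lm() on random inputs", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    g <- rbinom(n, 2, runif(1, 0.1, 0.5))
    if (var(g) == 0) next
    y <- 0.3 * g + rnorm(n)
    rec <- regress_pair(y, g)
    fit <- summary(lm(y ~ g))
    expect_equal(rec$beta, unname(coef(fit)[2, 1]), tolerance = 1e-10)
    expect_equal(rec$t_stat, unname(coef(fit)[2, 3]), tolerance = 1e-10)
    expect_equal(rec$nominal_p, unname(coef(fit)[2, 4]), tolerance = 1e-10)
    expect_equal(rec$r2, fit$r.squared, tolerance = 1e-10)
    expect_equal(rec$adj_r2, fit$adj.r.squared, tolerance = 1e-10)
  }
})

test_that("perfect correlation gives r2 = 1 and a vanishing P", {
  g <- c(0, 1, 2, 0, 1, 2)
  rec <- regress_pair(g, g)
  expect_equal(rec$r2, 1)
  expect_lt(rec$nominal_p, 1e-6)
})

test_that("constant genotype yields a degenerate record", {
  rec <- regress_pair(rnorm(10), rep(1, 10))
  expect_true(rec$degenerate)
  expect_equal(rec$nominal_p, 1)
  expect_equal(rec$beta, 0)
})

test_that("missing genotypes are dropped pairwise", {
  y <- c(1, 2, 3, 4, 5, 6)
  g <- c(0, 1, NA, 2, NA, 1)
  rec <- regress_pair(y, g)
  expect_equal(rec$n_used, 4L)
  ref <- summary(lm(y[!is.na(g)] ~ g[!is.na(g)]))
  expect_equal(rec$nominal_p, unname(coef(ref)[2, 4]), tolerance = 1e-10)
})

test_that("dominant coding groups carriers against non-carriers", {
  y <- c(1, 1.2, 3, 3.1, 3.2, 2.9)
  g <- c(0, 0, 1, 1, 2, 2)
  rec <- regress_pair(y, g, coding = "dominant")
  ref <- summary(lm(y ~ as.numeric(g >= 1)))
  expect_equal(rec$beta, unname(coef(ref)[2, 1]), tolerance = 1e-10)
  expect_equal(rec$nominal_p, unname(coef(ref)[2, 4]), tolerance = 1e-10)
})

test_that("length mismatch errors", {
  expect_error(regress_pair(1:5, 1:4), "length")
})

test_that("scan_all emits the full snp-major grid matching regress_pair", {
  cfg <- null_config(seed = 2, n_probes = 12,
                     snp_mafs = c(a = 0.3, b = 0.2, c = 0.4, d = 0.1,
                                  e = 0.25, f = 0.35, g = 0.45))
  coh <- make_residual_cohort(cfg)
  rec <- scan_all(coh$residuals, coh$genotypes)
  expect_equal(nrow(rec), 12 * 7)
  expect_equal(unique(rec$snp_id), colnames(coh$genotypes$codes))
  # snp-major: first block is all probes for the first SNP
  expect_equal(rec$probe_id[1:12], rownames(coh$residuals$residuals))

  # row-by-row agreement with the pairwise routine
  for (i in sample(nrow(rec), 10)) {
    one <- regress_pair(coh$residuals$residuals[rec$probe_id[i], ],
                        coh$genotypes$codes[, rec$snp_id[i]])
    expect_equal(rec$nominal_p[i], one$nominal_p, tolerance = 1e-12)
    expect_equal(rec$beta[i], one$beta, tolerance = 1e-12)
  }
})

test_that("scan_all handles missing genotypes like pairwise deletion", {
  cfg <- null_config(seed = 16, n_probes = 8)
  coh <- make_residual_cohort(cfg)
  codes <- coh$genotypes$codes
  codes[c(3, 10, 50), 1] <- NA
  gt <- genotype_table(codes)
  rec <- scan_all(coh$residuals, gt)
  expect_true(all(rec$n_used[rec$snp_id == "snpA"] == 118))
  one <- regress_pair(coh$residuals$residuals[2, ], codes[, 1])
  expect_equal(rec$nominal_p[rec$snp_id == "snpA" &
                               rec$probe_id == rownames(coh$residuals$residuals)[2]],
               one$nominal_p, tolerance = 1e-12)
})

test_that("probe order permutation permutes records identically", {
  cfg <- null_config(seed = 23, n_probes = 10)
  coh <- make_residual_cohort(cfg)
  rec <- scan_all(coh$residuals, coh$genotypes)
  shuffle <- sample(nrow(coh$residuals$residuals))
  rec2 <- scan_all(residual_matrix(coh$residuals$residuals[shuffle, ]),
                   coh$genotypes)
  key <- function(r) paste(r$snp_id, r$probe_id)
  m <- match(key(rec), key(rec2))
  expect_equal(rec$nominal_p, rec2$nominal_p[m])
  expect_equal(rec$beta, rec2$beta[m])
})

test_that("adjusted r2 never exceeds r2 and P decreases in |t|", {
  cfg <- null_config(seed = 41, n_probes = 30)
  coh <- make_residual_cohort(cfg)
  rec <- scan_all(coh$residuals, coh$genotypes)
  expect_true(all(rec$adj_r2 <= rec$r2 + 1e-12))
  ord <- order(abs(rec$t_stat))
  expect_true(all(diff(rec$nominal_p[ord]) <= 1e-12))
})

test_that("planted variance fraction is recovered in expectation", {
  # parameter recovery at the study's sample size, modest replicate count;
  # the full-scale calibration lives in the acceptance suite
  f <- 0.13
  reps <- 300
  est <- vapply(seq_len(reps), function(i) {
    cfg <- simulation_config(
      seed = 1000 + i, n_probes = 1,
      snp_mafs = c(rs10098821 = 0.127),
      planted_effects = data.frame(snp_id = "rs10098821", probe = 1L,
                                   variance_fraction = f),
      covariate_betas = c(age = 0, status = 0), detection_miss_rate = 0)
    g <- simulate_genotypes(cfg)
    cov <- simulate_covariates(cfg)
    expr <- simulate_expression(g, cov, cfg)
    regress_pair(expr$intensities[1, ], g$codes[, 1])$adj_r2
  }, numeric(1))
  se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - f), 3 * se)
})
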