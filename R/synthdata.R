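# Synthetic cohort generator. Emulates the statistical structure the
# association analysis assumes: Hardy-Weinberg genotypes at given MAFs, a
# case/control cohort with uniform ages inside stated ranges, log2-scale
# expression with additive planted SNP effects of a chosen population
# variance fraction, age and status covariate effects, and two-point
# detection-P patterns for exercising probe QC.

# Fixed offsets so each generator op draws from its own deterministic
# substream of the configured seed.
.SEED_GENO <- 101L
.SEED_COV <- 211L
.SEED_EXPR <- 307L

#' Simulation configuration
#'
#' Defaults describe a 74-case / 47-control lymphoblastoid cohort typed at
#' seven ovarian-cancer GWAS SNPs (case-group MAFs), with one planted
#' additive effect explaining 13% of one probe's residual-scale variance at
#' the rs10098821 case MAF of 0.127 — the anchor effect size used throughout
#' the calibration tests.
#'
#' @param n_cases,n_controls group sizes; `n_cases + n_controls >= 3`.
#' @param snp_mafs named numeric vector of minor-allele frequencies in
#'   `[0, 0.5]`, one per simulated SNP.
#' @param planted_effects data.frame with columns `snp_id`, `probe`
#'   (1-based probe index), `variance_fraction` in `[0, 1)`: the population
#'   fraction of that probe's genetic-plus-noise variance explained by the
#'   additive genotype term.
#' @param age_range_cases,age_range_controls length-2 `(min, max)` year
#'   ranges; ages are drawn uniformly within them.
#' @param covariate_betas length-2 numeric `(age_effect, status_effect)`:
#'   log2-expression units per year of age and for case vs control.
#' @param noise_sd residual standard deviation on the log2 scale.
#' @param n_probes number of simulated probes.
#' @param detection_miss_rate per-cell probability that a detection P-value
#'   is set above the 0.05 QC threshold (0.5 instead of 0.01).
#' @param ld_pairs optional data.frame `snp_a`, `snp_b`, `r` requesting a
#'   pairwise haplotype correlation `r` between two SNPs (default: all SNPs
#'   independent).
#' @param seed integer seed; all generator output is deterministic given it.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_cases = 74L,
                              n_controls = 47L,
                              snp_mafs = c(rs3814113 = 0.346,
                                           rs2072590 = 0.300,
                                           rs2665390 = 0.081,
                                           rs10088218 = 0.149,
                                           rs1516982 = 0.167,
                                           rs10098821 = 0.127,
                                           rs2363956 = 0.432),
                              planted_effects = data.frame(
                                snp_id = "rs10098821", probe = 1L,
                                variance_fraction = 0.13),
                              age_range_cases = c(21, 85),
                              age_range_controls = c(26, 89),
                              covariate_betas = c(age = 0.01, status = 0.25),
                              noise_sd = 1,
                              n_probes = 500L,
                              detection_miss_rate = 0.02,
                              ld_pairs = NULL,
                              seed = 1L) {
  n_cases <- check_count(n_cases, "n_cases", min = 0L)
  n_controls <- check_count(n_controls, "n_controls", min = 0L)
  if (n_cases + n_controls < 3L)
    stop_val("need at least 3 samples in total (got %d)", n_cases + n_controls)
  if (is.null(names(snp_mafs)) || any(!nzchar(names(snp_mafs))))
    stop_val("'snp_mafs' must be a named vector")
  for (s in names(snp_mafs)) {
    if (!is.finite(snp_mafs[[s]]) || snp_mafs[[s]] < 0 || snp_mafs[[s]] > 0.5)
      stop_val("MAF for SNP '%s' (%g) outside [0, 0.5]", s, snp_mafs[[s]])
  }
  if (nrow(planted_effects)) {
    need <- c("snp_id", "probe", "variance_fraction")
    if (!all(need %in% names(planted_effects)))
      stop_val("planted_effects needs columns %s", paste(need, collapse = ", "))
    if (any(planted_effects$variance_fraction < 0 |
            planted_effects$variance_fraction >= 1))
      stop_val("every planted variance_fraction must lie in [0, 1)")
    missing_snp <- setdiff(planted_effects$snp_id, names(snp_mafs))
    if (length(missing_snp))
      stop_val("planted effect refers to unknown SNP(s): %s",
               paste(missing_snp, collapse = ", "))
  }
  stopifnot(length(age_range_cases) == 2L, length(age_range_controls) == 2L)
  if (n_cases > 0L && age_range_cases[1] >= age_range_cases[2])
    stop_val("age_range_cases must satisfy min < max")
  if (n_controls > 0L && age_range_controls[1] >= age_range_controls[2])
    stop_val("age_range_controls must satisfy min < max")
  check_number(noise_sd, "noise_sd", lower = 0, closed_lower = FALSE)
  check_number(detection_miss_rate, "detection_miss_rate", 0, 1)
  n_probes <- check_count(n_probes, "n_probes", min = 1L)
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 snp_mafs = snp_mafs, planted_effects = planted_effects,
                 age_range_cases = age_range_cases,
                 age_range_controls = age_range_controls,
                 covariate_betas = covariate_betas, noise_sd = noise_sd,
                 n_probes = n_probes,
                 detection_miss_rate = detection_miss_rate,
                 ld_pairs = ld_pairs,
                 seed = check_count(seed, "seed")),
            class = "simulation_config")
}

.sim_sample_ids <- function(config) {
  c(if (config$n_cases) sprintf("case_%03d", seq_len(config$n_cases)),
    if (config$n_controls) sprintf("ctrl_%03d", seq_len(config$n_controls)))
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Draws additive codes per sample as Binomial(2, MAF), i.e. genotype
#' frequencies (1-p)^2, 2p(1-p), p^2 at minor-allele frequency p. SNPs are
#' independent unless `ld_pairs` requests a pairwise haplotype correlation,
#' in which case the two SNPs' haplotypes are sampled jointly with
#' disequilibrium D = r * sqrt(pA qA pB qB).
#'
#' @param config a [simulation_config()].
#' @return a [genotype_table()] with `n_cases + n_controls` rows.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + .SEED_GENO)
  n <- config$n_cases + config$n_controls
  mafs <- config$snp_mafs
  codes <- vapply(mafs, function(p) stats::rbinom(n, 2L, p), numeric(n))
  if (n == 1L) codes <- matrix(codes, nrow = 1L)
  dimnames(codes) <- list(.sim_sample_ids(config), names(mafs))
  if (!is.null(config$ld_pairs) && nrow(config$ld_pairs)) {
    for (k in seq_len(nrow(config$ld_pairs))) {
      pr <- config$ld_pairs[k, ]
      codes[, c(pr$snp_a, pr$snp_b)] <-
        .sim_ld_pair(n, mafs[[pr$snp_a]], mafs[[pr$snp_b]], pr$r)
    }
  }
  genotype_table(codes)
}

# Joint haplotype sampling for one SNP pair at correlation r: four haplotype
# frequencies pA*pB + D etc., two haplotypes per individual.
.sim_ld_pair <- function(n, pa, pb, r) {
  check_number(r, "r", -1, 1)
  d <- r * sqrt(pa * (1 - pa) * pb * (1 - pb))
  # clamp D into the feasible region so all four frequencies stay >= 0
  d <- max(min(d, min(pa * (1 - pb), (1 - pa) * pb)),
           -min(pa * pb, (1 - pa) * (1 - pb)))
  hap <- c(`11` = pa * pb + d, `10` = pa * (1 - pb) - d,
           `01` = (1 - pa) * pb - d, `00` = (1 - pa) * (1 - pb) + d)
  draws <- sample.int(4L, 2L * n, replace = TRUE, prob = hap)
  a_allele <- draws %in% c(1L, 2L)
  b_allele <- draws %in% c(1L, 3L)
  cbind(colSums(matrix(a_allele, 2L)), colSums(matrix(b_allele, 2L)))
}

#' Simulate cohort covariates
#'
#' Ages drawn uniformly within the configured per-group ranges (the study
#' design reports only median and range; uniform is the simplest distribution
#' consistent with the bounds); status fixed by group.
#'
#' @param config a [simulation_config()].
#' @return a [covariate_table()] with cases first, then controls.
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_cases < 1L || config$n_controls < 1L)
    stop_val("both groups must be non-empty (got %d cases, %d controls)",
             config$n_cases, config$n_controls)
  set.seed(config$seed + .SEED_COV)
  ages <- c(stats::runif(config$n_cases, config$age_range_cases[1],
                         config$age_range_cases[2]),
            stats::runif(config$n_controls, config$age_range_controls[1],
                         config$age_range_controls[2]))
  covariate_table(.sim_sample_ids(config), ages,
                  rep(c("case", "control"),
                      c(config$n_cases, config$n_controls)))
}

#' Convert a target variance fraction to a planted slope
#'
#' Under Hardy-Weinberg the additive genotype has variance 2p(1-p); a slope
#' beta = residual_sd * sqrt(f / ((1 - f) * 2p(1-p))) makes the genotype term
#' explain exactly the population fraction `f` of the genetic-plus-noise
#' variance, so a planted `f` plays the role of a target adjusted r-squared.
#'
#' @param variance_fraction target population R^2 in `[0, 1)`.
#' @param maf minor-allele frequency in `(0, 0.5]` (0 allowed only with
#'   `variance_fraction = 0`).
#' @param residual_sd residual standard deviation (> 0).
#' @return the slope per minor-allele copy.
#' @export
effect_size_to_beta <- function(variance_fraction, maf, residual_sd) {
  check_number(variance_fraction, "variance_fraction", 0, 1,
               closed_upper = FALSE)
  check_number(maf, "maf", 0, 0.5)
  check_number(residual_sd, "residual_sd", 0, closed_lower = FALSE)
  if (variance_fraction == 0) return(0)
  if (maf == 0)
    stop_val("maf = 0 gives no genotype variance to explain a nonzero effect")
  geno_var <- 2 * maf * (1 - maf)
  residual_sd * sqrt(variance_fraction / ((1 - variance_fraction) * geno_var))
}

#' Simulate log2-scale expression with planted effects
#'
#' Generative model mirrors the analysis model: for probe g and sample i,
#' `y_gi = mu_g + beta_age * age_i + beta_status * status_i +
#' sum(planted beta * G_si) + eps`, eps ~ Normal(0, noise_sd^2) on the log2
#' scale. Probes without planted effects are null pairs for every SNP.
#' Detection P-values are two-point (0.01 pass / 0.5 fail) with fail
#' probability `detection_miss_rate` per cell, since only the 0.05 threshold
#' matters downstream.
#'
#' @param genotypes a [genotype_table()] from [simulate_genotypes()].
#' @param covariates a [covariate_table()] from [simulate_covariates()].
#' @param config the same [simulation_config()].
#' @return an [expression_matrix()] (`n_probes` x samples, scale `"log2"`).
#' @export
simulate_expression <- function(genotypes, covariates, config) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(genotypes, "genotype_table"),
            inherits(covariates, "covariate_table"))
  if (!identical(sample_ids(genotypes), sample_ids(covariates)))
    stop_val("genotype and covariate sample sets differ")
  pe <- config$planted_effects
  if (nrow(pe) && any(pe$probe < 1L | pe$probe > config$n_probes))
    stop_val("planted probe index outside 1..n_probes (n_probes = %d)",
             config$n_probes)
  set.seed(config$seed + .SEED_EXPR)
  n <- length(sample_ids(genotypes))
  np <- config$n_probes
  mu <- stats::runif(np, 6, 12)  # typical log2 Illumina intensity range
  status01 <- as.numeric(covariates$status == "case")
  y <- matrix(mu, np, n) +
    matrix(stats::rnorm(np * n, sd = config$noise_sd), np, n)
  cov_shift <- config$covariate_betas[[1]] * covariates$age +
    config$covariate_betas[[2]] * status01
  y <- sweep(y, 2L, cov_shift, `+`)
  if (nrow(pe)) {
    for (k in seq_len(nrow(pe))) {
      beta <- effect_size_to_beta(pe$variance_fraction[k],
                                  config$snp_mafs[[pe$snp_id[k]]],
                                  config$noise_sd)
      g <- genotypes$codes[, pe$snp_id[k]]
      g[is.na(g)] <- 0
      y[pe$probe[k], ] <- y[pe$probe[k], ] + beta * g
    }
  }
  det <- matrix(ifelse(stats::runif(np * n) < config$detection_miss_rate,
                       0.5, 0.01), np, n)
  dimnames(y) <- list(sprintf("probe_%04d", seq_len(np)),
                      sample_ids(genotypes))
  dimnames(det) <- dimnames(y)
  expression_matrix(y, detection_p = det, scale = "log2")
}

#' Simulate a full cohort
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [simulate_covariates()] and [simulate_expression()] from one
#' configuration.
#'
#' @param config a [simulation_config()].
#' @return list with `expression`, `genotypes`, `covariates`, `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  genotypes <- simulate_genotypes(config)
  covariates <- simulate_covariates(config)
  expr <- simulate_expression(genotypes, covariates, config)
  list(expression = expr, genotypes = genotypes, covariates = covariates,
       config = config)
}
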