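# Shared fixtures, built in code at test time.

# Small expression matrix with hand-set detection P-values.
make_toy_expr <- function(n_probes = 4, n_samples = 4, scale = "log2",
                          detection = NULL, seed = 42) {
  set.seed(seed)
  m <- matrix(rnorm(n_probes * n_samples, mean = 8), n_probes, n_samples,
              dimnames = list(paste0("p", seq_len(n_probes)),
                              paste0("s", seq_len(n_samples))))
  expression_matrix(m, detection_p = detection, scale = scale)
}

# Null cohort (no planted effects) at a chosen size.
null_config <- function(seed, n_probes = 50,
                        snp_mafs = c(snpA = 0.3, snpB = 0.3), ...) {
  simulation_config(
    seed = seed, n_probes = n_probes, snp_mafs = snp_mafs,
    planted_effects = data.frame(snp_id = character(), probe = integer(),
                                 variance_fraction = numeric()),
    detection_miss_rate = 0, ...)
}

# Residuals ready for scanning: simulate, normalize, residualize.
make_residual_cohort <- function(config) {
  coh <- simulate_cohort(config)
  expr <- quantile_normalize(coh$expression)
  list(residuals = residualize(expr, coh$covariates),
       genotypes = coh$genotypes, covariates = coh$covariates)
}

# The six permutations of 1:3, hardcoded so oracle checks do not depend on
# the package's own permutation enumerator.
PERMS3 <- matrix(c(1, 2, 3,
                   1, 3, 2,
                   2, 1, 3,
                   2, 3, 1,
                   3, 1, 2,
                   3, 2, 1), ncol = 3, byrow = TRUE)
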