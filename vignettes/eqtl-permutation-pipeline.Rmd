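---
title: "Candidate-SNP eQTL scans with permutation-adjusted P-values"
author: "eqtlperm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-SNP eQTL scans with permutation-adjusted P-values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genome-wide association studies identify risk variants, but most of them
fall outside coding sequence, so their functional consequences are unclear.
A standard way to connect a risk SNP to putative target transcripts is an
expression quantitative trait locus (eQTL) analysis in a surrogate tissue
such as lymphoblastoid cell lines: genotype a handful of candidate SNPs in
a cohort, profile genome-wide transcript abundance on an expression
microarray, and test every SNP-transcript pair for association.

`eqtlperm` implements that design as a small, fully testable pipeline:

1. **Probe QC** by the array's per-probe, per-sample detection P-value.
2. **Quantile normalization** of log2 intensities.
3. **Covariate residualization**: remove age and case/control effects from
   each transcript by per-probe ordinary least squares, once, up front.
4. **Association scan**: simple linear regression of each probe's residuals
   on each SNP's additive genotype code.
5. **Permutation adjustment**: empirical P-values from relabelings of the
   phenotype relative to genotype.
6. **Genomic annotation**: cis/trans calls against a distance window,
   per-SNP significance counts, cross-SNP overlap summaries.
7. **Gene-set enrichment** of the significant transcripts (Fisher exact or
   EASE, Benjamini-Hochberg FDR), against user-supplied GMT annotation.

A synthetic-cohort generator with the same statistical structure makes
every stage runnable and checkable without any external download.

## The model

For probe $g$ and sample $i$, the analysis assumes log2 intensities

$$ y_{gi} = \mu_g + \beta_{\text{age}}\,\mathrm{age}_i
   + \beta_{\text{status}}\,\mathrm{case}_i + e_{gi}, $$

and the association test regresses the residual $e_{gi}$ on the additive
genotype code $G_{si} \in \{0,1,2\}$ of SNP $s$:

$$ e_{gi} = \alpha + \beta_s G_{si} + \varepsilon_{gi}. $$

Reported per pair: the slope $\beta_s$, the two-sided nominal P from the
$t$ distribution on $n-2$ degrees of freedom, $r^2$ (squared Pearson
correlation), and the one-predictor adjusted
$r^2 = 1-(1-r^2)(n-1)/(n-2)$. The residualization is two-stage by design:
covariates are fit once and the scan and all permutations reuse the same
residuals. A joint model (genotype and covariates refit together) gives
slightly different nominal P-values; the two-stage form was chosen because
it matches the pipeline's phrase-level contract ("residuals of expression
adjusted for age and status") and makes the permutation engine a pure
function of one residual matrix.

### Permutation-adjusted P-values

The adjusted ("permutated") P-value of a pair is the fraction of $B$
relabelings of the phenotype whose nominal P ties or beats the observed
one. Because the degrees of freedom are fixed within a SNP, comparing
nominal P-values is equivalent to comparing squared correlations, so one
relabeling's statistics for *all* pairs reduce to a single matrix product —
this is what makes $B = 10{,}000$ over tens of thousands of pairs
practical on one CPU.

Defaults and the reasoning behind them:

* `scheme = "joint"`: one relabeling of the whole residual matrix per
  iteration, shared by every pair. It is $O(B)$ relabelings rather than
  $O(B \times \text{pairs})$ and preserves transcript-transcript
  correlation; `per_pair` is available for comparison and the two agree in
  distribution per pair (tested).
* `pseudocount = "none"`: `perm_p = count/B`, so an effect stronger than
  every relabeling reports exactly 0 and the smallest positive value is
  $1/B$ ($10^{-4}$ at the default $B$). `add_one` gives the strictly
  positive $(count+1)/(B+1)$ variant.
* Ties count against the observed statistic (conservative, standard). Tied
  relabelings are detected with an absolute tolerance of $10^{-12}$ on
  $r^2$, because a relabeling that reproduces the observed grouping is
  algebraically identical but may differ in the last float ulp.
* Degenerate pairs (constant genotype or phenotype, or fewer than 3
  complete observations) are flagged and report `perm_p = 1`.

An exact oracle (`exact_permutation_oracle`) enumerates all $n!$
relabelings for $n \le 8$ and anchors the Monte-Carlo engine in the test
suite.

### QC and normalization

A probe is excluded when its detection P exceeds `alpha` (default 0.05) in
at least `fail_fraction` (default 25%) of samples. The published filters in
this area are worded both ways — "exclude if undetected in ≥ 25%" and
"keep if detected in ≥ 25%" — which differ: the first keeps probes detected
in more than 75% of samples. The package defaults to the stricter
exclusion rule and exposes `fail_fraction`, so the laxer reading is
`fail_fraction = 0.75`; neither is asserted as the only correct one.

Quantile normalization forces every sample's value distribution onto the
rank-wise across-sample means (delegated to
`limma::normalizeQuantiles(ties = TRUE)`, which averages tied ranks —
deterministic and standard). Raw intensities are log2-transformed first;
background-subtracted array data can contain non-positive values, so a
configurable offset (default +1) is added before the log when needed, and
logged.

### cis/trans and overlap bookkeeping

A SNP-transcript pair is *cis* when both loci share a chromosome and the
SNP point lies within `window` (default 1 Mb) of the gene interval, with a
closed boundary (exactly 1 Mb is cis). Whether such windows should be
measured from the gene edge, the TSS, or the probe position is rarely
stated in publications and cannot be recovered from printed distances;
the anchor is therefore a parameter (`edge`, the default, with 0 for a SNP
inside the gene; or `start`). BED input is converted from 0-based
half-open to the internal 1-based inclusive convention on load.

Threshold counts use strict inequality (`perm_p < 0.05`), matching the
"P<0.05" headers such summaries are printed under. Overlap percentages
(share of a SNP's significant transcripts common to all SNPs) are rounded
to the nearest integer with ties away from zero; an empty set yields an
undefined (`NA`) percentage rather than 0.

### Enrichment

The enrichment module is a local stand-in for web-service GO analysis:
Fisher's exact test is the hypergeometric upper tail
$\Pr[X \ge \text{count}]$ on the query/universe 2×2 table, and the EASE
variant removes one hit from the overlap cell before taking the tail,
which is strictly conservative (tested). FDR is Benjamini-Hochberg via
`stats::p.adjust`. Results from database-backed tools depend on their
annotation snapshots and background universes, so published pathway
P-values are treated as illustrative output format, not as values this
module should reproduce; the default universe is the QC-passing probe set
collapsed to unique gene symbols.

## The synthetic cohort

`simulation_config()` describes the cohort the generator emulates. The
defaults are fixed study conditions, not tuning knobs:

* 74 cases and 47 controls (121 samples), ages uniform on 21–85 (cases)
  and 26–89 (controls). Only the medians and ranges of the emulated cohort
  are known; uniform is the simplest distribution consistent with the
  bounds, and the distribution is configurable.
* Seven candidate SNPs at their case-group MAFs (0.346, 0.300, 0.081,
  0.149, 0.167, 0.127, 0.432), drawn under Hardy-Weinberg equilibrium,
  independent across SNPs. An optional pairwise-LD knob (haplotype
  sampling at correlation $r$, clamped to the feasible region given the
  allele frequencies) can recreate the correlated-hit pattern of SNPs in
  one locus; it is off by default because the analysis treats SNPs
  independently.
* Gaussian noise on the log2 scale (`noise_sd = 1`), probe baselines
  uniform on 6–12 log2 units — the typical intensity range of this array
  class.
* Covariate effects default to 0.01 log2-units per year of age and 0.25
  log2-units for case vs control: modest, detectable effects that make the
  residualization stage non-trivial. No published values exist for these;
  they were fixed once as plausible for lymphoblastoid expression data.
* One planted additive effect explaining 13% of one probe's
  genetic-plus-noise variance at MAF 0.127 — the anchor effect size used
  in the recovery tests, converted to a slope by
  `effect_size_to_beta()`: $\beta = \sigma\sqrt{f/((1-f)\,2p(1-p))}$, so
  the population $R^2$ of the genotype term is exactly $f$.
* Detection P-values are two-point (0.01 pass / 0.5 fail at rate
  `detection_miss_rate`), since only the 0.05 threshold matters
  downstream.

What the generator does **not** emulate: bead-level array artifacts, batch
effects, probe cross-hybridization, population structure, relatedness, and
linkage to untyped variants. Passing tests therefore demonstrate that the
statistical machinery is correct and calibrated under the assumed model,
not that any particular biological dataset would yield particular
associations.

## Numerical choices and degenerate inputs

* All OLS statistics come from closed-form correlation algebra; the
  pairwise route (`regress_pair`) and the vectorized route (`scan_all`)
  agree to $10^{-12}$ and both match `lm()` to $10^{-10}$ in tests.
* Missing genotypes are dropped pairwise, never imputed; `n_used` records
  the per-pair sample count. With missing data the permutation engine
  recomputes per-relabeling phenotype variances from subset row sums, so
  the null distribution stays exact.
* Constant covariates are dropped with a warning; constant genotypes or
  phenotypes yield flagged degenerate records rather than errors.
* Reruns with the same seed are byte-identical end to end; the generator
  derives separate substreams for genotypes, covariates and expression
  from one seed.

## Problem sizes used in the checks

The calibration suite runs at deliberately desk-friendly sizes chosen once:
null calibration uses 500 probes × 2 SNPs at $n = 121$ with $B = 1{,}000$
(1,000 pairs; the type-I error at 0.05 is checked within 3 Monte-Carlo
standard errors), effect-size recovery uses 1,000 replicates of the
13%-variance effect at $n = 121$, and oracle equivalence compares
$B = 10{,}000$ Monte-Carlo estimates against full enumeration at $n = 6$.
The same quantities are recomputed from scratch by
`scripts/acceptance.R`.

## Known limitations

* The scan is single-SNP, additive or dominant; no joint models,
  interactions, or mixed models for relatedness.
* Permutation is plain Monte-Carlo — no adaptive stopping or tail
  approximation — so extremely small adjusted P-values are bounded by
  $1/B$.
* Probe-to-gene assignment is taken from the input annotation as given;
  there is no re-mapping of probe sequences.
* The enrichment module tests over-representation only; it does not
  propagate GO structure or trim redundant terms.
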