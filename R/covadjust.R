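# Covariate residualization: per-probe ordinary least squares of expression
# on {intercept, age, case/control indicator}. The residuals are the
# phenotypes used by every downstream association test (two-stage design:
# covariates are removed once, before the scan and before permutation).

#' Residualize expression on age and case/control status
#'
#' Fits, for every probe, OLS of (normalized) log2 expression on an
#' intercept, age in years, and a 0/1 case indicator, and returns the
#' residuals. A covariate that is constant across samples (e.g. an
#' all-case cohort) is dropped with a warning. Residuals are orthogonal to
#' the fitted covariates and have per-probe mean zero.
#'
#' @param expr an [expression_matrix()] on the
#'   `"log2-quantile-normalized"` scale.
#' @param cov a [covariate_table()] covering exactly the same samples.
#' @return a [residual_matrix()] of the same probe x sample shape.
#' @export
residualize <- function(expr, cov) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(cov, "covariate_table"))
  if (expr$scale != SCALE_LOG2_QN)
    stop_val("expression must be quantile-normalized before residualization (scale is '%s')",
             expr$scale)
  es <- sample_ids(expr)
  cs <- sample_ids(cov)
  if (!setequal(es, cs)) {
    stop_val("sample mismatch between expression and covariates; only in expression: %s; only in covariates: %s",
             paste(setdiff(es, cs), collapse = ", "),
             paste(setdiff(cs, es), collapse = ", "))
  }
  cov <- cov[match(es, cs), , drop = FALSE]
  design <- cbind(intercept = 1,
                  age = cov$age,
                  status = as.numeric(cov$status == "case"))
  keep <- c(TRUE, apply(design[, -1, drop = FALSE], 2L,
                        function(v) stats::var(v) > 0))
  if (!all(keep)) {
    warning(sprintf("dropping constant covariate(s): %s",
                    paste(colnames(design)[!keep], collapse = ", ")),
            call. = FALSE)
    design <- design[, keep, drop = FALSE]
  }
  qr_x <- qr(design)
  res <- t(qr.resid(qr_x, t(expr$intensities)))
  dimnames(res) <- dimnames(expr$intensities)
  residual_matrix(res)
}
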