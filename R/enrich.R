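# Local gene-set over-representation testing: Fisher exact (hypergeometric
# upper tail) and the conservative EASE variant (one hit removed from the
# overlap cell), with Benjamini-Hochberg FDR across the tested sets.

#' Read a GMT gene-set file
#'
#' GMT is tab-separated: set id, description, then member gene symbols.
#' Duplicate members within a set are collapsed; empty sets are rejected.
#'
#' @param path GMT file path.
#' @return a `gene_set_collection`: list with `sets` (named list of member
#'   vectors), `descriptions` (named character), `source` (the path).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_val("GMT file '%s' is empty", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop_val("duplicate set IDs in '%s': %s", path,
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  desc <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else "",
                 character(1))
  members <- lapply(parts, function(p) {
    m <- unique(p[-(1:2)])
    m[nzchar(m)]
  })
  empty <- vapply(members, length, integer(1)) == 0L
  if (any(empty))
    stop_val("empty gene set(s) in '%s': %s", path,
             paste(ids[empty], collapse = ", "))
  names(members) <- ids
  names(desc) <- ids
  structure(list(sets = members, descriptions = desc, source = path),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets from %s\n",
              length(x$sets), x$source))
  invisible(x)
}

#' Gene-set over-representation test
#'
#' For each set (intersected with the universe first), tests whether the
#' query list hits it more often than expected under hypergeometric
#' sampling from the universe. `method = "fisher"` uses the exact upper
#' tail `Pr[X >= count]`; `"ease"` removes one hit from the overlap cell
#' before taking the tail (`Pr[X >= count - 1]`), the conservative EASE
#' score variant popularized by DAVID. Benjamini-Hochberg FDR is computed
#' across all tested sets.
#'
#' @param query character vector of query gene symbols (subset of
#'   `universe`).
#' @param universe character vector of background gene symbols (e.g. all
#'   QC-passing probes mapped to unique symbols).
#' @param sets a `gene_set_collection` from [read_gmt()].
#' @param method `"fisher"` or `"ease"`.
#' @return data.frame with `set_id`, `description`, `count`, `size`,
#'   `p_value`, `fdr`, `method`, ordered by increasing `p_value`; one row
#'   per set with at least one universe member.
#' @export
enrichment_test <- function(query, universe, sets,
                            method = c("fisher", "ease")) {
  method <- match.arg(method)
  stopifnot(inherits(sets, "gene_set_collection"))
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (!length(query)) stop_val("query gene list is empty")
  outside <- setdiff(query, universe)
  if (length(outside))
    stop_val("query genes absent from the universe: %s",
             paste(utils::head(outside, 10L), collapse = ", "))
  n_universe <- length(universe)
  n_query <- length(query)
  members <- lapply(sets$sets, intersect, y = universe)
  keep <- vapply(members, length, integer(1)) > 0L
  members <- members[keep]
  size <- vapply(members, length, integer(1))
  count <- vapply(members, function(m) length(intersect(m, query)),
                  integer(1))
  tail_from <- if (method == "fisher") count else pmax(count - 1L, 0L)
  # Pr[X >= tail_from] for X ~ Hypergeometric(size, n_universe - size,
  # n_query)
  p <- stats::phyper(tail_from - 1L, size, n_universe - size, n_query,
                     lower.tail = FALSE)
  p <- pmin(p, 1)
  out <- data.frame(set_id = names(members),
                    description = unname(sets$descriptions[names(members)]),
                    count = unname(count), size = unname(size),
                    p_value = unname(p), fdr = bh_fdr(unname(p)),
                    method = method, stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg FDR (step-up q-values)
#'
#' Thin wrapper over [stats::p.adjust()] with input validation:
#' `q_(i) = min_{j >= i} m * p_(j) / j` in sorted order, mapped back to the
#' input order.
#'
#' @param p_values numeric vector of P-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop_val("P-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p_values, method = "BH")
}
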