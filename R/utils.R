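#' @keywords internal
"_PACKAGE"

# Shared validation helpers and small numeric utilities.

stop_val <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         closed_lower = TRUE, closed_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_val("'%s' must be a single non-missing number", name)
  lo_ok <- if (closed_lower) x >= lower else x > lower
  hi_ok <- if (closed_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok)
    stop_val("'%s' = %g is outside the allowed range %s%g, %g%s", name, x,
             if (closed_lower) "[" else "(", lower, upper,
             if (closed_upper) "]" else ")")
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min)
    stop_val("'%s' must be an integer >= %d", name, min)
  as.integer(x)
}

#' Round to nearest integer, ties away from zero
#'
#' Commercial rounding used for reported percentages (base `round()` rounds
#' half to even, which would turn 50.5 into 50).
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' All permutations of 1..n
#'
#' Exhaustive enumeration used by the exact permutation oracle. Refuses
#' n > 8 (factorial growth).
#'
#' @param n number of elements (<= 8).
#' @return matrix with `factorial(n)` rows, each a permutation of `seq_len(n)`.
#' @export
all_permutations <- function(n) {
  n <- check_count(n, "n", min = 1L)
  if (n > 8L)
    stop_val("refusing to enumerate %d! permutations (n must be <= 8)", n)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (pos in seq_len(n)) {
    idx <- row + seq_len(nrow(sub))
    out[idx, pos] <- n
    out[idx, -pos] <- sub
    row <- row + nrow(sub)
  }
  out
}
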