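#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

check_finite <- function(x, what) {
  stop_if(any(!is.finite(x)), what, " contains non-finite values")
  invisible(x)
}

# standardize rows (genes) of a genes x samples matrix to mean 0, sd 1
standardize_rows <- function(x) {
  mu <- rowMeans(x)
  s <- apply(x, 1L, stats::sd)
  stop_if(any(s == 0), "zero-variance gene encountered where variance is required")
  (x - mu) / s
}

# deterministic sub-seed derivation; keeps results < 2^31
derive_seed <- function(seed, k) {
  (as.integer(seed) * 1103L + as.integer(k) * 12289L) %% 2147483587L
}

# adjusted Rand index between two labelings (used by pipeline reports and tests)
#' Adjusted Rand index between two partitions
#'
#' Measures agreement between two clusterings of the same items, corrected
#' for chance; 1 = identical partitions, ~0 = independent.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return numeric scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stop_if(length(a) != length(b), "label vectors must have equal length")
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  denom <- (ai + bj) / 2 - expected
  if (denom == 0) return(1)
  (nij - expected) / denom
}
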