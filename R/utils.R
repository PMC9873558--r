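#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. seed = NULL runs in the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

clamp01 <- function(x, tol = 1e-8, warn = TRUE) {
  out <- pmin(pmax(x, 0), 1)
  off <- !is.na(x) & (x < -tol | x > 1 + tol)
  if (warn && any(off)) {
    warning(sprintf("%d value(s) outside [0, 1] clamped", sum(off)))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items.
#' Items with `NA` in either vector (for example patients left unassigned by
#' the consensus rule) are dropped before comparison.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A number in \[-1, 1\]; 1 for identical partitions, ~0 for
#'   independent ones.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 2) stop("need at least 2 jointly labeled items")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(n)
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
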