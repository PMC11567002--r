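# Internal helpers.

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG
# state afterwards so generators are deterministic without side effects.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Euclidean distance matrix rows of a to rows of b (both n x 2).
.crossDist <- function(a, b) {
  sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
}

.sem <- function(x) stats::sd(x) / sqrt(length(x))

# Moving mean with window w (odd), edges shrink symmetrically.
.movingMean <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  h <- (w - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}
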