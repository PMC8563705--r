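# Internal helpers shared across modules.

# Deterministically derive a child RNG seed from a master seed and a sequence
# of integer offsets.  Pure integer arithmetic on doubles (< 2^53), reduced
# mod a Mersenne prime so the result always fits a 32-bit R integer.
derive_seed <- function(seed, ...) {
  s <- as.numeric(seed) %% 2147483647
  for (off in c(...)) {
    s <- (s * 48271 + as.numeric(off) + 1) %% 2147483647
  }
  as.integer(s)
}

# Stop with a consistent message prefix.
oc_stop <- function(...) stop(..., call. = FALSE)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

# Validate a square co-clustering/similarity matrix: symmetric, unit
# diagonal, entries in [0, 1], sample ids on both dimnames.
validate_connectivity <- function(C, what = "connectivity matrix") {
  if (!is.matrix(C) || nrow(C) != ncol(C))
    oc_stop(what, " must be a square matrix")
  if (is.null(rownames(C)) || !identical(rownames(C), colnames(C)))
    oc_stop(what, " must carry identical row and column sample ids")
  if (!isTRUE(all(C == t(C))))
    oc_stop(what, " must be exactly symmetric")
  if (any(C < 0 | C > 1))
    oc_stop(what, " entries must lie in [0, 1]")
  if (any(diag(C) != 1))
    oc_stop(what, " must have a unit diagonal")
  invisible(C)
}

# Relabel an integer/factor partition to consecutive integers 1..k, ordered
# by first appearance so the mapping is deterministic.
canonical_labels <- function(labels) {
  u <- unique(labels)
  out <- match(labels, u)
  names(out) <- names(labels)
  out
}

# k-means wrapper: seeded, multiple restarts, falls back to Lloyd if
# Hartigan-Wong aborts on degenerate configurations.  Per-start convergence
# warnings are suppressed: the best of nstart restarts is kept.
km_cluster <- function(X, k, nstart = 10L, seed = 1L) {
  if (nrow(unique(X)) < k)
    oc_stop("fewer than k distinct rows; cannot form ", k, " clusters")
  withr::with_seed(seed, {
    fit <- tryCatch(
      suppressWarnings(
        stats::kmeans(X, centers = k, nstart = nstart, iter.max = 100L)),
      error = function(e)
        suppressWarnings(
          stats::kmeans(X, centers = k, nstart = nstart, iter.max = 100L,
                        algorithm = "Lloyd"))
    )
    fit$cluster
  })
}
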