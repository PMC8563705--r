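# Randomized SVD dimension reduction.
#
# Each omics layer X (n samples x m features) is mean-centered by feature
# and approximated by its top singular subspace: a Gaussian sketch Z = X P
# is orthogonalized by QR, optionally refined by subspace (power)
# iterations, and a small exact SVD of Y = Q'X yields the right singular
# vectors V used as the rotation.  Scores X' = (X - center) V are the
# coordinates handed to clustering, and new samples are projected into the
# same space with the stored rotation.

#' Fit a randomized SVD model to an omics layer
#'
#' @param X An [omics_matrix()] or a numeric matrix with dimnames.
#' @param rank Number of components to retain; `1 <= rank <= min(n-1, m)`.
#' @param oversample Extra sketch columns beyond `rank` (default 10).
#' @param power_iters Subspace-iteration count (default 2); each iteration
#'   re-orthogonalizes by QR for numerical stability.
#' @param seed Integer seed for the Gaussian projection matrix.
#' @param center Mean-center features before decomposition? Default `TRUE`
#'   (PCA convention); the stored `center` vector is zero when `FALSE`.
#' @return An object of class `rsvd_model`: `rotation` (m x rank, columns
#'   orthonormal), `singular_values` (non-increasing, >= 0), `center`
#'   (length-m feature means), `rank`, `feature_ids`, `seed`.
#' @export
rsvd_fit <- function(X, rank, oversample = 10L, power_iters = 2L, seed = 1L,
                     center = TRUE) {
  vals <- if (inherits(X, "omics_matrix")) X$values else X
  if (!is.matrix(vals)) oc_stop("'X' must be a matrix or omics_matrix")
  n <- nrow(vals); m <- ncol(vals)
  if (!is_count(rank) || rank > min(n - 1L, m))
    oc_stop("'rank' must be an integer in [1, min(n-1, m)] = [1, ",
            min(n - 1L, m), "]")
  if (!is_count(oversample, min = 0L) || !is_count(power_iters, min = 0L))
    oc_stop("'oversample' and 'power_iters' must be non-negative integers")
  mu <- if (center) colMeans(vals) else rep(0, m)
  Xc <- sweep(vals, 2L, mu, "-")
  l <- min(rank + oversample, n, m)
  Q <- withr::with_seed(as.integer(seed), {
    P <- matrix(stats::rnorm(m * l), m, l)
    qr.Q(qr(Xc %*% P))
  })
  if (power_iters > 0L) {
    for (i in seq_len(power_iters)) {
      Q2 <- qr.Q(qr(crossprod(Xc, Q)))   # m x l
      Q  <- qr.Q(qr(Xc %*% Q2))          # n x l
    }
  }
  Y <- crossprod(Q, Xc)                  # l x m
  sv <- svd(Y, nu = 0L, nv = l)
  keep <- seq_len(rank)
  structure(
    list(rotation = sv$v[, keep, drop = FALSE],
         singular_values = pmax(sv$d[keep], 0),
         center = mu,
         rank = as.integer(rank),
         feature_ids = colnames(vals),
         seed = as.integer(seed)),
    class = "rsvd_model")
}

#' @export
print.rsvd_model <- function(x, ...) {
  cat(sprintf("rsvd_model: rank %d over %d features; top singular value %.4g\n",
              x$rank, length(x$center), x$singular_values[1L]))
  invisible(x)
}

#' Project samples into a fitted component space
#'
#' Computes `scores = (X - center) %*% rotation`. Applying the transform to
#' the fitting matrix reproduces the fit-time scores; feature ids must match
#' the fitting matrix in the same order.
#'
#' @param model An `rsvd_model` from [rsvd_fit()].
#' @param X An [omics_matrix()] or numeric matrix with the model's features.
#' @return An object of class `reduced_matrix`: `sample_ids` plus an
#'   `n x rank` `scores` matrix.
#' @export
rsvd_transform <- function(model, X) {
  vals <- if (inherits(X, "omics_matrix")) X$values else X
  if (!is.null(model$feature_ids)) {
    fid <- colnames(vals)
    if (is.null(fid) || length(fid) != length(model$feature_ids) ||
        any(fid != model$feature_ids)) {
      bad <- if (is.null(fid)) "<missing feature ids>" else {
        i <- which(fid != model$feature_ids)[1L]
        if (is.na(i)) "<length mismatch>" else fid[i]
      }
      oc_stop("feature mismatch with fitted model; first offending id: ", bad)
    }
  }
  scores <- sweep(vals, 2L, model$center, "-") %*% model$rotation
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  structure(list(sample_ids = rownames(vals), scores = scores),
            class = "reduced_matrix")
}

#' @export
print.reduced_matrix <- function(x, ...) {
  cat(sprintf("reduced_matrix: %d samples x %d components\n",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Choose a retained rank from a singular-value spectrum
#'
#' Returns the smallest `r` whose cumulative squared singular values reach
#' `var_threshold` of the total, capped at `max_rank`.
#'
#' @param singular_values Non-negative spectrum, at least one positive.
#' @param max_rank Upper bound on the returned rank (default 100).
#' @param var_threshold Fraction of (captured) variance to retain
#'   (default 0.9).
#' @return Integer rank.
#' @export
choose_rank <- function(singular_values, max_rank = 100L, var_threshold = 0.9) {
  if (length(singular_values) == 0L || any(singular_values < 0))
    oc_stop("'singular_values' must be a non-negative spectrum")
  tot <- sum(singular_values^2)
  if (tot == 0) oc_stop("all-zero spectrum; cannot choose a rank")
  r <- which(cumsum(singular_values^2) >= var_threshold * tot)[1L]
  as.integer(min(r, max_rank, length(singular_values)))
}

#' Fit a reduction with the automatic rank policy
#'
#' Convenience wrapper used by the pipeline: fits a randomized SVD at the
#' capped rank (`min(max_rank, n - 1, m)`) and truncates the model to the
#' smallest rank capturing `var_threshold` of the captured spectrum's
#' variance (see [choose_rank()]).
#'
#' @param vals Numeric samples-by-features matrix (or [omics_matrix()]).
#' @param max_rank Rank cap (default 100).
#' @param var_threshold Captured-variance fraction to retain (default 0.9).
#' @param oversample,power_iters,seed Passed to [rsvd_fit()].
#' @return A truncated `rsvd_model`.
#' @export
reduce_layer <- function(vals, max_rank = 100L, var_threshold = 0.9,
                         oversample = 10L, power_iters = 2L, seed = 1L) {
  if (inherits(vals, "omics_matrix")) vals <- vals$values
  fit_rank <- min(max_rank, nrow(vals) - 1L, ncol(vals))
  model <- rsvd_fit(vals, rank = fit_rank, oversample = oversample,
                    power_iters = power_iters, seed = seed)
  r <- choose_rank(model$singular_values, max_rank = max_rank,
                   var_threshold = var_threshold)
  model$rotation <- model$rotation[, seq_len(r), drop = FALSE]
  model$singular_values <- model$singular_values[seq_len(r)]
  model$rank <- r
  model
}
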