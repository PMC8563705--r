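# Perturbation clustering of a single (reduced) omics layer.
#
# For each candidate number of clusters k the unperturbed data are
# partitioned once (the "original" partition) and the data are repeatedly
# perturbed with Gaussian noise and re-partitioned.  Each partition yields a
# binary pairwise connectivity matrix; the entrywise mean of the perturbed
# connectivities measures how often each pair co-clusters under noise.  The
# k whose original connectivity is closest to its perturbed mean
# connectivity is the most noise-stable partition and is returned.

#' Add Gaussian noise to a matrix
#'
#' @param X Numeric matrix.
#' @param noise_sd Standard deviation of the iid Gaussian noise (>= 0).
#' @param seed Integer seed.
#' @return Matrix of the same shape, `X + N(0, noise_sd^2)` entrywise.
#' @export
perturb <- function(X, noise_sd, seed = 1L) {
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    oc_stop("'noise_sd' must be a single non-negative number")
  if (noise_sd == 0) return(X)
  X + withr::with_seed(as.integer(seed),
                       matrix(stats::rnorm(length(X), sd = noise_sd),
                              nrow(X), ncol(X)))
}

#' Binary connectivity matrix of a partition
#'
#' Entry (i, j) is 1 iff samples i and j carry the same label.
#'
#' @param labels Cluster labels (any atomic type); names, if present, become
#'   the sample ids of the matrix.
#' @return Symmetric 0/1 matrix with unit diagonal.
#' @export
connectivity_from_labels <- function(labels) {
  if (length(labels) < 1L) oc_stop("need at least one label")
  ids <- names(labels)
  if (is.null(ids)) ids <- as.character(seq_along(labels))
  f <- as.integer(factor(labels))
  ind <- matrix(0, length(f), max(f))
  ind[cbind(seq_along(f), f)] <- 1
  C <- tcrossprod(ind)
  dimnames(C) <- list(ids, ids)
  C
}

#' Mean connectivity under repeated Gaussian perturbation
#'
#' Each of `n_perturb` replicates adds independent Gaussian noise to `X`,
#' partitions the perturbed data with seeded k-means, and records the binary
#' connectivity; the entrywise mean over replicates is returned.
#'
#' @param X Numeric matrix (samples x components), rownames = sample ids.
#' @param k Number of clusters (>= 2, <= n).
#' @param n_perturb Number of perturbation replicates (default 50).
#' @param noise_sd Noise standard deviation; default is the median of the
#'   feature-wise standard deviations of `X`.
#' @param seed Integer master seed; each replicate derives its own seed, so
#'   results are independent of evaluation order.
#' @param nstart k-means restarts per replicate (default 10).
#' @return Symmetric matrix in \[0, 1\] with unit diagonal.
#' @export
perturbed_connectivity <- function(X, k, n_perturb = 50L, noise_sd = NULL,
                                   seed = 1L, nstart = 10L) {
  if (inherits(X, "reduced_matrix")) X <- scores_with_ids(X)
  if (!is_count(k, min = 2L)) oc_stop("'k' must be an integer >= 2")
  if (k > nrow(X)) oc_stop("'k' exceeds the number of samples")
  if (!is_count(n_perturb)) oc_stop("'n_perturb' must be a positive integer")
  if (is.null(noise_sd)) noise_sd <- default_noise_sd(X)
  acc <- matrix(0, nrow(X), nrow(X))
  for (rep_i in seq_len(n_perturb)) {
    Xp <- perturb(X, noise_sd, seed = derive_seed(seed, rep_i, 1L))
    lab <- km_cluster(Xp, k, nstart = nstart,
                      seed = derive_seed(seed, rep_i, 2L))
    acc <- acc + connectivity_from_labels(lab)
  }
  C <- acc / n_perturb
  C <- (C + t(C)) / 2
  diag(C) <- 1
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  dimnames(C) <- list(ids, ids)
  C
}

# Default perturbation scale: median feature-wise standard deviation.
default_noise_sd <- function(X) {
  stats::median(apply(X, 2L, stats::sd))
}

#' Stability of a partition's connectivity under perturbation
#'
#' `1 - mean(|original - perturbed|)` over off-diagonal pairs: 1 means the
#' perturbed co-clustering frequencies reproduce the unperturbed partition
#' exactly, 0 means maximal disagreement.
#'
#' @param original,perturbed Connectivity matrices over the same samples in
#'   the same order.
#' @return A number in \[0, 1\].
#' @export
stability_score <- function(original, perturbed) {
  if (!identical(dim(original), dim(perturbed)))
    oc_stop("connectivity matrices must have identical shape")
  if (!is.null(rownames(original)) && !is.null(rownames(perturbed)) &&
      !identical(rownames(original), rownames(perturbed)))
    oc_stop("connectivity matrices must cover the same samples in the same order")
  n <- nrow(original)
  if (n < 2L) return(1)
  off <- abs(original - perturbed)
  1 - sum(off[upper.tri(off)]) * 2 / (n * (n - 1))
}

#' Perturbation clustering of one data type
#'
#' For every k in `k_min:k_max`, partitions the unperturbed data, computes
#' the mean perturbed connectivity, and scores the partition's stability;
#' returns the partition of the most stable k. Stability ties (within 1e-9)
#' are broken toward the largest k: coarse merges of stable clusters are
#' themselves stable (k = 1 trivially so), so the finest equally stable
#' partition is the informative one.
#'
#' @param X A [rsvd_transform()] `reduced_matrix` or a numeric matrix with
#'   sample-id rownames.
#' @param k_min,k_max Candidate cluster-number range (defaults 2 and 10).
#' @param n_perturb Perturbation replicates per k (default 50).
#' @param noise_sd Noise standard deviation; default median feature-wise sd.
#' @param seed Integer master seed.
#' @param nstart k-means restarts (default 10).
#' @return An object of class `partition_result`: `labels` (named), `k`,
#'   `stability`, `connectivity` (mean perturbed connectivity of the chosen
#'   k) and `per_k_stability`.
#' @export
cluster_single <- function(X, k_min = 2L, k_max = 10L, n_perturb = 50L,
                           noise_sd = NULL, seed = 1L, nstart = 10L) {
  if (inherits(X, "reduced_matrix")) X <- scores_with_ids(X)
  n <- nrow(X)
  if (n < 3L) oc_stop("need at least 3 samples to cluster")
  if (!is_count(k_min, 2L) || !is_count(k_max, 2L) ||
      k_min > k_max || k_max > n - 1L)
    oc_stop("need 2 <= k_min <= k_max <= n-1")
  if (nrow(unique(X)) == 1L)
    oc_stop("degenerate input: all rows identical (zero variance)")
  if (is.null(noise_sd)) noise_sd <- default_noise_sd(X)
  ks <- k_min:k_max
  stab <- setNames(numeric(length(ks)), ks)
  best <- NULL
  cur_max <- -Inf
  for (i in seq_along(ks)) {
    k <- ks[i]
    base <- km_cluster(X, k, nstart = nstart, seed = derive_seed(seed, 0L, k))
    names(base) <- rownames(X)
    orig <- connectivity_from_labels(base)
    pert <- perturbed_connectivity(X, k, n_perturb = n_perturb,
                                   noise_sd = noise_sd, seed = seed,
                                   nstart = nstart)
    stab[i] <- stability_score(orig, pert)
    # Stability saturates for coarse partitions (k = 1 would always score a
    # perfect 1): a stable merge of stable clusters is itself stable.  Among
    # cluster numbers whose stability ties with the maximum (within 1e-9),
    # keep the largest k — the finest partition the data support.
    if (stab[i] >= cur_max - 1e-9) {
      cur_max <- max(cur_max, stab[i])
      best <- list(labels = canonical_labels(base), k = as.integer(k),
                   stability = stab[i], connectivity = pert)
    }
  }
  structure(c(best, list(per_k_stability = stab)), class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("partition_result: k = %d, stability = %.4f (%d samples)\n",
              x$k, x$stability, length(x$labels)))
  invisible(x)
}

# Internal: pull scores out of a reduced_matrix, carrying sample ids.
scores_with_ids <- function(rm) {
  s <- rm$scores
  rownames(s) <- rm$sample_ids
  s
}
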