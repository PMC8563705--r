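# Multi-omics integration: average the per-type connectivity matrices into
# one similarity matrix, generate candidate partitions of that matrix with
# several similarity-based clusterers, and keep the candidate that agrees
# best (mean adjusted Rand index) with the per-type partitions.

#' Average per-type connectivity matrices
#'
#' @param conns List of connectivity matrices over the same samples in the
#'   same order (a single matrix is also accepted).
#' @return The entrywise unweighted mean: a similarity matrix with the same
#'   symmetry/diagonal/range invariants.
#' @export
merge_connectivities <- function(conns) {
  if (is.matrix(conns)) conns <- list(conns)
  if (length(conns) < 1L) oc_stop("need at least one connectivity matrix")
  ref <- rownames(conns[[1L]])
  for (C in conns) {
    validate_connectivity(C)
    if (!identical(rownames(C), ref))
      oc_stop("connectivity matrices must cover identical samples in identical order")
  }
  S <- Reduce(`+`, conns) / length(conns)
  diag(S) <- 1
  S
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pairwise agreement; 1 for identical partitions (up to
#' relabeling), approximately 0 for independent ones.
#'
#' @param labels_a,labels_b Label vectors of equal length.
#' @return ARI in \[-1, 1\].
#' @export
agreement <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    oc_stop("label vectors must have equal length")
  n <- length(labels_a)
  tab <- table(labels_a, labels_b)
  sum_ij <- sum(choose(tab, 2))
  sum_a  <- sum(choose(rowSums(tab), 2))
  sum_b  <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_index - expected)
}

#' Candidate partitions of a similarity matrix
#'
#' Generates an ensemble of partitions of `S`: average-linkage hierarchical
#' cuts at every k in `k_min:k_max`, partitioning-around-medoids of the
#' distance `1 - S` at every k, and one dynamic branch cut of the
#' hierarchical dendrogram (its k emerges from the cut).
#'
#' @param S Similarity matrix (symmetric, unit diagonal, entries in
#'   \[0, 1\]).
#' @param k_min,k_max Cluster-number range for the fixed-k algorithms.
#' @param min_size Minimum cluster size for the dynamic branch cut
#'   (default 5).
#' @return List of candidates; each has `algorithm` (`"hierarchical"`,
#'   `"medoid"` or `"dynamic-tree-cut"`), `labels` (named) and `k`.
#' @export
candidate_partitions <- function(S, k_min = 2L, k_max = 10L, min_size = 5L) {
  validate_connectivity(S, "similarity matrix")
  n <- nrow(S)
  if (!is_count(k_min, 1L) || !is_count(k_max, 1L) || k_min > k_max)
    oc_stop("need 1 <= k_min <= k_max")
  if (k_max >= n) oc_stop("'k_max' must be smaller than the number of samples")
  d <- stats::as.dist(1 - S)
  hc <- stats::hclust(d, method = "average")
  out <- list()
  for (k in k_min:k_max) {
    lab <- stats::cutree(hc, k = k)
    out[[length(out) + 1L]] <- list(algorithm = "hierarchical",
                                    labels = canonical_labels(lab),
                                    k = length(unique(lab)))
  }
  for (k in k_min:k_max) {
    lab <- cluster::pam(d, k = k, pamonce = 5, cluster.only = TRUE)
    names(lab) <- rownames(S)
    out[[length(out) + 1L]] <- list(algorithm = "medoid",
                                    labels = canonical_labels(lab),
                                    k = length(unique(lab)))
  }
  lab <- dynamic_tree_cut(hc, min_size = min_size)
  names(lab) <- rownames(S)
  out[[length(out) + 1L]] <- list(algorithm = "dynamic-tree-cut",
                                  labels = canonical_labels(lab),
                                  k = length(unique(lab)))
  out
}

#' Dynamic branch cut of a dendrogram
#'
#' Deterministic, shape-based partitioning of a hierarchical tree: starting
#' at the root, a branch is split into its two children when both children
#' contain at least `min_size` leaves and the join height of the branch
#' stands clearly above its children's join heights (a relative gap of at
#' least `min_gap` of the total dendrogram height). Branches that fail the
#' test become clusters, so the number of clusters emerges from the shape of
#' the tree rather than from a fixed cut height.
#'
#' @param hc An `hclust` object.
#' @param min_size Minimum leaves per cluster (default 5).
#' @param min_gap Minimum relative join-height gap to accept a split
#'   (default 0.05).
#' @return Integer cluster labels in leaf order (1..k).
#' @export
dynamic_tree_cut <- function(hc, min_size = 5L, min_gap = 0.05) {
  n <- length(hc$order)
  h_range <- max(hc$height)
  if (h_range <= 0) return(rep(1L, n))
  # leaves and join height per internal node
  node_leaves <- vector("list", nrow(hc$merge))
  node_height <- hc$height
  leaves_of <- function(idx) {
    if (idx < 0L) -idx else node_leaves[[idx]]
  }
  height_of <- function(idx) if (idx < 0L) 0 else node_height[idx]
  for (i in seq_len(nrow(hc$merge)))
    node_leaves[[i]] <- c(leaves_of(hc$merge[i, 1L]),
                          leaves_of(hc$merge[i, 2L]))
  labels <- integer(n)
  next_label <- 0L
  assign_cluster <- function(idx) {
    next_label <<- next_label + 1L
    labels[leaves_of(idx)] <<- next_label
  }
  recurse <- function(idx) {
    if (idx < 0L) { assign_cluster(idx); return(invisible()) }
    kids <- hc$merge[idx, ]
    sizes <- c(length(leaves_of(kids[1L])), length(leaves_of(kids[2L])))
    gap <- node_height[idx] - max(height_of(kids[1L]), height_of(kids[2L]))
    if (all(sizes >= min_size) && gap >= min_gap * h_range) {
      recurse(kids[1L]); recurse(kids[2L])
    } else {
      assign_cluster(idx)
    }
  }
  recurse(nrow(hc$merge))
  labels
}

#' Select the final partition from the candidate ensemble
#'
#' Picks the candidate whose mean adjusted Rand index against the per-type
#' partitions is highest; ties are broken toward fewer clusters, then by
#' algorithm order hierarchical < medoid < dynamic-tree-cut.
#'
#' @param candidates List of candidates from [candidate_partitions()].
#' @param per_type_partitions List of `partition_result`s (or bare label
#'   vectors) for the individual data types.
#' @return A list with `labels` (named, consecutive integers from 1), `k`,
#'   `algorithm` and `agreement` (the winning mean ARI).
#' @export
ensemble_select <- function(candidates, per_type_partitions) {
  if (length(candidates) < 1L) oc_stop("empty candidate list")
  if (length(per_type_partitions) < 1L) oc_stop("need at least one per-type partition")
  type_labels <- lapply(per_type_partitions, function(p)
    if (inherits(p, "partition_result")) p$labels else p)
  alg_order <- c(hierarchical = 1L, medoid = 2L, `dynamic-tree-cut` = 3L)
  score <- vapply(candidates, function(cand)
    mean(vapply(type_labels, agreement, numeric(1L), labels_b = cand$labels)),
    numeric(1L))
  ks   <- vapply(candidates, `[[`, numeric(1L), "k")
  algs <- alg_order[vapply(candidates, `[[`, character(1L), "algorithm")]
  ord <- order(-round(score, 12L), ks, algs)
  best <- candidates[[ord[1L]]]
  list(labels = canonical_labels(best$labels), k = as.integer(best$k),
       algorithm = best$algorithm, agreement = score[ord[1L]])
}
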