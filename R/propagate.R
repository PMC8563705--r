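# Big-cohort path: sample a subset that has data in every layer, subtype it
# directly, and propagate labels to the remaining samples with an exact
# k-nearest-neighbour classifier in the sampled set's component space, with
# k chosen by cross-validation and per-type class probabilities averaged.

#' Split samples into sampled and propagated sets
#'
#' The sampled set is drawn from the samples present in every layer: all of
#' them when there are at most `max_sampled`, otherwise a seeded uniform
#' random subset of size `max_sampled`. Every other sample is propagated.
#'
#' @param dataset A `multiomics_dataset` from [align_layers()].
#' @param max_sampled Maximum sampled-set size (default 2000).
#' @param seed Integer seed for the random subset.
#' @return An object of class `sample_split` with `sampled_ids`,
#'   `propagated_ids` (both sorted), `max_sampled` and `seed`.
#' @export
split_samples <- function(dataset, max_sampled = 2000L, seed = 1L) {
  if (!is_count(max_sampled, 2L)) oc_stop("'max_sampled' must be >= 2")
  common <- dataset$common_samples
  if (length(common) == 0L) oc_stop("no samples common to all layers")
  sampled <- if (length(common) <= max_sampled) common else
    sort(withr::with_seed(as.integer(seed),
                          sample(common, size = max_sampled)))
  structure(
    list(sampled_ids = sampled,
         propagated_ids = setdiff(dataset$all_samples, sampled),
         max_sampled = as.integer(max_sampled), seed = as.integer(seed)),
    class = "sample_split")
}

#' @export
print.sample_split <- function(x, ...) {
  cat(sprintf("sample_split: %d sampled, %d propagated (max_sampled = %d)\n",
              length(x$sampled_ids), length(x$propagated_ids), x$max_sampled))
  invisible(x)
}

# Ordered neighbour indices of each query among the reference rows
# (Euclidean distance, distance ties broken by reference order).  Queries
# are processed in blocks so the distance workspace stays bounded by
# chunk x n_ref regardless of the query-set size.
ordered_neighbours <- function(ref, query, k, chunk = 2048L) {
  ref_sq <- rowSums(ref^2)
  nq <- nrow(query)
  out <- matrix(0L, nq, k)
  for (start in seq(1L, nq, by = chunk)) {
    idx <- start:min(start + chunk - 1L, nq)
    q <- query[idx, , drop = FALSE]
    d2 <- outer(rowSums(q^2), ref_sq, `+`) - 2 * tcrossprod(q, ref)
    out[idx, ] <- t(apply(d2, 1L, function(row)
      order(row, seq_along(row))[seq_len(k)]))
  }
  out
}

#' k-nearest-neighbour class probabilities
#'
#' For each query sample, the probability of class c is the fraction of its
#' k nearest reference samples (Euclidean distance in the reduced space)
#' that carry label c. Distance ties are broken by reference order, so the
#' result is deterministic.
#'
#' @param ref_scores Reference coordinates: a `reduced_matrix` or numeric
#'   matrix with sample-id rownames.
#' @param ref_labels Labels of the reference samples.
#' @param query_scores Query coordinates in the same component space.
#' @param k Number of neighbours (`1 <= k <=` number of references).
#' @return An object of class `class_probabilities`: `sample_ids`, `classes`
#'   (sorted unique reference labels) and a `probabilities` matrix whose
#'   rows sum to 1.
#' @export
knn_probabilities <- function(ref_scores, ref_labels, query_scores, k) {
  ref <- if (inherits(ref_scores, "reduced_matrix")) scores_with_ids(ref_scores) else ref_scores
  qry <- if (inherits(query_scores, "reduced_matrix")) scores_with_ids(query_scores) else query_scores
  if (is.null(dim(qry))) qry <- matrix(qry, nrow = 1L)
  if (nrow(ref) < 1L) oc_stop("empty reference set")
  if (length(ref_labels) != nrow(ref))
    oc_stop("'ref_labels' must have one label per reference row")
  if (!is_count(k) || k > nrow(ref))
    oc_stop("'k' must be an integer in [1, number of reference samples]")
  classes <- sort(unique(ref_labels))
  nn <- ordered_neighbours(ref, qry, k)
  counts <- vapply(classes, function(cl)
    rowSums(matrix(ref_labels[nn] == cl, nrow(qry), k)), numeric(nrow(qry)))
  probs <- matrix(counts, nrow(qry), length(classes)) / k
  ids <- rownames(qry)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(qry)))
  dimnames(probs) <- list(ids, as.character(classes))
  structure(list(sample_ids = ids, classes = classes, probabilities = probs),
            class = "class_probabilities")
}

#' Choose the number of neighbours by cross-validation
#'
#' Samples are assigned to folds uniformly at random (seeded, no
#' stratification); for each candidate k the mean misclassification rate of
#' majority-vote k-NN over held-out folds is computed, and the k with the
#' lowest error is returned (ties toward the smallest k). The grid is
#' truncated to at most `n_train - 1` neighbours.
#'
#' @param scores Reference coordinates (`reduced_matrix` or matrix).
#' @param labels Reference labels; every class needs at least 2 members.
#' @param k_grid Candidate neighbour counts (default `5:50`).
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return The selected k (integer).
#' @export
select_k <- function(scores, labels, k_grid = 5:50, folds = 5L, seed = 1L) {
  X <- if (inherits(scores, "reduced_matrix")) scores_with_ids(scores) else scores
  n <- nrow(X)
  if (length(labels) != n) oc_stop("'labels' must have one entry per row")
  if (!is_count(folds, 2L)) oc_stop("'folds' must be >= 2")
  class_sizes <- table(labels)
  if (any(class_sizes < 2L))
    oc_stop("every class needs at least 2 members (smallest has ",
            min(class_sizes), ")")
  fold_of <- withr::with_seed(as.integer(seed),
                              sample(rep(seq_len(folds), length.out = n)))
  classes <- sort(unique(labels))
  max_train <- min(vapply(seq_len(folds), function(f) sum(fold_of != f),
                          numeric(1L)))
  ks <- sort(unique(pmin(as.integer(k_grid), max_train - 1L)))
  ks <- ks[ks >= 1L]
  err <- matrix(NA_real_, folds, length(ks))
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    if (!any(!tr)) next
    nn <- ordered_neighbours(X[tr, , drop = FALSE], X[!tr, , drop = FALSE],
                             max(ks))
    nn_lab <- matrix(labels[tr][nn], nrow(nn), ncol(nn))
    truth <- labels[!tr]
    for (j in seq_along(ks)) {
      pred <- apply(nn_lab[, seq_len(ks[j]), drop = FALSE], 1L, function(v) {
        cnt <- vapply(classes, function(cl) sum(v == cl), numeric(1L))
        classes[which.max(cnt)]     # ties -> lowest class index
      })
      err[f, j] <- mean(pred != truth)
    }
  }
  mean_err <- colMeans(err, na.rm = TRUE)
  as.integer(ks[which(mean_err <= min(mean_err) + 1e-12)[1L]])
}

#' Combine per-type class probabilities into final labels
#'
#' For each query the probabilities are averaged over the data types in
#' which the query appears (unmatched samples use only the layers that
#' measured them), and the label with the highest average probability is
#' assigned (ties toward the lowest class index).
#'
#' @param per_type_probs List of `class_probabilities`, one per data type.
#' @return Named integer-label vector over the union of query ids.
#' @export
propagate_multiomics <- function(per_type_probs) {
  if (inherits(per_type_probs, "class_probabilities"))
    per_type_probs <- list(per_type_probs)
  if (length(per_type_probs) < 1L) oc_stop("need at least one probability table")
  classes <- sort(unique(unlist(lapply(per_type_probs, `[[`, "classes"))))
  ids <- sort(unique(unlist(lapply(per_type_probs, `[[`, "sample_ids"))))
  acc <- matrix(0, length(ids), length(classes),
                dimnames = list(ids, as.character(classes)))
  cnt <- setNames(integer(length(ids)), ids)
  for (tab in per_type_probs) {
    acc[tab$sample_ids, as.character(tab$classes)] <-
      acc[tab$sample_ids, as.character(tab$classes), drop = FALSE] +
      tab$probabilities
    cnt[tab$sample_ids] <- cnt[tab$sample_ids] + 1L
  }
  if (any(cnt == 0L))
    oc_stop("query appears in no probability table: ",
            names(cnt)[cnt == 0L][1L])
  avg <- acc / cnt
  setNames(vapply(seq_along(ids), function(i)
    as.integer(classes[which.max(avg[i, ])]), integer(1L)), ids)
}
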