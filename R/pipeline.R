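# End-to-end orchestration.
#
# Moderate cohorts (every sample in every layer, n <= max_sampled) are
# subtyped directly: reduce each layer, perturbation-cluster it, average the
# connectivity matrices and pick the ensemble partition.  Larger or
# partially overlapping cohorts first subtype a sampled subset of the
# samples common to all layers, then propagate labels to the remainder with
# per-layer k-NN classifiers in the sampled set's component space.  All
# pairwise (n x n) matrices are only ever formed for the sampled set.

#' Parameters of the subtyping pipeline
#'
#' @param max_sampled Sampled-set ceiling; cohorts above it are subtyped via
#'   sampling + propagation (default 2000).
#' @param k_min,k_max Cluster-number search range (defaults 2, 10).
#' @param n_perturb Perturbation replicates per k (default 50).
#' @param noise_sd Perturbation noise sd, or `NULL` for the per-layer
#'   median feature-wise sd of the reduced matrix (default).
#' @param max_rank,var_threshold Rank policy for the randomized SVD:
#'   smallest rank capturing `var_threshold` of the captured spectrum's
#'   variance, capped at `max_rank` (defaults 100, 0.9).
#' @param oversample,power_iters Randomized-SVD sketch parameters
#'   (defaults 10, 2).
#' @param knn_grid Candidate neighbour counts for propagation
#'   (default `5:50`).
#' @param folds Cross-validation folds for the neighbour count (default 5).
#' @param nstart k-means restarts (default 10).
#' @param seed Master seed; every stochastic step derives its own seed from
#'   it (default 1).
#' @return A validated list of class `subtyping_params`.
#' @export
subtyping_params <- function(max_sampled = 2000L, k_min = 2L, k_max = 10L,
                             n_perturb = 50L, noise_sd = NULL,
                             max_rank = 100L, var_threshold = 0.9,
                             oversample = 10L, power_iters = 2L,
                             knn_grid = 5:50, folds = 5L, nstart = 10L,
                             seed = 1L) {
  p <- list(max_sampled = as.integer(max_sampled), k_min = as.integer(k_min),
            k_max = as.integer(k_max), n_perturb = as.integer(n_perturb),
            noise_sd = noise_sd, max_rank = as.integer(max_rank),
            var_threshold = var_threshold, oversample = as.integer(oversample),
            power_iters = as.integer(power_iters),
            knn_grid = as.integer(knn_grid), folds = as.integer(folds),
            nstart = as.integer(nstart), seed = as.integer(seed))
  if (!is_count(p$k_min, 2L) || !is_count(p$k_max, 2L) || p$k_min > p$k_max)
    oc_stop("need 2 <= k_min <= k_max")
  if (!is_count(p$max_sampled, 2L) || p$max_sampled < p$k_max + 1L)
    oc_stop("'max_sampled' must be at least k_max + 1")
  if (!is_count(p$n_perturb) || !is_count(p$max_rank) ||
      !is_count(p$folds, 2L) || !is_count(p$nstart))
    oc_stop("'n_perturb', 'max_rank', 'folds' and 'nstart' must be positive integers")
  if (!is.null(p$noise_sd) && (!is.numeric(p$noise_sd) || p$noise_sd < 0))
    oc_stop("'noise_sd' must be NULL or a non-negative number")
  if (!is.numeric(p$var_threshold) || p$var_threshold <= 0 || p$var_threshold > 1)
    oc_stop("'var_threshold' must be in (0, 1]")
  structure(p, class = "subtyping_params")
}

#' Subtype a multi-omics dataset
#'
#' Runs the full workflow: per-layer randomized-SVD reduction, perturbation
#' clustering with automatic cluster-number selection, connectivity
#' averaging and ensemble selection — directly on all samples when the
#' cohort is moderate and fully matched, or on a sampled subset with k-NN
#' label propagation otherwise.
#'
#' @param dataset A `multiomics_dataset` from [align_layers()], or a
#'   `simulated_dataset`.
#' @param params A [subtyping_params()] record.
#' @return An object of class `subtyping_result`: `final_labels` (named,
#'   consecutive integers from 1, over all samples), `per_type_partitions`,
#'   `merged_similarity` (over the sampled set), `ensemble` (winning
#'   algorithm, k, agreement), `sampled_ids`, `propagated_ids`, `knn_k`
#'   (per-layer chosen neighbour count, propagation path only) and
#'   `parameters`.
#' @export
subtype <- function(dataset, params = subtyping_params()) {
  if (inherits(dataset, "simulated_dataset")) dataset <- dataset$dataset
  if (!inherits(dataset, "multiomics_dataset"))
    oc_stop("'dataset' must be a multiomics_dataset")
  if (!inherits(params, "subtyping_params"))
    oc_stop("'params' must come from subtyping_params()")
  seed <- params$seed
  all_common <- setequal(dataset$all_samples, dataset$common_samples)
  if (all_common && length(dataset$all_samples) <= params$max_sampled) {
    split <- structure(list(sampled_ids = dataset$common_samples,
                            propagated_ids = character(0L),
                            max_sampled = params$max_sampled, seed = seed),
                       class = "sample_split")
  } else {
    split <- split_samples(dataset, max_sampled = params$max_sampled,
                           seed = derive_seed(seed, 101L))
  }
  sampled <- split$sampled_ids
  if (length(sampled) < 3L) oc_stop("sampled set too small to cluster")

  models <- list(); partitions <- list(); sampled_scores <- list()
  for (li in seq_along(dataset$layers)) {
    lay <- dataset$layers[[li]]
    Xs <- layer_values(dataset, li, sampled)
    model <- reduce_layer(Xs, max_rank = params$max_rank,
                          var_threshold = params$var_threshold,
                          oversample = params$oversample,
                          power_iters = params$power_iters,
                          seed = derive_seed(seed, li, 1L))
    red <- rsvd_transform(model, Xs)
    part <- cluster_single(red, k_min = params$k_min, k_max = params$k_max,
                           n_perturb = params$n_perturb,
                           noise_sd = params$noise_sd,
                           seed = derive_seed(seed, li, 2L),
                           nstart = params$nstart)
    models[[lay$name]] <- model
    sampled_scores[[lay$name]] <- red
    partitions[[lay$name]] <- part
  }

  S <- merge_connectivities(lapply(partitions, `[[`, "connectivity"))
  cands <- candidate_partitions(S, k_min = params$k_min, k_max = params$k_max)
  chosen <- ensemble_select(cands, partitions)
  labels_sampled <- chosen$labels

  knn_k <- NULL
  labels_prop <- NULL
  if (length(split$propagated_ids) > 0L) {
    knn_k <- integer(0L)
    prob_tables <- list()
    for (li in seq_along(dataset$layers)) {
      lay <- dataset$layers[[li]]
      q_ids <- intersect(lay$sample_ids, split$propagated_ids)
      if (length(q_ids) == 0L) next
      grid <- params$knn_grid[params$knn_grid <= length(sampled) - 1L]
      if (length(grid) == 0L) grid <- min(5L, length(sampled) - 1L)
      kk <- select_k(sampled_scores[[lay$name]], labels_sampled,
                     k_grid = grid, folds = params$folds,
                     seed = derive_seed(seed, li, 3L))
      knn_k[lay$name] <- kk
      # project and classify propagated samples in bounded chunks so the
      # working set never scales with the propagated-set size
      chunk <- 5000L
      probs <- NULL
      for (start in seq(1L, length(q_ids), by = chunk)) {
        idx <- q_ids[start:min(start + chunk - 1L, length(q_ids))]
        red_q <- rsvd_transform(models[[lay$name]],
                                layer_values(dataset, li, idx))
        pt <- knn_probabilities(sampled_scores[[lay$name]], labels_sampled,
                                red_q, k = kk)
        probs <- rbind(probs, pt$probabilities)
      }
      prob_tables[[lay$name]] <- structure(
        list(sample_ids = rownames(probs),
             classes = sort(unique(labels_sampled)),
             probabilities = probs),
        class = "class_probabilities")
    }
    labels_prop <- propagate_multiomics(prob_tables)
  }

  final <- setNames(integer(length(dataset$all_samples)), dataset$all_samples)
  final[sampled] <- labels_sampled[sampled]
  if (!is.null(labels_prop)) final[names(labels_prop)] <- labels_prop
  final <- canonical_labels(final)

  structure(
    list(final_labels = final,
         per_type_partitions = partitions,
         merged_similarity = S,
         ensemble = chosen[c("algorithm", "k", "agreement")],
         sampled_ids = split$sampled_ids,
         propagated_ids = split$propagated_ids,
         knn_k = knn_k,
         parameters = unclass(params)),
    class = "subtyping_result")
}

#' @export
print.subtyping_result <- function(x, ...) {
  cat(sprintf(paste0("subtyping_result: %d samples -> %d subtypes ",
                     "(%s ensemble, agreement %.3f)\n"),
              length(x$final_labels), length(unique(x$final_labels)),
              x$ensemble$algorithm, x$ensemble$agreement))
  cat(sprintf("  sampled: %d, propagated: %d\n",
              length(x$sampled_ids), length(x$propagated_ids)))
  for (nm in names(x$per_type_partitions)) {
    p <- x$per_type_partitions[[nm]]
    cat(sprintf("  layer %s: k = %d, stability = %.4f\n", nm, p$k, p$stability))
  }
  invisible(x)
}
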