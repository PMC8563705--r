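block_similarity <- function(sizes, ids = NULL) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  S <- outer(lab, lab, function(a, b) as.numeric(a == b))
  if (is.null(ids)) ids <- sprintf("s%03d", 1:n)
  dimnames(S) <- list(ids, ids)
  S
}

test_that("merging averages connectivities entrywise", {
  ids <- c("a", "b")
  C1 <- matrix(1, 2, 2, dimnames = list(ids, ids))
  C2 <- diag(2); dimnames(C2) <- list(ids, ids)
  M <- merge_connectivities(list(C1, C2))
  expect_equal(unname(M), rbind(c(1, 0.5), c(0.5, 1)))
  expect_identical(merge_connectivities(list(C1)), C1)

  conns <- lapply(1:3, function(s) random_connectivity(6, seed = s))
  M3 <- merge_connectivities(conns)
  for (i in 1:6) for (j in 1:6) if (i != j)
    expect_equal(M3[i, j], (conns[[1]][i, j] + conns[[2]][i, j] +
                            conns[[3]][i, j]) / 3, tolerance = 1e-12)
  expect_true(all(M3 == t(M3)) && all(diag(M3) == 1) && all(M3 >= 0 & M3 <= 1))

  bad <- random_connectivity(6, seed = 9)
  rownames(bad) <- colnames(bad) <- letters[1:6]
  expect_error(merge_connectivities(list(conns[[1]], bad)), "identical samples")
})

test_that("agreement is the adjusted Rand index", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(agreement(a, a), 1)
  expect_equal(agreement(a, c(2, 2, 3, 3, 1, 1)), 1)  # relabeling invariance
  expect_error(agreement(a, a[-1]), "equal length")
  # chance-corrected null: independent labelings score near zero
  ab <- withr::with_seed(13, list(sample(1:3, 1000, TRUE),
                                  sample(1:3, 1000, TRUE)))
  expect_lt(abs(agreement(ab[[1]], ab[[2]])), 0.05)
})

test_that("agreement matches an independent ARI implementation", {
  skip_if_not_installed("mclust")
  for (s in 1:10) {
    ab <- withr::with_seed(s, list(sample(1:4, 60, TRUE),
                                   sample(1:3, 60, TRUE)))
    expect_equal(agreement(ab[[1]], ab[[2]]),
                 mclust::adjustedRandIndex(ab[[1]], ab[[2]]),
                 tolerance = 1e-12)
  }
})

test_that("all candidate algorithms recover perfect-similarity blocks", {
  S <- block_similarity(c(10, 10))
  cands <- candidate_partitions(S, k_min = 2, k_max = 4)
  truth <- rep(1:2, c(10, 10))
  for (cand in cands) {
    if (cand$k == 2)
      expect_equal(agreement(cand$labels, truth), 1,
                   info = cand$algorithm)
    expect_identical(length(unique(cand$labels)), as.integer(cand$k))
    expect_identical(names(cand$labels), rownames(S))
  }
  algs <- vapply(cands, `[[`, character(1), "algorithm")
  expect_setequal(unique(algs), c("hierarchical", "medoid", "dynamic-tree-cut"))
  # the dynamic cut finds k = 2 on its own
  expect_identical(cands[[which(algs == "dynamic-tree-cut")]]$k, 2L)
})

test_that("candidates have no empty clusters even on structureless input", {
  S <- diag(12); dimnames(S) <- list(paste0("s", 1:12), paste0("s", 1:12))
  cands <- candidate_partitions(S, k_min = 2, k_max = 3)
  for (cand in cands) {
    sizes <- table(cand$labels)
    expect_true(all(sizes >= 1))
    expect_identical(length(sizes), as.integer(cand$k))
  }
  expect_error(candidate_partitions(S, k_min = 2, k_max = 12), "k_max")
})

test_that("declared k matches the label vector on random similarity", {
  S <- random_connectivity(20, seed = 21)
  for (cand in candidate_partitions(S, k_min = 2, k_max = 5))
    expect_identical(length(unique(cand$labels)), as.integer(cand$k))
})

test_that("ensemble selection maximizes mean agreement with per-type labels", {
  truth <- rep(1:3, each = 8)
  cands <- list(
    list(algorithm = "hierarchical", labels = truth, k = 3L),
    list(algorithm = "medoid",
         labels = withr::with_seed(1, sample(1:3, 24, TRUE)), k = 3L))
  sel <- ensemble_select(cands, list(truth, truth))
  expect_identical(sel$algorithm, "hierarchical")
  expect_equal(sel$agreement, 1)
  # invariant to relabeling of the per-type partitions
  perm <- c(3L, 1L, 2L)[truth]
  sel2 <- ensemble_select(cands, list(perm, truth))
  expect_identical(sel2$algorithm, "hierarchical")
  expect_equal(sel2$agreement, 1)
  expect_error(ensemble_select(list(), list(truth)), "empty")
})

test_that("ensemble ties break toward fewer clusters then algorithm order", {
  truth <- rep(1:2, each = 6)
  cands <- list(
    list(algorithm = "medoid", labels = truth, k = 2L),
    list(algorithm = "hierarchical", labels = truth, k = 2L),
    list(algorithm = "hierarchical",
         labels = c(rep(1L, 6), rep(2L, 3), rep(3L, 3)), k = 3L))
  sel <- ensemble_select(cands, list(truth))
  expect_identical(sel$k, 2L)
  expect_identical(sel$algorithm, "hierarchical")
})

test_that("shared block structure across layers survives integration", {
  conns <- replicate(3, block_similarity(c(7, 6, 7)), simplify = FALSE)
  S <- merge_connectivities(conns)
  truth <- rep(1:3, c(7, 6, 7))
  parts <- lapply(1:3, function(i) truth)
  sel <- ensemble_select(candidate_partitions(S, 2, 5), parts)
  expect_equal(agreement(sel$labels, truth), 1)
  expect_identical(sel$k, 3L)
})
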