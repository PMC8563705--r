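test_that("perturbation adds zero-mean Gaussian noise of the stated scale", {
  X <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_identical(perturb(X, 0, seed = 1), X)
  expect_error(perturb(X, -1), "non-negative")
  diffs <- vapply(1:10000, function(i) perturb(X, 0.5, seed = i) - X,
                  matrix(0, 2, 2))
  expect_lt(max(abs(apply(diffs, c(1, 2), mean))), 0.05)
  expect_lt(abs(sd(diffs) - 0.5) / 0.5, 0.02)
})

test_that("connectivity_from_labels marks co-membership", {
  expect_equal(unname(connectivity_from_labels(c(1, 1, 2))),
               rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)))
  expect_equal(unname(connectivity_from_labels(rep("a", 4))), matrix(1, 4, 4))
  expect_equal(unname(connectivity_from_labels(1:5)), diag(5))
})

test_that("perturbed connectivity separates well-separated clouds", {
  blobs <- make_blobs(15, rbind(c(0, 0), c(100, 100)), sd = 0.5, seed = 3)
  C <- perturbed_connectivity(blobs$X, k = 2, n_perturb = 20, noise_sd = 1,
                              seed = 3)
  same <- outer(blobs$labels, blobs$labels, `==`)
  expect_equal(unname(C[same]), rep(1, sum(same)))
  expect_equal(unname(C[!same]), rep(0, sum(!same)))
  validate_ok <- function(M) {
    expect_true(all(M == t(M)))
    expect_true(all(diag(M) == 1))
    expect_true(all(M >= 0 & M <= 1))
  }
  validate_ok(C)
  # single perturbation gives a binary matrix
  C1 <- perturbed_connectivity(blobs$X, k = 2, n_perturb = 1, noise_sd = 1,
                               seed = 4)
  expect_true(all(C1 %in% c(0, 1)))
  validate_ok(C1)
})

test_that("identical duplicated samples always co-cluster", {
  blobs <- make_blobs(10, rbind(c(0, 0), c(50, 50)), sd = 0.5, seed = 5)
  X <- rbind(blobs$X, dup = blobs$X[1, ])
  C <- perturbed_connectivity(X, k = 2, n_perturb = 10, noise_sd = 0,
                              seed = 6)
  expect_equal(unname(C[1, nrow(X)]), 1)
})

test_that("stability_score is the mean off-diagonal agreement", {
  A <- connectivity_from_labels(c(1, 1, 2, 2))
  expect_equal(stability_score(A, A), 1)
  half <- matrix(0.5, 4, 4); diag(half) <- 1
  expect_equal(stability_score(A, half), 0.5)
  B <- random_connectivity(8, seed = 7)
  D <- random_connectivity(8, seed = 8)
  # naive double-loop oracle
  acc <- 0; cnt <- 0
  for (i in 1:8) for (j in 1:8) if (i != j) {
    acc <- acc + abs(B[i, j] - D[i, j]); cnt <- cnt + 1
  }
  expect_equal(stability_score(B, D), 1 - acc / cnt, tolerance = 1e-12)
  expect_equal(stability_score(B, D), stability_score(D, B))
  expect_error(stability_score(B, D[1:4, 1:4]), "shape")
})

test_that("cluster_single recovers blob structure and the cluster count", {
  b3 <- make_blobs(30, rbind(c(0, 0), c(10, 0), c(0, 10)), sd = 1, seed = 10)
  p3 <- cluster_single(b3$X, k_max = 6, noise_sd = 1, seed = 5)
  expect_identical(p3$k, 3L)
  expect_equal(agreement(p3$labels, b3$labels), 1)
  expect_identical(sort(names(p3$per_k_stability)), sort(as.character(2:6)))

  b2 <- make_blobs(60, rbind(c(0, 0), c(10, 10)), sd = 1, seed = 9)
  p2 <- cluster_single(b2$X, noise_sd = 1, seed = 5)
  expect_identical(p2$k, 2L)
  expect_gte(p2$stability, 0.99)
})

test_that("cluster_single is deterministic and rejects degenerate input", {
  b <- make_blobs(20, rbind(c(0, 0), c(8, 8)), sd = 1, seed = 11)
  p1 <- cluster_single(b$X, k_max = 4, n_perturb = 10, noise_sd = 1, seed = 7)
  p2 <- cluster_single(b$X, k_max = 4, n_perturb = 10, noise_sd = 1, seed = 7)
  expect_identical(p1$labels, p2$labels)
  expect_identical(p1$per_k_stability, p2$per_k_stability)

  flat <- matrix(1, 10, 3, dimnames = list(paste0("s", 1:10), NULL))
  expect_error(cluster_single(flat, k_max = 4, seed = 1), "zero variance")
  expect_error(cluster_single(b$X[1:2, ], seed = 1), "at least 3")
})

test_that("stability ties resolve to the finest stable partition", {
  # Three classes, one unambiguously better two-way merge: both k = 2 and
  # k = 3 are perfectly stable under vanishing noise, so the chosen k must
  # be 3, not the trivially-stable coarsening.
  b <- make_blobs(20, rbind(c(0, 0), c(0, 20), c(100, 10)), sd = 0.1,
                  seed = 12)
  p <- cluster_single(b$X, k_max = 4, n_perturb = 10, noise_sd = 0.05,
                      seed = 3)
  expect_identical(p$k, 3L)
  expect_equal(agreement(p$labels, b$labels), 1)
  expect_gte(p$per_k_stability[["2"]], 1 - 1e-9)
  expect_gte(p$per_k_stability[["3"]], 1 - 1e-9)
})
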