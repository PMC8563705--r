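sim_dataset <- function(ids_per_layer, m = 4, seed = 1) {
  layers <- lapply(seq_along(ids_per_layer), function(i) {
    ids <- ids_per_layer[[i]]
    withr::with_seed(seed + i, {
      v <- matrix(rnorm(length(ids) * m), length(ids), m,
                  dimnames = list(ids, paste0("g", 1:m)))
      omics_matrix(v, name = paste0("L", i))
    })
  })
  align_layers(layers)
}

test_that("split_samples keeps everything below the threshold", {
  ids <- sprintf("P%03d", 1:100)
  d <- sim_dataset(list(ids, ids))
  sp <- split_samples(d, max_sampled = 2000, seed = 1)
  expect_identical(sp$sampled_ids, sort(ids))
  expect_length(sp$propagated_ids, 0)
})

test_that("split_samples draws a deterministic subset above the threshold", {
  ids <- sprintf("P%04d", 1:500)
  d <- sim_dataset(list(ids))
  sp1 <- split_samples(d, max_sampled = 200, seed = 5)
  sp2 <- split_samples(d, max_sampled = 200, seed = 5)
  expect_identical(sp1$sampled_ids, sp2$sampled_ids)
  expect_length(sp1$sampled_ids, 200)
  expect_length(intersect(sp1$sampled_ids, sp1$propagated_ids), 0)
  expect_setequal(c(sp1$sampled_ids, sp1$propagated_ids), ids)
  sp3 <- split_samples(d, max_sampled = 200, seed = 6)
  expect_false(identical(sp1$sampled_ids, sp3$sampled_ids))
})

test_that("the sampled set is drawn only from fully matched samples", {
  d <- sim_dataset(list(c("A", "B", "C"), c("B", "C")))
  sp <- split_samples(d, max_sampled = 2000, seed = 1)
  expect_identical(sp$sampled_ids, c("B", "C"))
  expect_identical(sp$propagated_ids, "A")
})

test_that("select_k returns the smallest k when classes are separable", {
  blobs <- make_blobs(30, rbind(c(0, 0), c(50, 50)), sd = 1, seed = 2)
  k <- select_k(blobs$X, blobs$labels, k_grid = 5:20, folds = 5, seed = 3)
  expect_identical(k, 5L)
  expect_identical(select_k(blobs$X, blobs$labels, k_grid = 5:20, folds = 5,
                            seed = 3), k)
  expect_error(select_k(blobs$X, c(1, rep(2, 59)), seed = 1), "at least 2")
})

test_that("select_k matches a brute-force CV error table", {
  # a lone noise point inside the wrong class makes 1-NN overfit
  blobs <- make_blobs(20, rbind(c(0, 0), c(6, 0)), sd = 1, seed = 4)
  X <- rbind(blobs$X, noise = c(5.9, 0))
  labels <- c(blobs$labels, noise = 1L)
  grid <- c(1, 3, 5, 7, 9)
  k_sel <- select_k(X, labels, k_grid = grid, folds = 5, seed = 11)
  # oracle: same fold assignment, naive per-point majority vote
  fold_of <- withr::with_seed(11L, sample(rep(1:5, length.out = nrow(X))))
  classes <- sort(unique(labels))
  errs <- sapply(grid, function(k) {
    mean(sapply(1:5, function(f) {
      tr <- fold_of != f
      pred <- apply(X[!tr, , drop = FALSE], 1, function(q) {
        d <- apply(X[tr, , drop = FALSE], 1, function(r) sqrt(sum((q - r)^2)))
        nb <- labels[tr][order(d, seq_along(d))[1:k]]
        cnt <- vapply(classes, function(cl) sum(nb == cl), numeric(1))
        classes[which.max(cnt)]
      })
      mean(pred != labels[!tr])
    }))
  })
  expect_identical(k_sel, as.integer(grid[which.min(errs)]))
})

test_that("knn_probabilities counts neighbour votes", {
  ref <- matrix(c(0, 0, 0.1, 0, 5, 5), 3, 2, byrow = TRUE,
                dimnames = list(c("r1", "r2", "r3"), NULL))
  q <- matrix(c(0, 0.01), 1, 2, dimnames = list("q", NULL))
  p3 <- knn_probabilities(ref, c("a", "a", "b"), q, k = 3)
  expect_equal(unname(p3$probabilities), matrix(c(2 / 3, 1 / 3), 1))
  expect_identical(p3$classes, c("a", "b"))
  p1 <- knn_probabilities(ref, c("a", "a", "b"), q, k = 1)
  expect_equal(unname(p1$probabilities), matrix(c(1, 0), 1))
  expect_error(knn_probabilities(ref[0, ], character(0), q, 1), "empty")
  expect_error(knn_probabilities(ref, c("a", "a", "b"), q, 4), "k")
})

test_that("knn_probabilities matches the brute-force oracle", {
  withr::with_seed(15, {
    ref <- matrix(rnorm(200 * 3), 200, 3)
    labels <- sample(1:2, 200, TRUE)
    q <- matrix(rnorm(50 * 3), 50, 3)
  })
  got <- knn_probabilities(ref, labels, q, k = 7)
  expect_equal(unname(got$probabilities), unname(knn_oracle(ref, labels, q, 7)),
               tolerance = 1e-12)
  expect_equal(unname(rowSums(got$probabilities)), rep(1, 50))
})

test_that("per-type probabilities average into final labels", {
  one <- structure(list(sample_ids = "q", classes = c(1L, 2L),
                        probabilities = matrix(c(0.2, 0.8), 1,
                                               dimnames = list("q", 1:2))),
                   class = "class_probabilities")
  expect_identical(propagate_multiomics(list(one)), c(q = 2L))
  two <- one; two$probabilities <- matrix(c(1, 0), 1, dimnames = list("q", 1:2))
  # average of (1,0) and (0.2,0.8) is (0.6,0.4) -> class 1
  expect_identical(propagate_multiomics(list(two, one)), c(q = 1L))
  # a sample measured in one layer only uses that layer
  other <- structure(list(sample_ids = "w", classes = c(1L, 2L),
                          probabilities = matrix(c(0, 1), 1,
                                                 dimnames = list("w", 1:2))),
                     class = "class_probabilities")
  expect_identical(propagate_multiomics(list(two, other)),
                   c(q = 1L, w = 2L))
})

test_that("probability-tie votes go to the lowest class index", {
  ref <- matrix(c(0, 0, 1, 1, 2, 2, 3, 3), 4, 2, byrow = TRUE,
                dimnames = list(paste0("r", 1:4), NULL))
  p <- knn_probabilities(ref, c(2L, 2L, 1L, 1L), matrix(c(1.5, 1.5), 1), k = 4)
  expect_identical(unname(propagate_multiomics(list(p))), 1L)
})
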