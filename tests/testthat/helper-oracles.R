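# Fixture builders and independent oracles used across the suite.

# Gaussian blobs with known labels; rows get sample ids.
make_blobs <- function(n_per, centers, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
      matrix(stats::rnorm(n_per * ncol(centers), sd = sd), n_per,
             ncol(centers)) + rep(centers[i, ], each = n_per)))
    rownames(X) <- sprintf("s%03d", seq_len(nrow(X)))
    list(X = X, labels = stats::setNames(rep(seq_len(nrow(centers)),
                                             each = n_per), rownames(X)))
  })
}

# Random valid connectivity matrix (symmetric, [0,1], unit diagonal).
random_connectivity <- function(n, seed = 1) {
  withr::with_seed(seed, {
    A <- matrix(stats::runif(n * n), n, n)
    C <- (A + t(A)) / 2
    diag(C) <- 1
    dimnames(C) <- list(sprintf("s%03d", 1:n), sprintf("s%03d", 1:n))
    C
  })
}

# Random matrix with a decaying singular spectrum (the structure of
# real omics matrices); exact spectrum is returned for comparison.
random_decaying_matrix <- function(n, m, seed = 1,
                                   decay = function(i) 50 / i^2) {
  withr::with_seed(seed, {
    k <- min(n, m)
    U <- qr.Q(qr(matrix(stats::rnorm(n * k), n, k)))
    V <- qr.Q(qr(matrix(stats::rnorm(m * k), m, k)))
    s <- decay(seq_len(k))
    X <- U %*% (s * t(V))
    dimnames(X) <- list(sprintf("s%03d", 1:n), sprintf("g%03d", 1:m))
    X
  })
}

# Brute-force kNN class probabilities: per-query distance loop, full sort,
# reference-order tie-break.
knn_oracle <- function(ref, labels, query, k) {
  classes <- sort(unique(labels))
  t(apply(query, 1L, function(q) {
    d <- apply(ref, 1L, function(r) sqrt(sum((q - r)^2)))
    nb <- labels[order(d, seq_along(d))[1:k]]
    vapply(classes, function(cl) sum(nb == cl) / k, numeric(1L))
  }))
}

# Direct contingency-table NMI (arithmetic-mean normalization).
nmi_oracle <- function(a, b) {
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  mi <- 0
  for (x in ua) for (y in ub) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0) mi <- mi + pxy * log(pxy / (sum(a == x) / n * sum(b == y) / n))
  }
  ent <- function(l) {
    p <- table(l) / n
    -sum(p * log(p))
  }
  mi / ((ent(a) + ent(b)) / 2)
}

# Exact one-tailed rank-sum p-value by enumeration of all assignments of
# the pooled values to the first sample.
wilcoxon_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(x)])
  combs <- utils::combn(length(pooled), length(x))
  w_all <- apply(combs, 2L, function(idx) sum(r[idx]))
  mean(w_all <= w_obs)
}
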