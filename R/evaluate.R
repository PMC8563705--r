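# Evaluation statistics: survival-difference p-values for discovered
# subtypes, cluster-agreement metrics, and summaries of method-comparison
# p-value tables.

#' Cox proportional-hazards p-value for a subtyping
#'
#' Fits a proportional-hazards model with subtype membership as a
#' categorical covariate (largest subtype as reference level) and returns
#' the likelihood-ratio p-value.
#'
#' @param labels Named subtype labels (names = sample ids); at least two
#'   subtypes, each non-empty.
#' @param survival A [survival_table()] covering every labelled sample.
#' @return The likelihood-ratio p-value in \[0, 1\].
#' @export
survival_pvalue <- function(labels, survival) {
  ids <- names(labels)
  if (is.null(ids)) oc_stop("'labels' must be named by sample id")
  if (length(unique(labels)) < 2L)
    oc_stop("need at least two subtypes to test survival difference")
  i <- match(ids, survival$id)
  if (anyNA(i))
    oc_stop("sample(s) without survival data: ", ids[which(is.na(i))[1L]])
  time <- survival$time[i]; event <- survival$event[i]
  if (sum(event) == 0L) oc_stop("all samples censored; no events to model")
  grp <- factor(labels)
  grp <- stats::relevel(grp, ref = names(which.max(table(grp))))
  fit <- survival::coxph(survival::Surv(time, event) ~ grp)
  unname(summary(fit)$logtest["pvalue"])
}

#' Normalized mutual information between two partitions
#'
#' Mutual information normalized by the arithmetic mean of the two label
#' entropies. A constant labelling (zero entropy) paired with a
#' non-constant one yields 0; two identical labelings yield 1.
#'
#' @param labels_a,labels_b Label vectors of equal length.
#' @return NMI in \[0, 1\].
#' @export
nmi <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    oc_stop("label vectors must have equal length")
  n <- length(labels_a)
  tab <- table(labels_a, labels_b) / n
  pa <- rowSums(tab); pb <- colSums(tab)
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / outer(pa, pb)[nz]))
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  denom <- (ha + hb) / 2
  if (denom == 0) return(if (identical(as.vector(labels_a), as.vector(labels_b)) ||
                             (length(unique(labels_a)) == 1L &&
                              length(unique(labels_b)) == 1L)) 1 else 0)
  max(0, min(1, mi / denom))
}

#' Read a dataset-by-method p-value table from CSV
#'
#' First column = dataset names, remaining columns = one method each; every
#' cell must be a p-value in \[0, 1\].
#'
#' @param path Path to the CSV (e.g. the bundled benchmark table; see
#'   `system.file("extdata", "cox_pvalues_benchmark.csv", package =
#'   "omiclust")`).
#' @return Numeric matrix, rownames = datasets, colnames = methods.
#' @export
read_pvalue_table <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m) || anyNA(m) || any(m < 0 | m > 1))
    oc_stop("p-value table must be numeric with entries in [0, 1] and no missing cells")
  m
}

#' Summarize a dataset-by-method p-value table
#'
#' For each method, counts the datasets where its p-value is below `alpha`
#' (`n_significant`) and the datasets where it is both significant and
#' strictly the smallest in its row (`n_best_and_significant`); also counts
#' the datasets where no method is significant.
#'
#' @param table Numeric dataset-by-method matrix of p-values (see
#'   [read_pvalue_table()]).
#' @param alpha Significance threshold in (0, 1), default 0.05.
#' @return A list with `n_significant` and `n_best_and_significant` (named
#'   per method) and `n_datasets_no_method_significant`.
#' @export
summarize_pvalue_table <- function(table, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    oc_stop("'alpha' must be in (0, 1)")
  if (!is.matrix(table) || !is.numeric(table) || anyNA(table))
    oc_stop("'table' must be a complete numeric matrix")
  sig <- table < alpha
  best <- t(apply(table, 1L, function(r) r == min(r) & sum(r == min(r)) == 1L))
  list(n_significant = colSums(sig),
       n_best_and_significant = colSums(sig & best),
       n_datasets_no_method_significant = sum(rowSums(sig) == 0L))
}

#' One-tailed rank-sum comparison of one method against the rest
#'
#' Tests whether the named method's p-values are stochastically smaller
#' than the pooled p-values of all other methods (Wilcoxon rank-sum,
#' alternative "less").
#'
#' @param table Numeric dataset-by-method matrix of p-values.
#' @param method Column name of the method of interest.
#' @return The one-tailed rank-sum p-value.
#' @export
compare_methods_wilcoxon <- function(table, method) {
  if (ncol(table) < 2L) oc_stop("need at least two methods")
  if (!method %in% colnames(table)) oc_stop("method not in table: ", method)
  x <- table[, method]
  y <- as.vector(table[, setdiff(colnames(table), method), drop = FALSE])
  # exact null enumeration for small tie-free samples, normal approximation
  # otherwise (wilcox.test's own switching rule)
  suppressWarnings(stats::wilcox.test(x, y, alternative = "less")$p.value)
}
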