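# Synthetic multi-omics generator.
#
# Emulates the simulation design used to study scalability: each layer is a
# Gaussian background matrix (n samples x m features, default 5,000
# features) and each of the (default three) balanced sample classes has its
# own disjoint block of marker features shifted upward by `shift` background
# standard deviations.  Class labels are shared across layers.

#' Simulate a multi-omics dataset with known classes
#'
#' @param n Number of samples (>= `n_classes`).
#' @param m Features per layer (default 5000).
#' @param n_classes Number of sample classes (default 3).
#' @param n_layers Number of omics layers (default 2).
#' @param n_markers Up-regulated marker features per class (default 100);
#'   marker blocks are disjoint across classes, so
#'   `n_markers * n_classes <= m`.
#' @param shift Up-regulation effect size, in units of the background
#'   standard deviation (default 2).
#' @param noise_sd Background standard deviation (default 1).
#' @param seed Integer seed; identical parameters and seed give
#'   byte-identical output.
#' @return An object of class `simulated_dataset`: `dataset`
#'   (a `multiomics_dataset`), `true_labels` (named integer vector) and
#'   `params`.
#' @export
simulate_multiomics <- function(n, m = 5000L, n_classes = 3L, n_layers = 2L,
                                n_markers = 100L, shift = 2, noise_sd = 1,
                                seed = 1L) {
  if (!is_count(n, 2L) || !is_count(n_classes, 2L) || n < n_classes)
    oc_stop("need n >= n_classes >= 2")
  if (!is_count(m) || !is_count(n_layers) || !is_count(n_markers))
    oc_stop("'m', 'n_layers' and 'n_markers' must be positive integers")
  if (n_markers * n_classes > m)
    oc_stop("infeasible marker allocation: n_markers * n_classes > m")
  if (!is.numeric(shift) || !is.numeric(noise_sd) || noise_sd <= 0)
    oc_stop("'shift' must be numeric and 'noise_sd' positive")
  ids <- sprintf("S%06d", seq_len(n))
  # balanced classes: sizes differ by at most one
  labels <- setNames(rep(seq_len(n_classes), length.out = n), ids)
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    X <- withr::with_seed(derive_seed(seed, l), {
      X <- matrix(stats::rnorm(n * m, sd = noise_sd), n, m)
      for (cl in seq_len(n_classes)) {
        cols <- ((cl - 1L) * n_markers + 1L):(cl * n_markers)
        X[labels == cl, cols] <- X[labels == cl, cols] + shift * noise_sd
      }
      X
    })
    dimnames(X) <- list(ids, sprintf("g%05d", seq_len(m)))
    layers[[l]] <- omics_matrix(X, name = paste0("layer", l))
  }
  structure(
    list(dataset = align_layers(layers),
         true_labels = labels,
         params = list(n = n, m = m, n_classes = n_classes,
                       n_layers = n_layers, n_markers = n_markers,
                       shift = shift, noise_sd = noise_sd,
                       seed = as.integer(seed))),
    class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("simulated_dataset: %d samples x %d features x %d ",
                     "layer(s), %d classes (shift %.2g sd)\n"),
              p$n, p$m, p$n_layers, p$n_classes, p$shift))
  invisible(x)
}

#' Simulate survival times with class-specific hazards
#'
#' Convenience add-on for end-to-end testing of the survival evaluation:
#' exponential event times with one rate per class, censored by an
#' independent uniform censoring time.
#'
#' @param labels Named class labels (names = sample ids).
#' @param rates Event rate (hazard) per class, recycled to the number of
#'   classes; default 0.1 for every class (no survival difference).
#' @param censor_max Upper bound of the uniform censoring distribution
#'   (default `2 / min(rates)`).
#' @param seed Integer seed.
#' @return A [survival_table()].
#' @export
simulate_survival <- function(labels, rates = 0.1, censor_max = NULL,
                              seed = 1L) {
  classes <- sort(unique(labels))
  rates <- rep_len(rates, length(classes))
  if (any(rates <= 0)) oc_stop("'rates' must be positive")
  if (is.null(censor_max)) censor_max <- 2 / min(rates)
  withr::with_seed(as.integer(seed), {
    ev <- stats::rexp(length(labels), rate = rates[match(labels, classes)])
    cens <- stats::runif(length(labels), 0, censor_max)
    survival_table(id = names(labels),
                   time = pmin(ev, cens),
                   event = as.integer(ev <= cens))
  })
}
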