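# Domain containers and CSV readers/writers.
#
# An omics layer is stored as a plain numeric matrix (samples x features)
# with sample ids as rownames and feature ids as colnames, wrapped in a
# lightweight S3 class that enforces the validity invariants once at
# construction.

#' Construct and validate an omics layer
#'
#' Wraps a numeric samples-by-features matrix into an `omics_matrix`,
#' checking that sample and feature identifiers are unique, that every
#' entry is finite, and that the matrix has at least two samples and one
#' feature.
#'
#' @param values Numeric matrix, rows = samples, columns = features, with
#'   rownames (sample ids) and colnames (feature ids).
#' @param name Text label for the omics type (e.g. `"mRNA"`).
#' @return An object of class `omics_matrix`: a list with elements `name`,
#'   `sample_ids`, `feature_ids` and `values`.
#' @export
omics_matrix <- function(values, name = "omics") {
  if (!is.matrix(values) || !is.numeric(values))
    oc_stop("'values' must be a numeric matrix")
  sid <- rownames(values); fid <- colnames(values)
  if (is.null(sid) || is.null(fid))
    oc_stop("'values' must carry sample ids (rownames) and feature ids (colnames)")
  if (anyDuplicated(sid))
    oc_stop("duplicated sample id(s): ",
            paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (anyDuplicated(fid))
    oc_stop("duplicated feature id(s): ",
            paste(unique(fid[duplicated(fid)]), collapse = ", "))
  if (nrow(values) < 2L || ncol(values) < 1L)
    oc_stop("an omics layer needs at least 2 samples and 1 feature")
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    oc_stop("missing/non-finite value at sample '", sid[bad[1L, 1L]],
            "', feature '", fid[bad[1L, 2L]], "'")
  structure(
    list(name = name, sample_ids = sid, feature_ids = fid, values = values),
    class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix '%s': %d samples x %d features\n",
              x$name, length(x$sample_ids), length(x$feature_ids)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Read one omics layer from CSV
#'
#' The expected layout is the conventional expression-matrix CSV: the first
#' row holds feature ids (first cell empty or an id column name), every
#' following row starts with a sample id followed by numeric values. Row and
#' column order are preserved.
#'
#' @param path Path to the CSV file.
#' @param name Label for the omics type; defaults to the file stem.
#' @return A validated [omics_matrix()].
#' @export
read_omics_csv <- function(path, name = NULL) {
  if (!file.exists(path)) oc_stop("file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = list(character = 1L))
  if (ncol(dt) < 2L || nrow(dt) < 1L) oc_stop("empty omics matrix in ", path)
  sid <- as.character(dt[[1L]])
  if (anyDuplicated(sid))
    oc_stop("duplicated sample id(s) in ", path, ": ",
            paste(unique(sid[duplicated(sid)]), collapse = ", "))
  vals <- dt[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))[1L]
      if (!is.na(bad))
        oc_stop("non-numeric value '", col[bad], "' at sample '", sid[bad],
                "', feature '", names(vals)[j], "' in ", path)
      vals[[j]] <- num
    }
    nas <- which(is.na(vals[[j]]))[1L]
    if (!is.na(nas))
      oc_stop("missing value at sample '", sid[nas], "', feature '",
              names(vals)[j], "' in ", path)
  }
  m <- as.matrix(vals)
  rownames(m) <- sid
  omics_matrix(m, name = name)
}

#' Align omics layers into a multi-omics dataset
#'
#' Computes the set of samples present in every layer (the candidates for
#' direct integration) and the union of samples across layers. Both are
#' returned in lexicographic order so results are reproducible regardless of
#' input file ordering.
#'
#' @param layers A list of [omics_matrix()] objects (or a single one).
#' @return An object of class `multiomics_dataset` with elements `layers`
#'   (named list), `common_samples` and `all_samples`.
#' @export
align_layers <- function(layers) {
  if (inherits(layers, "omics_matrix")) layers <- list(layers)
  if (length(layers) < 1L) oc_stop("need at least one omics layer")
  for (l in layers)
    if (!inherits(l, "omics_matrix")) oc_stop("every layer must be an omics_matrix")
  nms <- vapply(layers, `[[`, character(1L), "name")
  if (anyDuplicated(nms)) oc_stop("layer names must be unique")
  names(layers) <- nms
  ids <- lapply(layers, `[[`, "sample_ids")
  common <- sort(Reduce(intersect, ids))
  all_s  <- sort(Reduce(union, ids))
  if (length(layers) > 1L && length(common) == 0L)
    oc_stop("no sample is present in every layer; integration impossible")
  structure(
    list(layers = layers, common_samples = common, all_samples = all_s),
    class = "multiomics_dataset")
}

#' @export
print.multiomics_dataset <- function(x, ...) {
  cat(sprintf("multiomics_dataset: %d layer(s) [%s], %d samples total, %d common\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              length(x$all_samples), length(x$common_samples)))
  invisible(x)
}

#' Extract a layer's value rows for a set of sample ids
#'
#' @param dataset A `multiomics_dataset`.
#' @param layer Layer name or index.
#' @param ids Sample ids to extract, in the requested order.
#' @return Numeric matrix restricted/reordered to `ids`.
#' @export
layer_values <- function(dataset, layer, ids) {
  lay <- dataset$layers[[layer]]
  missing_ids <- setdiff(ids, lay$sample_ids)
  if (length(missing_ids) > 0L)
    oc_stop("sample(s) absent from layer '", lay$name, "': ",
            paste(head(missing_ids, 3L), collapse = ", "))
  lay$values[ids, , drop = FALSE]
}

#' Read a survival table from CSV
#'
#' Expects columns `id`, `time` (non-negative, typically days) and `event`
#' (1 = event observed, 0 = censored).
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` of class `survival_table` with columns `id`,
#'   `time`, `event`.
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) oc_stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "time", "event") %in% names(df)))
    oc_stop("survival CSV must have columns id,time,event")
  survival_table(df$id, df$time, df$event)
}

#' Construct and validate a survival table
#'
#' @param id Sample identifiers (unique).
#' @param time Non-negative follow-up times.
#' @param event Binary event indicator (1 = event, 0 = censored).
#' @return A `data.frame` of class `survival_table`.
#' @export
survival_table <- function(id, time, event) {
  id <- as.character(id)
  if (anyDuplicated(id)) oc_stop("duplicated sample id(s) in survival table")
  if (!is.numeric(time) || any(!is.finite(time)) || any(time < 0))
    oc_stop("survival times must be finite and non-negative")
  if (!all(event %in% c(0, 1)))
    oc_stop("event indicator must be 0 (censored) or 1 (event)")
  structure(data.frame(id = id, time = as.numeric(time),
                       event = as.integer(event), stringsAsFactors = FALSE),
            class = c("survival_table", "data.frame"))
}

#' Write subtyping results to disk
#'
#' Emits `labels.csv` (`sample_id,subtype`), `parameters.json` (full
#' parameter/provenance record including the seed and the sampled/propagated
#' split) and, optionally, the merged similarity matrix as CSV for heatmap
#' rendering.
#'
#' @param result A `subtyping_result` from [subtype()].
#' @param dir Output directory (created if absent).
#' @param similarity Also write `similarity.csv`? Default `FALSE`.
#' @return Invisibly, the paths written.
#' @export
write_result <- function(result, dir, similarity = FALSE) {
  if (!inherits(result, "subtyping_result"))
    oc_stop("'result' must be a subtyping_result")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lab_path <- file.path(dir, "labels.csv")
  utils::write.csv(
    data.frame(sample_id = names(result$final_labels),
               subtype = unname(result$final_labels)),
    lab_path, row.names = FALSE, quote = FALSE)
  meta <- list(
    parameters = result$parameters,
    n_samples = length(result$final_labels),
    n_subtypes = length(unique(result$final_labels)),
    sampled_ids = result$sampled_ids,
    propagated_ids = result$propagated_ids,
    per_type = lapply(result$per_type_partitions, function(p)
      list(k = p$k, stability = p$stability)))
  json_path <- file.path(dir, "parameters.json")
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(lab_path, json_path)
  if (isTRUE(similarity)) {
    sim_path <- file.path(dir, "similarity.csv")
    utils::write.csv(result$merged_similarity, sim_path, quote = FALSE)
    paths <- c(paths, sim_path)
  }
  invisible(paths)
}

#' Read a labels CSV written by [write_result()]
#'
#' @param path Path to `labels.csv`.
#' @return Named integer vector of subtype labels.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  setNames(as.integer(df$subtype), as.character(df$sample_id))
}
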