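#' Labeled expression matrix
#'
#' The internal container for a samples-by-features numeric matrix with
#' per-sample class labels, per-feature identifiers and per-sample
#' identifiers. All supervised operations in the package run on this
#' representation; user-facing functions accept an ordinary data frame
#' (one row per sample, one numeric column per feature plus a label
#' column) and convert it with [as_labeled_matrix()].
#'
#' @param values numeric matrix, `n_samples x n_features`.
#' @param labels character vector of class labels, length `n_samples`.
#' @param feature_ids unique character vector, length `n_features`.
#' @param sample_ids unique character vector, length `n_samples`.
#'
#' @return An object of class `labeled_matrix`: a list with elements
#'   `values`, `labels`, `feature_ids`, `sample_ids` and `classes`
#'   (distinct labels in first-appearance order).
#' @export
new_labeled_matrix <- function(values, labels, feature_ids, sample_ids) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_bad_arg("`values` must be a numeric matrix")
  }
  labels <- as.character(labels)
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(labels)) {
    abort_bad_arg("`labels` length must equal the number of rows of `values`")
  }
  if (ncol(values) != length(feature_ids)) {
    abort_bad_arg("`feature_ids` length must equal the number of columns of `values`")
  }
  if (nrow(values) != length(sample_ids)) {
    abort_bad_arg("`sample_ids` length must equal the number of rows of `values`")
  }
  if (anyDuplicated(feature_ids)) {
    abort_bad_arg(sprintf(
      "duplicate feature id(s): %s",
      paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", ")
    ))
  }
  if (anyDuplicated(sample_ids)) abort_bad_arg("duplicate sample ids")
  if (anyNA(values)) abort_bad_arg("`values` must not contain missing values")
  if (anyNA(labels)) abort_bad_arg("`labels` must not contain missing values")
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(
    list(
      values = values, labels = labels,
      feature_ids = feature_ids, sample_ids = sample_ids,
      classes = unique(labels)
    ),
    class = "labeled_matrix"
  )
}

#' Convert a data frame to a labeled matrix
#'
#' @param data a data frame with one row per sample: a label column, an
#'   optional sample-id column (named `sample_id`, `sample` or `id`),
#'   and numeric feature columns; or an existing `labeled_matrix`,
#'   returned unchanged.
#' @param label_col name of the class-label column. Default `"label"`.
#'
#' @return A [new_labeled_matrix()] object.
#' @export
as_labeled_matrix <- function(data, label_col = "label") {
  if (inherits(data, "labeled_matrix")) {
    return(data)
  }
  if (!is.data.frame(data)) {
    abort_bad_arg("`data` must be a data frame or a labeled_matrix")
  }
  if (!label_col %in% names(data)) {
    abort_bad_arg(sprintf("label column '%s' not found in `data`", label_col))
  }
  id_col <- intersect(c("sample_id", "sample", "id"), setdiff(names(data), label_col))[1]
  sample_ids <- if (!is.na(id_col)) {
    as.character(data[[id_col]])
  } else {
    paste0("s", seq_len(nrow(data)))
  }
  feat_cols <- setdiff(names(data), c(label_col, id_col))
  if (length(feat_cols) == 0) abort_bad_arg("`data` contains no feature columns")
  non_num <- feat_cols[!vapply(data[feat_cols], is.numeric, logical(1))]
  if (length(non_num) > 0) {
    abort_bad_arg(sprintf(
      "non-numeric feature column(s): %s", paste(non_num, collapse = ", ")
    ))
  }
  values <- as.matrix(data[feat_cols])
  storage.mode(values) <- "double"
  new_labeled_matrix(values, data[[label_col]], feat_cols, sample_ids)
}

#' @export
print.labeled_matrix <- function(x, ...) {
  cat(sprintf(
    "<labeled_matrix> %d samples x %d features, classes: %s\n",
    nrow(x$values), ncol(x$values),
    paste(sprintf("%s (%d)", x$classes, tabulate(match(x$labels, x$classes))),
          collapse = ", ")
  ))
  invisible(x)
}

#' @export
as_tibble.labeled_matrix <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(sample_id = x$sample_ids, label = x$labels),
    tibble::as_tibble(x$values)
  )
}

# Restrict a labeled_matrix to a subset of features (by id, order kept as
# given) and/or samples (by index).
lm_subset <- function(lm, features = NULL, samples = NULL) {
  features <- features %||% lm$feature_ids
  samples <- samples %||% seq_along(lm$sample_ids)
  miss <- setdiff(features, lm$feature_ids)
  if (length(miss) > 0) {
    abort_bad_arg(sprintf("unknown feature id(s): %s",
                          paste(utils::head(miss, 5), collapse = ", ")))
  }
  new_labeled_matrix(
    lm$values[samples, features, drop = FALSE],
    lm$labels[samples], features, lm$sample_ids[samples]
  )
}

# Integer-encode labels 0..C-1 in first-appearance order of lm$classes.
lm_encoded_labels <- function(lm) match(lm$labels, lm$classes) - 1L

require_two_classes <- function(lm) {
  if (length(lm$classes) < 2) {
    abort_bad_arg("at least two distinct classes are required")
  }
  invisible(lm)
}
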