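#' Read a labeled expression matrix from delimited text
#'
#' Reads a CSV/TSV expression matrix in either orientation and returns a
#' [new_labeled_matrix()]. With `orientation = "samples_as_rows"` the file
#' has one row per sample, a header of feature names, an optional leading
#' id column and a label column. With `orientation = "features_as_rows"`
#' the first column holds feature ids, the remaining columns are samples
#' (header = sample ids), and the row whose id equals `label_column`
#' carries the class labels.
#'
#' Missing cells (`NA` or empty) are rejected by default; with
#' `impute = "mean"` they are replaced by the per-feature mean. Any other
#' non-numeric cell is always a parse error naming its location.
#'
#' @param path path to a delimited text file with a header row.
#' @param orientation `"samples_as_rows"` (default) or `"features_as_rows"`.
#' @param label_column name of the label column (or label row id in the
#'   transposed layout). Default `"label"`.
#' @param delim field delimiter; `NULL` (default) picks `,` for `.csv`
#'   and tab otherwise.
#' @param impute `"none"` (reject missing values, default) or `"mean"`
#'   (per-feature mean imputation).
#'
#' @return A `labeled_matrix`.
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("samples_as_rows",
                                                   "features_as_rows"),
                                   label_column = "label",
                                   delim = NULL,
                                   impute = c("none", "mean")) {
  orientation <- match.arg(orientation)
  impute <- match.arg(impute)
  if (!file.exists(path)) abort_bad_arg(sprintf("file not found: %s", path))
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) == 0 || ncol(raw) < 2) {
    abort_bad_arg(sprintf("file %s has no data rows", path))
  }

  if (orientation == "features_as_rows") {
    feature_ids <- as.character(raw[[1]])
    sample_ids <- names(raw)[-1]
    body <- t(as.matrix(raw[-1]))  # samples x features, character
    colnames(body) <- feature_ids
    rownames(body) <- sample_ids
    if (!label_column %in% feature_ids) {
      abort_bad_arg(sprintf("label row '%s' not found in %s", label_column, path))
    }
    labels <- body[, match(label_column, colnames(body))]
    body <- body[, colnames(body) != label_column, drop = FALSE]
  } else {
    if (!label_column %in% names(raw)) {
      abort_bad_arg(sprintf("label column '%s' not found in %s", label_column, path))
    }
    labels <- as.character(raw[[label_column]])
    id_col <- intersect(c("sample_id", "sample", "id"),
                        setdiff(names(raw), label_column))[1]
    sample_ids <- if (!is.na(id_col)) as.character(raw[[id_col]]) else
      paste0("s", seq_len(nrow(raw)))
    keep <- setdiff(names(raw), c(label_column, id_col))
    body <- as.matrix(raw[keep])
    rownames(body) <- sample_ids
  }

  if (anyDuplicated(colnames(body))) {
    abort_bad_arg(sprintf(
      "duplicate feature id(s) in %s: %s", path,
      paste(unique(colnames(body)[duplicated(colnames(body))]), collapse = ", ")
    ))
  }

  values <- parse_numeric_body(body, path, impute)
  new_labeled_matrix(values, labels, colnames(body), rownames(body))
}

# Character matrix -> numeric matrix with cell-level error reporting and
# optional per-feature mean imputation of missing cells.
parse_numeric_body <- function(body, path, impute) {
  values <- suppressWarnings(
    matrix(as.numeric(body), nrow(body), ncol(body), dimnames = dimnames(body))
  )
  missing_cell <- is.na(body) | trimws(body) == "" | toupper(trimws(body)) == "NA"
  bad <- which(is.na(values) & !missing_cell, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort_bad_arg(sprintf(
      "non-numeric value '%s' at sample '%s', feature '%s' in %s",
      body[bad[1, 1], bad[1, 2]],
      rownames(body)[bad[1, 1]], colnames(body)[bad[1, 2]], path
    ))
  }
  if (any(missing_cell)) {
    if (impute == "none") {
      mc <- which(missing_cell, arr.ind = TRUE)
      abort_bad_arg(sprintf(
        "missing value at sample '%s', feature '%s' in %s (use impute = \"mean\" to impute)",
        rownames(body)[mc[1, 1]], colnames(body)[mc[1, 2]], path
      ))
    }
    for (j in which(colSums(missing_cell) > 0)) {
      mu <- mean(values[, j], na.rm = TRUE)
      if (is.nan(mu)) abort_bad_arg(sprintf(
        "feature '%s' in %s is entirely missing", colnames(body)[j], path
      ))
      values[missing_cell[, j], j] <- mu
    }
  }
  values
}

#' Write a feature ranking to TSV
#'
#' Writes a ranking table with columns `rank`, `feature_id`, `score`.
#' Ranks must form a permutation of `1..K`; rows are written in rank
#' order so that re-reading reproduces the records exactly.
#'
#' @param records data frame with columns `rank` (positive integers),
#'   `feature_id` (unique strings) and `score` (numeric).
#' @param path output file path.
#'
#' @return `records` (ordered by rank), invisibly.
#' @export
write_ranking <- function(records, path) {
  records <- validate_ranking_records(records)
  readr::write_tsv(records[c("rank", "feature_id", "score")], path,
                   progress = FALSE)
  invisible(records)
}

validate_ranking_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort_bad_arg("`records` must be a nonempty data frame")
  }
  needed <- c("rank", "feature_id", "score")
  if (!all(needed %in% names(records))) {
    abort_bad_arg("`records` needs columns rank, feature_id, score")
  }
  rk <- records$rank
  if (anyDuplicated(rk)) abort_bad_arg("duplicate rank values in ranking")
  if (!setequal(rk, seq_len(nrow(records)))) {
    abort_bad_arg("ranks must be a permutation of 1..K")
  }
  if (anyDuplicated(records$feature_id)) {
    abort_bad_arg("duplicate feature ids in ranking")
  }
  tibble::as_tibble(records[order(rk), , drop = FALSE])
}

#' Read one ranking TSV
#'
#' @param path a TSV written by [write_ranking()].
#' @return A tibble with columns `rank`, `feature_id`, `score`, ordered
#'   by rank.
#' @export
read_ranking <- function(path) {
  if (!file.exists(path)) abort_bad_arg(sprintf("file not found: %s", path))
  tab <- readr::read_tsv(path, col_types = "icd", progress = FALSE,
                         show_col_types = FALSE)
  if (nrow(tab) == 0) abort_bad_arg(sprintf("empty ranking file: %s", path))
  validate_ranking_records(tab)
}

#' Read a collection of ranking files as ordered feature-id lists
#'
#' @param paths character vector of ranking TSV paths.
#' @return A list of character vectors (feature ids ordered by rank
#'   ascending). If list lengths differ across files a warning reports
#'   it; truncation is left to the caller (see [stability_report()]).
#' @export
read_rankings_collection <- function(paths) {
  lists <- lapply(paths, function(p) read_ranking(p)$feature_id)
  lens <- lengths(lists)
  if (length(unique(lens)) > 1) {
    warning(sprintf(
      "ranking lists have inconsistent lengths (%s); truncate before comparing",
      paste(unique(lens), collapse = ", ")
    ), call. = FALSE)
  }
  lists
}

#' Write a JSON run report
#'
#' @param report a named list (configuration echo, elimination log,
#'   final ranking, timings, ...).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
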