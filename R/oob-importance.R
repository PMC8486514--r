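# OOB permutation importance.
#
# For tree i with OOB accuracy C_i, permuting feature f among that
# tree's OOB samples and re-scoring gives C_i^f; the per-tree drop is
# E_i^f = C_i - C_i^f. Across the m usable trees:
#   E^f  = mean_i E_i^f
#   S^2  = sum_i (E_i^f - E^f)^2 / (m - 1)
#   fip  = E^f / S        (0 by convention when S = 0)
#
# Replacement is a permutation within the OOB set (preserves the
# marginal distribution); a feature never consulted by a tree leaves
# that tree's accuracy exactly unchanged, which the implementation
# exploits by only re-scoring (tree, feature) pairs where the tree's
# splits actually depend on the feature (directly for plain forests,
# through the bit definitions for random-bits forests).

# Map: raw feature index -> selected-bit columns referencing it.
selected_bit_feature_map <- function(ensemble) {
  defs <- ensemble$bit_layer$bits[ensemble$selected_bits]
  feat_by_bit <- lapply(defs, `[[`, "features")
  f2b <- vector("list", length(ensemble$feature_ids))
  for (b in seq_along(feat_by_bit)) {
    for (f in feat_by_bit[[b]]) f2b[[f]] <- c(f2b[[f]], b)
  }
  list(feat_by_bit = feat_by_bit, feat_to_bits = f2b)
}

# Rebuild one selected-bit column on the OOB rows with feature `f`
# replaced by `xf_perm`.
recompute_bit_column <- function(def, X_oob, f, xf_perm) {
  Z <- X_oob[, def$features, drop = FALSE]
  hit <- which(def$features == f)
  Z[, hit] <- xf_perm
  as.numeric((Z %*% def$weights) > def$threshold)
}

#' Per-tree OOB accuracy after permuting one feature
#'
#' Computes `C_i^f`: the accuracy of tree `tree_index` on its own
#' out-of-bag samples after the values of `feature` are randomly
#' permuted among those samples. The data itself is untouched.
#'
#' @param ensemble a [fit_bit_ensemble()] fit.
#' @param data the data the ensemble was fitted on (data frame or
#'   `labeled_matrix`).
#' @param feature a feature id.
#' @param tree_index tree number in `1..n_trees`; its OOB set must be
#'   nonempty.
#' @param seed integer seed for the permutation.
#' @param label_col label column name (default `"label"`).
#' @return The permuted OOB accuracy, a number in `[0, 1]`.
#' @export
permuted_tree_accuracy <- function(ensemble, data, feature, tree_index,
                                   seed = 0, label_col = "label") {
  lm <- as_labeled_matrix(data, label_col)
  check_ensemble_data(ensemble, lm)
  f <- match(feature, ensemble$feature_ids)
  if (is.na(f)) abort_bad_arg(sprintf("unknown feature id '%s'", feature))
  tree_index <- check_positive_int(tree_index, "tree_index")
  if (tree_index > length(ensemble$trees)) abort_bad_arg("`tree_index` out of range")
  tr <- ensemble$trees[[tree_index]]
  if (length(tr$oob) == 0) abort_bad_arg("tree has an empty OOB set")
  oob <- tr$oob
  y <- (lm_encoded_labels(lm) + 1L)[oob]
  R_oob <- ensemble_representation(ensemble, lm$values)[oob, , drop = FALSE]
  perm <- withr::with_seed(seed, sample.int(length(oob)))
  xf_perm <- lm$values[oob, f][perm]
  if (ensemble$config$base_learner == "random_bits_forest") {
    maps <- selected_bit_feature_map(ensemble)
    upd <- intersect(tr$used_features, maps$feat_to_bits[[f]])
    X_oob <- lm$values[oob, , drop = FALSE]
    for (b in upd) {
      def <- ensemble$bit_layer$bits[[ensemble$selected_bits[b]]]
      R_oob[, b] <- recompute_bit_column(def, X_oob, f, xf_perm)
    }
  } else if (f %in% tr$used_features) {
    R_oob[, f] <- xf_perm
  }
  mean(predict_cart(tr$tree, R_oob) == y)
}

check_ensemble_data <- function(ensemble, lm) {
  if (!inherits(ensemble, "bit_ensemble")) {
    abort_bad_arg("`ensemble` must be a bit_ensemble")
  }
  if (!identical(ensemble$feature_ids, lm$feature_ids)) {
    abort_bad_arg("`data` features do not match the ensemble's training features")
  }
  invisible(TRUE)
}

#' OOB permutation importance scores
#'
#' Computes, for each requested feature, the per-tree OOB accuracy drop
#' under within-OOB permutation, its mean `E^f`, variance `S^2`
#' (denominator `m - 1`) and the standardized importance
#' `fip = E^f / S` (0 when `S = 0`). Trees with an empty OOB set are
#' excluded from the averaging; the per-tree delta vectors have the same
#' length (number of usable trees) for every feature.
#'
#' @param ensemble a [fit_bit_ensemble()] fit.
#' @param data the data the ensemble was fitted on.
#' @param features feature ids to score (default: all).
#' @param seed integer seed; each (tree, feature, repeat) permutation
#'   gets its own seed derived from it, so results are deterministic.
#' @param n_permutations permutations averaged per (tree, feature)
#'   (default 1).
#' @param label_col label column name (default `"label"`).
#' @param keep_deltas keep the per-tree delta vectors as a list column
#'   (default TRUE).
#'
#' @return A tibble with columns `feature_id`, `mean_delta`, `variance`,
#'   `fip` and (optionally) `per_tree_delta`, one row per requested
#'   feature in the requested order. Attribute `n_trees_used` records
#'   the number of usable trees.
#' @export
importance_scores <- function(ensemble, data, features = NULL, seed = 0,
                              n_permutations = 1, label_col = "label",
                              keep_deltas = TRUE) {
  lm <- as_labeled_matrix(data, label_col)
  check_ensemble_data(ensemble, lm)
  n_permutations <- check_positive_int(n_permutations, "n_permutations")
  features <- features %||% ensemble$feature_ids
  req <- match(features, ensemble$feature_ids)
  if (anyNA(req)) {
    abort_bad_arg(sprintf("unknown feature id(s): %s",
                          paste(utils::head(features[is.na(req)], 5),
                                collapse = ", ")))
  }
  usable <- which(vapply(ensemble$trees, function(t) length(t$oob) > 0,
                         logical(1)))
  if (length(usable) == 0) abort_bad_arg("all trees have empty OOB sets")

  X <- lm$values
  y <- lm_encoded_labels(lm) + 1L
  R_full <- ensemble_representation(ensemble, X)
  rbf <- ensemble$config$base_learner == "random_bits_forest"
  if (rbf) maps <- selected_bit_feature_map(ensemble)
  req_flag <- logical(length(ensemble$feature_ids))
  req_flag[req] <- TRUE
  col_of <- integer(length(ensemble$feature_ids))
  col_of[req] <- seq_along(req)

  deltas <- matrix(0, length(usable), length(req))
  for (ti in seq_along(usable)) {
    i <- usable[ti]
    tr <- ensemble$trees[[i]]
    oob <- tr$oob
    n_oob <- length(oob)
    y_oob <- y[oob]
    R_oob <- R_full[oob, , drop = FALSE]
    X_oob <- X[oob, , drop = FALSE]
    # features this tree's prediction can depend on
    touch <- if (rbf) {
      sort(unique(unlist(maps$feat_by_bit[tr$used_features])))
    } else {
      tr$used_features
    }
    touch <- touch[req_flag[touch]]
    if (length(touch) == 0) next
    n_blk <- length(touch) * n_permutations
    big <- R_oob[rep.int(seq_len(n_oob), n_blk), , drop = FALSE]
    blk <- 0L
    for (f in touch) {
      for (rep_i in seq_len(n_permutations)) {
        rows <- blk * n_oob + seq_len(n_oob)
        blk <- blk + 1L
        perm <- withr::with_seed(derive_seed(seed, i, f, rep_i),
                                 sample.int(n_oob))
        xf_perm <- X_oob[, f][perm]
        if (rbf) {
          for (b in intersect(tr$used_features, maps$feat_to_bits[[f]])) {
            def <- ensemble$bit_layer$bits[[ensemble$selected_bits[b]]]
            big[rows, b] <- recompute_bit_column(def, X_oob, f, xf_perm)
          }
        } else {
          big[rows, f] <- xf_perm
        }
      }
    }
    pred <- predict_cart(tr$tree, big)
    ok <- pred == rep.int(y_oob, n_blk)
    acc <- colMeans(matrix(ok, n_oob, n_blk))
    acc_by_feature <- colMeans(matrix(acc, n_permutations, length(touch)))
    deltas[ti, col_of[touch]] <- tr$oob_accuracy - acc_by_feature
  }

  mean_delta <- colMeans(deltas)
  variance <- if (nrow(deltas) > 1) {
    colSums(sweep(deltas, 2, mean_delta)^2) / (nrow(deltas) - 1)
  } else {
    rep(0, ncol(deltas))
  }
  fip <- ifelse(variance > 0, mean_delta / sqrt(variance), 0)
  out <- tibble::tibble(
    feature_id = features,
    mean_delta = mean_delta,
    variance = variance,
    fip = fip
  )
  if (keep_deltas) {
    out$per_tree_delta <- lapply(seq_along(req), function(j) deltas[, j])
  }
  attr(out, "n_trees_used") <- length(usable)
  out
}

# Pure aggregation of per-tree deltas (Eqs for E^f, S^2, fip) used by
# tests as the hand-computable core.
aggregate_deltas <- function(per_tree_delta) {
  m <- length(per_tree_delta)
  e <- mean(per_tree_delta)
  s2 <- if (m > 1) sum((per_tree_delta - e)^2) / (m - 1) else 0
  list(mean_delta = e, variance = s2,
       fip = if (s2 > 0) e / sqrt(s2) else 0)
}
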