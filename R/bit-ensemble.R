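#' Bootstrap resampling split
#'
#' Draws `n_samples` sample indices with replacement (the in-bag
#' multiset) and returns the out-of-bag (OOB) complement — the samples
#' never drawn. Over many replicates about 36% of samples
#' (`1 - (1 - 1/N)^N`) end up out-of-bag.
#'
#' @param n_samples number of samples `N` (>= 1).
#' @param seed integer seed; the split is deterministic given the seed.
#'
#' @return A list with `in_bag` (integer vector of length `n_samples`,
#'   drawn with replacement) and `oob` (sorted integer vector, the
#'   complement of the distinct in-bag indices).
#' @export
bootstrap_split <- function(n_samples, seed = 0) {
  n_samples <- check_positive_int(n_samples, "n_samples")
  in_bag <- withr::with_seed(seed,
    sample.int(n_samples, n_samples, replace = TRUE))
  list(in_bag = in_bag, oob = setdiff(seq_len(n_samples), in_bag))
}

#' Generate a random-bits layer
#'
#' Builds `n_candidate_bits` randomized binary features ("bits"). Each
#' bit is a deterministic boolean function of at most three raw
#' features: a random sparse linear combination thresholded at a random
#' quantile (drawn uniformly in \[0.2, 0.8\]) of its value distribution
#' on the training matrix. The features entering the bits are allocated
#' by consuming successive random permutations of the feature set, so
#' layer coverage is balanced: no feature appears in a second bit
#' before every feature has had the chance to appear in one (with
#' enough bits, every feature is referenced by the layer). Bits whose
#' projection is (numerically) constant get their weights resampled up
#' to 10 times, then are dropped with a warning.
#'
#' @param X numeric training matrix (samples x features).
#' @param n_candidate_bits number of bits to generate (default 1024).
#' @param seed integer seed.
#'
#' @return An object of class `bit_layer`: list of per-bit definitions
#'   (`features`, `weights`, `threshold`). Apply with
#'   [apply_bit_layer()].
#' @export
make_random_bits <- function(X, n_candidate_bits = 1024, seed = 0) {
  n_candidate_bits <- check_positive_int(n_candidate_bits, "n_candidate_bits")
  if (!is.matrix(X) || ncol(X) < 1) abort_bad_arg("`X` must have >= 1 feature")
  p <- ncol(X)
  bits <- vector("list", n_candidate_bits)
  n_dropped <- 0L
  withr::with_seed(seed, {
    arity <- sample.int(min(3L, p), n_candidate_bits, replace = TRUE)
    pool <- unlist(lapply(seq_len(ceiling(sum(arity) / p)),
                          function(i) sample.int(p)))
    offset <- 0L
    for (b in seq_len(n_candidate_bits)) {
      feats <- unique(pool[offset + seq_len(arity[b])])
      offset <- offset + arity[b]
      for (try in seq_len(10L)) {
        w <- stats::rnorm(length(feats))
        proj <- as.vector(X[, feats, drop = FALSE] %*% w)
        if (diff(range(proj)) < 1e-12) next
        thr <- stats::quantile(proj, stats::runif(1, 0.2, 0.8), names = FALSE)
        if (all(proj > thr) || all(proj <= thr)) next
        bits[[b]] <- list(features = sort(feats), weights = w[order(feats)],
                          threshold = thr)
        break
      }
      if (is.null(bits[[b]])) n_dropped <- n_dropped + 1L
    }
  })
  if (n_dropped > 0) {
    warning(sprintf("%d random bit(s) dropped (constant projections)",
                    n_dropped), call. = FALSE)
    bits <- bits[!vapply(bits, is.null, logical(1))]
  }
  structure(list(bits = bits, n_features = p), class = "bit_layer")
}

#' Apply a bit layer to a matrix
#'
#' @param layer a [make_random_bits()] layer.
#' @param X numeric matrix with the same feature count as the training
#'   matrix.
#' @return A `nrow(X) x n_bits` 0/1 numeric matrix
#'   (`bit = projection > threshold`).
#' @export
apply_bit_layer <- function(layer, X) {
  if (!inherits(layer, "bit_layer")) abort_bad_arg("`layer` must be a bit_layer")
  if (ncol(X) != layer$n_features) {
    abort_bad_arg(sprintf("`X` has %d features; layer expects %d",
                          ncol(X), layer$n_features))
  }
  B <- matrix(0, nrow(X), length(layer$bits))
  for (b in seq_along(layer$bits)) {
    def <- layer$bits[[b]]
    B[, b] <- (X[, def$features, drop = FALSE] %*% def$weights) > def$threshold
  }
  B
}

#' Greedy boosted bit selection
#'
#' Forward selection of bits by training logistic loss of an additive
#' stump model: at each step every remaining bit is given its (Newton)
#' two-leaf adjustment, damped by `shrinkage`, and the bit whose stump
#' yields the lowest training loss is added (ties go to the lowest bit
#' index). The damping keeps the model from saturating on a handful of
#' bits at small sample sizes, so the selection spreads over the
#' distinct signal directions. Selection stops early only when no
#' remaining bit improves the loss at all. Two-class labels only.
#'
#' @param bits 0/1 numeric matrix (samples x bits).
#' @param labels class labels, exactly two distinct values; the first
#'   label in appearance order is the reference class.
#' @param n_selected_bits number of bits to keep (default 128); clamped
#'   to the number of available bits.
#' @param shrinkage boosting learning rate in (0, 1] (default 0.3).
#'
#' @return Integer vector of selected bit column indices, in selection
#'   order.
#' @export
boost_select_bits <- function(bits, labels, n_selected_bits = 128,
                              shrinkage = 0.3) {
  if (!is.matrix(bits) || ncol(bits) == 0) {
    abort_bad_arg("`bits` must be a nonempty matrix")
  }
  classes <- unique(as.character(labels))
  if (length(classes) < 2) abort_bad_arg("labels must contain >= 2 classes")
  if (length(classes) > 2) {
    abort_bad_arg("boost_select_bits supports exactly two classes")
  }
  n_selected_bits <- check_positive_int(n_selected_bits, "n_selected_bits")
  n <- nrow(bits)
  nb <- ncol(bits)
  y <- as.numeric(labels == classes[2])
  ysign <- 2 * y - 1
  p1 <- min(max(mean(y), 1e-6), 1 - 1e-6)
  Fm <- rep(log(p1 / (1 - p1)), n)
  n_keep <- min(n_selected_bits, nb)
  selected <- integer(0)
  taken <- logical(nb)
  cur_loss <- sum(log1p(exp(-ysign * Fm)))
  for (step in seq_len(n_keep)) {
    pr <- stats::plogis(Fm)
    g <- y - pr
    h <- pmax(pr * (1 - pr), 1e-10)
    s1g <- as.vector(crossprod(bits, g)); s1h <- as.vector(crossprod(bits, h))
    a1 <- shrinkage * pmin(pmax(s1g / pmax(s1h, 1e-10), -4), 4)
    a0 <- shrinkage * pmin(pmax((sum(g) - s1g) / pmax(sum(h) - s1h, 1e-10), -4), 4)
    # exact training loss of each candidate stump
    M <- Fm + rep(a0, each = n) + bits * rep(a1 - a0, each = n)
    loss <- colSums(log1p(exp(-ysign * M)))
    loss[taken] <- Inf
    j <- which.min(loss)  # ties -> lowest bit index
    if (!is.finite(loss[j]) || loss[j] >= cur_loss - 1e-10) break
    selected <- c(selected, j)
    taken[j] <- TRUE
    Fm <- Fm + a0[j] + (a1[j] - a0[j]) * bits[, j]
    cur_loss <- loss[j]
  }
  selected
}

#' Fit a bootstrap tree ensemble with per-tree OOB bookkeeping
#'
#' Fits `n_trees` CART classification trees, each on its own bootstrap
#' resample, and records every tree's in-bag multiset, out-of-bag (OOB)
#' sample set and OOB accuracy `C_i` (computed on that tree's own OOB
#' samples only). Two base learners share this contract:
#'
#' * `"random_bits_forest"`: a random-bits layer is generated from the
#'   training matrix ([make_random_bits()]), boosting selects the most
#'   predictive bits ([boost_select_bits()]), and the trees are grown on
#'   the selected-bit representation (two-class labels only).
#' * `"plain_forest"`: trees are grown on the raw features with
#'   per-node random feature subsampling (`mtry = floor(sqrt(p))`), the
#'   standard random-forest construction.
#'
#' @param data data frame (samples x features with a label column) or a
#'   `labeled_matrix`.
#' @param label_col label column name (default `"label"`).
#' @param n_trees ensemble size `m` (default 200).
#' @param base_learner `"random_bits_forest"` (default) or
#'   `"plain_forest"`.
#' @param n_candidate_bits bits generated per ensemble (default 1024).
#' @param n_selected_bits bits kept by boosting (default 128; must not
#'   exceed `n_candidate_bits`).
#' @param max_depth tree depth cap (default 30).
#' @param seed integer seed; fits are deterministic given the seed.
#'
#' @return An object of class `bit_ensemble` with elements `trees`
#'   (list of `tree`, `in_bag`, `oob`, `oob_accuracy`, `used_features`),
#'   `bit_layer` and `selected_bits` (NULL for `plain_forest`),
#'   `classes`, `feature_ids` and `config`.
#' @export
fit_bit_ensemble <- function(data, label_col = "label",
                             n_trees = 200,
                             base_learner = c("random_bits_forest",
                                              "plain_forest"),
                             n_candidate_bits = 1024,
                             n_selected_bits = 128,
                             max_depth = 30,
                             seed = 0) {
  base_learner <- match.arg(base_learner)
  n_trees <- check_positive_int(n_trees, "n_trees")
  n_candidate_bits <- check_positive_int(n_candidate_bits, "n_candidate_bits")
  n_selected_bits <- check_positive_int(n_selected_bits, "n_selected_bits")
  if (n_selected_bits > n_candidate_bits) {
    abort_bad_arg("`n_selected_bits` must not exceed `n_candidate_bits`")
  }
  lm <- as_labeled_matrix(data, label_col)
  require_two_classes(lm)
  n <- length(lm$sample_ids)
  if (n < 5) abort_bad_arg("at least 5 samples are required")
  y <- lm_encoded_labels(lm) + 1L
  n_classes <- length(lm$classes)

  if (base_learner == "random_bits_forest") {
    layer <- make_random_bits(lm$values, n_candidate_bits,
                              seed = derive_seed(seed, 1))
    B <- apply_bit_layer(layer, lm$values)
    sel <- boost_select_bits(B, lm$labels, n_selected_bits)
    if (length(sel) == 0) abort_bad_arg("no informative bits selected")
    train_X <- B[, sel, drop = FALSE]
    binary <- TRUE
    # per-node random bit subsampling decorrelates the bagged trees
    mtry <- max(1L, floor(sqrt(ncol(train_X))))
  } else {
    layer <- NULL
    sel <- NULL
    train_X <- lm$values
    binary <- FALSE
    mtry <- max(1L, floor(sqrt(ncol(train_X))))
  }

  trees <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    bs <- bootstrap_split(n, seed = derive_seed(seed, 2, i))
    tree <- withr::with_seed(derive_seed(seed, 3, i),
      fit_cart(train_X[bs$in_bag, , drop = FALSE], y[bs$in_bag],
               n_classes = n_classes, mtry = mtry,
               max_depth = max_depth, binary = binary))
    oob_acc <- if (length(bs$oob) > 0) {
      mean(predict_cart(tree, train_X[bs$oob, , drop = FALSE]) == y[bs$oob])
    } else {
      NA_real_
    }
    trees[[i]] <- list(tree = tree, in_bag = bs$in_bag, oob = bs$oob,
                       oob_accuracy = oob_acc,
                       used_features = cart_used_features(tree))
  }

  structure(list(
    trees = trees,
    bit_layer = layer,
    selected_bits = sel,
    classes = lm$classes,
    feature_ids = lm$feature_ids,
    config = list(n_trees = n_trees, base_learner = base_learner,
                  n_candidate_bits = n_candidate_bits,
                  n_selected_bits = n_selected_bits,
                  max_depth = max_depth, seed = seed)
  ), class = "bit_ensemble")
}

#' @export
print.bit_ensemble <- function(x, ...) {
  acc <- vapply(x$trees, `[[`, numeric(1), "oob_accuracy")
  cat(sprintf(
    "<bit_ensemble> %s, %d trees, %d features, mean per-tree OOB accuracy %.3f\n",
    x$config$base_learner, length(x$trees), length(x$feature_ids),
    mean(acc, na.rm = TRUE)
  ))
  invisible(x)
}

# Internal: representation of a raw feature matrix in the space the
# trees were trained on (selected bits for RBF, identity for plain).
ensemble_representation <- function(ensemble, X) {
  if (ensemble$config$base_learner == "random_bits_forest") {
    apply_bit_layer(ensemble$bit_layer, X)[, ensemble$selected_bits,
                                           drop = FALSE]
  } else {
    X
  }
}

#' Predict classes with a fitted ensemble
#'
#' Per-sample majority vote over all trees; ties break toward the class
#' listed earlier in `object$classes` (first-appearance order in the
#' training labels).
#'
#' @param object a [fit_bit_ensemble()] fit.
#' @param newdata data frame or numeric matrix of features in training
#'   column order (a label column, if present, is ignored).
#' @param ... unused.
#' @return Character vector of predicted class labels.
#' @export
predict.bit_ensemble <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) {
    newdata
  } else if (is.data.frame(newdata)) {
    keep <- intersect(object$feature_ids, names(newdata))
    if (length(keep) == length(object$feature_ids)) {
      as.matrix(newdata[object$feature_ids])
    } else {
      as.matrix(newdata[vapply(newdata, is.numeric, logical(1))])
    }
  } else {
    abort_bad_arg("`newdata` must be a matrix or data frame")
  }
  if (ncol(X) != length(object$feature_ids)) {
    abort_bad_arg(sprintf("`newdata` has %d features; ensemble expects %d",
                          ncol(X), length(object$feature_ids)))
  }
  R <- ensemble_representation(object, X)
  n_classes <- length(object$classes)
  votes <- matrix(0L, nrow(X), n_classes)
  for (tr in object$trees) {
    pc <- predict_cart(tr$tree, R)
    votes[cbind(seq_len(nrow(X)), pc)] <- votes[cbind(seq_len(nrow(X)), pc)] + 1L
  }
  object$classes[max.col(votes, ties.method = "first")]
}
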