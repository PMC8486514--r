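# Internal vectorized CART (Gini impurity, binary threshold splits,
# no pruning). Hand-rolled on flat node arrays so that the OOB
# permutation-importance bookkeeping can run tens of thousands of
# single-tree predictions on tiny row subsets per elimination round
# without per-call model-object overhead.
#
# Trees are stored as parallel vectors: feature[k] (0 for leaves),
# threshold[k], left[k]/right[k] child ids (x <= threshold goes left),
# pred[k] (1-based class index at leaves).
#
# `binary = TRUE` activates a fast path for 0/1 feature matrices (the
# random-bits representation): split counts for every candidate feature
# at once via one crossprod. Uses the current RNG state for the per-node
# feature subsampling (`mtry`); callers seed around the whole fit.

fit_cart <- function(X, y, n_classes, mtry = ncol(X), max_depth = 30L,
                     min_node = 2L, binary = FALSE) {
  n <- nrow(X)
  p <- ncol(X)
  cap <- 2L * n + 8L
  feature <- integer(cap); threshold <- numeric(cap)
  left <- integer(cap); right <- integer(cap); pred <- integer(cap)
  n_nodes <- 1L
  Y <- matrix(0, n, n_classes)
  Y[cbind(seq_len(n), y)] <- 1

  majority <- function(idx) {
    cnt <- colSums(Y[idx, , drop = FALSE])
    which.max(cnt)  # ties -> earlier class
  }

  # stack of open nodes: list of (node id, row indices, depth)
  stack <- list(list(id = 1L, idx = seq_len(n), depth = 0L))
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    idx <- top$idx
    yk <- y[idx]
    if (top$depth >= max_depth || length(idx) < min_node ||
        all(yk == yk[1])) {
      feature[top$id] <- 0L
      pred[top$id] <- majority(idx)
      next
    }
    cand <- if (mtry < p) sort(sample.int(p, mtry)) else seq_len(p)
    sp <- if (binary) {
      cart_split_binary(X, Y, idx, cand)
    } else {
      cart_split_scan(X, Y, idx, cand)
    }
    if (is.null(sp)) {
      feature[top$id] <- 0L
      pred[top$id] <- majority(idx)
      next
    }
    go_left <- X[idx, sp$feature] <= sp$threshold
    lid <- n_nodes + 1L
    rid <- n_nodes + 2L
    n_nodes <- n_nodes + 2L
    feature[top$id] <- sp$feature
    threshold[top$id] <- sp$threshold
    left[top$id] <- lid
    right[top$id] <- rid
    stack[[length(stack) + 1L]] <- list(id = lid, idx = idx[go_left],
                                        depth = top$depth + 1L)
    stack[[length(stack) + 1L]] <- list(id = rid, idx = idx[!go_left],
                                        depth = top$depth + 1L)
  }
  k <- seq_len(n_nodes)
  list(feature = feature[k], threshold = threshold[k], left = left[k],
       right = right[k], pred = pred[k])
}

# Best Gini split over 0/1 candidate features, fully vectorized.
# Returns NULL when no candidate reduces impurity.
cart_split_binary <- function(X, Y, idx, cand) {
  Yk <- Y[idx, , drop = FALSE]
  nk <- length(idx)
  cnt_all <- colSums(Yk)
  cnt1 <- crossprod(X[idx, cand, drop = FALSE], Yk)  # |cand| x C
  n1 <- rowSums(cnt1)
  n0 <- nk - n1
  cnt0 <- rep(cnt_all, each = length(cand)) - cnt1
  g1 <- n1 - rowSums(cnt1^2) / pmax(n1, 1)
  g0 <- n0 - rowSums(cnt0^2) / pmax(n0, 1)
  child <- (g0 + g1) / nk
  child[n1 == 0 | n0 == 0] <- Inf
  parent <- 1 - sum((cnt_all / nk)^2)
  j <- which.min(child)  # ties -> lowest candidate feature index
  if (!is.finite(child[j]) || parent - child[j] <= 1e-12) return(NULL)
  list(feature = cand[j], threshold = 0.5)
}

# Generic sorted-scan Gini split for continuous features.
cart_split_scan <- function(X, Y, idx, cand) {
  Yk <- Y[idx, , drop = FALSE]
  nk <- length(idx)
  cnt_all <- colSums(Yk)
  parent <- 1 - sum((cnt_all / nk)^2)
  best <- list(gain = 1e-12, feature = 0L, threshold = NA_real_)
  for (j in cand) {
    x <- X[idx, j]
    o <- order(x, method = "radix")
    xs <- x[o]
    valid <- which(xs[-nk] < xs[-1])
    if (length(valid) == 0) next
    cum <- apply(Yk[o, , drop = FALSE], 2, cumsum)  # nk x C
    nl <- valid
    nr <- nk - nl
    cl <- cum[valid, , drop = FALSE]
    cr <- rep(cnt_all, each = length(valid)) - cl
    gl <- nl - rowSums(cl^2) / nl
    gr <- nr - rowSums(cr^2) / nr
    child <- (gl + gr) / nk
    b <- which.min(child)
    gain <- parent - child[b]
    if (gain > best$gain) {
      best <- list(gain = gain, feature = j,
                   threshold = (xs[valid[b]] + xs[valid[b] + 1]) / 2)
    }
  }
  if (best$feature == 0L) return(NULL)
  best[c("feature", "threshold")]
}

# Vectorized prediction: routes all rows simultaneously. Returns 1-based
# class indices.
predict_cart <- function(tree, X) {
  node <- rep(1L, nrow(X))
  repeat {
    at_leaf <- tree$feature[node] == 0L
    if (all(at_leaf)) break
    act <- which(!at_leaf)
    nd <- node[act]
    go_left <- X[cbind(act, tree$feature[nd])] <= tree$threshold[nd]
    node[act] <- ifelse(go_left, tree$left[nd], tree$right[nd])
  }
  tree$pred[node]
}

# Distinct feature indices the tree actually splits on.
cart_used_features <- function(tree) {
  f <- tree$feature[tree$feature > 0L]
  if (length(f) == 0) integer(0) else sort(unique(f))
}
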