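#' Correlation distance between two feature vectors
#'
#' `D = 1 - r`, with `r` the sample Pearson correlation across samples,
#' so identical profiles are at distance 0 and anti-correlated profiles
#' at distance 2. A constant vector has undefined correlation; it is
#' treated as uncorrelated (`r = 0`, distance 1) with a warning.
#'
#' @param f_i,f_j numeric vectors of equal length `>= 2`.
#' @return A number in `[0, 2]`.
#' @export
correlation_distance <- function(f_i, f_j) {
  if (length(f_i) != length(f_j)) abort_bad_arg("vectors must have equal length")
  if (length(f_i) < 2) abort_bad_arg("vectors must have length >= 2")
  if (stats::sd(f_i) == 0 || stats::sd(f_j) == 0) {
    warning("constant vector: correlation undefined, returning distance 1",
            call. = FALSE)
    return(1)
  }
  1 - stats::cor(f_i, f_j)
}

# Standardize feature rows (features x samples) to zero mean / unit
# sample SD; constant rows become all-zero (distance 1 to every
# standardized vector under the correlation embedding).
standardize_feature_rows <- function(Fm) {
  mu <- rowMeans(Fm)
  sd <- apply(Fm, 1, stats::sd)
  Z <- (Fm - mu) / ifelse(sd > 0, sd, 1)
  Z[sd == 0, ] <- 0
  Z
}

# Lloyd K-means with k-means++ seeding on pre-standardized rows.
# Squared Euclidean distance between standardized feature vectors is a
# monotone transform of correlation distance: ||u - v||^2 = 2(n-1)(1-r),
# so minimizing the within-cluster squared distance clusters by
# correlation. Empty clusters are re-seeded from the point farthest
# from its assigned center. Deterministic given the seed.
kmeans_corr <- function(Z, k, max_iterations = 300, seed = 0) {
  p <- nrow(Z)
  if (k > p) abort_bad_arg("`n_clusters` must not exceed the feature count")
  rs <- rowSums(Z^2)
  withr::with_seed(seed, {
    # k-means++ seeding
    centers_idx <- integer(k)
    centers_idx[1] <- sample.int(p, 1)
    d2 <- pmax(rs + rs[centers_idx[1]] -
                 2 * as.vector(Z %*% Z[centers_idx[1], ]), 0)
    if (k > 1) {
      for (c in 2:k) {
        w <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / p, p)
        centers_idx[c] <- sample.int(p, 1, prob = w)
        d2c <- pmax(rs + rs[centers_idx[c]] -
                      2 * as.vector(Z %*% Z[centers_idx[c], ]), 0)
        d2 <- pmin(d2, d2c)
      }
    }
    centers <- Z[centers_idx, , drop = FALSE]
    assign_old <- rep(0L, p)
    for (it in seq_len(max_iterations)) {
      cross <- Z %*% t(centers)                       # p x k
      cd2 <- outer(rs, rowSums(centers^2), "+") - 2 * cross
      assign_new <- max.col(-cd2, ties.method = "first")
      # re-seed empty clusters from the farthest point
      for (c in which(tabulate(assign_new, k) == 0)) {
        far <- which.max(cd2[cbind(seq_len(p), assign_new)])
        assign_new[far] <- c
        centers[c, ] <- Z[far, ]
      }
      if (identical(assign_new, assign_old)) break
      assign_old <- assign_new
      centers <- rowsum(Z, assign_new) /
        as.vector(tabulate(assign_new, k))
    }
  })
  assign_old
}

#' Cluster features by correlation distance
#'
#' Partitions the (active) features into `n_clusters` feature classes
#' with K-means under the correlation distance: each feature's
#' across-sample profile is standardized and clustered with squared
#' Euclidean K-means, which orders pairs identically to `1 - r` since
#' `||u - v||^2 = 2(n-1)(1-r)` for standardized vectors. Seeding is
#' k-means++ style; empty clusters are re-seeded from the farthest
#' point; the partition is deterministic given `seed`.
#'
#' @param data data frame (samples x features, label column ignored) or
#'   `labeled_matrix`.
#' @param n_clusters number of feature classes; default
#'   `ceiling(sqrt(p))` for `p` active features.
#' @param active_features character vector of feature ids to cluster
#'   (default: all).
#' @param max_iterations Lloyd iteration cap (default 300).
#' @param seed integer seed.
#' @param label_col label column name (default `"label"`).
#'
#' @return A tibble with columns `feature_id` and `cluster` (integers
#'   `1..n_clusters`); the clusters partition `active_features`.
#' @export
cluster_features <- function(data, n_clusters = NULL, active_features = NULL,
                             max_iterations = 300, seed = 0,
                             label_col = "label") {
  lm <- as_labeled_matrix(data, label_col)
  active_features <- active_features %||% lm$feature_ids
  lm <- lm_subset(lm, features = active_features)
  p <- length(active_features)
  n_clusters <- n_clusters %||% ceiling(sqrt(p))
  n_clusters <- check_positive_int(n_clusters, "n_clusters")
  if (n_clusters > p) {
    abort_bad_arg("`n_clusters` must not exceed the number of active features")
  }
  Z <- standardize_feature_rows(t(lm$values))
  assign <- kmeans_corr(Z, n_clusters, max_iterations, seed)
  out <- tibble::tibble(feature_id = active_features, cluster = assign)
  stopifnot(setequal(out$feature_id, active_features),
            !anyDuplicated(out$feature_id))
  out
}
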