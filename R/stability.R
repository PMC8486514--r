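#' Normalized top-t prefix disagreement between two rankings
#'
#' For two equal-length rankings, `delta_t` is the size of the symmetric
#' difference between their top-`t` prefix sets divided by `2t`: 0 for
#' identical prefixes, 1 for disjoint ones. Order inside the prefix is
#' ignored.
#'
#' @param f_i,f_j character vectors of distinct feature ids, equal
#'   length `k`.
#' @param t prefix length, `1 <= t <= k`.
#' @return A number in `[0, 1]`.
#' @export
prefix_delta <- function(f_i, f_j, t) {
  check_ranked_pair(f_i, f_j)
  t <- check_positive_int(t, "t")
  if (t > length(f_i)) abort_bad_arg("`t` must not exceed the list length")
  a <- f_i[seq_len(t)]
  b <- f_j[seq_len(t)]
  (sum(!a %in% b) + sum(!b %in% a)) / (2 * t)
}

check_ranked_pair <- function(f_i, f_j) {
  if (length(f_i) != length(f_j)) {
    abort_bad_arg("rankings must have equal length (truncate first; see truncate_ranking())")
  }
  if (length(f_i) < 1) abort_bad_arg("rankings must be nonempty")
  if (anyDuplicated(f_i) || anyDuplicated(f_j)) {
    abort_bad_arg("rankings must not contain duplicate ids")
  }
  invisible(TRUE)
}

#' Intersection metric between two top-k rankings
#'
#' The Fagin-style intersection metric: the mean over prefix lengths
#' `t = 1..k` of the normalized top-`t` set disagreement
#' ([prefix_delta()]). 0 for identical rankings, 1 for disjoint ones;
#' symmetric in its arguments.
#'
#' @inheritParams prefix_delta
#' @return A number in `[0, 1]`.
#' @export
intersection_metric <- function(f_i, f_j) {
  check_ranked_pair(f_i, f_j)
  k <- length(f_i)
  pos <- match(f_i, f_j)                 # position of f_i's items in f_j
  t_all <- seq_len(k)
  common_t <- vapply(t_all, function(t) {
    sum(pos[seq_len(t)] <= t, na.rm = TRUE)
  }, numeric(1))
  # |top_t(i) \ top_t(j)| = |top_t(j) \ top_t(i)| = t - common_t
  mean(((t_all - common_t) + (t_all - common_t)) / (2 * t_all))
}

#' Similarity of two top-k rankings
#'
#' `sim_IM = 1 - IM`: 1 for identical rankings, 0 for disjoint ones.
#'
#' @inheritParams prefix_delta
#' @return A number in `[0, 1]`.
#' @export
similarity_im <- function(f_i, f_j) 1 - intersection_metric(f_i, f_j)

#' Truncate a ranking to its top k
#'
#' @param ranking character vector of distinct ids.
#' @param k prefix length to keep.
#' @return The first `k` ids.
#' @export
truncate_ranking <- function(ranking, k) {
  k <- check_positive_int(k, "k")
  if (length(ranking) < k) {
    abort_bad_arg(sprintf("ranking has %d items; cannot truncate to k = %d",
                          length(ranking), k))
  }
  ranking[seq_len(k)]
}

#' Pairwise stability report for a collection of rankings
#'
#' Truncates each ranking to its top `k`, computes all pairwise
#' similarities [similarity_im()] and their mean over the strictly
#' upper triangle — the feature-selection stability of the collection
#' at subset size `k`.
#'
#' @param rankings list of at least two character vectors (feature ids
#'   ordered most-important first), each of length `>= k`.
#' @param k subset size at which stability is measured.
#' @return An object of class `stability_report`: list with `k`,
#'   `n_lists`, `pairwise` (symmetric similarity matrix, unit diagonal)
#'   and `mean_sim`. Methods: `tidy()`, `glance()`.
#' @export
stability_report <- function(rankings, k) {
  if (!is.list(rankings) || length(rankings) < 2) {
    abort_bad_arg("`rankings` must be a list of at least two rankings")
  }
  k <- check_positive_int(k, "k")
  tops <- lapply(rankings, truncate_ranking, k = k)
  n <- length(tops)
  pw <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      pw[i, j] <- pw[j, i] <- similarity_im(tops[[i]], tops[[j]])
    }
  }
  structure(list(
    k = k, n_lists = n, pairwise = pw,
    mean_sim = mean(pw[upper.tri(pw)])
  ), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %d rankings, k = %d, mean sim_IM = %.4f\n",
              x$n_lists, x$k, x$mean_sim))
  invisible(x)
}

#' @rdname stability_report
#' @param x a `stability_report`.
#' @param ... unused.
#' @export
tidy.stability_report <- function(x, ...) {
  n <- x$n_lists
  idx <- which(upper.tri(x$pairwise), arr.ind = TRUE)
  tibble::tibble(
    list_i = idx[, 1], list_j = idx[, 2],
    sim_im = x$pairwise[idx], k = x$k
  )
}

#' @rdname stability_report
#' @export
glance.stability_report <- function(x, ...) {
  tibble::tibble(k = x$k, n_lists = x$n_lists, mean_sim = x$mean_sim)
}

#' Stability as a function of subset size
#'
#' Computes [stability_report()] mean similarity on a grid of subset
#' sizes, the datum behind stability-versus-k curves.
#'
#' @inheritParams stability_report
#' @param k_grid increasing integer vector of subset sizes.
#' @return A tibble with columns `k` and `mean_sim`, classed
#'   `stability_curve` for [autoplot()][ggplot2::autoplot()].
#' @export
stability_curve <- function(rankings, k_grid) {
  if (is.unsorted(k_grid, strictly = TRUE)) {
    abort_bad_arg("`k_grid` must be strictly increasing")
  }
  out <- tibble::tibble(
    k = as.integer(k_grid),
    mean_sim = vapply(k_grid, function(k) stability_report(rankings, k)$mean_sim,
                      numeric(1))
  )
  class(out) <- c("stability_curve", class(out))
  out
}

#' @rdname stability_curve
#' @param object a `stability_curve` (possibly with a `method` column).
#' @param ... unused.
#' @export
autoplot.stability_curve <- function(object, ...) {
  aes <- if ("method" %in% names(object)) {
    ggplot2::aes(.data$k, .data$mean_sim, colour = .data$method)
  } else {
    ggplot2::aes(.data$k, .data$mean_sim)
  }
  ggplot2::ggplot(object, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "number of selected features (k)",
                  y = expression(mean ~ sim[IM]),
                  title = "Feature-selection stability vs subset size") +
    ggplot2::theme_minimal()
}

#' Prior probability that two random k-subsets are identical
#'
#' For two independent uniformly drawn size-`k` subsets of `m` features:
#' `P(identical) = k!(m-k)!/m! = 1/C(m,k)`, computed in log space.
#'
#' @param m_total total feature count `m`.
#' @param k subset size, `k <= m`.
#' @return A probability.
#' @export
prob_identical_subsets <- function(m_total, k) {
  m_total <- check_positive_int(m_total, "m_total")
  k <- check_positive_int(k, "k")
  if (k > m_total) abort_bad_arg("`k` must not exceed `m_total`")
  exp(-lchoose(m_total, k))
}

#' Prior probability that two random k-subsets share a feature
#'
#' For two independent uniformly drawn size-`k` subsets of `m`
#' features: `P(|intersection| >= 1) = 1 - C(m-k, k)/C(m, k)` (the
#' hypergeometric complement), which is 1 whenever `2k > m` and
#' non-decreasing in `k` — larger selected subsets overlap more, the
#' combinatorial driver of the stability-vs-k trend.
#'
#' @inheritParams prob_identical_subsets
#' @return A probability.
#' @export
prob_share_feature <- function(m_total, k) {
  m_total <- check_positive_int(m_total, "m_total")
  k <- check_positive_int(k, "k")
  if (k > m_total) abort_bad_arg("`k` must not exceed `m_total`")
  1 - exp(lchoose(m_total - k, k) - lchoose(m_total, k))
}
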