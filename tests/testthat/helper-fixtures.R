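# Shared fixtures and independent oracles, built in code at test time.

# Small linearly separable two-feature toy: class follows feature x1.
toy_separable <- function(n = 20, seed = 1) {
  withr::with_seed(seed, {
    x1 <- c(stats::rnorm(n / 2, -2, 0.5), stats::rnorm(n / 2, 2, 0.5))
    tibble::tibble(
      sample_id = paste0("s", seq_len(n)),
      label = rep(c("neg", "pos"), each = n / 2),
      x1 = x1,
      x2 = stats::rnorm(n)
    )
  })
}

# Brute-force prefix-set intersection metric, independent of the
# package implementation: literal set arithmetic per prefix length.
im_bruteforce <- function(a, b) {
  k <- length(a)
  deltas <- vapply(seq_len(k), function(t) {
    at <- a[seq_len(t)]
    bt <- b[seq_len(t)]
    (length(setdiff(at, bt)) + length(setdiff(bt, at))) / (2 * t)
  }, numeric(1))
  mean(deltas)
}

# Exhaustive-enumeration oracles for the subset-overlap priors.
enum_prob_identical <- function(m, k) {
  subs <- utils::combn(m, k, simplify = FALSE)
  hits <- 0
  for (a in subs) for (b in subs) hits <- hits + identical(a, b)
  hits / length(subs)^2
}

enum_prob_share <- function(m, k) {
  subs <- utils::combn(m, k, simplify = FALSE)
  hits <- 0
  for (a in subs) for (b in subs) hits <- hits + (length(intersect(a, b)) >= 1)
  hits / length(subs)^2
}

# A leaf-only CART tree predicting a fixed class, for hand-built
# ensembles.
leaf_tree <- function(class_index) {
  list(feature = 0L, threshold = 0, left = 0L, right = 0L,
       pred = as.integer(class_index))
}
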