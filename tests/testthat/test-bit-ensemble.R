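test_that("bootstrap splits partition samples and are deterministic", {
  one <- bootstrap_split(1, seed = 5)
  expect_equal(one$in_bag, 1L)
  expect_length(one$oob, 0)

  for (seed in 1:20) {
    n <- sample(2:200, 1)
    bs <- bootstrap_split(n, seed = seed)
    expect_length(bs$in_bag, n)
    expect_setequal(c(unique(bs$in_bag), bs$oob), seq_len(n))
    expect_length(intersect(unique(bs$in_bag), bs$oob), 0)
  }
  expect_identical(bootstrap_split(50, 3), bootstrap_split(50, 3))
  expect_error(bootstrap_split(0), "positive")
})

test_that("the never-sampled fraction approaches (1 - 1/N)^N, about 36%", {
  n <- 500
  frac <- mean(vapply(1:200, function(s) {
    length(bootstrap_split(n, seed = s)$oob) / n
  }, numeric(1)))
  expect_equal(frac, (1 - 1 / n)^n, tolerance = 0.02)
})

test_that("random bit layers are binary, non-degenerate and deterministic", {
  withr::with_seed(1, X <- matrix(stats::rnorm(50 * 20), 50, 20))
  layer <- make_random_bits(X, 64, seed = 2)
  expect_identical(layer, make_random_bits(X, 64, seed = 2))
  B <- apply_bit_layer(layer, X)
  expect_true(all(B %in% c(0, 1)))
  # every bit column has both values on its training data
  expect_true(all(colSums(B) > 0 & colSums(B) < nrow(B)))
  expect_true(all(vapply(layer$bits, function(b) length(b$features) <= 3,
                         logical(1))))
  # balanced allocation: with 64 bits x arity <= 3 over 20 features,
  # every feature is referenced
  expect_setequal(unique(unlist(lapply(layer$bits, `[[`, "features"))), 1:20)
})

test_that("a bit thresholded at the median fires on about half the samples", {
  withr::with_seed(3, x <- stats::rnorm(100))
  layer <- structure(list(
    bits = list(list(features = 1L, weights = 1,
                     threshold = stats::median(x))),
    n_features = 1L
  ), class = "bit_layer")
  B <- apply_bit_layer(layer, matrix(x, ncol = 1))
  expect_gte(mean(B), 0.4)
  expect_lte(mean(B), 0.6)
})

test_that("boosting picks the label-matching bit first, by exact loss", {
  withr::with_seed(4, {
    labels <- rep(c("a", "b"), each = 30)
    bits <- matrix(rbinom(60 * 100, 1, 0.5), 60, 100)
    bits[, 37] <- as.numeric(labels == "b")  # a perfect bit
  })
  sel <- boost_select_bits(bits, labels, n_selected_bits = 5)
  expect_equal(sel[1], 37)

  # independent oracle: the first pick minimizes one-stump training
  # logistic loss over all bits (brute force, any leaf values on a grid)
  y <- as.numeric(labels == "b")
  stump_loss <- vapply(seq_len(ncol(bits)), function(j) {
    grid <- seq(-3, 3, by = 0.25)
    best <- Inf
    for (a0 in grid) {
      f0 <- ifelse(bits[, j] == 1, 0, a0)
      l <- vapply(grid, function(a1) {
        f <- f0 + ifelse(bits[, j] == 1, a1, 0)
        sum(log1p(exp(-(2 * y - 1) * f)))
      }, numeric(1))
      best <- min(best, min(l))
    }
    best
  }, numeric(1))
  expect_equal(which.min(stump_loss), 37)
})

test_that("boosting clamps to the available bits and validates labels", {
  labels <- rep(c("a", "b"), each = 10)
  bits <- cbind(as.numeric(labels == "b"),
                c(rep(0, 9), 1, rep(1, 9), 0),
                c(rep(0, 8), 1, 1, rep(1, 8), 0, 0))
  sel <- boost_select_bits(bits, labels, n_selected_bits = 50)
  expect_setequal(sel, 1:3)  # clamped to the available informative bits
  expect_equal(sel[1], 1)    # the perfect bit leads
  expect_error(boost_select_bits(bits, rep("a", 20), 2), ">= 2 classes")
  expect_error(boost_select_bits(bits, rep(c("a", "b", "c"), 7)[1:20], 2),
               "two classes")
})

test_that("ensembles separate a separable toy and are deterministic", {
  df <- toy_separable(n = 20)
  for (learner in c("random_bits_forest", "plain_forest")) {
    ens <- fit_bit_ensemble(df, n_trees = 50, base_learner = learner,
                            n_candidate_bits = 64, n_selected_bits = 16,
                            seed = 1)
    acc <- vapply(ens$trees, `[[`, numeric(1), "oob_accuracy")
    # mtry = 1 of 2 raw features halves the informative splits for the
    # plain forest, so its per-tree bound is looser
    expect_gte(mean(acc, na.rm = TRUE),
               if (learner == "plain_forest") 0.8 else 0.9)
    expect_gte(mean(predict(ens, df) == df$label), 0.95)
    ens2 <- fit_bit_ensemble(df, n_trees = 50, base_learner = learner,
                             n_candidate_bits = 64, n_selected_bits = 16,
                             seed = 1)
    expect_identical(
      vapply(ens$trees, `[[`, numeric(1), "oob_accuracy"),
      vapply(ens2$trees, `[[`, numeric(1), "oob_accuracy")
    )
  }
})

test_that("shuffled labels give chance-level OOB accuracy", {
  df <- toy_separable(n = 40)
  df$label <- withr::with_seed(9, sample(df$label))
  ens <- fit_bit_ensemble(df, n_trees = 60, n_candidate_bits = 64,
                          n_selected_bits = 16, seed = 2)
  acc <- vapply(ens$trees, `[[`, numeric(1), "oob_accuracy")
  maj <- max(table(df$label)) / nrow(df)
  expect_lt(abs(mean(acc, na.rm = TRUE) - maj), 0.1)
})

test_that("prediction ties go to the first-listed class and votes aggregate", {
  # hand-built ensemble: two leaf trees that always disagree
  ens <- structure(list(
    trees = list(
      list(tree = leaf_tree(1), in_bag = 1L, oob = 2L, oob_accuracy = 1,
           used_features = integer(0)),
      list(tree = leaf_tree(2), in_bag = 2L, oob = 1L, oob_accuracy = 1,
           used_features = integer(0))
    ),
    bit_layer = NULL, selected_bits = NULL,
    classes = c("first", "second"), feature_ids = "x1",
    config = list(base_learner = "plain_forest", n_trees = 2L)
  ), class = "bit_ensemble")
  X <- matrix(stats::rnorm(5), ncol = 1)
  expect_equal(predict(ens, X), rep("first", 5))

  # single-tree ensemble predicts exactly its tree
  ens$trees <- ens$trees[2]
  expect_equal(predict(ens, X), rep("second", 5))
})

test_that("plain forest agrees broadly with randomForest as a reference", {
  skip_if_not_installed("randomForest")
  sim <- simulate_expression(n_samples = 60, n_features = 50,
                             n_informative = 8, n_blocks = 10,
                             effect_size = 2, seed = 11)
  ens <- fit_bit_ensemble(sim$data, n_trees = 100,
                          base_learner = "plain_forest", seed = 3)
  mine <- mean(vapply(ens$trees, `[[`, numeric(1), "oob_accuracy"),
               na.rm = TRUE)
  X <- as.matrix(sim$data[sim$truth$feature_id])
  rf <- withr::with_seed(3,
    randomForest::randomForest(X, factor(sim$data$label), ntree = 100))
  ref <- 1 - rf$err.rate[100, "OOB"]
  expect_equal(mine, ref, tolerance = 0.15, ignore_attr = TRUE)
})

test_that("input contracts are enforced", {
  df <- toy_separable()
  expect_error(fit_bit_ensemble(df[c(1:2, 11:12), ], n_trees = 5),
               "5 samples")
  expect_error(fit_bit_ensemble(df[1:8, ], n_trees = 5), "two")
  expect_error(fit_bit_ensemble(df, n_candidate_bits = 8,
                                n_selected_bits = 16), "exceed")
  ens <- fit_bit_ensemble(df, n_trees = 5, n_candidate_bits = 32,
                          n_selected_bits = 8, seed = 1)
  expect_error(predict(ens, matrix(0, 2, 5)), "features")
})
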