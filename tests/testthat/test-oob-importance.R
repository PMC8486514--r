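test_that("the delta aggregation matches the hand-worked example", {
  agg <- rbfrce:::aggregate_deltas(c(0.2, 0.1))
  expect_equal(agg$mean_delta, 0.15)
  expect_equal(agg$variance, 0.005)  # (0.05^2 + 0.05^2) / (2 - 1)
  expect_equal(agg$fip, 0.15 / sqrt(0.005))
  expect_equal(agg$fip, 2.1213, tolerance = 1e-4)

  zero <- rbfrce:::aggregate_deltas(rep(0, 10))
  expect_equal(zero$mean_delta, 0)
  expect_equal(zero$variance, 0)
  expect_equal(zero$fip, 0)  # zero-variance convention

  # the aggregation is invariant to tree order
  withr::with_seed(1, d <- stats::rnorm(30))
  expect_equal(rbfrce:::aggregate_deltas(d),
               rbfrce:::aggregate_deltas(rev(d)))
})

test_that("importance_scores implements the aggregation it documents", {
  df <- toy_separable(n = 20)
  ens <- fit_bit_ensemble(df, n_trees = 40, base_learner = "plain_forest",
                          seed = 1)
  imp <- importance_scores(ens, df, seed = 2)
  expect_equal(imp$feature_id, c("x1", "x2"))
  lens <- lengths(imp$per_tree_delta)
  expect_length(unique(lens), 1)  # identical across features
  for (i in seq_len(nrow(imp))) {
    agg <- rbfrce:::aggregate_deltas(imp$per_tree_delta[[i]])
    expect_equal(imp$mean_delta[i], agg$mean_delta)
    expect_equal(imp$variance[i], agg$variance)
    expect_equal(imp$fip[i], agg$fip)
  }
  # the informative feature dominates
  expect_gt(imp$fip[imp$feature_id == "x1"],
            imp$fip[imp$feature_id == "x2"])
  expect_gt(imp$mean_delta[imp$feature_id == "x1"], 0)
})

test_that("permuting a feature a tree never uses leaves C_i unchanged", {
  df <- toy_separable(n = 20)
  df$junk <- 0  # constant: no tree can split on it
  ens <- fit_bit_ensemble(df, n_trees = 20, base_learner = "plain_forest",
                          seed = 3)
  for (i in c(1, 7, 13)) {
    expect_equal(
      permuted_tree_accuracy(ens, df, "junk", i, seed = 99),
      ens$trees[[i]]$oob_accuracy
    )
  }
  imp <- importance_scores(ens, df, seed = 4)
  expect_true(all(imp$per_tree_delta[[which(imp$feature_id == "junk")]] == 0))
  expect_equal(imp$fip[imp$feature_id == "junk"], 0)
})

test_that("permuting the informative feature hurts most trees", {
  df <- toy_separable(n = 24)
  ens <- fit_bit_ensemble(df, n_trees = 40, base_learner = "plain_forest",
                          seed = 5)
  drops <- vapply(seq_len(40), function(i) {
    ens$trees[[i]]$oob_accuracy -
      permuted_tree_accuracy(ens, df, "x1", i, seed = i)
  }, numeric(1))
  expect_gt(mean(drops > 0), 0.5)
  expect_gt(mean(drops), 0)
})

test_that("importance is invariant to feature relabeling and request order", {
  sim <- simulate_expression(n_samples = 40, n_features = 30,
                             n_informative = 5, n_blocks = 6,
                             effect_size = 2, seed = 6)
  ens <- fit_bit_ensemble(sim$data, n_trees = 30, n_candidate_bits = 64,
                          n_selected_bits = 32, seed = 7)
  imp <- importance_scores(ens, sim$data, seed = 8)
  # request order: reversed feature list gives the same values
  imp_rev <- importance_scores(ens, sim$data,
                               features = rev(sim$truth$feature_id), seed = 8)
  merged <- merge(imp[c("feature_id", "fip")], imp_rev[c("feature_id", "fip")],
                  by = "feature_id")
  expect_equal(merged$fip.x, merged$fip.y)

  # relabeled ids: identical matrix under new names gives identical fips
  df2 <- sim$data
  names(df2) <- sub("^f", "gene", names(df2))
  ens2 <- fit_bit_ensemble(df2, n_trees = 30, n_candidate_bits = 64,
                           n_selected_bits = 32, seed = 7)
  imp2 <- importance_scores(ens2, df2, seed = 8)
  expect_equal(imp2$fip, imp$fip)
  expect_equal(imp2$feature_id, sub("^f", "gene", imp$feature_id))
})

test_that("pure-noise features score near zero on null labels", {
  sim <- simulate_expression(n_samples = 40, n_features = 50,
                             n_informative = 0, n_blocks = 10, rho = 0,
                             effect_size = 0, seed = 9)
  ens <- fit_bit_ensemble(sim$data, n_trees = 50, n_candidate_bits = 128,
                          n_selected_bits = 32, seed = 10)
  imp <- importance_scores(ens, sim$data, seed = 11)
  expect_lt(abs(mean(imp$fip)), 0.5)
})

test_that("importance validates its inputs", {
  df <- toy_separable()
  ens <- fit_bit_ensemble(df, n_trees = 10, n_candidate_bits = 32,
                          n_selected_bits = 8, seed = 1)
  expect_error(importance_scores(ens, df, features = "nope"), "unknown feature")
  expect_error(permuted_tree_accuracy(ens, df, "nope", 1), "unknown feature")
  expect_error(permuted_tree_accuracy(ens, df, "x1", 99), "out of range")
})
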