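test_that("cluster scores take the best member", {
  fip <- c(a = 0.5, b = 1.2, c = 0.3, d = -0.2, e = 0)
  expect_equal(score_cluster(c("a", "b", "c"), fip), 1.2)
  expect_equal(score_cluster("d", fip), -0.2)
  expect_equal(score_cluster(c("e"), fip), 0)
  expect_error(score_cluster(character(0), fip), "nonempty")
  expect_error(score_cluster(c("a", "zz"), fip), "zz")
})

# small but non-trivial selection problem shared by the loop tests
rce_fixture <- function(seed = 1) {
  simulate_expression(n_samples = 40, n_features = 120, n_informative = 6,
                      n_blocks = 12, rho = 0.6, effect_size = 3, seed = seed)
}

fast_rce <- function(data, ...) {
  rbf_rce(data, n_trees = 40, n_candidate_bits = 128, n_selected_bits = 32,
          ...)
}

test_that("the elimination loop shrinks monotonically to the target", {
  sim <- rce_fixture()
  res <- fast_rce(sim$data, target_features = 15, n_clusters = 10,
                  switch_threshold = 5, seed = 2)
  expect_s3_class(res, "rce_result")
  expect_length(res$selected, 15)
  # ranking is a permutation of all original features
  expect_setequal(res$ranking$feature_id, sim$truth$feature_id)
  expect_equal(res$ranking$rank, seq_len(120))
  # per-round deletions are nonempty, so counts strictly decrease
  per_round <- table(res$log$iteration)
  expect_true(all(per_round >= 1))
  expect_equal(sum(per_round), 120 - length(setdiff(sim$truth$feature_id,
                                                    res$log$feature_id)))
  # nothing deleted twice
  expect_false(anyDuplicated(res$log$feature_id) > 0)
})

test_that("cluster rounds delete ceil(drop_fraction x clusters) clusters", {
  sim <- rce_fixture(seed = 3)
  res <- fast_rce(sim$data, target_features = 10, n_clusters = 10,
                  drop_fraction = 0.1, switch_threshold = 4, seed = 3)
  log <- res$log
  cl <- cluster_features(sim$data, n_clusters = 10,
                         seed = rbfrce:::derive_seed(3, 13))
  live <- 10L
  for (it in unique(log$iteration[log$phase == "cluster_elimination"])) {
    deleted <- log$feature_id[log$iteration == it]
    del_clusters <- unique(cl$cluster[cl$feature_id %in% deleted])
    expect_length(del_clusters, ceiling(0.1 * live))
    # whole clusters leave together (no partial deletion before the cap)
    members <- cl$feature_id[cl$cluster %in% del_clusters]
    still_active <- setdiff(members, log$feature_id[log$iteration <= it])
    expect_length(still_active, 0)
    live <- live - length(del_clusters)
  }
  # the switch happened: later rounds are feature-level
  expect_true("feature_elimination" %in% log$phase)
})

test_that("the phase switches when clusters drop below the threshold", {
  sim <- rce_fixture(seed = 4)
  # initial clusters (6) already below threshold (30): feature phase only
  res <- fast_rce(sim$data, target_features = 30, n_clusters = 6,
                  switch_threshold = 30, seed = 4)
  expect_true(all(res$log$phase == "feature_elimination"))

  # threshold 1: cluster phase all the way down
  res2 <- fast_rce(sim$data, target_features = 30, n_clusters = 6,
                   switch_threshold = 1, seed = 4)
  expect_true(all(res2$log$phase == "cluster_elimination"))
})

test_that("feature rounds delete the lowest-fip fraction, capped at target", {
  sim <- rce_fixture(seed = 5)
  res <- fast_rce(sim$data, target_features = 100, n_clusters = 5,
                  switch_threshold = 30, feature_drop_fraction = 0.1,
                  seed = 5)
  # 120 -> ceil(12) = 12 deleted, but cap at 120 - 100 = 20: one round
  expect_equal(res$n_rounds, 2)
  expect_equal(sum(res$log$iteration == 1), 12)
  expect_equal(sum(res$log$iteration == 2), 8)  # capped partial batch
  expect_length(res$selected, 100)
})

test_that("a target at or above p degenerates to one importance fit", {
  sim <- rce_fixture(seed = 6)
  res <- fast_rce(sim$data, target_features = 120, seed = 6)
  expect_equal(res$n_rounds, 0)
  expect_equal(nrow(res$log), 0)
  expect_length(res$selected, 120)
  # ranking ordered by the single fit's fip, descending
  expect_true(all(diff(res$ranking$score) <= 1e-12))
})

test_that("selection is deterministic end to end", {
  sim <- rce_fixture(seed = 7)
  r1 <- fast_rce(sim$data, target_features = 20, seed = 8)
  r2 <- fast_rce(sim$data, target_features = 20, seed = 8)
  expect_identical(r1$ranking, r2$ranking)
  expect_identical(r1$log, r2$log)
  r3 <- fast_rce(sim$data, target_features = 20, seed = 9)
  expect_false(identical(r1$ranking$feature_id, r3$ranking$feature_id))
})

test_that("reclustering each round preserves the loop contract", {
  sim <- rce_fixture(seed = 10)
  res <- fast_rce(sim$data, target_features = 20, n_clusters = 10,
                  switch_threshold = 4, recluster_each_round = TRUE,
                  seed = 10)
  expect_length(res$selected, 20)
  expect_setequal(res$ranking$feature_id, sim$truth$feature_id)
})

test_that("strong planted signal survives the elimination", {
  sim <- rce_fixture(seed = 11)
  inf <- sim$truth$feature_id[sim$truth$informative]
  res <- fast_rce(sim$data, target_features = 20, seed = 11)
  expect_gte(sum(res$selected %in% inf), 4)  # >= 2/3 of 6 planted
})

test_that("tidy, glance and autoplot expose the result", {
  sim <- rce_fixture(seed = 12)
  res <- fast_rce(sim$data, target_features = 60, seed = 12)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("rank", "feature_id", "score"))
  g <- glance(res)
  expect_equal(g$n_features, 120)
  expect_equal(g$n_selected, 60)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
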