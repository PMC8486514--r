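#' Score a feature cluster
#'
#' A feature class is scored by its best member:
#' `Score(S) = max over members of fip`.
#'
#' @param member_ids nonempty character vector of member feature ids.
#' @param fip named numeric vector of importance scores covering every
#'   member.
#' @return The maximum member `fip`.
#' @export
score_cluster <- function(member_ids, fip) {
  if (length(member_ids) == 0) abort_bad_arg("cluster must be nonempty")
  miss <- setdiff(member_ids, names(fip))
  if (length(miss) > 0) {
    abort_bad_arg(sprintf("no importance value for member(s): %s",
                          paste(utils::head(miss, 5), collapse = ", ")))
  }
  max(fip[member_ids])
}

# One elimination round. `state` carries: iteration, active (character),
# clusters (tibble feature_id/cluster or NULL in feature phase), phase,
# log (list of tibbles), last_importance. Returns the updated state.
rce_round <- function(state, lm, config) {
  if (length(state$active) <= config$target_features) {
    warning("already at or below target_features; no-op", call. = FALSE)
    return(state)
  }
  iter <- state$iteration + 1L
  round_seed <- config$round_seeds[iter]
  lm_act <- lm_subset(lm, features = state$active)
  ens <- fit_bit_ensemble(
    lm_act,
    n_trees = config$n_trees, base_learner = config$base_learner,
    n_candidate_bits = config$n_candidate_bits,
    n_selected_bits = config$n_selected_bits,
    max_depth = config$max_depth, seed = round_seed
  )
  imp <- importance_scores(ens, lm_act, seed = derive_seed(round_seed, 7),
                           keep_deltas = FALSE)
  fip <- stats::setNames(imp$fip, imp$feature_id)
  cap <- length(state$active) - config$target_features

  if (state$phase == "cluster_elimination") {
    live <- state$clusters[state$clusters$feature_id %in% state$active, ]
    split_members <- split(live$feature_id, live$cluster)
    split_members <- split_members[lengths(split_members) > 0]
    scores <- vapply(split_members, score_cluster, numeric(1), fip = fip)
    # deletion order: score ascending; ties -> cluster holding the
    # lexicographically smallest feature id first
    min_member <- vapply(split_members, min, character(1))
    ord <- order(scores, min_member)
    n_del <- ceiling(config$drop_fraction * length(split_members))
    batch <- ord[seq_len(min(n_del, length(ord)))]
    # within the batch, features leave lowest-fip-first (ties: lex id)
    del <- unlist(lapply(batch, function(ci) {
      mem <- split_members[[ci]]
      mem[order(fip[mem], mem)]
    }), use.names = FALSE)
    del_scores <- rep(scores[batch], lengths(split_members[batch]))
    if (length(del) > cap) {  # partial deletion of the last batch
      del_scores <- del_scores[seq_len(cap)]
      del <- del[seq_len(cap)]
    }
    state$active <- setdiff(state$active, del)
    live_after <- sum(vapply(split_members,
                             function(m) any(m %in% state$active), logical(1)))
    if (live_after < config$switch_threshold) state$phase <- "feature_elimination"
    deleted_tbl <- tibble::tibble(
      iteration = iter, phase = "cluster_elimination",
      feature_id = del, score = unname(del_scores)
    )
  } else {
    ord <- state$active[order(fip[state$active], state$active)]
    n_del <- min(ceiling(config$feature_drop_fraction * length(state$active)),
                 cap)
    del <- ord[seq_len(n_del)]
    state$active <- setdiff(state$active, del)
    deleted_tbl <- tibble::tibble(
      iteration = iter, phase = "feature_elimination",
      feature_id = del, score = unname(fip[del])
    )
  }

  if (config$recluster_each_round && state$phase == "cluster_elimination" &&
      length(state$active) > config$target_features) {
    k_new <- min(ceiling(sqrt(length(state$active))), length(state$active))
    state$clusters <- cluster_features(
      lm, n_clusters = k_new, active_features = state$active,
      max_iterations = config$max_cluster_iterations,
      seed = derive_seed(round_seed, 11)
    )
    if (k_new < config$switch_threshold) state$phase <- "feature_elimination"
  }

  state$iteration <- iter
  state$log[[iter]] <- deleted_tbl
  state$last_importance <- imp
  state
}

#' RBF-RCE recursive cluster-elimination feature selection
#'
#' Runs the full selection loop: features are clustered by correlation
#' distance ([cluster_features()]); each round a bootstrap ensemble is
#' refit on the surviving features ([fit_bit_ensemble()]), OOB
#' permutation importance is computed ([importance_scores()]), clusters
#' are scored by their best member ([score_cluster()]) and the
#' lowest-scoring fraction of clusters is deleted wholesale. Once fewer
#' than `switch_threshold` clusters remain, elimination switches to
#' individual features (lowest `fip` first). The loop stops at
#' `target_features` or fewer; the final batch is cut lowest-scores
#' first so the count never undershoots the target.
#'
#' The returned ranking covers every original feature: survivors first,
#' ordered by final-round `fip` descending, then eliminated features in
#' reverse deletion order (later-deleted = more important).
#'
#' @param data data frame (samples x features plus a label column) or
#'   `labeled_matrix`. Two or more classes;
#'   `"random_bits_forest"` requires exactly two.
#' @param label_col label column name (default `"label"`).
#' @param target_features stop when at most this many features remain
#'   (default 50).
#' @param drop_fraction fraction of clusters deleted per round
#'   (default 0.1).
#' @param switch_threshold cluster count below which elimination
#'   switches to the feature level (default 30).
#' @param feature_drop_fraction fraction of features deleted per
#'   feature-level round (default 0.1).
#' @param n_clusters initial number of feature clusters; default
#'   `ceiling(sqrt(p))`.
#' @param recluster_each_round recluster surviving features after every
#'   cluster-phase round (default FALSE: cluster once, carry the
#'   partition).
#' @param max_cluster_iterations K-means iteration cap (default 300).
#' @param n_trees,base_learner,n_candidate_bits,n_selected_bits,max_depth
#'   ensemble configuration, see [fit_bit_ensemble()].
#' @param seed integer seed; the whole run is deterministic given it.
#'
#' @return An object of class `rce_result` with elements:
#'   \describe{
#'     \item{ranking}{tibble `rank`, `feature_id`, `score` over all
#'       original features.}
#'     \item{selected}{the top `target_features` ids.}
#'     \item{log}{elimination log tibble: `iteration`, `phase`,
#'       `feature_id`, `score` at deletion.}
#'     \item{n_rounds}{rounds executed.}
#'   }
#'   Methods: [tidy()][generics::tidy()], [glance()][generics::glance()],
#'   [autoplot()][ggplot2::autoplot()].
#' @examples
#' sim <- simulate_expression(n_samples = 30, n_features = 80,
#'                            n_informative = 5, n_blocks = 8, seed = 1)
#' res <- rbf_rce(sim$data, target_features = 10, n_trees = 30,
#'                n_candidate_bits = 128, n_selected_bits = 32, seed = 1)
#' head(tidy(res))
#' @export
rbf_rce <- function(data, label_col = "label",
                    target_features = 50,
                    drop_fraction = 0.1,
                    switch_threshold = 30,
                    feature_drop_fraction = 0.1,
                    n_clusters = NULL,
                    recluster_each_round = FALSE,
                    max_cluster_iterations = 300,
                    n_trees = 200,
                    base_learner = c("random_bits_forest", "plain_forest"),
                    n_candidate_bits = 1024,
                    n_selected_bits = 128,
                    max_depth = 30,
                    seed = 0) {
  base_learner <- match.arg(base_learner)
  lm <- as_labeled_matrix(data, label_col)
  require_two_classes(lm)
  p <- length(lm$feature_ids)
  target_features <- check_positive_int(target_features, "target_features")
  check_fraction(drop_fraction, "drop_fraction")
  check_fraction(feature_drop_fraction, "feature_drop_fraction")
  switch_threshold <- check_positive_int(switch_threshold, "switch_threshold")
  n_clusters <- n_clusters %||% ceiling(sqrt(p))
  n_clusters <- check_positive_int(min(n_clusters, p), "n_clusters")

  max_rounds <- 10L * (ceiling(log(max(p, 2)) /
                                 -log(1 - min(drop_fraction,
                                              feature_drop_fraction))) + 10L)
  config <- list(
    target_features = target_features, drop_fraction = drop_fraction,
    switch_threshold = switch_threshold,
    feature_drop_fraction = feature_drop_fraction,
    recluster_each_round = recluster_each_round,
    max_cluster_iterations = max_cluster_iterations,
    n_trees = n_trees, base_learner = base_learner,
    n_candidate_bits = n_candidate_bits, n_selected_bits = n_selected_bits,
    max_depth = max_depth, seed = seed,
    round_seeds = withr::with_seed(derive_seed(seed, 97),
                                   sample.int(2147483646L, max_rounds))
  )

  state <- list(
    iteration = 0L,
    active = lm$feature_ids,
    clusters = NULL,
    phase = "cluster_elimination",
    log = list(),
    last_importance = NULL
  )
  if (p > target_features) {
    state$clusters <- cluster_features(
      lm, n_clusters = n_clusters, max_iterations = max_cluster_iterations,
      seed = derive_seed(seed, 13)
    )
    if (n_clusters < switch_threshold) state$phase <- "feature_elimination"
    while (length(state$active) > target_features) {
      n_before <- length(state$active)
      state <- rce_round(state, lm, config)
      stopifnot(length(state$active) < n_before)
    }
  }

  # final importance for the survivor ordering
  if (is.null(state$last_importance) ||
      !all(state$active %in% state$last_importance$feature_id)) {
    fin_seed <- config$round_seeds[state$iteration + 1L]
    ens <- fit_bit_ensemble(
      lm_subset(lm, features = state$active),
      n_trees = n_trees, base_learner = base_learner,
      n_candidate_bits = n_candidate_bits, n_selected_bits = n_selected_bits,
      max_depth = max_depth, seed = fin_seed
    )
    state$last_importance <- importance_scores(
      ens, lm_subset(lm, features = state$active),
      seed = derive_seed(fin_seed, 7), keep_deltas = FALSE
    )
  }
  imp <- state$last_importance
  surv_fip <- stats::setNames(imp$fip, imp$feature_id)[state$active]
  survivors <- state$active[order(-surv_fip, state$active)]
  log_tbl <- if (length(state$log) > 0) {
    dplyr::bind_rows(state$log)
  } else {
    tibble::tibble(iteration = integer(), phase = character(),
                   feature_id = character(), score = numeric())
  }
  eliminated <- rev(log_tbl$feature_id)
  elim_scores <- rev(log_tbl$score)
  ranking <- tibble::tibble(
    rank = seq_len(p),
    feature_id = c(survivors, eliminated),
    score = c(unname(surv_fip[survivors]), elim_scores)
  )
  stopifnot(setequal(ranking$feature_id, lm$feature_ids))

  structure(list(
    ranking = ranking,
    selected = utils::head(ranking$feature_id, target_features),
    log = log_tbl,
    n_rounds = state$iteration,
    n_features = p,
    target_features = target_features,
    classes = lm$classes,
    config = config[setdiff(names(config), "round_seeds")]
  ), class = "rce_result")
}

#' @export
print.rce_result <- function(x, ...) {
  cat(sprintf(
    "<rce_result> %d -> %d features in %d rounds (%s)\n",
    x$n_features, length(x$selected), x$n_rounds, x$config$base_learner
  ))
  cat("top features:", paste(utils::head(x$selected, 8), collapse = ", "),
      "...\n")
  invisible(x)
}

#' @rdname rbf_rce
#' @param x,object an `rce_result`.
#' @param ... unused.
#' @export
tidy.rce_result <- function(x, ...) x$ranking

#' @rdname rbf_rce
#' @export
glance.rce_result <- function(x, ...) {
  tibble::tibble(
    n_features = x$n_features,
    n_selected = length(x$selected),
    n_rounds = x$n_rounds,
    n_cluster_rounds = length(unique(
      x$log$iteration[x$log$phase == "cluster_elimination"])),
    base_learner = x$config$base_learner,
    seed = x$config$seed
  )
}

#' @rdname rbf_rce
#' @export
autoplot.rce_result <- function(object, ...) {
  traj <- object$log |>
    dplyr::count(.data$iteration, .data$phase, name = "deleted") |>
    dplyr::arrange(.data$iteration) |>
    dplyr::mutate(remaining = object$n_features - cumsum(.data$deleted))
  traj <- dplyr::bind_rows(
    tibble::tibble(iteration = 0L, phase = traj$phase[1] %||% "start",
                   deleted = 0L, remaining = object$n_features),
    traj
  )
  ggplot2::ggplot(traj, ggplot2::aes(.data$iteration, .data$remaining)) +
    ggplot2::geom_step(linewidth = 0.4, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$phase), size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "elimination round", y = "features remaining",
                  colour = "phase",
                  title = "RBF-RCE elimination trajectory") +
    ggplot2::theme_minimal()
}
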