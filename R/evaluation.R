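#' Repeated stratified holdout evaluation of feature-selection methods
#'
#' The experimental protocol behind accuracy and stability comparisons:
#' for each of `n_repeats` repeats, the data are split into a stratified
#' training fraction (default 2/3) and a test third; each method selects
#' features on the training split only; the same ensemble family is
#' refit on the selected top `target_features` and scored on the test
#' split; the per-repeat full rankings feed stability-versus-k curves
#' ([stability_curve()]).
#'
#' Methods:
#' * `"rbf_rce"` — the full [rbf_rce()] loop.
#' * `"plain_forest_importance"` — rank all features by a single plain
#'   random forest's OOB permutation importance (no elimination), the
#'   traditional forest baseline.
#'
#' @param data data frame (samples x features plus label column) or
#'   `labeled_matrix`; at least 9 samples.
#' @param label_col label column name (default `"label"`).
#' @param methods character subset of
#'   `c("rbf_rce", "plain_forest_importance")`.
#' @param n_repeats holdout repeats (default 10).
#' @param train_fraction training fraction (default 2/3). Per-class
#'   training counts are clamped so both splits contain every class.
#' @param k_grid increasing subset sizes for the stability curves
#'   (default `c(10, 20, 50)` clipped to the feature count).
#' @param target_features features kept by each method for the accuracy
#'   refit (default 50, clipped to the feature count).
#' @param seed integer seed; the whole harness is deterministic given it.
#' @param ... further arguments passed to [rbf_rce()] and, where they
#'   apply, to [fit_bit_ensemble()] for the baseline and the accuracy
#'   refits (e.g. `n_trees`, `n_candidate_bits`, `n_selected_bits`).
#'
#' @return An object of class `eval_result`: per method
#'   `mean_accuracy`, `per_repeat_accuracy`, `rankings` (list of full
#'   per-repeat rankings) and `stability` (a [stability_curve()]
#'   tibble). Methods: `tidy()`, `glance()`,
#'   [autoplot()][ggplot2::autoplot()].
#' @export
run_evaluation <- function(data, label_col = "label",
                           methods = c("rbf_rce", "plain_forest_importance"),
                           n_repeats = 10,
                           train_fraction = 2 / 3,
                           k_grid = c(10, 20, 50),
                           target_features = 50,
                           seed = 0, ...) {
  methods <- match.arg(methods, several.ok = TRUE)
  lm <- as_labeled_matrix(data, label_col)
  require_two_classes(lm)
  n <- length(lm$sample_ids)
  if (n < 9) abort_bad_arg("at least 9 samples are required")
  n_repeats <- check_positive_int(n_repeats, "n_repeats")
  check_fraction(train_fraction, "train_fraction")
  p <- length(lm$feature_ids)
  target_features <- min(check_positive_int(target_features, "target_features"), p)
  k_grid <- sort(unique(pmin(as.integer(k_grid), p)))

  dots <- list(...)
  ens_args <- dots[intersect(names(dots),
                             c("n_trees", "n_candidate_bits",
                               "n_selected_bits", "max_depth"))]

  splits <- lapply(seq_len(n_repeats), function(r) {
    stratified_split(lm$labels, train_fraction, derive_seed(seed, 41, r))
  })

  per_method <- list()
  for (method in methods) {
    accs <- numeric(n_repeats)
    rankings <- vector("list", n_repeats)
    for (r in seq_len(n_repeats)) {
      tr_idx <- splits[[r]]$train
      te_idx <- splits[[r]]$test
      lm_tr <- lm_subset(lm, samples = tr_idx)
      m_seed <- derive_seed(seed, 43, r)
      if (method == "rbf_rce") {
        fit <- do.call(rbf_rce, c(
          list(data = lm_tr, target_features = target_features, seed = m_seed),
          dots
        ))
        ranking <- fit$ranking$feature_id
      } else {
        ens <- do.call(fit_bit_ensemble, c(
          list(data = lm_tr, base_learner = "plain_forest", seed = m_seed),
          ens_args
        ))
        imp <- importance_scores(ens, lm_tr, seed = derive_seed(m_seed, 7),
                                 keep_deltas = FALSE)
        ranking <- imp$feature_id[order(-imp$fip, imp$feature_id)]
      }
      rankings[[r]] <- ranking
      sel <- ranking[seq_len(target_features)]
      refit <- do.call(fit_bit_ensemble, c(
        list(data = lm_subset(lm_tr, features = sel),
             base_learner = if (method == "rbf_rce") "random_bits_forest"
                            else "plain_forest",
             seed = derive_seed(m_seed, 5)),
        ens_args
      ))
      pred <- predict(refit, lm$values[te_idx, sel, drop = FALSE])
      accs[r] <- mean(pred == lm$labels[te_idx])
    }
    curve <- stability_curve(rankings, k_grid)
    per_method[[method]] <- list(
      mean_accuracy = mean(accs),
      per_repeat_accuracy = accs,
      rankings = rankings,
      stability = curve
    )
  }

  structure(list(
    per_method = per_method,
    n_repeats = n_repeats,
    train_fraction = train_fraction,
    k_grid = k_grid,
    target_features = target_features,
    seed = seed
  ), class = "eval_result")
}

# Stratified train/test split: per class, round(train_fraction * n_c)
# training samples, clamped to [1, n_c - 1] so every class appears in
# both splits. Deterministic given the seed.
stratified_split <- function(labels, train_fraction, seed) {
  idx_by_class <- split(seq_along(labels), labels)
  if (any(lengths(idx_by_class) < 2)) {
    abort_bad_arg("every class needs at least 2 samples for a stratified split")
  }
  withr::with_seed(seed, {
    train <- unlist(lapply(idx_by_class, function(idx) {
      n_tr <- min(max(round(train_fraction * length(idx)), 1L),
                  length(idx) - 1L)
      sample(idx, n_tr)
    }), use.names = FALSE)
  })
  list(train = sort(train),
       test = setdiff(seq_along(labels), train))
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %d repeats, train fraction %.2f, target %d\n",
              x$n_repeats, x$train_fraction, x$target_features))
  for (m in names(x$per_method)) {
    cat(sprintf("  %-25s mean accuracy %.3f\n", m,
                x$per_method[[m]]$mean_accuracy))
  }
  invisible(x)
}

#' @rdname run_evaluation
#' @param x,object an `eval_result`.
#' @export
tidy.eval_result <- function(x, ...) {
  purrr::imap_dfr(x$per_method, function(res, m) {
    tibble::tibble(method = m, repeat_index = seq_along(res$per_repeat_accuracy),
                   accuracy = res$per_repeat_accuracy)
  })
}

#' @rdname run_evaluation
#' @export
glance.eval_result <- function(x, ...) {
  purrr::imap_dfr(x$per_method, function(res, m) {
    tibble::tibble(
      method = m,
      mean_accuracy = res$mean_accuracy,
      sd_accuracy = stats::sd(res$per_repeat_accuracy),
      mean_sim_at_max_k = res$stability$mean_sim[nrow(res$stability)],
      n_repeats = x$n_repeats
    )
  })
}

#' Stability curves of an evaluation, one row per method and k
#'
#' @param x an `eval_result`.
#' @return A `stability_curve` tibble with a `method` column.
#' @export
eval_stability_curves <- function(x) {
  out <- purrr::imap_dfr(x$per_method, function(res, m) {
    dplyr::mutate(tibble::as_tibble(res$stability), method = m)
  })
  class(out) <- c("stability_curve", class(out))
  out
}

#' @rdname run_evaluation
#' @export
autoplot.eval_result <- function(object, ...) {
  autoplot.stability_curve(eval_stability_curves(object))
}
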