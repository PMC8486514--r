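#' Simulate high-dimensional small-sample expression data
#'
#' Generates a two-class samples-by-features matrix shaped like a
#' microarray study (thousands of features, tens of samples) with a
#' small planted set of class-informative features embedded in
#' correlated feature blocks.
#'
#' Each feature belongs to one of `n_blocks` contiguous blocks and is
#' built as `noise_sd * (sqrt(rho) * block_factor + sqrt(1 - rho) *
#' idiosyncratic)`, with standard-normal latent factors, so that any two
#' features in the same block have correlation `rho` in expectation and
#' unit-variance noise scale `noise_sd`. Class labels are drawn first
#' (Bernoulli `class_balance` for the second class, `"case"`); the
#' `n_informative` informative features — spread round-robin across
#' blocks — additionally get a mean shift of `effect_size * noise_sd`
#' in class `"case"`.
#'
#' @param n_samples,n_features matrix dimensions. Defaults 60 x 2000.
#' @param n_informative number of planted class-informative features
#'   (default 20). Must not exceed `n_features`.
#' @param n_blocks number of correlated feature blocks (default 50).
#' @param rho within-block feature-feature correlation in `[0, 1)`
#'   (default 0.6).
#' @param effect_size class mean shift on informative features, in
#'   units of `noise_sd` (default 1.5).
#' @param noise_sd marginal feature standard deviation (default 1).
#' @param class_balance probability of the `"case"` class (default 0.5).
#' @param seed integer seed; the output is bit-identical for a given
#'   seed (default 0).
#'
#' @return A list with:
#'   \describe{
#'     \item{data}{tibble with columns `sample_id`, `label` and one
#'       numeric column per feature (`f0001`, ...).}
#'     \item{truth}{tibble with columns `feature_id`, `block`,
#'       `informative` — the planted ground truth.}
#'   }
#' @examples
#' sim <- simulate_expression(n_samples = 20, n_features = 50,
#'                            n_informative = 5, n_blocks = 10, seed = 1)
#' dim(sim$data)
#' sum(sim$truth$informative)
#' @export
simulate_expression <- function(n_samples = 60,
                                n_features = 2000,
                                n_informative = 20,
                                n_blocks = 50,
                                rho = 0.6,
                                effect_size = 1.5,
                                noise_sd = 1,
                                class_balance = 0.5,
                                seed = 0) {
  n_samples <- check_positive_int(n_samples, "n_samples")
  n_features <- check_positive_int(n_features, "n_features")
  n_blocks <- check_positive_int(n_blocks, "n_blocks")
  if (n_informative < 0 || n_informative != floor(n_informative)) {
    abort_bad_arg("`n_informative` must be a non-negative integer")
  }
  if (n_informative > n_features) {
    abort_bad_arg("`n_informative` must not exceed `n_features`")
  }
  if (n_blocks > n_features) {
    abort_bad_arg("`n_blocks` must not exceed `n_features`")
  }
  if (rho < 0 || rho >= 1) abort_bad_arg("`rho` must be in [0, 1)")
  if (effect_size < 0) abort_bad_arg("`effect_size` must be >= 0")
  if (noise_sd <= 0) abort_bad_arg("`noise_sd` must be > 0")
  check_fraction(class_balance, "class_balance")

  feature_ids <- sprintf(paste0("f%0", max(4, nchar(n_features)), "d"),
                         seq_len(n_features))
  block <- sort(rep_len(seq_len(n_blocks), n_features))

  withr::with_seed(seed, {
    # informative features spread round-robin across blocks, at a random
    # position within each block so their ids carry no ordering signal
    members <- split(seq_len(n_features), block)
    informative_idx <- integer(n_informative)
    for (i in seq_len(n_informative)) {
      b <- ((i - 1L) %% n_blocks) + 1L
      while (length(members[[b]]) == 0) b <- (b %% n_blocks) + 1L
      pick <- members[[b]][sample.int(length(members[[b]]), 1)]
      members[[b]] <- setdiff(members[[b]], pick)
      informative_idx[i] <- pick
    }
    informative <- seq_len(n_features) %in% informative_idx
    labels <- ifelse(stats::runif(n_samples) < class_balance, "case", "control")
    block_factor <- matrix(stats::rnorm(n_samples * n_blocks),
                           n_samples, n_blocks)
    eps <- matrix(stats::rnorm(n_samples * n_features), n_samples, n_features)
    values <- noise_sd *
      (sqrt(rho) * block_factor[, block, drop = FALSE] + sqrt(1 - rho) * eps)
    if (n_informative > 0) {
      shift <- effect_size * noise_sd
      values[labels == "case", informative_idx] <-
        values[labels == "case", informative_idx] + shift
    }
  })
  colnames(values) <- feature_ids

  list(
    data = dplyr::bind_cols(
      tibble::tibble(sample_id = paste0("s", seq_len(n_samples)),
                     label = labels),
      tibble::as_tibble(values)
    ),
    truth = tibble::tibble(
      feature_id = feature_ids, block = block, informative = informative
    )
  )
}
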