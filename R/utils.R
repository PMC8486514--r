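# Internal helpers shared across modules.

# Deterministic child-seed derivation. Mixes up to four integer components
# into a single seed < 2^31 so every randomized stage can be re-run in
# isolation. Products stay < 2^53 so double arithmetic is exact.
derive_seed <- function(...) {
  parts <- vapply(list(...), function(x) as.numeric(x)[1], numeric(1))
  mult <- c(1, 7919, 104729, 1299709)[seq_along(parts)]
  as.integer((sum((parts %% 2147483629) * mult) %% 2147483629) + 1)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_bad_arg <- function(msg) stop(msg, call. = FALSE)

check_positive_int <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x < 1 || x != floor(x)) {
    abort_bad_arg(sprintf("`%s` must be a single positive integer", name))
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x <= 0 || x >= 1) {
    abort_bad_arg(sprintf("`%s` must be a single number in (0, 1)", name))
  }
  as.numeric(x)
}
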