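# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_config <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "transdx_config_error")
}

abort_format <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "transdx_format_error")
}

abort_infeasible <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "transdx_infeasible_error")
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= 1
}

is_prob <- function(x) is.numeric(x) && length(x) == 1L && x >= 0 && x <= 1

#' @noRd
draw_seed <- function(n = 1L) sample.int(.Machine$integer.max, n)

# Stratified train indices: round(train_fraction * n_c) per class, clamped so
# both portions keep at least one member of every class.
stratified_train_idx <- function(y, train_fraction) {
  idx <- integer(0)
  for (lev in levels(y)) {
    rows <- which(y == lev)
    n_tr <- round(train_fraction * length(rows))
    n_tr <- min(max(n_tr, 1L), length(rows) - 1L)
    idx <- c(idx, sample(rows, n_tr))
  }
  sort(idx)
}

# Stratified fold labels in 1..k, balanced within each class.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lev in levels(y)) {
    rows <- which(y == lev)
    fold[rows] <- sample(rep_len(seq_len(k), length(rows)))
  }
  fold
}
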