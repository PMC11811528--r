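# The conservative chance-level significance criterion and FDR correction
# across feature sets.
#
# The criterion standardizes the mean of the split-wise validation
# accuracies by their *standard deviation* — not the standard error — and
# refers the statistic to the upper tail of a Student t distribution whose
# degrees of freedom equal the number of shuffle-splits.  Dividing by the
# standard deviation rather than sd/sqrt(n) makes the criterion a factor
# sqrt(n) more stringent than a one-sample t-test against chance: it asks
# whether the whole accuracy distribution sits above the chance line, not
# merely its mean.

#' Conservative test of classification above chance
#'
#' Computes `t = (mean(acc) - chance) / sd(acc)` and the one-sided upper
#' tail probability of Student's t with `df = n_splits` (the number of
#' shuffle-splits, used literally as the degrees of freedom).
#'
#' Zero-variance accuracy vectors are degenerate: the tail probability is
#' reported as the limit 0 when the mean exceeds chance, 0.5 at chance, and
#' 1 below chance, with `degenerate = TRUE`.
#'
#' @param accuracies a `split_accuracies` object or numeric vector of
#'   per-split accuracies in `[0, 1]` (length >= 2).
#' @param chance chance-level accuracy (0.5 for balanced binary).
#' @param alpha significance threshold.
#' @return a `significance_result` list: `mean_accuracy`, `std_accuracy`,
#'   `t_value`, `df`, `p_uncorrected`, `significant_uncorrected`,
#'   `degenerate`, plus the cell identity when available.
#' @export
chance_test <- function(accuracies, chance = 0.5, alpha = 0.05) {
  cell <- list()
  if (inherits(accuracies, "split_accuracies")) {
    cell <- accuracies$cell
    acc <- accuracies$accuracies
  } else acc <- as.numeric(accuracies)
  if (length(acc) < 2) abort_config("need at least two split accuracies")
  if (any(acc < 0 | acc > 1)) abort_config("accuracies must lie in [0, 1]")
  m <- mean(acc); s <- stats::sd(acc); df <- length(acc)
  degenerate <- s == 0
  if (degenerate) {
    t_val <- if (m > chance) Inf else if (m < chance) -Inf else 0
    p <- if (m > chance) 0 else if (m < chance) 1 else 0.5
  } else {
    t_val <- (m - chance) / s
    p <- stats::pt(t_val, df = df, lower.tail = FALSE)
  }
  structure(list(mean_accuracy = m, std_accuracy = s, t_value = t_val,
                 df = df, p_uncorrected = p,
                 significant_uncorrected = is.finite(p) && p < alpha,
                 degenerate = degenerate, cell = cell),
            class = "significance_result")
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' @param p_values vector of uncorrected p-values in (0, 1].
#' @param alpha significance threshold applied to the corrected values.
#' @return list with `p_adjusted` (step-up adjusted values, in (0, 1]) and
#'   `significant` (`p_adjusted < alpha`); empty input gives empty output.
#' @export
fdr_correct <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0)
    return(list(p_adjusted = numeric(0), significant = logical(0)))
  if (any(p_values <= 0 | p_values > 1))
    abort_config("p-values must lie in (0, 1]")
  adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, significant = adj < alpha)
}

#' Assemble the per-cell results table with FDR across feature sets
#'
#' Applies Benjamini-Hochberg correction within each (group, model) pair
#' across exactly the feature sets named in `scope` (e.g. the 2 structural
#' sets for the primary analysis, or all 20 sets for the expanded one — a
#' wider scope carries a heavier correction burden, so a cell significant
#' under a narrow scope can lose significance as the scope widens).  No
#' correction is applied across diagnostic groups.
#'
#' @param cells tibble with columns `group`, `feature_set`, `model`,
#'   `n_splits`, `mean_acc`, `std_acc`, `t`, `p_uncorrected` (see
#'   [summarize_cells()]).
#' @param scope character vector of feature-set names to correct across;
#'   every (group, scope set, model) cell must be present.
#' @param alpha significance threshold on corrected p-values.
#' @param trend_upper upper edge of the trend band (`alpha <= p <
#'   trend_upper`).
#' @return the scoped rows of `cells` with added `p_fdr`, `significant`,
#'   `trend` columns.
#' @export
build_results_table <- function(cells, scope = unique(cells$feature_set),
                                alpha = 0.05, trend_upper = 0.10) {
  cells <- cells[cells$feature_set %in% scope, , drop = FALSE]
  combos <- unique(cells[, c("group", "model")])
  for (i in seq_len(nrow(combos))) {
    sel <- cells$group == combos$group[i] & cells$model == combos$model[i]
    missing <- setdiff(scope, cells$feature_set[sel])
    if (length(missing) > 0)
      abort_config("missing cell: group %s, model %s, feature set %s",
                   combos$group[i], combos$model[i], missing[1])
  }
  cells$p_fdr <- NA_real_
  for (i in seq_len(nrow(combos))) {
    sel <- which(cells$group == combos$group[i] & cells$model == combos$model[i])
    cells$p_fdr[sel] <- fdr_correct(cells$p_uncorrected[sel], alpha)$p_adjusted
  }
  cells$significant <- cells$p_fdr < alpha
  cells$trend <- cells$p_fdr >= alpha & cells$p_fdr < trend_upper
  cells
}

#' Summarize classification cells into the results-table layout
#'
#' @param results list of `split_accuracies` objects whose `cell` fields
#'   name `group` and `feature_set` (and optionally `model`).
#' @param chance,alpha passed to [chance_test()].
#' @return tibble, one row per cell, with the columns expected by
#'   [build_results_table()].
#' @export
summarize_cells <- function(results, chance = 0.5, alpha = 0.05) {
  rows <- lapply(results, function(r) {
    ct <- chance_test(r, chance = chance, alpha = alpha)
    tibble::tibble(
      group = r$cell$group %||% NA_character_,
      feature_set = r$cell$feature_set %||% NA_character_,
      model = r$cell$model %||% r$family,
      n_splits = r$n_splits,
      mean_acc = ct$mean_accuracy, std_acc = ct$std_accuracy,
      t = ct$t_value, p_uncorrected = ct$p_uncorrected)
  })
  do.call(rbind, rows)
}
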