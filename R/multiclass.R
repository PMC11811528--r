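# One-vs-rest multiclass diagnostic classification over disjoint,
# size-matched groups plus the control class.

#' Build disjoint multiclass labels from unique case lists
#'
#' @param unique_cases named list label -> case ids (pairwise disjoint, as
#'   produced by [unique_case_list()]); overlap raises an error.
#' @param control_ids ids of the control class.
#' @param control_label label for the control class.
#' @return named factor of class labels indexed by participant id.
#' @export
multiclass_labels <- function(unique_cases, control_ids,
                              control_label = "control") {
  sets <- c(unique_cases, stats::setNames(list(control_ids), control_label))
  all_ids <- unlist(sets)
  if (anyDuplicated(all_ids))
    abort_config("overlapping class membership: id %s appears in more than one class",
                 all_ids[duplicated(all_ids)][1])
  lab <- rep(names(sets), lengths(sets))
  stats::setNames(factor(lab, levels = names(sets)), all_ids)
}

#' One-vs-rest multiclass classification with a pooled confusion matrix
#'
#' Trains one fixed-settings random forest per class (positive = that
#' class, negative = all others) inside a standardization + fixed-rank PCA
#' pipeline, over stratified shuffle-splits.  A held-out sample's predicted
#' label is the class with maximal positive-class probability (ties by
#' class order); each subject's final label is the majority vote over the
#' splits in which it was held out.  Subjects never held out across the
#' splits receive one extra prediction from a model trained on the covered
#' subjects only.
#'
#' @param features numeric matrix, rows aligned to `labels`.
#' @param labels factor of class labels (>= 3 classes, equal class sizes).
#' @param n_splits number of stratified 80/20 shuffle-splits.
#' @param train_fraction training fraction per split.
#' @param num_trees random-forest tree count (fixed, default 250).
#' @param pca_rank PCA rank cap (resolved to `min(pca_rank, p, n_train-1)`).
#' @param seed integer seed.
#' @return a `confusion_matrix` object: `counts` (true x predicted),
#'   `labels`, `misclassification_rate`.
#' @export
run_multiclass <- function(features, labels, n_splits = 100,
                           train_fraction = 0.8, num_trees = 250,
                           pca_rank = 50, seed = 1L) {
  y <- factor(labels)
  if (nlevels(y) < 3) abort_config("run_multiclass needs at least three classes")
  if (length(unique(table(y))) != 1)
    abort_config("classes must be size-matched (equal class sizes)")
  X <- drop_constant_columns(as.matrix(features))
  n <- nrow(X)
  if (n != length(y)) abort_config("features and labels are not row-aligned")
  withr::local_seed(seed)
  levs <- levels(y)
  votes <- matrix(0L, n, length(levs), dimnames = list(NULL, levs))

  ovr_predict <- function(tr, te) {
    mu <- colMeans(X[tr, , drop = FALSE])
    sd <- apply(X[tr, , drop = FALSE], 2, stats::sd); sd[sd == 0] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, sd, "/")
    pc <- stats::prcomp(Xs[tr, , drop = FALSE], center = FALSE, scale. = FALSE)
    r <- min(pca_rank, ncol(X), length(tr) - 1)
    Z <- Xs %*% pc$rotation[, seq_len(r), drop = FALSE]
    colnames(Z) <- paste0("PC", seq_len(r))
    prob <- matrix(0, length(te), length(levs))
    for (ci in seq_along(levs)) {
      ybin <- factor(ifelse(y == levs[ci], "pos", "neg"),
                     levels = c("neg", "pos"))
      fit <- ranger::ranger(x = as.data.frame(Z[tr, , drop = FALSE]),
                            y = ybin[tr], num.trees = num_trees,
                            probability = TRUE, seed = draw_seed(1),
                            num.threads = 1)
      prob[, ci] <- stats::predict(fit,
        as.data.frame(Z[te, , drop = FALSE]))$predictions[, "pos"]
    }
    apply(prob, 1, which.max)
  }

  for (s in seq_len(n_splits)) {
    tr <- stratified_train_idx(y, train_fraction)
    te <- setdiff(seq_len(n), tr)
    pred <- ovr_predict(tr, te)
    votes[cbind(te, pred)] <- votes[cbind(te, pred)] + 1L
  }
  uncovered <- which(rowSums(votes) == 0)
  if (length(uncovered) > 0) {
    pred <- ovr_predict(setdiff(seq_len(n), uncovered), uncovered)
    votes[cbind(uncovered, pred)] <- 1L
  }
  final <- factor(levs[max.col(votes, ties.method = "first")], levels = levs)
  counts <- table(true = y, predicted = final)
  structure(list(counts = unclass(counts), labels = levs,
                 misclassification_rate = 1 - sum(diag(counts)) / n),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d classes, misclassification rate %.3f\n",
              length(x$labels), x$misclassification_rate))
  invisible(x)
}
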