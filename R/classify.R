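# The evaluation engine: per-split standardization -> PCA -> classifier,
# with hyperparameters (including the PCA rank) selected by nested
# stratified k-fold cross-validation confined to the training rows of each
# outer split.  All preprocessing statistics are estimated on training rows
# only.

#' Specify a classifier family with fixed settings and a tuning grid
#'
#' Defaults follow the benchmark's conventions: random forests with the
#' tree count fixed at 250 and tree depth plus split-feature fraction
#' tuned; support vector classifiers with cost and kernel tuned; k-nearest
#' neighbors with neighbor count, weight function and distance metric
#' tuned.  The PCA rank is tuned for every family.  All grids are
#' overridable; a one-row grid disables the inner cross-validation.
#'
#' @param family one of `"random_forest"`, `"support_vector"`,
#'   `"k_nearest_neighbors"`.
#' @param fixed named list of fixed settings (e.g. `num_trees`); merged
#'   over family defaults.
#' @param grid named list of hyperparameter candidate vectors; merged over
#'   family defaults.  `pca_rank` may include `Inf`, resolved at fit time
#'   to the maximal admissible rank `min(p, n_train - 1)`.
#' @return a `model_spec` list with the expanded tuning grid.
#' @export
model_spec <- function(family = c("random_forest", "support_vector",
                                  "k_nearest_neighbors"),
                       fixed = list(), grid = list()) {
  family <- match.arg(family)
  def_fixed <- switch(family,
    random_forest = list(num_trees = 250),
    support_vector = list(),
    k_nearest_neighbors = list())
  def_grid <- switch(family,
    random_forest = list(pca_rank = c(10, 25, 50, Inf),
                         max_depth = c(0, 5, 10),
                         mtry_fraction = c(NA, 0.25, 0.5)),
    support_vector = list(pca_rank = c(10, 25, 50, Inf),
                          cost = c(0.1, 1, 10),
                          kernel = c("linear", "radial")),
    k_nearest_neighbors = list(pca_rank = c(10, 25, 50, Inf),
                               k = c(5, 15, 31),
                               weights = c("uniform", "distance"),
                               metric = c("euclidean", "manhattan")))
  fixed <- utils::modifyList(def_fixed, fixed)
  grid_list <- utils::modifyList(def_grid, grid)
  if (any(lengths(grid_list) == 0)) abort_config("tuning grid entries must be non-empty")
  grid_df <- do.call(expand.grid,
                     c(grid_list, list(stringsAsFactors = FALSE)))
  structure(list(family = family, fixed = fixed, grid = grid_df),
            class = "model_spec")
}

fit_classifier <- function(family, Z, y, params, fixed, seed) {
  switch(family,
    random_forest = {
      p <- ncol(Z)
      mtry <- if (is.na(params$mtry_fraction)) max(1L, floor(sqrt(p)))
              else max(1L, round(params$mtry_fraction * p))
      fit <- ranger::ranger(x = as.data.frame(Z), y = y,
                            num.trees = fixed$num_trees, mtry = min(mtry, p),
                            max.depth = params$max_depth,
                            seed = seed, num.threads = 1)
      list(kind = "ranger", fit = fit)
    },
    support_vector = {
      fit <- e1071::svm(Z, y, cost = params$cost, kernel = params$kernel,
                        scale = FALSE)
      list(kind = "svm", fit = fit)
    },
    k_nearest_neighbors = {
      list(kind = "knn", Z = Z, y = y,
           k = params$k, weights = params$weights, metric = params$metric)
    })
}

predict_classifier <- function(clf, Znew) {
  switch(clf$kind,
    ranger = stats::predict(clf$fit, as.data.frame(Znew))$predictions,
    svm = stats::predict(clf$fit, Znew),
    knn = knn_predict(clf$Z, clf$y, Znew, clf$k, clf$weights, clf$metric))
}

# k-nearest-neighbor prediction supporting Manhattan distance and
# inverse-distance weighting (beyond what class::knn offers).  Ties in the
# neighbor ranking are broken by training-row order; vote ties by class
# level order.  Both rules are deterministic.
knn_predict <- function(Ztr, ytr, Zte, k, weights = "uniform",
                        metric = "euclidean") {
  k <- min(k, nrow(Ztr))
  if (metric == "euclidean") {
    d2 <- outer(rowSums(Zte^2), rowSums(Ztr^2), "+") - 2 * Zte %*% t(Ztr)
    D <- sqrt(pmax(d2, 0))
  } else {
    D <- matrix(0, nrow(Zte), nrow(Ztr))
    for (j in seq_len(ncol(Ztr)))
      D <- D + abs(outer(Zte[, j], Ztr[, j], "-"))
  }
  levs <- levels(ytr)
  pred <- character(nrow(Zte))
  for (i in seq_len(nrow(Zte))) {
    nb <- order(D[i, ])[seq_len(k)]
    w <- if (weights == "distance") 1 / (D[i, nb] + 1e-12) else rep(1, k)
    votes <- vapply(levs, function(l) sum(w[ytr[nb] == l]), 0)
    pred[i] <- levs[which.max(votes)]
  }
  factor(pred, levels = levs)
}

# Fit the full preprocessing + classifier pipeline on training rows only.
fit_pipeline <- function(X, y, params, model, seed) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sd, "/")
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  r <- min(params$pca_rank, ncol(X), nrow(X) - 1)
  rot <- pc$rotation[, seq_len(r), drop = FALSE]
  Z <- Xs %*% rot
  colnames(Z) <- paste0("PC", seq_len(r))
  clf <- fit_classifier(model$family, Z, y, params, model$fixed, seed)
  list(mu = mu, sd = sd, rotation = rot, clf = clf)
}

predict_pipeline <- function(pipe, Xnew) {
  Xs <- sweep(sweep(Xnew, 2, pipe$mu), 2, pipe$sd, "/")
  Z <- Xs %*% pipe$rotation
  colnames(Z) <- paste0("PC", seq_len(ncol(Z)))
  predict_classifier(pipe$clf, Z)
}

# Inner stratified k-fold CV over the tuning grid; returns the best grid
# row (first maximum on ties — grid order is deterministic).
tune_params <- function(X, y, model, inner_folds) {
  grid <- model$grid
  if (nrow(grid) == 1) return(grid[1, , drop = FALSE])
  fold <- stratified_folds(y, inner_folds)
  seeds <- draw_seed(nrow(grid) * inner_folds)
  score <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    acc <- numeric(inner_folds)
    for (f in seq_len(inner_folds)) {
      tr <- fold != f
      pipe <- fit_pipeline(X[tr, , drop = FALSE], y[tr],
                           grid[gi, , drop = FALSE], model,
                           seeds[(gi - 1) * inner_folds + f])
      pred <- predict_pipeline(pipe, X[!tr, , drop = FALSE])
      acc[f] <- mean(pred == y[!tr])
    }
    score[gi] <- mean(acc)
  }
  grid[which.max(score), , drop = FALSE]
}

drop_constant_columns <- function(X) {
  keep <- apply(X, 2, function(col) any(col != col[1]))
  if (!all(keep))
    rlang::warn(sprintf("dropping %d constant feature column(s): %s",
                        sum(!keep),
                        paste(colnames(X)[!keep], collapse = ", ")))
  X[, keep, drop = FALSE]
}

#' Case-control classification over stratified shuffle-splits
#'
#' For each of `n_splits` stratified training/validation splits (default
#' 80/20), hyperparameters — including the PCA rank — are selected by inner
#' stratified `inner_folds`-fold cross-validation on the training portion
#' only; standardization and PCA are then refit on the full training
#' portion and validation-set accuracy is recorded.  The result is the
#' vector of per-split validation accuracies whose distribution feeds the
#' chance-level significance criterion ([chance_test()]).
#'
#' @param features numeric matrix, rows aligned with `labels`.
#' @param labels two-level factor (or coercible) of case/control status;
#'   matching upstream guarantees balance.
#' @param model a [model_spec()].
#' @param n_splits number of shuffle-splits (>= 2); the benchmark default
#'   is 100.
#' @param train_fraction training fraction per split.
#' @param inner_folds folds of the nested tuning CV.
#' @param seed integer; the full accuracy vector is deterministic given it.
#' @param cell optional named list identifying the (group, feature set,
#'   model) cell, carried into results tables.
#' @param return_details if `TRUE`, also record per-split training indices
#'   and selected hyperparameters (used e.g. to audit leakage).
#' @return a `split_accuracies` object: `accuracies` (length `n_splits`),
#'   `n_splits`, `family`, `cell`, `seed`, and optionally `details`.
#' @export
run_binary <- function(features, labels, model = model_spec(),
                       n_splits = 100, train_fraction = 0.8,
                       inner_folds = 5, seed = 1L, cell = list(),
                       return_details = FALSE) {
  if (n_splits < 2) abort_config("n_splits must be at least 2")
  y <- factor(labels)
  if (nlevels(y) != 2) abort_config("run_binary needs exactly two classes")
  if (nrow(features) != length(y))
    abort_config("features and labels are not row-aligned")
  X <- drop_constant_columns(as.matrix(features))
  withr::local_seed(seed)
  acc <- numeric(n_splits)
  details <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    tr <- stratified_train_idx(y, train_fraction)
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    best <- tune_params(Xtr, ytr, model, inner_folds)
    pipe <- fit_pipeline(Xtr, ytr, best, model, draw_seed(1))
    pred <- predict_pipeline(pipe, X[-tr, , drop = FALSE])
    acc[s] <- mean(pred == y[-tr])
    if (return_details)
      details[[s]] <- list(train_idx = tr, params = best)
  }
  structure(list(accuracies = acc, n_splits = n_splits,
                 family = model$family, cell = cell, seed = seed,
                 details = if (return_details) details),
            class = "split_accuracies")
}

#' @export
print.split_accuracies <- function(x, ...) {
  cat(sprintf("<split_accuracies> %s, %d splits: mean %.3f (sd %.3f)\n",
              x$family, x$n_splits, mean(x$accuracies),
              stats::sd(x$accuracies)))
  invisible(x)
}

#' Leave-one-site-out cross-validation
#'
#' Trains the same standardization/PCA/classifier pipeline once per held-out
#' acquisition site on the remaining sites (with nested tuning) and records
#' held-out accuracy per site.  Sites lacking one of the two classes are
#' skipped with a warning.
#'
#' @inheritParams run_binary
#' @param site_labels vector of site identifiers, row-aligned to `features`.
#' @return tibble with columns `site`, `n`, `accuracy`; the across-site
#'   mean is attached as attribute `mean_accuracy`.
#' @export
run_logo <- function(features, labels, site_labels, model = model_spec(),
                     inner_folds = 5, seed = 1L) {
  y <- factor(labels)
  if (nlevels(y) != 2) abort_config("run_logo needs exactly two classes")
  sites <- unique(site_labels)
  if (length(sites) < 2) abort_config("run_logo needs at least two sites")
  X <- drop_constant_columns(as.matrix(features))
  withr::local_seed(seed)
  rows <- list()
  for (s in sites) {
    held <- site_labels == s
    if (nlevels(droplevels(y[held])) < 2) {
      rlang::warn(sprintf("site %s lacks one class; fold skipped", s))
      next
    }
    best <- tune_params(X[!held, , drop = FALSE], y[!held], model, inner_folds)
    pipe <- fit_pipeline(X[!held, , drop = FALSE], y[!held], best, model,
                         draw_seed(1))
    pred <- predict_pipeline(pipe, X[held, , drop = FALSE])
    rows[[length(rows) + 1]] <- tibble::tibble(
      site = s, n = sum(held), accuracy = mean(pred == y[held]))
  }
  if (length(rows) == 0) abort_config("no site fold has both classes")
  out <- do.call(rbind, rows)
  attr(out, "mean_accuracy") <- mean(out$accuracy)
  out
}
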