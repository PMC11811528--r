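test_that("null labels give chance-level accuracy and in-range outputs", {
  cell <- gauss_cell(60, 8, d = 0, seed = 101)
  y_null <- withr::with_seed(5, sample(cell$y))
  sa <- run_binary(cell$X, y_null, quick_rf(), n_splits = 12, seed = 3)
  expect_length(sa$accuracies, 12)
  expect_true(all(sa$accuracies >= 0 & sa$accuracies <= 1))
  tol <- 3 * sd(sa$accuracies) / sqrt(12)
  expect_lt(abs(mean(sa$accuracies) - 0.5), max(tol, 0.1))
})

test_that("well-separated blobs are classified nearly perfectly", {
  cell <- gauss_cell(125, 5, d = 6, k_affected = 1, seed = 7)
  sa <- run_binary(cell$X, cell$y, quick_rf(pca_rank = 5), n_splits = 10,
                   seed = 2)
  expect_gt(mean(sa$accuracies), 0.95)
})

test_that("tuning and preprocessing depend only on training rows", {
  cell <- gauss_cell(40, 6, d = 0.8, k_affected = 3, seed = 11)
  spec <- model_spec("k_nearest_neighbors",
                     grid = list(pca_rank = c(2, 6), k = c(3, 9),
                                 weights = "uniform", metric = "euclidean"))
  r1 <- run_binary(cell$X, cell$y, spec, n_splits = 2, seed = 9,
                   return_details = TRUE)
  # corrupt every row outside split 1's training set
  X2 <- cell$X
  val1 <- setdiff(seq_len(nrow(X2)), r1$details[[1]]$train_idx)
  X2[val1, ] <- 1e6 * matrix(rnorm(length(val1) * ncol(X2)), length(val1))
  r2 <- run_binary(X2, cell$y, spec, n_splits = 2, seed = 9,
                   return_details = TRUE)
  expect_identical(r2$details[[1]]$train_idx, r1$details[[1]]$train_idx)
  expect_identical(r2$details[[1]]$params, r1$details[[1]]$params)
})

test_that("label permutations center every family at chance", {
  cell <- gauss_cell(40, 6, d = 1.5, k_affected = 3, seed = 13)
  for (spec in list(quick_rf(4), quick_svc(4), quick_knn(4, k = 7))) {
    means <- vapply(1:20, function(i) {
      y_perm <- withr::with_seed(100 + i, sample(cell$y))
      mean(run_binary(cell$X, y_perm, spec, n_splits = 4,
                      seed = 200 + i)$accuracies)
    }, 0)
    expect_lt(abs(mean(means) - 0.5), 0.05)
  }
})

test_that("the split-accuracy vector is deterministic given the seed", {
  cell <- gauss_cell(30, 5, d = 0.5, seed = 17)
  a <- run_binary(cell$X, cell$y, quick_knn(4), n_splits = 6, seed = 42)
  b <- run_binary(cell$X, cell$y, quick_knn(4), n_splits = 6, seed = 42)
  expect_identical(a$accuracies, b$accuracies)
})

test_that("constant feature columns are dropped with a warning", {
  cell <- gauss_cell(20, 4, d = 0, seed = 19)
  cell$X[, 2] <- 3.14
  expect_warning(
    run_binary(cell$X, cell$y, quick_knn(3), n_splits = 2, seed = 1),
    "constant")
  expect_error(run_binary(cell$X, cell$y, quick_knn(3), n_splits = 1),
               class = "transdx_config_error")
})

test_that("the k-NN predictor agrees with class::knn on its shared cell", {
  skip_if_not_installed("class")
  withr::local_seed(23)
  Ztr <- matrix(rnorm(80 * 4), 80)
  ytr <- factor(sample(c("a", "b"), 80, replace = TRUE))
  Zte <- matrix(rnorm(30 * 4), 30)
  mine <- transdx:::knn_predict(Ztr, ytr, Zte, k = 7,
                                weights = "uniform", metric = "euclidean")
  ref <- class::knn(Ztr, Zte, ytr, k = 7)
  expect_identical(as.character(mine), as.character(ref))
})

test_that("LOGO matches shuffle-splits without site effects and collapses under pure site signal", {
  # planted group effect, sites carry no signal
  cell <- gauss_cell(150, 8, d = 0.8, k_affected = 4, seed = 29)
  sites <- rep_len(1:3, length(cell$y))
  lg <- run_logo(cell$X, cell$y, sites, quick_knn(6), seed = 4)
  sa <- run_binary(cell$X, cell$y, quick_knn(6), n_splits = 20, seed = 4)
  expect_equal(nrow(lg), 3)
  expect_lt(abs(attr(lg, "mean_accuracy") - mean(sa$accuracies)), 0.05)

  # labels dominated by site parity, features carry only site offsets:
  # shuffle-splits inflate, LOGO collapses.  Each site keeps a minority of
  # the other class so every fold is evaluable; neighboring sites carry
  # opposite majority labels, so a held-out site inherits the wrong one.
  withr::local_seed(31)
  site <- rep(1:4, each = 40)
  offsets <- c(0, 2, 5, 9)
  X <- matrix(rnorm(160 * 3, sd = 0.1), 160, 3) + offsets[site]
  majority <- ifelse(site %% 2 == 1, "case", "control")
  minority <- ifelse(site %% 2 == 1, "control", "case")
  y <- ifelse(seq_along(site) %% 8 == 0, minority, majority)
  lg2 <- run_logo(X, y, site, quick_knn(2, k = 5), seed = 6)
  sa2 <- run_binary(X, y, quick_knn(2, k = 5), n_splits = 10, seed = 6)
  expect_lte(attr(lg2, "mean_accuracy"), 0.5)
  expect_gt(mean(sa2$accuracies), 0.7)
})

test_that("LOGO reproduces a hand-computed two-site nearest-neighbor result", {
  X <- matrix(c(0, 1, 0.6, 0.9), 4, 1)
  y <- c("a", "b", "a", "b")
  sites <- c(1, 1, 2, 2)
  lg <- run_logo(X, y, sites, quick_knn(1, k = 1), seed = 1)
  # site 1 held out: train {0.6->a, 0.9->b}; 0 -> a, 1 -> b: accuracy 1
  # site 2 held out: train {0->a, 1->b}; 0.6 -> b (wrong), 0.9 -> b: 0.5
  expect_equal(lg$accuracy[lg$site == 1], 1)
  expect_equal(lg$accuracy[lg$site == 2], 0.5)

  # a site lacking one class is skipped with a warning
  expect_warning(
    lg3 <- run_logo(rbind(X, c(0.5)), c(y, "a"), c(sites, 3),
                    quick_knn(1, k = 1), seed = 1),
    "lacks one class")
  expect_equal(nrow(lg3), 2)
})
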