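# Shared builders: single-configuration model specs (one-row grids disable
# the inner tuning CV, keeping unit tests fast) and small planted-effect
# fixtures built in code.

quick_rf <- function(pca_rank = 6) {
  model_spec("random_forest",
             grid = list(pca_rank = pca_rank, max_depth = 0, mtry_fraction = NA))
}

quick_svc <- function(pca_rank = 6, cost = 1, kernel = "linear") {
  model_spec("support_vector",
             grid = list(pca_rank = pca_rank, cost = cost, kernel = kernel))
}

quick_knn <- function(pca_rank = 6, k = 15, weights = "uniform",
                      metric = "euclidean") {
  model_spec("k_nearest_neighbors",
             grid = list(pca_rank = pca_rank, k = k, weights = weights,
                         metric = metric))
}

# Balanced two-class Gaussian cell: n_per_class rows per class, `d` mean
# shift on the first `k_affected` of `p` features.
gauss_cell <- function(n_per_class, p, d, k_affected = p, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    y <- rep(c("case", "control"), each = n_per_class)
    X[y == "case", seq_len(k_affected)] <-
      X[y == "case", seq_len(k_affected)] + d
    list(X = X, y = y)
  })
}

# Minimal participant tibble from parallel vectors; icd10 given as
# semicolon strings for readability.
participants_tbl <- function(id, sex, age, motion, icd10 = NULL, site = NULL) {
  codes <- if (is.null(icd10)) replicate(length(id), character(0), simplify = FALSE)
           else lapply(strsplit(icd10, ";", fixed = TRUE), function(x) x[nzchar(x)])
  tibble::tibble(id = id, sex = sex, age = age, motion = motion,
                 site = site %||% rep(1L, length(id)), icd10 = codes)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Independent Student-t upper-tail oracle by numerical integration of the
# density (no use of pt()).
t_tail_oracle <- function(t, df) {
  dens <- function(x)
    exp(lgamma((df + 1) / 2) - lgamma(df / 2) - 0.5 * log(df * pi) -
          (df + 1) / 2 * log1p(x^2 / df))
  stats::integrate(dens, t, Inf, rel.tol = 1e-13, abs.tol = 1e-14)$value
}

# Brute-force Benjamini-Hochberg step-up from the definition:
# adj_(i) = min_{j >= i} m * p_(j) / j, capped at 1, mapped back to the
# original order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- vapply(seq_len(m), function(i)
    min(1, min((m / (i:m)) * p[o][i:m])), 0)
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}
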