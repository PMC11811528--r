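test_that("identical config and seed give a bit-identical cohort", {
  cfg <- cohort_config(400, seed = 11,
    group_specs = list(group_spec("F32", "F30-F39", 0.1)),
    feature_set_specs = list(feature_set_spec("fs", 5,
      affected_features_per_group = list(F32 = 1:2),
      effect_size_per_group = list(F32 = 0.5))))
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$participants, b$participants)
  expect_identical(a$features, b$features)
})

test_that("case counts follow the configured prevalence (binomial oracle)", {
  cfg <- cohort_config(20000, seed = 3,
    group_specs = list(group_spec("G35", "G35-G37", 0.01)))
  ch <- generate_cohort(cfg)
  n_cases <- sum(vapply(ch$participants$icd10, function(x) "G35" %in% x, TRUE))
  bounds <- qbinom(c(0.0005, 0.9995), 20000, 0.01)
  expect_gte(n_cases, bounds[1])
  expect_lte(n_cases, bounds[2])
})

test_that("positive comorbidity coupling raises P(both | either)", {
  p_both_given_either <- function(coupling, seed) {
    cfg <- cohort_config(1000, seed = seed,
      group_specs = list(group_spec("F32", "F30-F39", 0.1),
                         group_spec("F41", "F40-F48", 0.1)),
      comorbidity_coupling = matrix(c(0, coupling, coupling, 0), 2))
    ch <- generate_cohort(cfg)
    a <- vapply(ch$participants$icd10, function(x) "F32" %in% x, TRUE)
    b <- vapply(ch$participants$icd10, function(x) "F41" %in% x, TRUE)
    sum(a & b) / sum(a | b)
  }
  seeds <- 1:50
  coupled <- vapply(seeds, function(s) p_both_given_either(2.5, s), 0)
  uncoupled <- vapply(seeds, function(s) p_both_given_either(0, s), 0)
  expect_gt(mean(coupled), mean(uncoupled))
  # and decisively so: the coupled overlap should exceed the null by a wide
  # margin, not by Monte-Carlo luck
  expect_gt(mean(coupled) - mean(uncoupled), 0.05)
})

test_that("zero-effect features are independent of diagnosis labels", {
  cfg <- cohort_config(1500, seed = 5,
    group_specs = list(group_spec("F32", "F30-F39", 0.3)),
    feature_set_specs = list(feature_set_spec("nullfs", 200)))
  ch <- generate_cohort(cfg)
  is_case <- vapply(ch$participants$icd10, function(x) "F32" %in% x, TRUE)
  pvals <- apply(ch$features$nullfs, 2, function(col)
    t.test(col[is_case], col[!is_case])$p.value)
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("planted effect sizes are calibrated in Cohen's d units", {
  d <- 0.5
  cfg <- cohort_config(12000, seed = 9,
    group_specs = list(group_spec("G40", "G40-G47", 0.3)),
    feature_set_specs = list(feature_set_spec("fs", 3,
      affected_features_per_group = list(G40 = 1L),
      effect_size_per_group = list(G40 = d), noise_sd = 2)))
  ch <- generate_cohort(cfg)
  is_case <- vapply(ch$participants$icd10, function(x) "G40" %in% x, TRUE)
  x1 <- ch$features$fs[is_case, 1]; x0 <- ch$features$fs[!is_case, 1]
  n1 <- length(x1); n0 <- length(x0)
  sp <- sqrt(((n1 - 1) * var(x1) + (n0 - 1) * var(x0)) / (n1 + n0 - 2))
  d_hat <- (mean(x1) - mean(x0)) / sp
  se_d <- sqrt(1 / n1 + 1 / n0 + d_hat^2 / (2 * (n1 + n0)))
  expect_lt(abs(d_hat - d), 3 * se_d)
})

test_that("covariate shifts tilt case covariates in the stated direction", {
  cfg <- cohort_config(20000, seed = 13,
    group_specs = list(group_spec("G35", "G35-G37", 0.1,
      covariate_shifts = list(age_shift_years = 5))))
  ch <- generate_cohort(cfg)
  is_case <- vapply(ch$participants$icd10, function(x) "G35" %in% x, TRUE)
  shift <- mean(ch$participants$age[is_case]) - mean(ch$participants$age)
  expect_gt(shift, 3)
  expect_lt(shift, 7)
})

test_that("cohorts round-trip through CSV exactly", {
  cfg <- cohort_config(10, seed = 21,
    group_specs = list(group_spec("F32", "F30-F39", 0.4)),
    feature_set_specs = list(feature_set_spec("a", 3),
                             feature_set_spec("b", 2)))
  ch <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  back <- read_cohort(dir)
  expect_identical(back$participants$id, ch$participants$id)
  expect_identical(back$participants$icd10, ch$participants$icd10)
  expect_equal(back$participants$age, ch$participants$age, tolerance = 0)
  expect_equal(back$features, ch$features, tolerance = 0)
  # empty code sets serialize to empty fields and parse back to empty sets
  empties <- lengths(ch$participants$icd10) == 0
  expect_true(any(empties))
  expect_identical(lengths(back$participants$icd10)[empties],
                   rep(0L, sum(empties)) |> stats::setNames(NULL))
})

test_that("foreign feature rows and invalid configs are rejected", {
  cfg <- cohort_config(5, seed = 2,
    feature_set_specs = list(feature_set_spec("a", 2)))
  ch <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  df <- readr::read_csv(file.path(dir, "a.csv"), show_col_types = FALSE)
  df$id[3] <- "GHOST01"
  readr::write_csv(df, file.path(dir, "a.csv"))
  expect_error(read_cohort(dir), "GHOST01", class = "transdx_format_error")

  expect_error(cohort_config(0), class = "transdx_config_error")
  expect_error(
    cohort_config(10,
      group_specs = list(group_spec("F32", "F30-F39", 0.1),
                         group_spec("G35", "G35-G37", 0.1)),
      comorbidity_coupling = matrix(c(0, 1, 2, 0), 2)),
    class = "transdx_config_error")
  expect_error(group_spec("F32", "G35-G37", 0.1), class = "transdx_config_error")
  expect_error(feature_set_spec("x", 3,
    affected_features_per_group = list(F32 = 1:5),
    effect_size_per_group = list(F32 = 1)), class = "transdx_config_error")
})
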