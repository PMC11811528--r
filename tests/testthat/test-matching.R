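test_that("matching honors the sex > age > motion priority", {
  participants <- participants_tbl(
    id = c("case1", "p1", "p2", "p3"),
    sex = c("F", "F", "F", "M"),
    age = c(50, 50, 60, 50),
    motion = c(0.2, 0.9, 0.2, 0.2))
  pool <- participants[-1, ]
  m <- match_controls(list(G = "case1"), pool, participants, seed = 1)
  # sex is exact, and the exact-age match beats the exact-motion match
  expect_equal(m$G$pairs$control_id, "p1")
})

test_that("controls are consumed at most once, globally across groups", {
  participants <- participants_tbl(
    id = c("a", "b", "c", "d"),
    sex = rep("F", 4), age = rep(50, 4), motion = rep(0.1, 4))
  pool <- participants[3:4, ]
  m <- match_controls(list(G1 = "a", G2 = "b"), pool, participants, seed = 1)
  ctrls <- c(m$G1$pairs$control_id, m$G2$pairs$control_id)
  expect_length(unique(ctrls), 2)

  # same-group variant: two identical cases, two identical controls
  m2 <- match_controls(list(G = c("a", "b")), pool, participants, seed = 1)
  expect_length(unique(m2$G$pairs$control_id), 2)
})

test_that("pool exhaustion raises an infeasibility error naming the stratum", {
  participants <- participants_tbl(
    id = c("a", "b", "c"), sex = c("F", "F", "M"),
    age = rep(50, 3), motion = rep(0.1, 3))
  expect_error(
    match_controls(list(G = c("a", "b")), participants[3, ], participants,
                   seed = 1),
    class = "transdx_config_error")   # pool smaller than cases
  participants4 <- participants_tbl(
    id = c("a", "b", "c", "d"), sex = c("F", "F", "M", "M"),
    age = rep(50, 4), motion = rep(0.1, 4))
  err <- expect_error(
    match_controls(list(G = c("a", "b")), participants4[3:4, ], participants4,
                   seed = 1),
    class = "transdx_infeasible_error")
  expect_match(conditionMessage(err), "G")
  expect_match(conditionMessage(err), "F")
})

make_match_cohort <- function(seed, n_cases = 120, n_pool = 3000) {
  withr::with_seed(seed, {
    n <- n_cases + n_pool
    participants_tbl(
      id = sprintf("P%05d", seq_len(n)),
      sex = sample(c("F", "M"), n, replace = TRUE),
      age = round(runif(n, 40, 70)),       # integer years: age ties engage
      motion = rlnorm(n, -2, 0.4))         # the motion tie-break
  })
}

test_that("matched groups are balanced: sex exactly, age and motion closely", {
  reports <- lapply(1:20, function(s) {
    pt <- make_match_cohort(s)
    cases <- pt$id[1:120]
    m <- match_controls(list(G = cases), pt[-(1:120), ], pt, seed = s)
    balance_report(m$G, pt)
  })
  expect_true(all(vapply(reports, function(b) b$sex_chi2_stat, 0) == 0))
  expect_true(all(vapply(reports, function(b) b$sex_chi2_p, 0) == 1))
  expect_gt(mean(vapply(reports, function(b) b$age_p, 0)), 0.3)
  expect_gt(mean(vapply(reports, function(b) b$motion_p, 0)), 0.7)
})

test_that("no unused same-sex control beats a chosen match on age", {
  pt <- make_match_cohort(99)
  cases <- pt$id[1:120]
  m <- match_controls(list(G = cases), pt[-(1:120), ], pt, seed = 7)
  unused <- pt[-(1:120), ]
  unused <- unused[!(unused$id %in% m$G$pairs$control_id), ]
  for (i in seq_len(nrow(m$G$pairs))) {
    case <- pt[pt$id == m$G$pairs$case_id[i], ]
    rival <- min(abs(unused$age[unused$sex == case$sex] - case$age))
    expect_gte(rival, m$G$pairs$age_diff[i])
  }
})

test_that("matching is deterministic given seed and case sets", {
  pt <- make_match_cohort(5, n_cases = 40, n_pool = 400)
  cases <- pt$id[1:40]
  m1 <- match_controls(list(G = cases), pt[-(1:40), ], pt, seed = 3)
  m2 <- match_controls(list(G = cases), pt[-(1:40), ], pt, seed = 3)
  expect_identical(m1$G$pairs, m2$G$pairs)
})

test_that("subsampling to a reference preserves pairs and tracks covariates", {
  pt <- make_match_cohort(17, n_cases = 500, n_pool = 3000)
  cases <- pt$id[1:500]
  m <- match_controls(list(G = cases), pt[-(1:500), ], pt, seed = 1)

  # identity: a group already at target size returns its own pairs
  small <- m$G
  small$pairs <- small$pairs[1:125, ]
  ref_self <- pt[match(small$pairs$case_id, pt$id), c("id", "sex", "age", "motion")]
  sub_self <- subsample_to_reference(small, ref_self, pt, target_n = 125, seed = 2)
  expect_setequal(sub_self$pairs$case_id, small$pairs$case_id)

  # a fresh reference: exact sex composition, pairs keep original controls
  ref <- withr::with_seed(42, participants_tbl(
    id = sprintf("R%03d", 1:125),
    sex = sample(c("F", "M"), 125, replace = TRUE),
    age = rnorm(125, 45, 1), motion = rlnorm(125, -2, 0.4)))
  sub <- subsample_to_reference(m$G, ref, pt, target_n = 125, seed = 2)
  expect_equal(nrow(sub$pairs), 125)
  sel <- pt[match(sub$pairs$case_id, pt$id), ]
  expect_equal(c(table(factor(sel$sex, c("F", "M")))),
               c(table(factor(ref$sex, c("F", "M")))))
  expect_true(all(sub$pairs$control_id %in% m$G$pairs$control_id))

  # selected cases hug the reference mean age more closely than a random
  # 125-subset in nearly every repetition
  wins <- vapply(1:100, function(s) {
    sub_s <- subsample_to_reference(m$G, ref, pt, target_n = 125, seed = s)
    matched_mean <- mean(pt$age[match(sub_s$pairs$case_id, pt$id)])
    rand_mean <- withr::with_seed(1000 + s,
      mean(pt$age[match(sample(cases, 125), pt$id)]))
    abs(matched_mean - mean(ref$age)) < abs(rand_mean - mean(ref$age))
  }, TRUE)
  expect_gte(mean(wins), 0.95)

  expect_error(subsample_to_reference(small, ref, pt, target_n = 300),
               class = "transdx_config_error")
})

test_that("balance reports handle degenerate and extreme inputs", {
  pt <- participants_tbl(
    id = sprintf("x%02d", 1:20), sex = rep(c("F", "M"), 10),
    age = rep(c(70, 40), each = 10), motion = runif(20))
  cohort <- structure(list(label = "G",
                           pairs = tibble::tibble(case_id = pt$id[1:10],
                                                  control_id = pt$id[11:20],
                                                  age_diff = 30, motion_diff = 0),
                           covariates = c("sex", "age", "motion")),
                      class = "matched_cohort")
  b <- balance_report(cohort, pt)
  expect_lt(b$age_p, 1e-6)    # all cases aged 70, all controls 40

  # cohort vs itself: every test degenerates to p = 1
  self <- cohort
  self$pairs$control_id <- self$pairs$case_id
  bs <- balance_report(self, pt)
  expect_equal(bs$sex_chi2_p, 1)
  expect_equal(bs$age_p, 1)
  expect_equal(bs$motion_p, 1)

  # single-sex table: flagged degenerate, p reported as 1
  pt_f <- pt
  pt_f$sex <- "F"
  bf <- balance_report(cohort, pt_f)
  expect_true(bf$degenerate)
  expect_equal(bf$sex_chi2_p, 1)
})
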