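# Prioritized, globally unique case-control matching.
#
# Each case receives a control of identical sex; among unused same-sex
# controls the one with minimal |age difference| is chosen, ties broken by
# minimal |motion difference|, then by smallest control id.  Controls are
# consumed at most once across all groups of a run.  Groups are processed
# in ascending size (protecting small groups from pool depletion) and cases
# within a group in a seed-shuffled order.

match_one <- function(case_sex, case_age, case_motion, pool, used) {
  cand <- which(!used & pool$sex == case_sex)
  if (length(cand) == 0) return(NA_integer_)
  d_age <- abs(pool$age[cand] - case_age)
  cand <- cand[d_age == min(d_age)]
  if (length(cand) > 1) {
    d_mot <- abs(pool$motion[cand] - case_motion)
    cand <- cand[d_mot == min(d_mot)]
  }
  if (length(cand) > 1) cand <- cand[order(pool$id[cand])][1]
  cand
}

#' Match unique healthy controls to each diagnostic group's cases
#'
#' @param groups named list: group label -> case-id character vector.
#' @param control_pool participant tibble (columns id, sex, age, motion)
#'   restricted to eligible controls (no in-scope diagnosis, complete
#'   features); must be disjoint from all case sets.
#' @param participants participant tibble used to look up case covariates.
#' @param priority matching covariates in priority order; only the default
#'   `c("sex", "age", "motion")` is supported.
#' @param seed integer; shuffles case order within groups.
#' @return named list of `matched_cohort` objects with elements `label`,
#'   `pairs` (tibble case_id, control_id, age_diff, motion_diff) and
#'   `covariates`.
#' @export
match_controls <- function(groups, control_pool, participants,
                           priority = c("sex", "age", "motion"), seed = 1L) {
  if (!identical(priority, c("sex", "age", "motion")))
    abort_config("only the sex > age > motion priority order is supported")
  total_cases <- sum(lengths(groups))
  if (nrow(control_pool) < total_cases)
    abort_config("control pool (%d) smaller than total cases (%d)",
                 nrow(control_pool), total_cases)
  withr::local_seed(seed)
  pool <- control_pool[order(control_pool$id), ]
  used <- logical(nrow(pool))
  cov <- participants[match(unlist(groups), participants$id), ]
  cov_idx <- stats::setNames(seq_len(nrow(cov)), cov$id)

  out <- list()
  for (label in names(groups)[order(lengths(groups))]) {
    case_ids <- groups[[label]]
    case_ids <- case_ids[sample.int(length(case_ids))]
    pairs <- vector("list", length(case_ids))
    for (j in seq_along(case_ids)) {
      ci <- cov_idx[[case_ids[j]]]
      hit <- match_one(cov$sex[ci], cov$age[ci], cov$motion[ci], pool, used)
      if (is.na(hit))
        abort_infeasible("control pool exhausted for group %s, sex stratum %s",
                         label, cov$sex[ci])
      used[hit] <- TRUE
      pairs[[j]] <- tibble::tibble(
        case_id = case_ids[j], control_id = pool$id[hit],
        age_diff = abs(pool$age[hit] - cov$age[ci]),
        motion_diff = abs(pool$motion[hit] - cov$motion[ci]))
    }
    out[[label]] <- structure(
      list(label = label, pairs = do.call(rbind, pairs),
           covariates = priority),
      class = "matched_cohort")
  }
  out[names(groups)]
}

#' Subsample a matched group to a reference group's size and covariates
#'
#' Selects `target_n` cases from `cohort` as the prioritized nearest
#' matches (sex exact, then age, then motion, then smallest id) to the
#' reference group's cases, reusing the same greedy rule as
#' [match_controls()].  Selected pairs keep their original controls.
#'
#' @param cohort a `matched_cohort`.
#' @param reference_cases tibble of reference-case covariates (id, sex,
#'   age, motion).
#' @param participants participant tibble for covariate lookup.
#' @param target_n number of pairs to retain (default 125).
#' @param seed shuffles the reference-case processing order.
#' @return a `matched_cohort` with `target_n` pairs.
#' @export
subsample_to_reference <- function(cohort, reference_cases, participants,
                                   target_n = 125, seed = 1L) {
  if (nrow(cohort$pairs) < target_n)
    abort_config("group %s has %d cases, fewer than target_n = %d",
                 cohort$label, nrow(cohort$pairs), target_n)
  if (nrow(reference_cases) < target_n)
    abort_config("reference group has fewer than target_n cases")
  withr::local_seed(seed)
  ref <- reference_cases[sample.int(nrow(reference_cases)), ][seq_len(target_n), ]
  pool <- participants[match(cohort$pairs$case_id, participants$id), ]
  pool <- pool[order(pool$id), c("id", "sex", "age", "motion")]
  used <- logical(nrow(pool))
  keep <- character(target_n)
  for (j in seq_len(target_n)) {
    hit <- match_one(ref$sex[j], ref$age[j], ref$motion[j], pool, used)
    if (is.na(hit))
      abort_infeasible("group %s: no unused case in sex stratum %s to match reference",
                       cohort$label, ref$sex[j])
    used[hit] <- TRUE
    keep[j] <- pool$id[hit]
  }
  structure(list(label = cohort$label,
                 pairs = cohort$pairs[cohort$pairs$case_id %in% keep, ],
                 covariates = cohort$covariates),
            class = "matched_cohort")
}

#' Covariate balance diagnostics for one matched cohort
#'
#' Sex is tested by a chi-square on the 2x2 sex-by-status table without
#' continuity correction (so perfectly matched groups give statistic 0 and
#' p = 1 exactly); age and motion by two-sided two-sample t-tests; site
#' (when present) by a chi-square over the site-by-status table.
#'
#' @param cohort a `matched_cohort`.
#' @param participants participant tibble (id, sex, age, motion, and
#'   optionally site).
#' @return a `balance_report` list: `sex_chi2_stat`, `sex_chi2_p`, `age_p`,
#'   `motion_p`, `site_p` (NA without site data), `site_counts`,
#'   `degenerate` flag (single-sex table).
#' @export
balance_report <- function(cohort, participants) {
  look <- function(ids) participants[match(ids, participants$id), ]
  cases <- look(cohort$pairs$case_id)
  controls <- look(cohort$pairs$control_id)
  if (anyNA(cases$id) || anyNA(controls$id))
    abort_format("balance_report: unresolvable participant ids in cohort %s",
                 cohort$label)
  status <- rep(c("case", "control"), each = nrow(cases))
  sexes <- c(cases$sex, controls$sex)
  degenerate <- length(unique(sexes)) < 2
  if (degenerate) {
    sex_stat <- 0; sex_p <- 1
  } else {
    tab <- table(sexes, status)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    sex_stat <- unname(ct$statistic); sex_p <- unname(ct$p.value)
  }
  safe_t <- function(x, y) {
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
      return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
    stats::t.test(x, y)$p.value
  }
  site_p <- NA_real_; site_counts <- NULL
  if ("site" %in% names(participants)) {
    site_tab <- table(factor(c(cases$site, controls$site)), status)
    site_counts <- site_tab
    if (nrow(site_tab) > 1)
      site_p <- suppressWarnings(stats::chisq.test(site_tab)$p.value)
  }
  structure(list(label = cohort$label,
                 sex_chi2_stat = sex_stat, sex_chi2_p = sex_p,
                 age_p = safe_t(cases$age, controls$age),
                 motion_p = safe_t(cases$motion, controls$motion),
                 site_p = site_p, site_counts = site_counts,
                 degenerate = degenerate),
            class = "balance_report")
}
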