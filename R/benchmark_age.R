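# Oldest-vs-youngest age classification benchmark: an upper-bound
# reference for what the classification machinery can achieve on the same
# feature sets.

#' Specify the age benchmark arms
#'
#' @param old_range age range (years) of the "case" arm, default 67-70.
#' @param young_range age range of the "control" arm, default 40-42.
#' @param n_large size of the large arm (even; half old, half young).
#' @param n_small size of the small arm (even).
#' @return an `age_benchmark_spec` list.
#' @export
age_benchmark_spec <- function(old_range = c(67, 70), young_range = c(40, 42),
                               n_large = 2656, n_small = 252) {
  if (max(young_range) >= min(old_range))
    abort_config("old_range and young_range must be disjoint, old above young")
  for (n in c(n_large, n_small))
    if (!is_count(n) || n %% 2 != 0)
      abort_config("arm sizes must be positive even integers")
  structure(list(old_range = old_range, young_range = young_range,
                 n_large = as.integer(n_large), n_small = as.integer(n_small)),
            class = "age_benchmark_spec")
}

# Greedy extreme-age pairing: old candidates are visited in descending age
# order; each is paired with the youngest unused same-sex young candidate,
# age ties broken by nearest head motion, then smallest id.
pair_extremes <- function(old, young, n_pairs) {
  used <- logical(nrow(young))
  sel_old <- integer(0); sel_young <- integer(0)
  for (i in order(-old$age, old$id)) {
    cand <- which(!used & young$sex == old$sex[i])
    if (length(cand) == 0) next
    cand <- cand[young$age[cand] == min(young$age[cand])]
    if (length(cand) > 1) {
      d <- abs(young$motion[cand] - old$motion[i])
      cand <- cand[d == min(d)]
    }
    j <- cand[order(young$id[cand])][1]
    used[j] <- TRUE
    sel_old <- c(sel_old, i); sel_young <- c(sel_young, j)
    if (length(sel_old) == n_pairs) break
  }
  if (length(sel_old) < n_pairs) {
    short <- names(which.max(table(old$sex[setdiff(order(-old$age), sel_old)])))
    abort_infeasible(
      "cannot form %d sex-matched old/young pairs; sex stratum %s exhausted",
      n_pairs, short %||% "?")
  }
  list(old = sel_old, young = sel_young)
}

#' Build oldest-vs-youngest benchmark groups
#'
#' The eligible pool is passed by the caller (members of any retained
#' diagnostic group plus the undiagnosed pool).  Pairs maximize the age
#' difference subject to exact sex match, with nearest head motion as the
#' tie-break; both arms end up exactly half old (the "case" class) and
#' half young (the "control" class), sex-matched by construction.  The
#' small arm is a fresh selection at `n_small` by default, or a subset of
#' the large arm with `small_as_subset = TRUE`.
#'
#' @param participants participant tibble (id, sex, age, motion) of the
#'   eligible pool.
#' @param spec an [age_benchmark_spec()].
#' @param seed integer seed (tie-shuffling and the subset draw).
#' @param small_as_subset draw the small arm as a subset of the large one.
#' @return list of two tibbles `large` and `small` with columns `id`,
#'   `sex`, `age`, `motion`, `label` (`"old"`/`"young"`).
#' @export
build_age_groups <- function(participants, spec = age_benchmark_spec(),
                             seed = 1L, small_as_subset = FALSE) {
  withr::local_seed(seed)
  in_range <- function(x, r) x >= r[1] & x <= r[2]
  old <- participants[in_range(participants$age, spec$old_range), ]
  young <- participants[in_range(participants$age, spec$young_range), ]
  build_arm <- function(n) {
    if (n / 2 > min(nrow(old), nrow(young)))
      abort_infeasible("not enough participants in the age extremes for an arm of %d", n)
    sel <- pair_extremes(old, young, n / 2)
    rbind(
      tibble::tibble(id = old$id[sel$old], sex = old$sex[sel$old],
                     age = old$age[sel$old], motion = old$motion[sel$old],
                     label = "old"),
      tibble::tibble(id = young$id[sel$young], sex = young$sex[sel$young],
                     age = young$age[sel$young],
                     motion = young$motion[sel$young], label = "young"))
  }
  large <- build_arm(spec$n_large)
  small <- if (small_as_subset) {
    olds <- which(large$label == "old"); yngs <- which(large$label == "young")
    large[c(sample(olds, spec$n_small / 2), sample(yngs, spec$n_small / 2)), ]
  } else build_arm(spec$n_small)
  list(large = large, small = small)
}
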