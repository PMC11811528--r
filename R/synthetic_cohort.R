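#' Specify one planted diagnostic group
#'
#' A group plants an ICD-10 code (e.g. `"G35"`) in the cohort at a given
#' prevalence.  Optional covariate shifts make cases differ from the
#' population in age, sex composition, or head motion, emulating the
#' confounding structure that case-control matching is meant to absorb.
#'
#' `covariate_shifts` are interpreted as target case-minus-population mean
#' differences and are translated into logistic-regression coefficients on
#' the diagnosis propensity (an exponential-tilting approximation:
#' `beta = shift / var(covariate)`), so e.g. `age_shift_years = 5` yields
#' cases roughly five years older than the cohort mean.
#'
#' @param code ICD-10 code string planted for members, e.g. `"F32"`.
#' @param parent_range broad range label containing `code`, e.g. `"F30-F39"`.
#' @param prevalence marginal probability of membership, in (0, 1).
#' @param covariate_shifts optional list with any of `age_shift_years`,
#'   `sex_log_odds` (added to the logit for female participants) and
#'   `motion_shift`.
#' @return a `group_spec` list.
#' @export
group_spec <- function(code, parent_range, prevalence, covariate_shifts = NULL) {
  if (!is_prob(prevalence) || prevalence <= 0 || prevalence >= 1)
    abort_config("prevalence must lie strictly in (0, 1), got %s", prevalence)
  parsed <- icd10_parse(code)
  if (!icd10_in_range(code, parent_range))
    abort_config("code %s does not fall inside parent_range %s", code, parent_range)
  shifts <- covariate_shifts %||% list()
  structure(list(code = code, parent_range = parent_range,
                 prevalence = prevalence,
                 covariate_shifts = list(
                   age_shift_years = shifts$age_shift_years %||% 0,
                   sex_log_odds = shifts$sex_log_odds %||% 0,
                   motion_shift = shifts$motion_shift %||% 0)),
            class = "group_spec")
}

#' Specify one synthetic feature set
#'
#' Features are generated as Gaussian noise with standard deviation
#' `noise_sd` plus planted additive effects: diagnostic-group effects in
#' Cohen's d units (a mean shift of `d * noise_sd` on the configured
#' feature indices for group members), a linear age slope, a standardized
#' sex shift, and deterministic mean-centered per-site offsets.
#'
#' @param name feature-set name; also the file stem used by [write_cohort()].
#' @param n_features number of features (columns).
#' @param affected_features_per_group named list: group code -> integer
#'   vector of 1-based feature indices carrying that group's effect.
#' @param effect_size_per_group named list: group code -> standardized mean
#'   shift (Cohen's d) applied to that group's affected features.
#' @param age_effect list with `slope` (feature units per year) and
#'   `features` (indices); `NULL` for none.
#' @param sex_effect list with `d` (standardized shift added for female
#'   participants) and `features`; `NULL` for none.
#' @param noise_sd positive noise standard deviation.
#' @param site_shift magnitude of the per-site additive offset, in units of
#'   `noise_sd`; sites receive mean-centered equally spaced offsets.
#' @return a `feature_set_spec` list.
#' @export
feature_set_spec <- function(name, n_features,
                             affected_features_per_group = list(),
                             effect_size_per_group = list(),
                             age_effect = NULL, sex_effect = NULL,
                             noise_sd = 1, site_shift = 0) {
  if (!is_count(n_features)) abort_config("n_features must be a positive integer")
  if (!is.numeric(noise_sd) || noise_sd <= 0) abort_config("noise_sd must be > 0")
  if (!setequal(names(affected_features_per_group), names(effect_size_per_group)))
    abort_config("affected_features_per_group and effect_size_per_group must name the same groups")
  for (g in names(affected_features_per_group)) {
    idx <- affected_features_per_group[[g]]
    if (any(idx < 1 | idx > n_features))
      abort_config("affected feature indices for group %s fall outside 1..%d", g, n_features)
  }
  for (eff in list(age_effect, sex_effect)) {
    if (!is.null(eff) && any(eff$features < 1 | eff$features > n_features))
      abort_config("age/sex effect feature indices fall outside 1..%d", n_features)
  }
  structure(list(name = name, n_features = as.integer(n_features),
                 affected_features_per_group = affected_features_per_group,
                 effect_size_per_group = effect_size_per_group,
                 age_effect = age_effect, sex_effect = sex_effect,
                 noise_sd = noise_sd, site_shift = site_shift),
            class = "feature_set_spec")
}

#' Configure a synthetic cohort
#'
#' Collects the population-level settings of the generator: covariate
#' distributions (sex Bernoulli, age uniform on a bounded range, head motion
#' log-normal, site categorical), diagnostic group specs, feature-set specs,
#' and a symmetric pairwise log-odds comorbidity coupling between groups.
#'
#' @param n_participants cohort size.
#' @param sex_fraction probability of being recorded female.
#' @param age_range numeric `c(min, max)` in years.
#' @param motion_distribution list with `location` and `scale` of the
#'   log-normal head-motion law (`meanlog`/`sdlog`).
#' @param n_sites number of acquisition sites (uniform assignment).
#' @param group_specs list of [group_spec()] objects.
#' @param feature_set_specs list of [feature_set_spec()] objects.
#' @param comorbidity_coupling symmetric matrix (side = number of groups,
#'   zero diagonal) of pairwise log-odds increments; `NULL` means no
#'   coupling.
#' @param seed integer seed; the cohort is a deterministic function of the
#'   config including the seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_participants, sex_fraction = 0.5,
                          age_range = c(40, 70),
                          motion_distribution = list(location = -2, scale = 0.4),
                          n_sites = 3,
                          group_specs = list(),
                          feature_set_specs = list(),
                          comorbidity_coupling = NULL,
                          seed = 1L) {
  if (!is_count(n_participants)) abort_config("n_participants must be a positive integer")
  if (!is_prob(sex_fraction)) abort_config("sex_fraction must lie in [0, 1]")
  if (length(age_range) != 2 || age_range[1] >= age_range[2])
    abort_config("age_range must be c(min, max) with min < max")
  if (!is_count(n_sites)) abort_config("n_sites must be >= 1")
  g <- length(group_specs)
  if (is.null(comorbidity_coupling)) comorbidity_coupling <- matrix(0, g, g)
  if (!is.matrix(comorbidity_coupling) ||
      nrow(comorbidity_coupling) != g || ncol(comorbidity_coupling) != g)
    abort_config("comorbidity_coupling must be a %d x %d matrix", g, g)
  if (g > 0 && !isTRUE(all.equal(comorbidity_coupling, t(comorbidity_coupling))))
    abort_config("comorbidity_coupling must be symmetric")
  if (g > 0 && any(diag(comorbidity_coupling) != 0))
    abort_config("comorbidity_coupling must have a zero diagonal")
  structure(list(n_participants = as.integer(n_participants),
                 sex_fraction = sex_fraction, age_range = age_range,
                 motion_distribution = motion_distribution,
                 n_sites = as.integer(n_sites),
                 group_specs = group_specs,
                 feature_set_specs = feature_set_specs,
                 comorbidity_coupling = comorbidity_coupling,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Diagnosis indicators under the pairwise log-odds (Ising-style) model:
# independent Bernoulli draws from the per-participant base logits, then a
# fixed number of Gibbs sweeps through the groups with coupling J.
sample_diagnoses <- function(h, J, n_sweeps = 10L) {
  n <- nrow(h); g <- ncol(h)
  D <- matrix(stats::rbinom(n * g, 1L, stats::plogis(h)), n, g)
  if (g > 1 && any(J != 0)) {
    for (s in seq_len(n_sweeps)) {
      for (k in seq_len(g)) {
        logit <- h[, k] + D[, -k, drop = FALSE] %*% J[k, -k]
        D[, k] <- stats::rbinom(n, 1L, stats::plogis(logit))
      }
    }
  }
  D
}

#' Generate a synthetic cohort with planted effects
#'
#' Produces a participant table (id, sex, age, motion, site, ICD-10 code
#' set) and one feature matrix per configured feature set, row-aligned to
#' the participant table.  Deterministic given the config (which includes
#' the seed).
#'
#' Diagnosis assignment uses each group's prevalence (plus optional
#' covariate-dependent tilts) as per-participant base log-odds, coupled
#' across groups through the pairwise log-odds `comorbidity_coupling`
#' matrix and sampled by a fixed number of Gibbs sweeps.  With zero
#' coupling, group indicators are independent Bernoulli draws at exactly
#' the configured prevalences.
#'
#' @param config a [cohort_config()].
#' @return list with `participants` (a tibble; `icd10` is a list-column of
#'   character vectors) and `features` (named list of matrices whose
#'   rownames are participant ids).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) abort_config("config must be a cohort_config")
  withr::local_seed(config$seed)
  n <- config$n_participants
  id <- sprintf("S%06d", seq_len(n))
  sex <- ifelse(stats::runif(n) < config$sex_fraction, "F", "M")
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  motion <- stats::rlnorm(n, config$motion_distribution$location,
                          config$motion_distribution$scale)
  site <- sample.int(config$n_sites, n, replace = TRUE)

  g <- length(config$group_specs)
  codes <- vector("list", n)
  for (i in seq_len(n)) codes[[i]] <- character(0)
  D <- matrix(0L, n, g)
  if (g > 0) {
    h <- matrix(0, n, g)
    for (k in seq_len(g)) {
      gs <- config$group_specs[[k]]
      base <- stats::qlogis(gs$prevalence)
      cs <- gs$covariate_shifts
      tilt <- 0
      if (cs$age_shift_years != 0)
        tilt <- tilt + cs$age_shift_years / stats::var(age) * (age - mean(age))
      if (cs$motion_shift != 0)
        tilt <- tilt + cs$motion_shift / stats::var(motion) * (motion - mean(motion))
      if (cs$sex_log_odds != 0)
        tilt <- tilt + cs$sex_log_odds * (sex == "F")
      h[, k] <- base + tilt
    }
    D <- sample_diagnoses(h, config$comorbidity_coupling)
    for (k in seq_len(g)) {
      members <- which(D[, k] == 1L)
      code <- config$group_specs[[k]]$code
      for (i in members) codes[[i]] <- c(codes[[i]], code)
    }
  }

  participants <- tibble::tibble(id = id, sex = sex, age = age,
                                 motion = motion, site = site, icd10 = codes)

  features <- list()
  for (fs in config$feature_set_specs) {
    p <- fs$n_features
    X <- matrix(stats::rnorm(n * p, 0, fs$noise_sd), n, p,
                dimnames = list(id, sprintf("%s_f%03d", fs$name, seq_len(p))))
    for (gname in names(fs$affected_features_per_group)) {
      k <- which(vapply(config$group_specs, function(x) x$code, "") == gname)
      if (length(k) != 1)
        abort_config("feature set %s references unknown group %s", fs$name, gname)
      idx <- fs$affected_features_per_group[[gname]]
      d <- fs$effect_size_per_group[[gname]]
      X[D[, k] == 1L, idx] <- X[D[, k] == 1L, idx] + d * fs$noise_sd
    }
    if (!is.null(fs$age_effect))
      X[, fs$age_effect$features] <- X[, fs$age_effect$features] +
        fs$age_effect$slope * (age - mean(config$age_range))
    if (!is.null(fs$sex_effect))
      X[sex == "F", fs$sex_effect$features] <-
        X[sex == "F", fs$sex_effect$features] + fs$sex_effect$d * fs$noise_sd
    if (fs$site_shift != 0) {
      offsets <- fs$site_shift * fs$noise_sd *
        (seq_len(config$n_sites) - (config$n_sites + 1) / 2)
      X <- X + offsets[site]
    }
    features[[fs$name]] <- X
  }

  list(participants = participants, features = features)
}

#' Write a cohort to a directory of CSV files
#'
#' `participants.csv` carries columns id, sex, age, motion, site, icd10
#' (semicolon-delimited code list; empty field for an empty set).  Each
#' feature set is written as `<name>.csv` with an `id` first column.
#' Floats are written round-trippably.
#'
#' @param cohort list as returned by [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  # %.17g guarantees bit-exact double round-trips through text
  fmt <- function(x) sprintf("%.17g", x)
  pt <- cohort$participants
  flat <- tibble::tibble(id = pt$id, sex = pt$sex, age = fmt(pt$age),
                         motion = fmt(pt$motion), site = pt$site,
                         icd10 = vapply(pt$icd10, paste, "", collapse = ";"))
  paths <- file.path(dir, "participants.csv")
  readr::write_csv(flat, paths[1])
  for (nm in names(cohort$features)) {
    X <- cohort$features[[nm]]
    df <- tibble::as_tibble(apply(X, 2, fmt), .name_repair = "minimal")
    df <- tibble::add_column(df, id = rownames(X), .before = 1)
    path <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(df, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a cohort written by [write_cohort()]
#'
#' Every `*.csv` file in `dir` other than `participants.csv` is read as a
#' feature set.  Feature rows must map one-to-one onto participant ids;
#' unknown or missing ids and missing feature cells raise a format error
#' naming the offending participant.
#'
#' @param dir directory containing `participants.csv` and feature CSVs.
#' @return list with `participants` and `features`, matching the
#'   [generate_cohort()] layout.
#' @export
read_cohort <- function(dir) {
  ppath <- file.path(dir, "participants.csv")
  if (!file.exists(ppath)) abort_format("no participants.csv in %s", dir)
  # numeric columns come in as text and go through strtod (as.numeric) for
  # bit-exact round-trips; vroom's fast parser can be off by one ulp
  flat <- readr::read_csv(ppath, col_types = readr::cols(.default = "c"))
  flat$age <- as.numeric(flat$age)
  flat$motion <- as.numeric(flat$motion)
  flat$site <- as.integer(flat$site)
  codes <- strsplit(ifelse(is.na(flat$icd10), "", flat$icd10), ";", fixed = TRUE)
  codes <- lapply(codes, function(x) x[nzchar(x)])
  participants <- tibble::tibble(id = flat$id, sex = flat$sex, age = flat$age,
                                 motion = flat$motion, site = flat$site,
                                 icd10 = codes)
  features <- list()
  for (path in sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))) {
    if (basename(path) == "participants.csv") next
    df <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
    unknown <- setdiff(df$id, participants$id)
    if (length(unknown) > 0)
      abort_format("feature file %s has row id %s absent from participant table",
                   basename(path), unknown[1])
    X <- suppressWarnings(
      vapply(df[, -1, drop = FALSE], as.numeric, numeric(nrow(df))))
    if (!is.matrix(X))
      X <- matrix(X, nrow = nrow(df), dimnames = list(NULL, names(df)[-1]))
    bad <- df$id[!stats::complete.cases(X)]
    if (length(bad) > 0)
      abort_format("feature file %s has missing values for participant %s",
                   basename(path), bad[1])
    rownames(X) <- df$id
    features[[sub("\\.csv$", "", basename(path))]] <- X
  }
  list(participants = participants, features = features)
}
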