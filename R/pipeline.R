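# End-to-end orchestration: cohort -> group selection -> matching ->
# classification -> inference, with optional multiclass, leave-one-site-out
# and age-benchmark stages, all driven by one config and one seed.

default_run_config <- function() {
  list(seed = 1L,
       cohort = NULL,                # cohort_config, or list(dir = path)
       hierarchy = NULL,             # NULL -> default_hierarchy()
       min_cases = 125,
       stages = c("groups", "match", "classify", "infer"),
       feature_sets = NULL,          # NULL -> all generated sets
       models = "random_forest",
       grid = list(),                # grid overrides applied to every model
       n_splits = 100, train_fraction = 0.8, inner_folds = 5,
       correction_scope = NULL,      # NULL -> feature_sets
       multiclass = FALSE, logo = FALSE,
       age_benchmark = NULL)         # an age_benchmark_spec to enable
}

validate_run_config <- function(config) {
  config <- utils::modifyList(default_run_config(), config)
  if (is.null(config$cohort))
    abort_config("config$cohort is required (a cohort_config or list(dir = ...))")
  needed <- c("groups", "match", "classify", "infer")
  missing <- setdiff(needed, config$stages)
  if (length(missing) > 0)
    abort_config("config omits required stage(s): %s",
                 paste(missing, collapse = ", "))
  if (config$n_splits < 2) abort_config("n_splits must be at least 2")
  config
}

#' Coerce a plain list (e.g. parsed YAML) to a cohort configuration
#'
#' Accepts the field-for-field list layout of [cohort_config()], with
#' `group_specs` and `feature_set_specs` given as lists of argument lists
#' and `comorbidity_coupling` as a nested list or matrix.
#'
#' @param x a `cohort_config` (returned unchanged) or a named list.
#' @return a validated [cohort_config()].
#' @export
as_cohort_config <- function(x) {
  if (inherits(x, "cohort_config")) return(x)
  if (!is.list(x)) abort_config("cannot interpret cohort specification")
  x$group_specs <- lapply(x$group_specs, function(g)
    if (inherits(g, "group_spec")) g else do.call(group_spec, g))
  x$feature_set_specs <- lapply(x$feature_set_specs, function(f)
    if (inherits(f, "feature_set_spec")) f else do.call(feature_set_spec, f))
  if (!is.null(x$comorbidity_coupling) && !is.matrix(x$comorbidity_coupling))
    x$comorbidity_coupling <-
      do.call(rbind, lapply(x$comorbidity_coupling, unlist))
  if (!is.null(x$age_range)) x$age_range <- unlist(x$age_range)
  do.call(cohort_config, x[intersect(names(x), names(formals(cohort_config)))])
}

#' Read a run configuration from YAML
#'
#' Scalar fields mirror the [run_pipeline()] config list; `cohort: {dir: }`
#' points at a cohort directory written by [write_cohort()], while an
#' inline `cohort:` block mirroring [cohort_config()] field-for-field asks
#' the pipeline to generate the cohort.
#'
#' @param path YAML file path.
#' @return a validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$age_benchmark))
    cfg$age_benchmark <- do.call(age_benchmark_spec, cfg$age_benchmark)
  validate_run_config(cfg)
}

#' Run the full benchmark pipeline from one configuration
#'
#' Stages run in dependency order: cohort load/generate, diagnostic group
#' selection, case-control matching, per-(group x feature set x model)
#' shuffle-split classification, significance and FDR inference, and the
#' optional multiclass, leave-one-site-out and age-benchmark comparisons.
#' All randomness flows from `config$seed`; re-running an identical config
#' reproduces `results.csv` byte-for-byte.
#'
#' @param config config list (see `validate_run_config` fields) or a YAML
#'   path.
#' @param out_dir output directory; created if missing.
#' @return invisibly, a list with the in-memory stage outputs (`cohort`,
#'   `groups`, `matches`, `balance`, `accuracies`, `results`, plus
#'   `confusion`, `logo`, `age` when enabled) and the `manifest`.  Files
#'   written: `manifest.json`, `groups.json`, `matches.csv`,
#'   `balance.json`, `accuracies.csv`, `results.csv`, and per-stage extras
#'   (`confusion.csv`, `logo.csv`, `age_groups.csv`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = rlang::hash(config), seed = config$seed,
                   package_version = as.character(utils::packageVersion("transdx")),
                   started = format(Sys.time(), tz = "UTC"),
                   stages = list())
  out <- list()
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- "failed"
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      rlang::abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                   parent = e)
    })
    manifest$stages[[name]] <<- "ok"
    res
  }
  seeds <- withr::with_seed(config$seed, draw_seed(8))

  cohort <- run_stage("cohort", function() {
    if (is.list(config$cohort) && !is.null(config$cohort$dir))
      read_cohort(config$cohort$dir)
    else generate_cohort(as_cohort_config(config$cohort))
  })
  out$cohort <- cohort
  fsets <- config$feature_sets %||% names(cohort$features)
  scope <- config$correction_scope %||% fsets

  hierarchy <- config$hierarchy %||% default_hierarchy()
  groups <- run_stage("groups", function() {
    membership <- assign_members(cohort$participants, hierarchy)
    retained <- retain_groups(membership, config$min_cases)
    if (length(retained) == 0) abort_config("no diagnostic group meets min_cases")
    list(membership = membership, retained = retained,
         comorbidity = comorbidity_stats(retained),
         unique_cases = unique_case_list(retained))
  })
  out$groups <- groups
  jsonlite::write_json(
    lapply(groups$retained, function(g)
      list(label = g$label, level = g$level, n = length(g$case_ids),
           case_ids = g$case_ids)),
    file.path(out_dir, "groups.json"), auto_unbox = TRUE)

  matches <- run_stage("match", function() {
    diagnosed <- unique(unlist(groups$membership$broad))
    pool <- cohort$participants[!(cohort$participants$id %in% diagnosed), ]
    match_controls(lapply(groups$retained, function(g) g$case_ids),
                   pool, cohort$participants, seed = seeds[1])
  })
  out$matches <- matches
  match_rows <- do.call(rbind, lapply(matches, function(m)
    tibble::add_column(m$pairs, group_label = m$label, .before = 1)))
  readr::write_csv(match_rows, file.path(out_dir, "matches.csv"))
  out$balance <- lapply(matches, balance_report, participants = cohort$participants)
  jsonlite::write_json(
    lapply(out$balance, function(b) b[c("label", "sex_chi2_stat", "sex_chi2_p",
                                        "age_p", "motion_p", "degenerate")]),
    file.path(out_dir, "balance.json"), auto_unbox = TRUE)

  accs <- run_stage("classify", function() {
    cells <- list()
    cell_seeds <- withr::with_seed(seeds[2],
      draw_seed(length(matches) * length(fsets) * length(config$models)))
    i <- 0
    for (m in matches) for (fs in fsets) for (fam in config$models) {
      i <- i + 1
      ids <- c(m$pairs$case_id, m$pairs$control_id)
      X <- cohort$features[[fs]][ids, , drop = FALSE]
      y <- rep(c("case", "control"), each = nrow(m$pairs))
      spec <- model_spec(fam, grid = config$grid)
      cells[[i]] <- run_binary(X, y, spec, n_splits = config$n_splits,
                               train_fraction = config$train_fraction,
                               inner_folds = config$inner_folds,
                               seed = cell_seeds[i],
                               cell = list(group = m$label, feature_set = fs,
                                           model = fam))
    }
    cells
  })
  out$accuracies <- accs
  acc_rows <- do.call(rbind, lapply(accs, function(a)
    tibble::tibble(group = a$cell$group, feature_set = a$cell$feature_set,
                   model = a$cell$model, split_index = seq_len(a$n_splits),
                   accuracy = a$accuracies)))
  readr::write_csv(acc_rows, file.path(out_dir, "accuracies.csv"))

  results <- run_stage("infer", function() {
    build_results_table(summarize_cells(accs), scope = scope)
  })
  out$results <- results
  readr::write_csv(results, file.path(out_dir, "results.csv"))

  if (isTRUE(config$multiclass)) {
    out$confusion <- run_stage("multiclass", function() {
      m <- min(lengths(groups$unique_cases))
      if (m < 2) abort_config("unique case lists too small for multiclass")
      withr::local_seed(seeds[3])
      cases <- lapply(groups$unique_cases, function(ids)
        ids[sample.int(length(ids))][seq_len(m)])
      control_ids <- setdiff(match_rows$control_id, unlist(cases))
      control_ids <- control_ids[sample.int(length(control_ids))][seq_len(m)]
      labs <- multiclass_labels(cases, control_ids)
      X <- cohort$features[[fsets[1]]][names(labs), , drop = FALSE]
      run_multiclass(X, labs, n_splits = config$n_splits,
                     train_fraction = config$train_fraction, seed = seeds[4])
    })
    cm <- out$confusion$counts
    conf_rows <- tibble::tibble(
      true_label = rep(rownames(cm), times = ncol(cm)),
      predicted_label = rep(colnames(cm), each = nrow(cm)),
      count = as.vector(cm))
    readr::write_csv(conf_rows, file.path(out_dir, "confusion.csv"))
  }

  if (isTRUE(config$logo)) {
    out$logo <- run_stage("logo", function() {
      rows <- list()
      for (m in matches) {
        ids <- c(m$pairs$case_id, m$pairs$control_id)
        X <- cohort$features[[fsets[1]]][ids, , drop = FALSE]
        y <- rep(c("case", "control"), each = nrow(m$pairs))
        sites <- cohort$participants$site[match(ids, cohort$participants$id)]
        lg <- run_logo(X, y, sites, model_spec(config$models[1],
                                               grid = config$grid),
                       inner_folds = config$inner_folds, seed = seeds[5])
        rows[[m$label]] <- tibble::add_column(lg, group = m$label, .before = 1)
      }
      do.call(rbind, rows)
    })
    readr::write_csv(out$logo, file.path(out_dir, "logo.csv"))
  }

  if (!is.null(config$age_benchmark)) {
    out$age <- run_stage("age_benchmark", function() {
      eligible <- unique(c(unlist(lapply(groups$retained, function(g) g$case_ids)),
                           match_rows$control_id,
                           cohort$participants$id[
                             !(cohort$participants$id %in%
                                 unique(unlist(groups$membership$broad)))]))
      pool <- cohort$participants[cohort$participants$id %in% eligible, ]
      arms <- build_age_groups(pool, config$age_benchmark, seed = seeds[6])
      arm_rows <- rbind(tibble::add_column(arms$large, arm = "large", .before = 1),
                        tibble::add_column(arms$small, arm = "small", .before = 1))
      accs <- lapply(arms, function(arm) {
        X <- cohort$features[[fsets[1]]][arm$id, , drop = FALSE]
        run_binary(X, arm$label, model_spec(config$models[1],
                                            grid = config$grid),
                   n_splits = config$n_splits,
                   train_fraction = config$train_fraction,
                   inner_folds = config$inner_folds, seed = seeds[7],
                   cell = list(group = "age", feature_set = fsets[1],
                               model = config$models[1]))
      })
      list(arms = arm_rows, accuracies = accs)
    })
    readr::write_csv(out$age$arms, file.path(out_dir, "age_groups.csv"))
  }

  manifest$finished <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out$manifest <- manifest
  invisible(out)
}
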