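#' Study-shaped synthetic benchmark configuration
#'
#' A ready-made [cohort_config()] emulating the structure of the
#' transdiagnostic benchmark at desk scale: 17 diagnostic groups drawn from
#' ICD-10 Chapters V and VI — sixteen of them around 250 cases (including a
#' small demyelinating-disease-like group, `G35`) and one large
#' depression-like group (`F32`, around 2,600 cases at the default cohort
#' size — mirroring the 125–1,329-case spread and a large depression group
#' of the real cohort); two 20-feature sets standing in for structural and
#' functional imaging-derived phenotypes.  Two effects are planted: a
#' strong one (`strong_d`, default 1.0 SD) for the small `G35` group on the
#' first six `structural` features, and a weak one (`weak_d`, default 0.3
#' SD) for the large `F32` group on the first six `functional` features.
#' Every other group x feature-set combination is null.  A mild linear age
#' effect on six `structural` features supports the oldest-vs-youngest
#' benchmark.
#'
#' Optionally, `coupling` adds a pairwise log-odds increment between the
#' mood/anxiety groups (`F32`, `F33`, `F41`), reproducing the
#' anxiety-depression comorbidity overlap structurally.
#'
#' @param seed integer seed stored in the config.
#' @param n_participants cohort size (default 20,000).
#' @param strong_d planted effect (Cohen's d) for `G35` on `structural`.
#' @param weak_d planted effect for `F32` on `functional`.
#' @param age_slope per-year slope of the age effect on `structural`
#'   features 7-12.
#' @param coupling log-odds comorbidity increment among `F32`, `F33`,
#'   `F41` (0 disables it).
#' @return a [cohort_config()].
#' @export
study_benchmark_config <- function(seed = 1L, n_participants = 20000,
                                   strong_d = 1.0, weak_d = 0.3,
                                   age_slope = 0.05, coupling = 0) {
  codes <- c(F06 = "F00-F09", F10 = "F10-F19", F17 = "F10-F19",
             F31 = "F30-F39", F32 = "F30-F39", F33 = "F30-F39",
             F41 = "F40-F48", F43 = "F40-F48", F45 = "F40-F48",
             G25 = "G20-G26", G35 = "G35-G37", G40 = "G40-G47",
             G43 = "G40-G47", G45 = "G40-G47", G47 = "G40-G47",
             G56 = "G50-G59", G62 = "G60-G64")
  small_prev <- 250 / n_participants
  large_prev <- 2600 / n_participants
  groups <- lapply(names(codes), function(code)
    group_spec(code, codes[[code]],
               prevalence = if (code == "F32") large_prev else small_prev))
  J <- matrix(0, length(codes), length(codes),
              dimnames = list(names(codes), names(codes)))
  if (coupling != 0) {
    mood <- c("F32", "F33", "F41")
    J[mood, mood] <- coupling
    diag(J) <- 0
  }
  fsets <- list(
    feature_set_spec("structural", 20,
                     affected_features_per_group = list(G35 = 1:6),
                     effect_size_per_group = list(G35 = strong_d),
                     age_effect = list(slope = age_slope, features = 7:12)),
    feature_set_spec("functional", 20,
                     affected_features_per_group = list(F32 = 1:6),
                     effect_size_per_group = list(F32 = weak_d)))
  cohort_config(n_participants, sex_fraction = 0.5, age_range = c(40, 70),
                n_sites = 3, group_specs = groups,
                feature_set_specs = fsets, comorbidity_coupling = J,
                seed = seed)
}
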