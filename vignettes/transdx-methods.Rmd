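---
title: "Methods: transdiagnostic case-control classification benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transdiagnostic case-control classification benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(transdx)
```

## The problem

Large epidemiological imaging cohorts attach ICD-10 hospital diagnoses to
tens of thousands of participants with imaging-derived phenotypes (IDPs).
A natural question is how well standard machine-learning pipelines can
separate members of a diagnostic group from carefully matched healthy
controls — and, when they mostly cannot, whether that failure is a
property of the features, the models, or the diagnostic ontology itself.
`transdx` implements the full benchmark needed to ask that question
rigorously: hierarchical diagnostic group selection, prioritized unique
case-control matching, a leakage-free classification engine evaluated
over stratified shuffle-splits, a deliberately conservative chance-level
significance criterion, FDR control across feature sets, and an
oldest-vs-youngest age classification that serves as an upper-bound
reference. Because the motivating cohort data are access-restricted, the
package also ships a synthetic cohort generator with planted effects, so
every stage is exercised end to end by code anyone can run.

## Diagnostic groups

ICD-10 organizes diagnoses hierarchically: chapter (V, mental and
behavioural disorders; VI, diseases of the nervous system), first-level
block ("broad" group, e.g. G35–G37), and second-level code ("narrow"
group, e.g. F32). `assign_members()` rolls decimal subcodes up to their
2-digit parent and computes broad and narrow membership; `retain_groups()`
applies the retention rule: a narrow group is kept when it has at least
`min_n` cases (default 125); when no narrow group in a block qualifies but
the block as a whole does, the broad group is kept instead; blocks below
threshold at both levels are dropped. When a narrow group qualifies, its
sub-threshold siblings are dropped entirely rather than merged — the rule
as stated, applied literally. `comorbidity_stats()` reports the fraction
of diagnosed individuals in more than one retained group and the
conditional pairwise overlap matrix; `unique_case_list()` removes every
multi-group individual, producing the disjoint class sets that the
multiclass analysis requires.

## Matching

`match_controls()` pairs every case with a healthy control (no chapter
V/VI codes) by lexicographic closeness: the control must have identical
sex; among unused same-sex controls the minimal absolute age difference
wins; ties go to minimal absolute head-motion difference, then to the
smallest control id (for reproducibility). Each control is consumed at
most once across *all* groups of a run. Design choices the data do not
dictate: groups are processed in ascending size so small groups are not
starved by pool depletion, and cases within a group are visited in a
seed-shuffled order; matching is greedy per case rather than a global
optimal assignment, because the per-case priority rule is the semantics
being implemented, not total distance minimization. Age is compared as
floating-point years. Sex matching is exact by construction, so the
case-control sex chi-square statistic is identically zero; age and head
motion are checked by two-sample t-tests in `balance_report()` (chi-square
without continuity correction, so a perfectly balanced table reports
p = 1 exactly).

`subsample_to_reference()` implements size-matched re-analysis: a large
group is reduced to the size of the smallest retained group (125 pairs by
default) by matching its cases to the reference group's cases under the
same sex > age > motion rule, keeping the original controls.

## The classification engine

`run_binary()` evaluates one (group × feature set × model) cell.  Within
each of `n_splits` stratified training/validation splits (default 100
splits, 80/20):

1. feature-wise standardization is fit on the training rows only;
2. PCA is fit on the standardized training rows only;
3. hyperparameters — including the PCA rank — are chosen by an inner
   stratified 5-fold cross-validation confined to the training rows, with
   accuracy as the selection metric (matching the outer metric);
4. the pipeline is refit on the full training portion and validation
   accuracy is recorded.

The returned object is the vector of per-split validation accuracies; its
distribution, not just its mean, is the unit of inference. Three
classifier families share the identical pipeline: random forests
(`ranger`, tree count fixed at 250; depth and split-feature fraction
tunable), support vector classifiers (`e1071`; cost and kernel tunable),
and k-nearest neighbors (neighbor count, weight function, and distance
metric tunable; implemented in-package because distance weighting and
Manhattan distance are part of the tuning surface). Default grids are
placeholders in the literal sense — any serious run should set them
deliberately — and a one-row grid switches the inner CV off.

Constant feature columns are dropped up front with a warning (they carry
no information and break standardization). Columns constant within a
training split only are given unit scale. The whole accuracy vector is a
deterministic function of the seed; random-number consumption depends
only on data dimensions, never on feature values, which is what makes the
leakage audit in the test suite possible (corrupting validation rows must
leave the fitted pipeline of a split unchanged).

`run_logo()` replaces the shuffle-splits with leave-one-site-out folds to
expose site effects: a model is trained on all but one acquisition site
and tested on the held-out site. A held-out site lacking one of the two
classes is skipped with a warning. `run_multiclass()` implements the
one-vs-rest formulation over the disjoint size-matched classes plus
controls: one fixed-settings random forest per class (250 trees, default
Gini splitting) inside a standardization + fixed-rank PCA pipeline, with
the predicted label being the class of maximal positive-class
probability. A pooled confusion matrix by itself does not fix a
validation scheme, so the package uses stratified 80/20
shuffle-splits with a per-subject majority vote over the splits in which
the subject was held out; at reduced split counts a subject can escape
every validation set, in which case it receives one extra prediction from
a model trained on the covered subjects only — no leakage, and row sums
always equal the true class sizes.

## The significance criterion

For split accuracies \(a_1, \dots, a_n\) and chance level 0.5,

\[ t = \frac{\bar{a} - 0.5}{s_a}, \qquad p = P_{\mathrm{St}}(T \ge t \mid n), \]

where \(s_a\) is the *sample standard deviation* of the split accuracies
and the Student-t degrees of freedom equal the number of shuffle-splits
\(n\) — literally \(n\), not \(n - 1\), a deliberate deviation from
textbook convention that follows the criterion as defined. Because the
denominator is \(s_a\) rather than \(s_a/\sqrt{n}\), the criterion is a
factor \(\sqrt{n}\) more stringent than a one-sample t-test against
chance: it asks whether the whole accuracy distribution sits above the
chance line, not merely whether the mean does. The test suite verifies
both properties — agreement with an independent numerically integrated
t-tail oracle to 1e-10, and dominance over the one-sample t-test p-value
on every vector with mean above chance — and confirms empirically that
the criterion's type-I error on null cohorts is far below the nominal
\(\alpha = 0.05\).

Zero-variance accuracy vectors are degenerate for this statistic; the
package reports the limiting tail probability (0 above chance, 0.5 at
chance, 1 below) with an explicit `degenerate` flag rather than `NaN`.

Multiple-comparison correction uses Benjamini–Hochberg FDR *within each
diagnostic group across feature sets* — the correction scope is an
explicit argument of `build_results_table()`, because the benchmark's own
logic turns on it: a cell can be significant when corrected across the 2
structural sets yet lose significance across all 20 sets, purely through
the heavier correction burden. No correction is applied across diagnostic
groups: the scientific question is per-group, across the feature sets tried for it. Flags follow the reporting
convention `significant` (corrected p < 0.05) and `trend`
(0.05 ≤ corrected p < 0.10).

## The age benchmark

`build_age_groups()` forms an oldest (67–70, the "case" class) versus
youngest (40–42, "control") contrast from the diagnosed-plus-undiagnosed
pool, pairing extremes greedily: old candidates in descending age order
each take the youngest unused same-sex candidate, with nearest head
motion breaking age ties. Arms are exactly half old and half young and
sex-matched by construction. The large and small arms mirror the largest
and smallest diagnostic groups; the small arm is a fresh selection by
default (`small_as_subset = TRUE` draws it from the large arm instead —
both readings of "subsampling" are defensible). The same
`run_binary()` engine then quantifies an effect that is essentially
always detectable, providing the upper-bound contrast against which the
diagnostic accuracies are read.

## The synthetic cohort generator

`generate_cohort()` draws sex (Bernoulli), age (uniform on a bounded
range, 40–70 by default), head motion (log-normal — the positive-skewed
shape typical of in-scanner motion summaries; the matching covariate's
true law is not documented, so a minimal-parameter choice is used), and
site (uniform categorical). Diagnoses follow per-group prevalences
optionally tilted by covariates: a target case-vs-population mean shift
is converted to a logistic coefficient by the exponential-tilting
approximation `beta = shift / var(covariate)`. Pairwise comorbidity is
induced by an Ising-style pairwise log-odds coupling sampled with a fixed
number (10) of Gibbs sweeps — chosen as the minimal-parameter generative
form able to produce controllable overlap; with zero coupling the group
indicators are exact independent Bernoulli draws. Coupling shifts the
realized marginal prevalences slightly; prevalences are therefore base
rates, not guaranteed margins.

Features are Gaussian noise plus additive planted effects: a group effect
expressed in Cohen's d units (a mean shift of `d * noise_sd` on the
configured indices — calibrated, and verified in the tests, against a
two-sample Cohen's d estimator), a linear age slope, a standardized sex
shift, and deterministic mean-centered equally spaced per-site offsets.
Feature indices are 1-based. What the generator deliberately does *not*
emulate: raw images or time series (features are generated at IDP level),
longitudinal structure or diagnosis dates, non-Gaussian feature marginals,
and realistic covariate-diagnosis confounding magnitudes (these are
config knobs, not asserted facts). Tests passing on synthetic cohorts
therefore certify the pipeline's statistical machinery — calibration,
leakage-freedom, conservativeness, recovery of planted effects — not any
claim about real cohort separability.

`study_benchmark_config()` packages the study-shaped conditions used by
the test suite and the acceptance script: 20,000 participants, 17
diagnostic groups (sixteen near 250 cases, one depression-like group near
2,600, mirroring the 125–1,329-case spread of the motivating cohort), two
20-feature sets standing in for structural and functional IDPs, a strong
(d = 1.0) effect for the small demyelinating-like group on six structural
features, a weak (d = 0.3) effect for the large group on six functional
features, a mild age slope (0.05 SD/year) on six structural features, and
optional mood/anxiety comorbidity coupling. The strong/weak magnitudes
were chosen once to reproduce the qualitative finding pattern — a small
group detectable through effect size, a large group detectable through
sample size, everything else null.

## Problem sizes and numerical choices

The heavy simulation checks are scaled to run on one CPU in minutes, as
the package's own choice of problem size: 20 shuffle-splits instead of
100 where the property under test does not depend on the split count,
one-row tuning grids where tuning is not the property under test, and the
fast k-nearest-neighbors family for the largest simulated cohorts (the
chance-level and type-I properties being verified are
classifier-agnostic; random forests at the fixed 250 trees are used
wherever cell sizes keep them affordable, including the multiclass chance
floor and the effect-size monotonicity check, which covers all three
families). Tie-breaks are deterministic everywhere: first grid row on
tied inner-CV scores, training-row order in the k-NN neighbor ranking,
class order on tied votes, smallest id in matching. All file output
formats round-trip doubles bit-exactly (`%.17g` on write, `strtod` on
read).

## Limitations

The package evaluates accuracy only (no ROC or calibration analysis, as
in the benchmark design); matching offers the priority rule only (no
propensity scores or calipers); the default hyperparameter grids are
conveniences, not reconstructions of any published grid; and the shipped
ICD-10 hierarchy covers chapters V–VI at block/second level as a
convenience default, without claiming to reproduce any particular
cohort's retained group list.
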