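---
title: "Methods: image-based profiling and the cell-injury classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based profiling and the cell-injury classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoprofile)
```

# The processing model

An image-based profiling experiment measures hundreds of morphology
features per cell across multi-plate screens. cytoprofile models the data
at every stage as a *profile table*: a rectangular table whose columns are
partitioned, by the `Metadata_` prefix convention (case sensitive), into
metadata (plate, well, treatment, …) and numeric features. The partition is
derived from column names rather than stored state, so any stage can accept
a plain data frame, and the invariant that numeric operations never touch
metadata holds by construction. Missing feature values are legal
everywhere; on delimited text the tokens `""`, `"NA"`, `"NaN"`, `"nan"`
read as missing and missing writes as the empty field, which fixes an
otherwise ambiguous CSV dialect.

Single-cell input follows the CellProfiler relational schema: an image
table keyed by `ImageNumber` carrying plate/well metadata, and one object
table per compartment keyed by `(ImageNumber, ObjectNumber)`. The store is
persisted as a directory of plain CSV tables — one file per relation — a
transparent, diff-able text serialization of the same schema. Object and
image numbers are 1-based as produced upstream and are never renumbered, so
every merged cell remains traceable to its source image. The cytoplasm
table carries explicit `Parent_Cells` / `Parent_Nuclei` link columns, and
the compartment merge follows those links rather than assuming equal object
numbers; segmentation does not guarantee aligned numbering, and assuming
equality would silently mispair compartments. Cells absent from any
requested compartment are excluded by the inner join and counted in the
merge report. Which key columns a given upstream pipeline uses for the
merge is a convention choice; the parent-link rule used here is the one
CellProfiler's own output supports and is stated as such.

## Aggregation, annotation, consensus

Cells collapse to wells by the per-feature median (default) or mean over
the group's non-missing values; whole-cell deletion on any missing feature
would bias cell counts, so missingness is handled per feature. The median
of an even count is the mean of the two central order statistics. A
per-group observation count is appended as metadata, and the counts always
sum to the input row count. Annotation is a left join against the plate
map: profile rows are never discarded by annotation, unmatched rows keep
missing annotations, and the count of unmatched rows is attached as a
report. Consensus profiles are the same aggregation applied at
perturbation-level strata (e.g. compound × concentration).

## Normalization

All three methods are fitted on a *reference population* — by default all
rows, in practice the negative-control (DMSO) wells selected by a predicate
such as `Metadata_compound == 'DMSO'` — and the model records that
predicate and the reference size. Fitting provably uses only reference
rows.

* **standardize**: location is the reference mean, scale the reference
  *population* standard deviation (denominator *n*), matching the common
  scaler convention in profiling pipelines and making the
  reference-maps-to-mean-0/SD-1 invariant exact.
* **mad_robustize**: location is the median and scale the median absolute
  deviation times 1.4826, the constant that makes the MAD unbiased for
  Gaussian scale. Cytotoxic treatments produce extreme feature values, so
  the robust pair is the default in the pipeline stages.
* **spherize**: ZCA whitening. With eigendecomposition
  `Σ = E diag(λ) Eᵀ` of the reference sample covariance, the transform is
  `W = E diag(1/√(λ + ε)) Eᵀ` and rows map as `v ↦ (v − μ̂) W`. The ZCA
  orientation (rather than PCA) keeps each transformed feature aligned
  with its original, preserving interpretability. Fitted on negative
  controls, whitening compresses the covariance directions that batch
  effects inflate: on synthetic screens with a plate-level offset of 1 SD,
  sphering on controls removes well over half of the between-plate
  variance fraction of informative features (this is asserted in the test
  suite).

Numerical choices: every per-feature scale is floored at
`epsilon = 1e-18`, so constant features yield huge but finite values
rather than division by zero; eigenvalues are clipped at zero before the
ridge `regularization` (default `1e-6`) is added, and a rank-deficient
covariance with zero regularization is an explicit error rather than an
infinite transform. Models serialize to JSON (method, vectors, whitening
matrix, feature list in fitted order) and refuse application to tables
missing any fitted feature.

# Feature selection

The filters and their exact comparison semantics:

* **variance_threshold**: over non-missing entries, let `r` be the count
  of the second-most-frequent value over the count of the most frequent,
  and `u` the distinct-value fraction. Drop when `r ≤ freq_cut` **or**
  `u ≤ unique_cut`. The boundary is inclusive: a feature at exactly the
  cutoff is removed. Default `freq_cut = 0.05`; `unique_cut = 0.01` is a
  package default, stated as such.
* **drop_na_columns**: drop when the missing fraction strictly *exceeds*
  `na_cutoff` (default 0.05) — a feature at exactly 5% missing survives.
  The two filters deliberately use opposite boundary conventions; both are
  tested at their boundaries.
* **correlation_threshold**: Pearson correlations over pairwise-complete
  observations; a pair with fewer than 3 complete observations, or
  involving a zero-variance feature, counts as correlation 0 (removing
  zero-variance features is the variance filter's job). Greedily, the pair
  with the largest `|r| ≥ corr_threshold` is found and the member with the
  larger mean absolute correlation to all remaining features is dropped;
  exact ties drop the later column, making the procedure deterministic
  across platforms. The survivor set is verified against an independent
  exhaustive oracle on small random tables.
* **blocklist**: glob patterns over feature names, for families known to
  be unreliable in a given assay.

`feature_select()` applies the configured operations in order, each on the
survivors of the previous one — cheap filters first by default — and
attributes each dropped feature to the first rule that fired, so the
report (feature, status, rule, statistic) is deterministic and covers
every input feature exactly once.

One subtlety the synthetic tests document: when a feature and its
near-exact duplicate both survive to the correlation filter, the duplicate
(carrying a trace more noise) is very slightly *less* correlated with the
rest of the panel, so the mean-|r| rule systematically drops the original
and keeps the copy. The information content of the survivor set is the
same; tests therefore assert that each duplicate pair collapses to exactly
one member rather than that the parent by name survives.

# The cell-injury workflow

## Labels

The vocabulary is fixed at 15 classes: Control plus Cytoskeletal, Hsp90,
Kinase, Genotoxin, Miscellaneous, Redox, HDAC, mTOR, Proteasome, Saponin,
Mitochondria, Ferroptosis, Tannin, and Nonspecific Reactive. DMSO wells
are Control; wells whose compound has no known injury association are
removed (and counted) rather than guessed. Schemes may carry InChIKeys,
the structure-hash identifiers used to match treatments across datasets.

## Holdouts and split

Generalization is probed at three granularities, constructed in a fixed
sequence so the assignment is deterministic: first whole plates (10 by
default), then whole treatments — only injuries with strictly more than 10
distinct treatments qualify, one treatment per qualifying injury held out
by default — then per-plate wells (5 controls + 10 injury wells from each
remaining plate; a plate lacking enough eligible wells contributes what it
has and the shortfall is recorded). A well caught by an earlier holdout is
never reassigned, so the three holdouts and the modeling set partition the
labeled wells exactly. The per-plate composition reading (15 wells total:
5 controls plus 10 injury wells) is one of two possible readings of the
design it emulates; it is the default and is configurable.

The modeling set splits 80/20 stratified by label. The test size is
`ceiling(0.2 · n)` — under which a 13,502-well modeling set yields exactly
10,801 training and 2,701 test wells — with per-class test counts assigned
by largest-fractional-part rounding, so per-class proportions match the
global split within one well.

## Classifier

Multinomial logistic regression with class weights inversely proportional
to class frequency (`n / (k · n_c)`), which counteracts the heavy
Control-class imbalance of injury screens; on imbalanced synthetic data
the weighted model strictly improves minority recall over the unweighted
one. Hyperparameters are chosen by randomized search: candidates are
sampled without replacement from the valid combinations of penalty
{L1, L2, elastic net}, inverse regularization strength
C ∈ {1e-4, 1e-2, 0.1, 1, 10, 100}, convergence tolerance {1e-6, 1e-3},
and, for elastic net only, L1 ratio {0.1, 0.3, 0.5, 0.7, 0.9} — the ratio
axis exists only for the elastic-net penalty, and invalid combinations are
excluded from sampling rather than failing at fit time. Default budget: 50
candidates, 5-fold stratified cross-validation scored by macro-F1; both
are explicit configuration, since a search budget is a resource choice,
not a property of the model.

Fits use coordinate descent (glmnet), the single solver of the fitting
engine; the penalty is mapped as `lambda = 1 / (n · C)` with mixing
`alpha` = 1 (L1), 0 (L2) or the L1 ratio, which makes C the inverse of the
total penalty weight on the summed log-likelihood, the usual
parameterization of regularized logistic regression. Features are not
re-standardized inside the fit (profiles are normalized upstream).
Remaining missing values are imputed with training-set feature medians;
the medians are stored in the model bundle and reapplied at prediction, so
training and application see the same transform. Convergence warnings are
recorded in the bundle, not swallowed. The bundle (classes, dense
coefficient matrix, intercepts, hyperparameters, feature list, imputation
medians, search settings, seed) serializes to JSON, and prediction is pure
linear algebra plus softmax on the stored coefficients — probabilities row-sum
to 1 by construction.

## Evaluation and the shuffled baseline

Per split (train, test, each holdout): per-class precision, recall, F1
(zero-denominator cases score 0), a confusion matrix whose rows sum to the
true class counts, macro-F1, and the per-well probability table.

The shuffled baseline is the dataset-level permutation null: labels of
*every* split are permuted, the full randomized search is retrained on the
permuted training split, and the null model is scored against the permuted
labels — the same construction as a permutation test of the entire
training procedure. Two tempting shortcuts fail. Refitting only the
winning hyperparameters can degenerate, under permutation, into a constant
predictor (a strongly regularized winner has nothing to fit), scoring
macro-F1 near `1/k²` instead of chance. Permuting only the training labels
while scoring against real test labels makes the null, on well-separated
classes, a function of a random mapping of k clusters onto k labels —
enormous variance around chance. Only the full dataset-level permutation
concentrates the null at `1/k`, which is what "chance level" should mean.

## External application

Applying a trained model to a dataset with a different feature panel uses
the shared feature space (`intersect_features()`, order taken from the
model) and matches treatments across datasets by InChIKey; matched wells
carry the scheme's injury as ground truth for evaluating the transfer.

# The synthetic-screen generator

The generator emulates the structure of a cytotoxicity screen — U-2OS-style
multi-plate layouts with DMSO control wells and compound-treated wells —
with known ground truth for every well and feature:

* **Class phenotypes**: each injury class shifts a random half of the
  informative features by `effect_size` standard deviations with a random
  sign per (class, feature). Sparse signed shifts mimic distinct
  morphological signatures while keeping the Bayes-optimal classifier
  derivable and keeping between-feature correlations induced by class
  structure moderate.
* **Plate batch effects**: each plate draws one offset
  `δ_p ~ N(0, plate_effect_sd)` entering all informative features through
  a fixed loading vector — the low-rank structure real plate effects
  exhibit, and the structure sphering can remove.
* **Feature panel**: alongside informative features, the panel contains
  near-constant features (one dominant value at frequency ≥ 0.96),
  duplicated features (an informative parent plus noise of SD 1e-6) and
  high-missing features (missing completely at random at `nan_rate`). The
  default composition is 70/10/10/10 over 100 features.
* **Missingness is MCAR only**; no informative-missingness mechanism is
  modeled, which keeps the feature-selection oracles exact.
* **Determinism**: one global seed drives every sub-generator through a
  fixed derivation rule; the same design reproduces its screen exactly.

Defaults: 10 plates × 96 wells, 25% control wells, all 14 injury classes
with 4 treatments each, effect size 3 SD, plate effect SD 0.5, 10%
missingness on high-missing features. Where a scenario needs specific
conditions (e.g. a 30-plate screen for holdout construction, or ~200 wells
per class over 5 classes at effect size 3 for classifier recovery), the
tests state those designs explicitly.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: realistic morphology covariance beyond the
stated blocks, spatial (edge/gradient) plate effects, concentration-response
structure, segmentation artifacts, or informative missingness. Synthetic
classes at 3 SD separation are far cleaner than real injury phenotypes;
recovery results on synthetic screens validate the machinery, not
biological performance.

# Pipeline and provenance

`run_pipeline()` executes a declarative YAML configuration (global seed,
output directory, ordered stages mirroring the API). The whole
configuration is validated before anything runs; every artifact gets a
provenance sidecar with tool version, config hash, seed and input digests;
a failing stage removes its partial outputs. Identical configuration and
seed reproduce identical artifacts and report values. The thin
command-line wrapper (`inst/cli/cytoprofile.R`) maps subcommands onto
`run_stage()`/`run_pipeline()`.

# Problem sizes and limitations

The test suite and the acceptance script run on deliberately modest
synthetic sizes — screens of 4–30 plates at 24–96 wells, feature panels of
29–100 columns, classifier runs near 1,000 wells with a 20-candidate
search — sizes a scientist would choose for fast, deterministic checks of
the machinery. Known limitations: no MODZ-style weighted consensus; no
per-batch linear-model correction beyond sphering; the correlation filter
is greedy (optimal subset selection under a correlation bound is NP-hard);
imputation is median-only; and the classifier is linear by design — the
demonstration's point is the processing layer, not model capacity.
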