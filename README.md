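# cytoprofile

Image-based profiling pipelines for high-content screens, in R.

High-content microscopy experiments — Cell Painting assays in particular —
produce per-cell morphology measurements (shapes, sizes, stain intensities,
textures) extracted by tools such as CellProfiler. Between those raw
single-cell features and any biological analysis sits a bioinformatics
layer: merging compartment tables into cells, aggregating cells into
well-level profiles, attaching the experimental design from plate maps,
normalizing against negative controls, correcting plate batch effects, and
discarding uninformative or redundant features. cytoprofile implements that
layer for R users, together with a complete demonstration workflow that
trains a multi-class classifier to recognize compounds causing nonspecific
cell injury — the "nuisance compounds" that confound phenotypic screens —
and a synthetic-screen generator with known ground truth so that every stage
is testable without any external download.

## What is implemented

**Profile I/O.** Profile tables (CSV/TSV/Parquet) follow the profiling
community's column convention: columns named `Metadata_*` are identifiers
and annotations, all other columns are numeric morphology features. Plate
maps assign compound, InChIKey, concentration and perturbation type to each
well; well identifiers are normalized to the `A01` convention.
CellProfiler-style single-cell stores (an image table plus `cells`,
`cytoplasm`, `nuclei` object tables, with explicit parent links on the
cytoplasm table) are merged into one row per cell, with orphan objects
excluded and counted.

**Profiling core.** `aggregate_profiles()` collapses cells to well profiles
(median or mean per feature, missing values ignored, per-group counts
appended); `annotate_profiles()` is a reporting left join against the plate
map; `consensus_profiles()` collapses replicates per perturbation.
`fit_normalization()` / `apply_normalization()` support three methods
fitted on a reference population (typically the DMSO wells):

* *standardize* — per-feature `(x − mean) / sd` with the **population** SD;
* *mad_robustize* — `(x − median) / (1.4826 · MAD)`, robust to the extreme
  values cytotoxic compounds produce;
* *spherize* — ZCA whitening `v ↦ (v − μ) W` with
  `W = E diag(1/√(λ + ε)) Eᵀ` from the eigendecomposition of the reference
  covariance; fitted on negative controls it acts as a batch-effect
  correction.

**Feature selection.** `feature_select()` chains auditable filters: a
near-zero-variance rule (second/first value-count ratio `r ≤ freq_cut`, or
distinct-value fraction `u ≤ unique_cut`), a missingness rule (drop when
the missing fraction strictly exceeds `na_cutoff`), a greedy
correlation filter (repeatedly drop the member of the worst offending pair
with the larger mean absolute correlation), and a name blocklist. The
result carries a per-feature report of which rule fired and with what
statistic.

**Injury classification.** A label scheme maps compounds to 15 classes
(Control plus 14 injury mechanisms); holdouts are constructed in the fixed
sequence plate → treatment → well; an 80/20 stratified split preserves
class proportions; the classifier is a class-weighted multinomial logistic
regression tuned by randomized search (penalty ∈ {L1, L2, elastic net},
strength C ∈ {1e-4 … 100}, tolerance, elastic-net ratio) with stratified
cross-validation scored by macro-F1, evaluated against a label-permutation
baseline, and applicable to external profile tables through shared-feature
intersection and InChIKey treatment matching.

**Synthetic screens.** `generate_screen()` emits profiles, plate map and
ground truth for a configurable design: sparse class-specific mean shifts,
low-rank plate batch effects, near-constant / duplicated / high-missing
feature blocks, and MCAR missingness.

## Worked example

```r
library(cytoprofile)

design <- screen_design(
  n_plates = 6, wells_per_plate = 96,
  classes = c("Cytoskeletal", "Hsp90", "Kinase", "Genotoxin"),
  treatments_per_class = 4, effect_size = 3, seed = 7)
screen <- generate_screen(design)
screen$profiles
#> profile_table: 576 observations, 2 metadata + 100 feature columns
#>   missing feature values: 595
#>   Metadata_Plate Metadata_Well Cells_Intensity_Feature_001 ...
#>   ... 572 more rows, 96 more columns

wells <- annotate_profiles(screen$profiles, screen$platemap)
norm  <- fit_normalization(wells, "mad_robustize",
                           reference = "Metadata_compound == 'DMSO'")
norm
#> normalization_model: mad_robustize over 100 features
#>   reference: Metadata_compound == 'DMSO' (144 rows); epsilon 1e-18
normalized <- apply_normalization(wells, norm)

sel <- feature_select(normalized,
                      operations = c("variance_threshold", "drop_na_columns",
                                     "correlation_threshold"))
sel$report
#> feature_selection_report: 70 of 100 features selected
#>   dropped by variance_threshold: 10
#>   dropped by drop_na_columns: 10
#>   dropped by correlation_threshold: 10

labeled <- label_wells(sel$profiles, as_injury_label_scheme(screen$ground_truth))
part <- make_holdouts(labeled, n_plates = 1, min_treatments = 10, seed = 7)
part
#> holdout_partition over 576 wells (seed 7):
#>   plate holdout:        96 wells (1 plates)
#>   treatment holdout:     0 wells (0 treatments)
#>   well holdout:         75 wells
#>   modeling set:        405 wells

splits <- split_train_test(as.data.frame(labeled)[part$modeling, ],
                           test_fraction = 0.2, seed = 7)
model <- train_injury_classifier(splits$train, n_candidates = 10,
                                 cv_folds = 5, seed = 7)
model
#> injury_model: 5 classes, 70 features (n_train = 324)
#>   penalty l2, C = 10, tol = 1e-06; class weights: balanced
#>   best CV macro-F1: 1.000 over 10 candidates

evaluate_model(model, list(train = splits$train, test = splits$test),
               shuffled_baseline = TRUE, seed = 7)
#> evaluation_report
#>   train              n =   324  macro-F1 = 1.000
#>   test               n =    81  macro-F1 = 1.000
#>   shuffled baseline:
#>   train*             n =   324  macro-F1 = 0.559
#>   test*              n =    81  macro-F1 = 0.165
```

The synthetic classes here are separated by 3 SD on a sparse subset of
features, so the real model recovers them essentially perfectly
(macro-F1 = 1.000 on held-out wells), while the label-permutation baseline
sits at chance for five classes (≈ 0.2): the model's performance reflects
real class structure, not capacity. Every number above is reproducible from
the seed. The same workflow runs unattended from a declarative YAML
configuration via `run_pipeline()` or the command-line wrapper in
`inst/cli/cytoprofile.R`, which writes a provenance sidecar (tool version,
config hash, seed, input digests) next to every artifact.

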