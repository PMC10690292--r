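# Shared fixture builders: small synthetic designs and labeled tables.

tiny_design <- function(seed = 1L, n_plates = 4L, wells_per_plate = 24L,
                        classes = c("Cytoskeletal", "Hsp90", "Kinase",
                                    "Genotoxin"),
                        treatments_per_class = 3L,
                        feature_composition = c(informative = 20L,
                                                near_constant = 3L,
                                                duplicated = 3L,
                                                high_missing = 3L),
                        ...) {
  screen_design(n_plates = n_plates, wells_per_plate = wells_per_plate,
                classes = classes,
                treatments_per_class = treatments_per_class,
                feature_composition = feature_composition, seed = seed, ...)
}

# Labeled Gaussian table: class k shifts feature ((k - 1) %% p) + 1 by
# `effect`; the Bayes-optimal rule is recoverable by construction.
make_labeled <- function(classes, n_per_class, n_features = 6L, effect = 0,
                         seed = 1L) {
  set.seed(seed)
  lab <- rep(classes, times = n_per_class)
  n <- length(lab)
  m <- matrix(stats::rnorm(n * n_features), n)
  colnames(m) <- sprintf("Cells_Feature_%02d", seq_len(n_features))
  for (k in seq_along(classes)) {
    j <- ((k - 1L) %% n_features) + 1L
    m[lab == classes[k], j] <- m[lab == classes[k], j] + effect
  }
  df <- data.frame(Metadata_Plate = sprintf("Plate_%02d",
                                            rep_len(1:4, n)),
                   Metadata_injury = lab, stringsAsFactors = FALSE)
  profile_table(cbind(df, as.data.frame(m)))
}

# end-to-end pipeline configuration over a small synthetic screen
pipeline_config <- function(dir, seed = 5L) {
  list(
    seed = seed, output_dir = dir,
    stages = list(
      list(stage = "synth", profiles = "profiles.parquet",
           platemap = "platemap.csv", ground_truth = "truth.json",
           scheme = "scheme.csv",
           design = list(n_plates = 4L, wells_per_plate = 48L,
                         classes = c("Cytoskeletal", "Hsp90", "Kinase",
                                     "Genotoxin"),
                         treatments_per_class = 3L,
                         feature_composition = list(informative = 20L,
                                                 near_constant = 3L,
                                                 duplicated = 3L,
                                                 high_missing = 3L),
                         seed = seed)),
      list(stage = "annotate", input = "profiles.parquet",
           platemap = "platemap.csv", output = "annotated.parquet"),
      list(stage = "normalize", input = "annotated.parquet",
           method = "mad_robustize",
           reference = "Metadata_compound == 'DMSO'",
           output = "normalized.parquet", model = "norm_model.json"),
      list(stage = "feature-select", input = "normalized.parquet",
           output = "selected.parquet", report = "fs_report.csv"),
      list(stage = "label", input = "selected.parquet", scheme = "scheme.csv",
           output = "labeled.parquet"),
      list(stage = "holdout-split", input = "labeled.parquet",
           train = "train.parquet", test = "test.parquet",
           plate_holdout = "plate_holdout.parquet",
           well_holdout = "well_holdout.parquet",
           n_plates = 1L, min_treatments = 10L, seed = seed),
      list(stage = "injury-train", input = "train.parquet",
           model = "model.json", n_candidates = 3L, cv_folds = 3L,
           seed = seed),
      list(stage = "injury-evaluate", model = "model.json",
           splits = list(train = "train.parquet", test = "test.parquet",
                         plate_holdout = "plate_holdout.parquet",
                         well_holdout = "well_holdout.parquet"),
           shuffled_baseline = TRUE, report = "evaluation.json",
           seed = seed)))
}

# in-memory plate map (via the package-internal validator)
as_platemap_for_test <- function(df) as_platemap(df)

write_temp_csv <- function(lines, ext = ".csv") {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

random_profile_table <- function(n = 12L, p = 5L, na_rate = 0.1, seed = 1L) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n * p), n)
  m[matrix(stats::runif(n * p) < na_rate, n)] <- NA_real_
  colnames(m) <- sprintf("Cells_Feature_%02d", seq_len(p))
  profile_table(cbind(
    data.frame(Metadata_Plate = sprintf("P%d", rep_len(1:3, n)),
               Metadata_Well = sprintf("A%02d", seq_len(n)),
               stringsAsFactors = FALSE),
    as.data.frame(m)))
}
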