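test_that("a design fully determines its screen", {
  d <- tiny_design(seed = 17L)
  s1 <- generate_screen(d)
  s2 <- generate_screen(d)
  expect_identical(as.data.frame(s1$profiles), as.data.frame(s2$profiles))
  expect_identical(s1$platemap, s2$platemap)
  expect_identical(s1$ground_truth$wells, s2$ground_truth$wells)
  s3 <- generate_screen(tiny_design(seed = 18L))
  expect_false(identical(as.data.frame(s1$profiles),
                         as.data.frame(s3$profiles)))
})

test_that("screen dimensions follow the design arithmetic", {
  d <- tiny_design(seed = 2L, n_plates = 10L, wells_per_plate = 96L)
  s <- generate_screen(d)
  expect_equal(nrow(s$profiles), 960L)
  expect_equal(length(feature_cols(s$profiles)), d$n_features)
  expect_equal(nrow(s$platemap), 960L)
  # ground truth covers every emitted well and feature
  expect_equal(nrow(s$ground_truth$wells), 960L)
  expect_setequal(s$ground_truth$features$feature, feature_cols(s$profiles))
  # control fraction per plate
  ctl <- tapply(s$platemap$compound == "DMSO", s$platemap$plate, sum)
  expect_true(all(ctl == round(0.25 * 96)))
})

test_that("zero effect size leaves class means indistinguishable", {
  pvals <- vapply(1:12, function(seed) {
    d <- tiny_design(seed = seed, effect_size = 0, plate_effect_sd = 0,
                     classes = c("Hsp90", "Kinase"), n_plates = 2L)
    s <- generate_screen(d)
    cls <- s$ground_truth$wells$class
    f <- feature_matrix(s$profiles)[, 1L]
    stats::t.test(f[cls == "Hsp90"], f[cls == "Kinase"])$p.value
  }, numeric(1))
  # p-values behave like a null sample: no excess of small values
  expect_lte(sum(pvals < 0.05), 3L)
  expect_gt(mean(pvals), 0.2)
})

test_that("sphering on controls removes most of the plate batch effect", {
  d <- tiny_design(seed = 23L, n_plates = 8L, wells_per_plate = 96L,
                   plate_effect_sd = 1)
  s <- generate_screen(d)
  ann <- annotate_profiles(s$profiles, s$platemap)
  between_plate_fraction <- function(tab, feats) {
    m <- feature_matrix(tab, feats)
    plate <- as.data.frame(tab)$Metadata_Plate
    mean(vapply(seq_along(feats), function(j) {
      fit <- stats::anova(stats::lm(m[, j] ~ plate))
      fit$`Sum Sq`[1] / sum(fit$`Sum Sq`)
    }, numeric(1)))
  }
  inf <- s$ground_truth$features$feature[
    s$ground_truth$features$role == "informative"]
  before <- between_plate_fraction(ann, inf)
  model <- fit_normalization(ann, "spherize",
                             reference = "Metadata_compound == 'DMSO'",
                             regularization = 1e-6)
  after <- between_plate_fraction(apply_normalization(ann, model), inf)
  expect_lt(after, 0.5 * before)
})

test_that("feature selection at the reference thresholds recovers the panel roles", {
  # default design (all fourteen injury classes): with class phenotypes
  # spread over many classes, informative features stay below the
  # correlation threshold while exact duplicates sit at |r| ~ 1
  d <- screen_design(n_plates = 6L, wells_per_plate = 96L, seed = 29L)
  s <- generate_screen(d)
  res <- feature_select(s$profiles,
                        operations = c("variance_threshold",
                                       "drop_na_columns",
                                       "correlation_threshold"),
                        freq_cut = 0.05, na_cutoff = 0.05,
                        corr_threshold = 0.9)
  roles <- s$ground_truth$features
  kept <- attr(res$report, "selected")
  dup <- roles[roles$role == "duplicated", ]
  # informative features without a duplicate are all retained
  solo_inf <- setdiff(roles$feature[roles$role == "informative"],
                      dup$duplicate_of)
  expect_true(all(solo_inf %in% kept))
  expect_false(any(roles$feature[roles$role == "near_constant"] %in% kept))
  expect_false(any(roles$feature[roles$role == "high_missing"] %in% kept))
  # each parent/copy pair collapses to exactly one surviving member
  expect_true(all(xor(dup$feature %in% kept, dup$duplicate_of %in% kept)))
})

test_that("external screens expose a feature superset and the requested overlap", {
  s <- generate_screen(tiny_design(seed = 31L))
  sch <- as_injury_label_scheme(s$ground_truth)
  ext <- generate_external_screen(
    tiny_design(seed = 37L, n_plates = 3L),
    sch, overlap = 24L, class_effects = s$ground_truth$class_effects)
  expect_equal(nrow(match_treatments(sch, ext$platemap)), 24L)
  expect_equal(nrow(ext$ground_truth$overlap), 24L)
  # overlap injuries agree with the wells' true generator classes
  expect_equal(ext$ground_truth$overlap$injury,
               with(ext$ground_truth,
                    wells$class[match(paste(overlap$plate, overlap$well),
                                      paste(wells$plate, wells$well))]))
  shared <- intersect_features(feature_cols(s$profiles),
                               feature_cols(ext$profiles))
  expect_equal(shared, feature_cols(s$profiles))
  expect_gt(length(feature_cols(ext$profiles)), length(shared))

  none <- generate_external_screen(
    tiny_design(seed = 41L, n_plates = 2L), sch, overlap = 0L,
    class_effects = s$ground_truth$class_effects)
  expect_equal(nrow(none$ground_truth$overlap), 0L)
  expect_equal(nrow(match_treatments(sch, none$platemap)), 0L)
})

test_that("designs validate their composition and vocabulary", {
  expect_error(screen_design(classes = "Stardust"), "vocabulary")
  expect_error(screen_design(feature_composition = c(informative = 0L,
                                                     near_constant = 1L,
                                                     duplicated = 0L,
                                                     high_missing = 0L)),
               "infeasible")
  expect_error(screen_design(control_fraction = 1.5))
})

test_that("ground truth serializes to JSON", {
  s <- generate_screen(tiny_design(seed = 43L, n_plates = 2L))
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(s$ground_truth, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(nrow(back$wells), nrow(s$ground_truth$wells))
  expect_equal(back$seed, s$ground_truth$seed)
})
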