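demo_scheme <- function() injury_label_scheme(data.frame(
  compound = c("cytochalasin-b", "geldanamycin", "etoposide"),
  injury = c("Cytoskeletal", "Hsp90", "Genotoxin"),
  inchikey = c("AAAAAAAAAAAAAA-BBBBBBBBBB-N",
               "CCCCCCCCCCCCCC-DDDDDDDDDD-N",
               "EEEEEEEEEEEEEE-FFFFFFFFFF-N")))

test_that("the class vocabulary has exactly the fifteen injury labels", {
  cls <- injury_classes()
  expect_length(cls, 15L)
  expect_equal(anyDuplicated(cls), 0L)
  expect_true("Control" %in% cls)
})

test_that("label schemes enforce the vocabulary and control mapping", {
  expect_error(injury_label_scheme(data.frame(compound = "x",
                                              injury = "Sparkles")),
               "vocabulary")
  expect_error(injury_label_scheme(data.frame(compound = "DMSO",
                                              injury = "Kinase")),
               "Control")
  expect_error(injury_label_scheme(data.frame(compound = c("a", "a"),
                                              injury = c("Kinase", "Redox"))),
               "more than once")
  sch <- demo_scheme()
  expect_equal(unname(sch$map[["DMSO"]]), "Control")  # auto-added control
})

test_that("wells are labeled by compound and unknown treatments removed", {
  profiles <- profile_table(data.frame(
    Metadata_Well = c("A01", "A02", "A03", "A04"),
    Metadata_compound = c("DMSO", "cytochalasin-b", "mystery-juice",
                          "geldanamycin"),
    Cells_F1 = 1:4))
  lab <- label_wells(profiles, demo_scheme())
  expect_equal(lab$Metadata_injury, c("Control", "Cytoskeletal", "Hsp90"))
  expect_equal(op_report(lab)$n_excluded, 1L)
  unknown_only <- profile_table(data.frame(Metadata_compound = "mystery",
                                           Cells_F1 = 1))
  expect_error(label_wells(unknown_only, demo_scheme()), "no wells")
})

test_that("labeling a synthetic screen keeps exactly the mapped wells", {
  s <- generate_screen(tiny_design(seed = 21L))
  ann <- annotate_profiles(s$profiles, s$platemap)
  sch <- as_injury_label_scheme(s$ground_truth)
  # oracle from the generator ground truth (all compounds are mapped)
  lab <- label_wells(ann, sch)
  expect_equal(nrow(lab), nrow(s$ground_truth$wells))
  expect_equal(lab$Metadata_injury, s$ground_truth$wells$class)
})

test_that("feature intersection preserves the first list's order", {
  expect_equal(intersect_features(c("A", "B", "C"), c("C", "B", "D")),
               c("B", "C"))
  expect_equal(intersect_features(c("A", "B"), c("A", "B")), c("A", "B"))
  expect_error(intersect_features(c("A"), c("B")), "no features")
})

test_that("treatments are matched across datasets by InChIKey", {
  sch <- demo_scheme()
  pm <- as_platemap_for_test(data.frame(
    plate = "X1", well = c("A01", "A02", "A03"),
    inchikey = c("AAAAAAAAAAAAAA-BBBBBBBBBB-N", "ZZZZZZZZZZZZZZ-YYYYYYYYYY-N",
                 "EEEEEEEEEEEEEE-FFFFFFFFFF-N")))
  hits <- match_treatments(sch, pm)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$injury, c("Cytoskeletal", "Genotoxin"))
  none <- as_platemap_for_test(data.frame(plate = "X1", well = "A01",
                                          inchikey = "QQQQQQQQQQQQQQ-QQQQQQQQQQ-N"))
  expect_equal(nrow(match_treatments(sch, none)), 0L)
})

labeled_screen <- function(seed = 31L, ...) {
  s <- generate_screen(tiny_design(seed = seed, ...))
  ann <- annotate_profiles(s$profiles, s$platemap)
  label_wells(ann, as_injury_label_scheme(s$ground_truth))
}

test_that("holdouts partition the labeled wells in sequence", {
  lab <- labeled_screen(n_plates = 6L)
  part <- make_holdouts(lab, n_plates = 2L, min_treatments = 2L, seed = 5L)
  idx <- c(part$plate_holdout, part$treatment_holdout, part$well_holdout,
           part$modeling)
  expect_equal(sort(idx), seq_len(nrow(lab)))       # disjoint and exhaustive
  expect_length(part$held_plates, 2L)
  expect_setequal(unique(lab$Metadata_Plate[part$plate_holdout]),
                  part$held_plates)
  # held-out treatments outside held plates end up in the treatment holdout
  tr_wells <- lab$Metadata_compound[part$treatment_holdout]
  expect_true(all(tr_wells %in% part$held_treatments))
  # well holdout never touches held plates
  expect_false(any(lab$Metadata_Plate[part$well_holdout] %in%
                     part$held_plates))
})

test_that("the treatment-count qualification rule is strict", {
  lab <- labeled_screen(n_plates = 6L)
  # every injury has 3 treatments; > 10 qualifies nothing
  part <- make_holdouts(lab, n_plates = 2L, min_treatments = 10L, seed = 1L)
  expect_length(part$treatment_holdout, 0L)
  expect_error(make_holdouts(lab, n_plates = 99L), "99")
})

test_that("holdout construction is reproducible by seed", {
  lab <- labeled_screen(n_plates = 6L)
  p1 <- make_holdouts(lab, n_plates = 2L, min_treatments = 2L, seed = 7L)
  p2 <- make_holdouts(lab, n_plates = 2L, min_treatments = 2L, seed = 7L)
  p3 <- make_holdouts(lab, n_plates = 2L, min_treatments = 2L, seed = 8L)
  expect_identical(p1$modeling, p2$modeling)
  expect_false(identical(p1$held_plates, p3$held_plates) &&
                 identical(p1$modeling, p3$modeling))
})

test_that("stratified splits preserve class proportions within one well", {
  pt <- make_labeled(c("Control", "Hsp90"), c(5, 5), seed = 2L)
  sp <- split_train_test(pt, 0.2, seed = 1L)
  expect_equal(nrow(sp$train), 8L)
  expect_equal(nrow(sp$test), 2L)
  expect_equal(as.vector(table(sp$test$Metadata_injury)), c(1L, 1L))

  for (seed in 1:3) {
    pt <- make_labeled(c("Control", "Kinase", "Redox"), c(53, 21, 11),
                       seed = seed)
    sp <- split_train_test(pt, 0.2, seed = seed)
    n <- nrow(pt)
    expect_equal(nrow(sp$test), ceiling(0.2 * n))
    for (cl in unique(pt$Metadata_injury)) {
      n_cl <- sum(pt$Metadata_injury == cl)
      in_test <- sum(sp$test$Metadata_injury == cl)
      expect_lte(abs(in_test - 0.2 * n_cl), 1)
    }
  }
})

test_that("split validation rejects degenerate requests", {
  pt <- make_labeled(c("Control", "Hsp90"), c(5, 1), seed = 1L)
  expect_error(split_train_test(pt, 0.2), "Hsp90")
  ok <- make_labeled(c("Control", "Hsp90"), c(5, 5), seed = 1L)
  expect_error(split_train_test(ok, 0), "between 0 and 1")
  expect_error(split_train_test(ok, 1), "between 0 and 1")
})
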