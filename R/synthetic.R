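#' Describe a synthetic screen
#'
#' Fixes the design of a synthetic multi-plate Cell Painting style screen:
#' plate count and layout, the fraction of vehicle-control (DMSO) wells, the
#' injury classes present and their treatment counts, the feature panel
#' composition (informative, near-constant, duplicated, high-missing), the
#' per-class effect size in noise-SD units, the plate batch-effect scale,
#' the missing-value rate on high-missing features, and the per-well cell
#' count model. One global seed drives every sub-generator through a fixed
#' derivation rule, so a design reproduces its screen exactly.
#'
#' @param n_plates number of plates (default 10).
#' @param wells_per_plate wells per plate, at most 384 (default 96).
#' @param control_fraction fraction of wells carrying DMSO (default 0.25).
#' @param classes injury classes present; must belong to the
#'   [injury_classes()] vocabulary (default: all fourteen non-control
#'   classes).
#' @param treatments_per_class distinct compounds per class (default 4).
#' @param feature_composition named counts of `informative`,
#'   `near_constant`, `duplicated` and `high_missing` features (default
#'   70/10/10/10).
#' @param effect_size class mean shift on affected informative features, in
#'   units of the unit within-class SD (default 3).
#' @param plate_effect_sd SD of the per-plate batch offset (default 0.5);
#'   the offset enters all informative features through a shared loading
#'   vector, the usual low-rank structure of plate effects.
#' @param nan_rate missing-completely-at-random rate on high-missing
#'   features (default 0.1).
#' @param cells_per_well mean cells per well for the single-cell store.
#' @param cells_distribution `"fixed"` or `"poisson"`.
#' @param orphan_fraction fraction of cells dropped from the nuclei table in
#'   the single-cell store (default 0).
#' @param seed global integer seed.
#' @return a `screen_design` list.
#' @export
screen_design <- function(n_plates = 10L, wells_per_plate = 96L,
                          control_fraction = 0.25,
                          classes = setdiff(injury_classes(), "Control"),
                          treatments_per_class = 4L,
                          feature_composition = c(informative = 70L,
                                                  near_constant = 10L,
                                                  duplicated = 10L,
                                                  high_missing = 10L),
                          effect_size = 3, plate_effect_sd = 0.5,
                          nan_rate = 0.1, cells_per_well = 50L,
                          cells_distribution = c("fixed", "poisson"),
                          orphan_fraction = 0, seed = 1L) {
  cells_distribution <- match.arg(cells_distribution)
  classes <- as.character(unlist(classes))
  stopifnot(n_plates >= 1L, wells_per_plate >= 2L, wells_per_plate <= 384L,
            control_fraction >= 0, control_fraction <= 1,
            treatments_per_class >= 1L,
            effect_size >= 0, plate_effect_sd >= 0,
            nan_rate >= 0, nan_rate <= 1,
            orphan_fraction >= 0, orphan_fraction < 1,
            cells_per_well >= 1L)
  bad <- setdiff(classes, setdiff(injury_classes(), "Control"))
  if (length(bad) > 0L) stop("class(es) outside the injury vocabulary: ",
                             paste(bad, collapse = ", "), call. = FALSE)
  need <- c("informative", "near_constant", "duplicated", "high_missing")
  if (!all(need %in% names(feature_composition))) {
    stop("feature_composition must name counts for: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  comp <- feature_composition[need]
  if (comp[["informative"]] < 1L || any(comp < 0L)) {
    stop("infeasible feature composition", call. = FALSE)
  }
  structure(list(n_plates = as.integer(n_plates),
                 wells_per_plate = as.integer(wells_per_plate),
                 control_fraction = control_fraction,
                 classes = classes,
                 treatments_per_class = as.integer(treatments_per_class),
                 feature_composition = vapply(comp, as.integer, 0L),
                 n_features = as.integer(sum(comp)),
                 effect_size = effect_size,
                 plate_effect_sd = plate_effect_sd,
                 nan_rate = nan_rate,
                 cells_per_well = as.integer(cells_per_well),
                 cells_distribution = cells_distribution,
                 orphan_fraction = orphan_fraction,
                 seed = as.integer(seed)),
            class = "screen_design")
}

# canonical well ids for a plate layout (row-major over an 8x12 or 16x24 grid)
plate_well_ids <- function(wells_per_plate) {
  if (wells_per_plate <= 96L) {
    rows <- LETTERS[1:8]; n_col <- 12L
  } else {
    rows <- LETTERS[1:16]; n_col <- 24L
  }
  ids <- as.vector(t(outer(rows, seq_len(n_col),
                           function(r, c) sprintf("%s%02d", r, c))))
  ids[seq_len(wells_per_plate)]
}

# deterministic synthetic InChIKey-like identifier (27-char hashed id shape)
synthetic_inchikey <- function(k, seed) {
  with_seed(derive_seed(seed, 500000L + k), {
    paste0(paste(sample(LETTERS, 14L, replace = TRUE), collapse = ""), "-",
           paste(sample(LETTERS, 10L, replace = TRUE), collapse = ""), "-N")
  })
}

#' Generate a synthetic screen with known ground truth
#'
#' Emits well-level profiles, the plate map, and the generator's ground
#' truth. Informative features are unit-variance Gaussian noise; wells of an
#' injury class gain a mean shift of `effect_size` SD (random sign) on a
#' random half of the informative features, giving each class a distinct
#' sparse phenotype. Every plate adds a shared batch offset
#' `N(0, plate_effect_sd)` entering all informative features through a fixed
#' loading vector. Near-constant features hold one dominant value at
#' frequency at least 0.96; duplicated features equal a random informative
#' parent plus noise of SD 1e-6; high-missing features carry missing values
#' completely at random at `nan_rate`.
#'
#' @param design a [screen_design()].
#' @param class_effects optionally, the `class_effects` element of another
#'   screen's ground truth: the new screen then reuses those phenotype
#'   definitions (required when profiles from two screens must be comparable,
#'   as in a cross-dataset application).
#' @return list with `profiles` (a [profile_table] keyed by
#'   `Metadata_Plate`/`Metadata_Well`), `platemap` (a `plate_map` with
#'   compound, InChIKey, concentration and perturbation type) and
#'   `ground_truth` (wells with true classes, feature roles, plate offsets,
#'   class effects, seed).
#' @export
generate_screen <- function(design, class_effects = NULL) {
  stopifnot(inherits(design, "screen_design"))
  d <- design
  seed <- d$seed
  wells <- plate_well_ids(d$wells_per_plate)
  plates <- sprintf("Plate_%02d", seq_len(d$n_plates))
  layout <- expand.grid(well = wells, plate = plates,
                        stringsAsFactors = FALSE)[, c("plate", "well")]
  n <- nrow(layout)

  # treatment assignment: per plate, a fixed count of control wells at
  # random positions; treatments cycle over the remaining wells
  n_ctl <- round(d$control_fraction * d$wells_per_plate)
  compounds <- unlist(lapply(d$classes, function(cl) {
    sprintf("cmpd-%s-%02d", gsub("[^A-Za-z]+", "-", tolower(cl)),
            seq_len(d$treatments_per_class))
  }))
  cmpd_class <- stats::setNames(rep(d$classes, each = d$treatments_per_class),
                                compounds)
  layout$compound <- NA_character_
  treated_slots <- integer(0)
  for (p in seq_len(d$n_plates)) {
    rows <- which(layout$plate == plates[p])
    ctl <- with_seed(derive_seed(seed, 10L + p), sample(rows, n_ctl))
    layout$compound[ctl] <- "DMSO"
    treated_slots <- c(treated_slots, setdiff(rows, ctl))
  }
  n_treated <- length(treated_slots)
  if (n_treated > 0L) {
    assignment <- with_seed(derive_seed(seed, 2L),
                            sample(rep_len(compounds, n_treated)))
    layout$compound[treated_slots] <- assignment
  }
  layout$class <- ifelse(layout$compound == "DMSO", "Control",
                         unname(cmpd_class[layout$compound]))

  # feature panel
  comp <- d$feature_composition
  f_inf <- sprintf("Cells_Intensity_Feature_%03d", seq_len(comp[["informative"]]))
  f_nc <- sprintf("Nuclei_Texture_Feature_%03d",
                  seq_len(comp[["near_constant"]]))
  f_dup <- sprintf("Cytoplasm_AreaShape_Feature_%03d",
                   seq_len(comp[["duplicated"]]))
  f_hm <- sprintf("Cells_Correlation_Feature_%03d",
                  seq_len(comp[["high_missing"]]))

  x_inf <- with_seed(derive_seed(seed, 3L),
                     matrix(stats::rnorm(n * length(f_inf)), nrow = n,
                            dimnames = list(NULL, f_inf)))
  # sparse class phenotypes: each class shifts a random half of the
  # informative features with a random sign
  reuse <- !is.null(class_effects)
  if (reuse) {
    missing_cls <- setdiff(d$classes, names(class_effects))
    if (length(missing_cls) > 0L) {
      stop("supplied class_effects lack class(es): ",
           paste(missing_cls, collapse = ", "), call. = FALSE)
    }
  } else {
    class_effects <- list()
  }
  for (k in seq_along(d$classes)) {
    cl <- d$classes[k]
    eff <- if (reuse) class_effects[[cl]] else {
      with_seed(derive_seed(seed, 200L + k), {
        sel <- which(stats::runif(length(f_inf)) < 0.5)
        if (length(sel) == 0L) sel <- sample(length(f_inf), 1L)
        data.frame(feature = f_inf[sel],
                   shift = d$effect_size * sample(c(-1, 1), length(sel),
                                                  replace = TRUE),
                   stringsAsFactors = FALSE)
      })
    }
    if (!all(eff$feature %in% f_inf)) {
      stop("class_effects refer to features outside this design's panel",
           call. = FALSE)
    }
    class_effects[[cl]] <- eff
    rows <- which(layout$class == cl)
    if (length(rows) > 0L) {
      x_inf[rows, eff$feature] <-
        x_inf[rows, eff$feature, drop = FALSE] +
        matrix(eff$shift, nrow = length(rows), ncol = nrow(eff), byrow = TRUE)
    }
  }
  # low-rank plate batch effect
  plate_offsets <- with_seed(derive_seed(seed, 4L),
                             stats::setNames(stats::rnorm(d$n_plates, 0,
                                                          d$plate_effect_sd),
                                             plates))
  loadings <- with_seed(derive_seed(seed, 5L),
                        stats::setNames(stats::runif(length(f_inf), 0.5, 1.5),
                                        f_inf))
  x_inf <- x_inf + outer(plate_offsets[layout$plate], loadings)

  x_nc <- NULL
  if (length(f_nc) > 0L) {
    x_nc <- with_seed(derive_seed(seed, 6L), {
      m <- matrix(NA_real_, n, length(f_nc), dimnames = list(NULL, f_nc))
      n_alt <- floor(0.03 * n)
      for (j in seq_along(f_nc)) {
        m[, j] <- round(stats::rnorm(1), 3)
        if (n_alt > 0L) {
          alt <- sample(n, n_alt)
          m[alt, j] <- stats::rnorm(n_alt)
        }
      }
      m
    })
  }
  dup_parent <- character(0)
  x_dup <- NULL
  if (length(f_dup) > 0L) {
    dup_parent <- with_seed(derive_seed(seed, 7L),
                            sample(f_inf, length(f_dup),
                                   replace = length(f_dup) > length(f_inf)))
    x_dup <- x_inf[, dup_parent, drop = FALSE] +
      with_seed(derive_seed(seed, 9L),
                matrix(stats::rnorm(n * length(f_dup), 0, 1e-6), nrow = n))
    colnames(x_dup) <- f_dup
  }
  x_hm <- NULL
  if (length(f_hm) > 0L) {
    x_hm <- with_seed(derive_seed(seed, 8L), {
      m <- matrix(stats::rnorm(n * length(f_hm)), nrow = n,
                  dimnames = list(NULL, f_hm))
      m[matrix(stats::runif(length(m)) < d$nan_rate, nrow = n)] <- NA_real_
      m
    })
  }

  profiles <- cbind(data.frame(Metadata_Plate = layout$plate,
                               Metadata_Well = layout$well,
                               stringsAsFactors = FALSE),
                    as.data.frame(x_inf),
                    if (!is.null(x_nc)) as.data.frame(x_nc),
                    if (!is.null(x_dup)) as.data.frame(x_dup),
                    if (!is.null(x_hm)) as.data.frame(x_hm))

  inchikeys <- stats::setNames(
    vapply(seq_along(compounds), function(k) synthetic_inchikey(k, seed), ""),
    compounds)
  platemap <- data.frame(
    plate = layout$plate, well = layout$well, compound = layout$compound,
    inchikey = ifelse(layout$compound == "DMSO", NA_character_,
                      unname(inchikeys[layout$compound])),
    concentration = ifelse(layout$compound == "DMSO", NA_real_, 10),
    concentration_units = "uM",
    perturbation_type = ifelse(layout$compound == "DMSO", "control",
                               "chemical"),
    stringsAsFactors = FALSE)
  class(platemap) <- c("plate_map", "data.frame")

  roles <- data.frame(
    feature = c(f_inf, f_nc, f_dup, f_hm),
    role = rep(c("informative", "near_constant", "duplicated", "high_missing"),
               times = c(length(f_inf), length(f_nc), length(f_dup),
                         length(f_hm))),
    duplicate_of = c(rep(NA_character_, length(f_inf) + length(f_nc)),
                     dup_parent, rep(NA_character_, length(f_hm))),
    stringsAsFactors = FALSE)
  ground_truth <- structure(list(
    wells = data.frame(plate = layout$plate, well = layout$well,
                       compound = layout$compound,
                       inchikey = platemap$inchikey,
                       class = layout$class, stringsAsFactors = FALSE),
    features = roles,
    plate_offsets = plate_offsets,
    plate_loadings = loadings,
    class_effects = class_effects,
    seed = seed), class = "screen_ground_truth")

  list(profiles = profile_table(profiles), platemap = platemap,
       ground_truth = ground_truth)
}

#' Label scheme implied by a synthetic screen's ground truth
#'
#' @param ground_truth a `screen_ground_truth` from [generate_screen()].
#' @return an [injury_label_scheme()] mapping the screen's compounds (with
#'   their synthetic InChIKeys) to their true classes.
#' @export
as_injury_label_scheme <- function(ground_truth) {
  stopifnot(inherits(ground_truth, "screen_ground_truth"))
  w <- ground_truth$wells
  u <- unique(w[w$compound != "DMSO", c("compound", "inchikey", "class")])
  injury_label_scheme(data.frame(compound = u$compound, injury = u$class,
                                 inchikey = u$inchikey,
                                 stringsAsFactors = FALSE))
}

#' Write a screen's ground truth as JSON
#'
#' @param ground_truth a `screen_ground_truth`.
#' @param path JSON output path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  stopifnot(inherits(ground_truth, "screen_ground_truth"))
  jsonlite::write_json(unclass(ground_truth), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Generate a synthetic single-cell compartment store
#'
#' Writes a relational store (see [compartment_store]) for a design: one
#' image per well with plate/well metadata, and cells / cytoplasm / nuclei
#' object tables whose per-well cell counts follow the design's cell-count
#' model. Cytoplasm objects carry `Parent_Cells` / `Parent_Nuclei` links.
#' A fraction `orphan_fraction` of cells is removed from the nuclei table,
#' leaving orphan objects that a compartment merge must exclude.
#'
#' @param design a [screen_design()]; plate and well counts may be kept
#'   small, single-cell stores are large.
#' @param path store directory to create.
#' @return invisibly, a list with `path`, `n_cells` (cells emitted),
#'   `n_orphans` (cells lacking a nuclei row) and the per-image counts.
#' @export
generate_compartment_store <- function(design, path) {
  stopifnot(inherits(design, "screen_design"))
  d <- design
  seed <- d$seed
  wells <- plate_well_ids(d$wells_per_plate)
  plates <- sprintf("Plate_%02d", seq_len(d$n_plates))
  image <- expand.grid(Metadata_Well = wells, Metadata_Plate = plates,
                       stringsAsFactors = FALSE)
  image <- data.frame(ImageNumber = seq_len(nrow(image)),
                      Metadata_Plate = image$Metadata_Plate,
                      Metadata_Well = image$Metadata_Well,
                      stringsAsFactors = FALSE)
  counts <- if (d$cells_distribution == "fixed") {
    rep(d$cells_per_well, nrow(image))
  } else {
    with_seed(derive_seed(seed, 30L),
              pmax(1L, stats::rpois(nrow(image), d$cells_per_well)))
  }
  img_no <- rep(image$ImageNumber, counts)
  obj_no <- unlist(lapply(counts, seq_len), use.names = FALSE)
  n_cells <- length(img_no)
  feat_names <- sprintf("Intensity_MeanIntensity_Ch%d", 1:4)
  gen_feats <- function(stream) {
    with_seed(derive_seed(seed, stream),
              stats::setNames(as.data.frame(matrix(stats::rnorm(n_cells * 4L),
                                                   ncol = 4L)), feat_names))
  }
  cells <- cbind(data.frame(ImageNumber = img_no, ObjectNumber = obj_no),
                 gen_feats(31L))
  nuclei <- cbind(data.frame(ImageNumber = img_no, ObjectNumber = obj_no),
                  gen_feats(32L))
  cytoplasm <- cbind(data.frame(ImageNumber = img_no, ObjectNumber = obj_no,
                                Parent_Cells = obj_no, Parent_Nuclei = obj_no),
                     gen_feats(33L))
  orphan <- with_seed(derive_seed(seed, 34L),
                      stats::runif(n_cells) < d$orphan_fraction)
  nuclei <- nuclei[!orphan, , drop = FALSE]
  store <- structure(list(image = image,
                          compartments = list(cells = cells,
                                              cytoplasm = cytoplasm,
                                              nuclei = nuclei)),
                     class = "compartment_store")
  write_compartment_store(store, path)
  invisible(list(path = path, n_cells = n_cells, n_orphans = sum(orphan),
                 cells_per_image = counts))
}

#' Generate an external screen overlapping the injury scheme
#'
#' Emulates applying a pre-trained injury model to an external dataset: the
#' external profiles use the design's feature panel *plus* extra features of
#' their own (a feature superset, so the shared space must be computed with
#' [intersect_features()]), and exactly `overlap` treated wells carry
#' InChIKeys that map into the supplied label scheme. All other wells carry
#' novel compounds unknown to the scheme.
#'
#' @param design a [screen_design()] for the external screen.
#' @param scheme an [injury_label_scheme()] with InChIKeys (for example from
#'   [as_injury_label_scheme()]).
#' @param overlap number of wells whose InChIKey maps into the scheme.
#'   Overlapping wells are chosen among treated wells whose true class is in
#'   the scheme, and receive an InChIKey of a scheme compound with that same
#'   injury -- the key match is then biologically consistent.
#' @param class_effects phenotype definitions to reuse, normally the
#'   training screen's `ground_truth$class_effects`, so that profiles are
#'   comparable across the two screens.
#' @param n_extra_features external-only feature columns added (default 10).
#' @return list with `profiles`, `platemap` and `ground_truth`; the ground
#'   truth marks the overlapping wells and their scheme injuries.
#' @export
generate_external_screen <- function(design, scheme, overlap,
                                     class_effects = NULL,
                                     n_extra_features = 10L) {
  stopifnot(inherits(design, "screen_design"),
            inherits(scheme, "injury_label_scheme"))
  if (is.null(scheme$inchikey_map) || length(scheme$inchikey_map) == 0L) {
    stop("scheme carries no InChIKeys to overlap on", call. = FALSE)
  }
  base <- generate_screen(design, class_effects = class_effects)
  pm <- as.data.frame(base$platemap)
  truth_class <- base$ground_truth$wells$class
  sch <- scheme$table[!is.na(scheme$table$inchikey), , drop = FALSE]
  treated <- which(pm$perturbation_type != "control")
  eligible <- treated[truth_class[treated] %in% sch$injury]
  if (overlap > length(eligible)) {
    stop("overlap (", overlap, ") exceeds the ", length(eligible),
         " treated wells with a scheme-covered class", call. = FALSE)
  }
  # rename every compound to an external id with a novel InChIKey
  ext_ids <- unique(pm$compound[treated])
  renames <- stats::setNames(sprintf("ext-cmpd-%03d", seq_along(ext_ids)),
                             ext_ids)
  pm$compound[treated] <- renames[pm$compound[treated]]
  pm$inchikey[treated] <- vapply(match(pm$compound[treated], renames),
                                 function(k) synthetic_inchikey(900000L + k,
                                                                design$seed),
                                 "")
  overlap_rows <- integer(0)
  overlap_injury <- character(0)
  if (overlap > 0L) {
    overlap_rows <- with_seed(derive_seed(design$seed, 60L),
                              sample(eligible, overlap))
    # per overlapping well, a scheme compound of the well's own class
    keys <- vapply(overlap_rows, function(r) {
      cand <- sch$inchikey[sch$injury == truth_class[r]]
      cand[[1L + (r %% length(cand))]]
    }, "")
    pm$inchikey[overlap_rows] <- keys
    pm$compound[overlap_rows] <- sch$compound[match(keys, sch$inchikey)]
    overlap_injury <- truth_class[overlap_rows]
  }
  class(pm) <- c("plate_map", "data.frame")

  profiles <- as.data.frame(base$profiles)
  if (n_extra_features > 0L) {
    extra <- with_seed(derive_seed(design$seed, 61L),
                       matrix(stats::rnorm(nrow(profiles) * n_extra_features),
                              nrow = nrow(profiles)))
    colnames(extra) <- sprintf("External_Granularity_Feature_%02d",
                               seq_len(n_extra_features))
    profiles <- cbind(profiles, as.data.frame(extra))
  }
  gt <- base$ground_truth
  gt$wells$compound <- pm$compound
  gt$wells$inchikey <- pm$inchikey
  gt$overlap <- data.frame(plate = pm$plate[overlap_rows],
                           well = pm$well[overlap_rows],
                           inchikey = pm$inchikey[overlap_rows],
                           injury = overlap_injury,
                           stringsAsFactors = FALSE)
  list(profiles = profile_table(profiles), platemap = pm, ground_truth = gt)
}
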