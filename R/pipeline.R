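#' Run one pipeline stage
#'
#' Executes a single processing stage from a declarative configuration and
#' writes its artifact(s) plus a provenance sidecar
#' (`<artifact>.provenance.json` with tool version, stage, config hash, seed
#' and md5 digests of the inputs). On a stage error, partially written
#' outputs are removed before the error propagates.
#'
#' Available stages and their configuration keys (paths are resolved
#' against `output_dir` when relative):
#'
#' * `synth`: `design` (list of [screen_design()] arguments), outputs
#'   `profiles`, and optionally `platemap`, `ground_truth`, `scheme`.
#' * `load-cells`: `store` directory, `output`; optional `compartments`.
#' * `aggregate` / `consensus`: `input`, `output`; `strata`
#'   (default plate + well for aggregate), optional `statistic`.
#' * `annotate`: `input`, `platemap`, `output`.
#' * `normalize`: `input`, `output`; optional `method`, `reference`
#'   (expression string selecting the reference rows), `epsilon`,
#'   `regularization`, `model` (JSON output).
#' * `feature-select`: `input`, `output`; optional `report`, `operations`,
#'   `freq_cut`, `unique_cut`, `na_cutoff`, `corr_threshold`,
#'   `blocklist_patterns`.
#' * `label`: `input`, `scheme` (CSV of compound,injury\[,inchikey\]),
#'   `output`; optional `compound_col`.
#' * `holdout-split`: `input`, outputs `train` and `test`; optional outputs
#'   `plate_holdout`, `treatment_holdout`, `well_holdout`; parameters
#'   `n_plates`, `min_treatments`, `treatments_per_injury`, `test_fraction`.
#' * `injury-train`: `input` (training profiles), `model` (JSON output);
#'   optional `n_candidates`, `cv_folds`, `label_col`, `class_weight`.
#' * `injury-evaluate`: `model`, `splits` (named map split -> path),
#'   `report` (JSON/CSV output); optional `shuffled_baseline`.
#' * `injury-predict`: `model`, `input`, `output` (CSV or Parquet
#'   probability table).
#'
#' @param name stage name (see above).
#' @param config named list of stage configuration values.
#' @param output_dir base directory for relative paths (default `"."`).
#' @param seed integer seed for the stage.
#' @return invisibly, a list describing the stage run (`stage`, `outputs`,
#'   `seed`).
#' @export
run_stage <- function(name, config, output_dir = ".", seed = 0L) {
  runner <- stage_runners()[[name]]
  if (is.null(runner)) {
    stop("unknown stage '", name, "'; available: ",
         paste(names(stage_runners()), collapse = ", "), call. = FALSE)
  }
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(output_dir, p)
  }
  out_keys <- stage_output_keys()[[name]]
  req <- stage_required_keys()[[name]]
  missing_keys <- setdiff(req, names(config))
  if (length(missing_keys) > 0L) {
    stop("stage '", name, "' config lacks required key(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  outputs <- unlist(lapply(out_keys, function(k) {
    if (k == "splits") NULL else resolve(config[[k]])
  }))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok && length(outputs) > 0L) unlink(outputs, recursive = TRUE))
  inputs <- runner(config, resolve, seed)
  ok <- TRUE
  for (out in outputs) {
    if (!is.null(out) && file.exists(out)) {
      write_provenance(out, name, config, seed, inputs)
    }
  }
  invisible(list(stage = name, outputs = outputs, seed = seed))
}

write_provenance <- function(artifact, stage, config, seed, inputs) {
  digests <- if (length(inputs) > 0L) {
    files <- inputs[file.exists(inputs) & !dir.exists(inputs)]
    as.list(tools::md5sum(files))
  } else list()
  side <- list(tool = "cytoprofile",
               version = as.character(utils::packageVersion("cytoprofile")),
               stage = stage,
               config_hash = object_md5(config),
               seed = seed,
               input_digests = digests,
               created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(side, paste0(artifact, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA)
}

# Each runner executes one stage and returns the character vector of input
# paths it consumed (for provenance digests).
stage_runners <- function() list(
  `synth` = function(cfg, resolve, seed) {
    design_args <- cfg$design %||% list()
    if (!is.null(design_args$feature_composition)) {
      design_args$feature_composition <-
        unlist(design_args$feature_composition)
    }
    design_args$seed <- design_args$seed %||% seed
    design <- do.call(screen_design, design_args)
    screen <- generate_screen(design)
    write_profiles(screen$profiles, resolve(cfg$profiles))
    if (!is.null(cfg$platemap)) {
      utils::write.csv(as.data.frame(screen$platemap), resolve(cfg$platemap),
                       row.names = FALSE, na = "")
    }
    if (!is.null(cfg$ground_truth)) {
      write_ground_truth(screen$ground_truth, resolve(cfg$ground_truth))
    }
    if (!is.null(cfg$scheme)) {
      sch <- as_injury_label_scheme(screen$ground_truth)
      write_injury_scheme(sch, resolve(cfg$scheme))
    }
    character(0)
  },
  `load-cells` = function(cfg, resolve, seed) {
    store <- resolve(cfg$store)
    cells <- load_single_cells(store,
                               compartments = unlist(cfg$compartments) %||%
                                 c("cells", "cytoplasm", "nuclei"))
    write_profiles(cells, resolve(cfg$output))
    store
  },
  `aggregate` = function(cfg, resolve, seed) {
    input <- resolve(cfg$input)
    x <- read_profiles(input)
    out <- aggregate_profiles(x,
                              strata = unlist(cfg$strata) %||%
                                c("Metadata_Plate", "Metadata_Well"),
                              statistic = cfg$statistic %||% "median")
    write_profiles(out, resolve(cfg$output))
    input
  },
  `consensus` = function(cfg, resolve, seed) {
    input <- resolve(cfg$input)
    x <- read_profiles(input)
    out <- consensus_profiles(x, strata = unlist(cfg$strata),
                              statistic = cfg$statistic %||% "median")
    write_profiles(out, resolve(cfg$output))
    input
  },
  `annotate` = function(cfg, resolve, seed) {
    input <- resolve(cfg$input); pm_path <- resolve(cfg$platemap)
    x <- read_profiles(input)
    pm <- read_platemap(pm_path)
    out <- annotate_profiles(x, pm,
                             plate_col = cfg$plate_col %||% "Metadata_Plate",
                             well_col = cfg$well_col %||% "Metadata_Well")
    write_profiles(out, resolve(cfg$output))
    c(input, pm_path)
  },
  `normalize` = function(cfg, resolve, seed) {
    input <- resolve(cfg$input)
    x <- read_profiles(input)
    model <- fit_normalization(x, method = cfg$method %||% "mad_robustize",
                               reference = cfg$reference,
                               epsilon = cfg$epsilon %||% 1e-18,
                               regularization = cfg$regularization %||% 1e-6)
    out <- apply_normalization(x, model)
    write_profiles(out, resolve(cfg$output))
    if (!is.null(cfg$model)) write_normalization_model(model, resolve(cfg$model))
    input
  },
  `feature-select` = function(cfg, resolve, seed) {
    input <- resolve(cfg$input)
    x <- read_profiles(input)
    res <- feature_select(x,
      operations = unlist(cfg$operations) %||%
        c("variance_threshold", "drop_na_columns", "correlation_threshold"),
      freq_cut = cfg$freq_cut %||% 0.05,
      unique_cut = cfg$unique_cut %||% 0.01,
      na_cutoff = cfg$na_cutoff %||% 0.05,
      corr_threshold = cfg$corr_threshold %||% 0.9,
      blocklist_patterns = unlist(cfg$blocklist_patterns) %||% character(0))
    write_profiles(res$profiles, resolve(cfg$output))
    if (!is.null(cfg$report)) write_selection_report(res$report,
                                                     resolve(cfg$report))
    input
  },
  `label` = function(cfg, resolve, seed) {
    input <- resolve(cfg$input); sch_path <- resolve(cfg$scheme)
    x <- read_profiles(input)
    scheme <- read_injury_scheme(sch_path)
    out <- label_wells(x, scheme,
                       compound_col = cfg$compound_col %||% "Metadata_compound")
    write_profiles(out, resolve(cfg$output))
    c(input, sch_path)
  },
  `holdout-split` = function(cfg, resolve, seed) {
    input <- resolve(cfg$input)
    x <- read_profiles(input)
    part <- make_holdouts(x,
                          n_plates = cfg$n_plates %||% 10L,
                          min_treatments = cfg$min_treatments %||% 10L,
                          treatments_per_injury = cfg$treatments_per_injury %||% 1L,
                          seed = cfg$seed %||% seed)
    df <- as.data.frame(x)
    sp <- split_train_test(df[part$modeling, , drop = FALSE],
                           test_fraction = cfg$test_fraction %||% 0.2,
                           seed = cfg$seed %||% seed)
    write_profiles(sp$train, resolve(cfg$train))
    write_profiles(sp$test, resolve(cfg$test))
    for (k in c("plate_holdout", "treatment_holdout", "well_holdout")) {
      if (!is.null(cfg[[k]]) && length(part[[k]]) > 0L) {
        write_profiles(profile_table(df[part[[k]], , drop = FALSE]),
                       resolve(cfg[[k]]))
      }
    }
    input
  },
  `injury-train` = function(cfg, resolve, seed) {
    input <- resolve(cfg$input)
    x <- read_profiles(input)
    model <- train_injury_classifier(x,
      n_candidates = cfg$n_candidates %||% 50L,
      cv_folds = cfg$cv_folds %||% 5L,
      label_col = cfg$label_col %||% "Metadata_injury",
      class_weight = cfg$class_weight %||% "balanced",
      seed = cfg$seed %||% seed)
    write_injury_model(model, resolve(cfg$model))
    input
  },
  `injury-evaluate` = function(cfg, resolve, seed) {
    model_path <- resolve(cfg$model)
    model <- read_injury_model(model_path)
    split_paths <- vapply(cfg$splits, function(p) resolve(p), "")
    splits <- lapply(split_paths, read_profiles)
    report <- evaluate_model(model, splits,
                             label_col = cfg$label_col %||% "Metadata_injury",
                             shuffled_baseline = isTRUE(cfg$shuffled_baseline),
                             seed = cfg$seed %||% seed)
    write_evaluation_report(report, resolve(cfg$report))
    c(model_path, unname(split_paths))
  },
  `injury-predict` = function(cfg, resolve, seed) {
    model_path <- resolve(cfg$model); input <- resolve(cfg$input)
    model <- read_injury_model(model_path)
    x <- read_profiles(input)
    shared <- intersect_features(model$features, feature_cols(x))
    keep <- c(metadata_cols(x), shared)
    probs <- predict_injury(model, profile_table(as.data.frame(x)[keep]))
    out <- resolve(cfg$output)
    if (tolower(tools::file_ext(out)) == "parquet") {
      arrow::write_parquet(probs, out, compression = "snappy")
    } else {
      utils::write.csv(probs, out, row.names = FALSE)
    }
    c(model_path, input)
  })

stage_required_keys <- function() list(
  `synth` = "profiles",
  `load-cells` = c("store", "output"),
  `aggregate` = c("input", "output"),
  `consensus` = c("input", "output", "strata"),
  `annotate` = c("input", "platemap", "output"),
  `normalize` = c("input", "output"),
  `feature-select` = c("input", "output"),
  `label` = c("input", "scheme", "output"),
  `holdout-split` = c("input", "train", "test"),
  `injury-train` = c("input", "model"),
  `injury-evaluate` = c("model", "splits", "report"),
  `injury-predict` = c("model", "input", "output"))

stage_output_keys <- function() list(
  `synth` = c("profiles", "platemap", "ground_truth", "scheme"),
  `load-cells` = "output",
  `aggregate` = "output",
  `consensus` = "output",
  `annotate` = "output",
  `normalize` = c("output", "model"),
  `feature-select` = c("output", "report"),
  `label` = "output",
  `holdout-split` = c("train", "test", "plate_holdout", "treatment_holdout",
                      "well_holdout"),
  `injury-train` = "model",
  `injury-evaluate` = "report",
  `injury-predict` = "output")

stage_input_keys <- function() list(
  `synth` = character(0),
  `load-cells` = "store",
  `aggregate` = "input",
  `consensus` = "input",
  `annotate` = c("input", "platemap"),
  `normalize` = "input",
  `feature-select` = "input",
  `label` = c("input", "scheme"),
  `holdout-split` = "input",
  `injury-train` = "input",
  `injury-evaluate` = "model",
  `injury-predict` = c("model", "input"))

#' Run a multi-stage pipeline from a declarative configuration
#'
#' The configuration (a list, or a path to a YAML file) holds a global
#' `seed`, an `output_dir`, and a `stages` list; each entry names its
#' `stage` plus the stage's own keys (see [run_stage()]). The whole
#' configuration is validated before anything runs: unknown stage names,
#' missing required keys, and stage inputs that neither exist on disk nor
#' are produced by an earlier stage all fail upfront. Stages then execute in
#' order, each with a seed derived from the global one, persisting every
#' intermediate artifact with its provenance sidecar; the first failing
#' stage aborts the run. A machine-readable run summary is written to
#' `run_summary.json` under `output_dir`.
#'
#' Two runs with an identical configuration and seed produce identical
#' artifacts and report values.
#'
#' @param config list or YAML file path.
#' @return invisibly, the run summary list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  stages <- config$stages
  if (is.null(stages) || length(stages) == 0L) {
    stop("config has no stages", call. = FALSE)
  }
  output_dir <- config$output_dir %||% "."
  seed <- config$seed %||% 0L
  # upfront validation
  produced <- character(0)
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p
                         else file.path(output_dir, p)
  for (i in seq_along(stages)) {
    st <- stages[[i]]
    nm <- st$stage
    if (is.null(nm) || !nm %in% names(stage_runners())) {
      stop("stage ", i, ": unknown or missing stage name", call. = FALSE)
    }
    missing_keys <- setdiff(stage_required_keys()[[nm]], names(st))
    if (length(missing_keys) > 0L) {
      stop("stage ", i, " ('", nm, "') lacks required key(s): ",
           paste(missing_keys, collapse = ", "), call. = FALSE)
    }
    for (k in stage_input_keys()[[nm]]) {
      p <- st[[k]]
      if (is.null(p)) next
      rp <- resolve(p)
      if (!file.exists(rp) && !dir.exists(rp) && !rp %in% produced) {
        stop("stage ", i, " ('", nm, "'): input '", p,
             "' neither exists nor is produced by an earlier stage",
             call. = FALSE)
      }
    }
    if (nm == "injury-evaluate") {
      for (p in unlist(st$splits)) {
        rp <- resolve(p)
        if (!file.exists(rp) && !rp %in% produced) {
          stop("stage ", i, ": split input '", p, "' unavailable",
               call. = FALSE)
        }
      }
    }
    outs <- unlist(lapply(stage_output_keys()[[nm]],
                          function(k) if (k == "splits") NULL else st[[k]]))
    produced <- c(produced, vapply(outs, resolve, ""))
  }
  # execution
  summary <- list(seed = seed, output_dir = output_dir, stages = list())
  for (i in seq_along(stages)) {
    st <- stages[[i]]
    res <- run_stage(st$stage, st[setdiff(names(st), "stage")],
                     output_dir = output_dir,
                     seed = st$seed %||% derive_seed(seed, i))
    summary$stages[[i]] <- list(stage = st$stage, outputs = res$outputs)
  }
  jsonlite::write_json(summary, file.path(output_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

#' Write an injury label scheme to CSV
#'
#' @param scheme an [injury_label_scheme()].
#' @param path CSV output path.
#' @export
write_injury_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "injury_label_scheme"))
  utils::write.csv(scheme$table, path, row.names = FALSE, na = "")
  invisible(path)
}
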