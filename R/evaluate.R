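#' Classification metrics
#'
#' `confusion_matrix()` cross-tabulates truth (rows) against prediction
#' (columns) over a fixed class set, so each row sums to that class's true
#' count. `class_metrics()` derives per-class precision, recall and F1
#' (a metric with a zero denominator is reported as 0); `macro_f1()` is the
#' unweighted mean of the per-class F1 scores.
#'
#' @param truth,pred character vectors of true and predicted labels.
#' @param classes class set fixing the matrix dimensions.
#' @return `confusion_matrix()`: an integer matrix; `class_metrics()`: a
#'   data.frame (class, precision, recall, f1, support); `macro_f1()`: a
#'   number.
#' @export
confusion_matrix <- function(truth, pred, classes = sort(unique(truth))) {
  table(truth = factor(truth, levels = classes),
        pred = factor(pred, levels = classes))
}

#' @rdname confusion_matrix
#' @export
class_metrics <- function(truth, pred, classes = sort(unique(truth))) {
  cm <- confusion_matrix(truth, pred, classes)
  tp <- diag(cm)
  pred_n <- colSums(cm)
  true_n <- rowSums(cm)
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(true_n > 0, tp / true_n, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  data.frame(class = classes, precision = as.numeric(precision),
             recall = as.numeric(recall), f1 = as.numeric(f1),
             support = as.numeric(true_n), stringsAsFactors = FALSE)
}

#' @rdname confusion_matrix
#' @export
macro_f1 <- function(truth, pred, classes = sort(unique(truth))) {
  mean(class_metrics(truth, pred, classes)$f1)
}

#' Evaluate an injury model across data splits
#'
#' Computes per-class precision/recall/F1, the confusion matrix and the
#' per-well class-probability table for each named split. With
#' `shuffled_baseline = TRUE`, a dataset-level permutation null is added:
#' the labels of every split are permuted (features intact), a second model
#' is trained on the permuted training split with the same randomized-search
#' settings as the original, and it is scored against the permuted labels --
#' the same construction as a permutation test of the whole training
#' procedure, whose macro-F1 concentrates at 1/n_classes.
#'
#' @param model an `injury_model`.
#' @param splits named list of labeled profile tables
#'   (e.g. `list(train = ..., test = ..., plate_holdout = ...)`). The
#'   shuffled baseline requires a `"train"` split.
#' @param label_col label metadata column.
#' @param shuffled_baseline also evaluate the label-permutation null.
#' @param seed seed for the label permutation.
#' @return an `evaluation_report`: per split, `metrics`, `confusion`,
#'   `macro_f1` and `probabilities`; when requested, a `baseline` element of
#'   the same shape with `shuffled = TRUE`.
#' @export
evaluate_model <- function(model, splits, label_col = "Metadata_injury",
                           shuffled_baseline = FALSE, seed = 0L) {
  stopifnot(inherits(model, "injury_model"), is.list(splits),
            length(splits) > 0L, !is.null(names(splits)))
  eval_one <- function(m, splits) {
    lapply(splits, function(s) {
      s <- as_profile_table(s)
      truth <- as.character(as.data.frame(s)[[label_col]])
      p <- predict(m, s, type = "prob")
      pred <- colnames(p)[max.col(p, ties.method = "first")]
      list(metrics = class_metrics(truth, pred, m$classes),
           confusion = confusion_matrix(truth, pred, m$classes),
           macro_f1 = macro_f1(truth, pred, m$classes),
           probabilities = p)
    })
  }
  report <- list(splits = eval_one(model, splits), shuffled = FALSE,
                 classes = model$classes)
  if (shuffled_baseline) {
    if (!"train" %in% names(splits)) {
      stop("shuffled baseline needs a 'train' split to retrain on",
           call. = FALSE)
    }
    permuted <- lapply(seq_along(splits), function(i) {
      shuffle_labels(splits[[i]], label_col, derive_seed(seed, 41L + i))
    })
    names(permuted) <- names(splits)
    null_model <- refit_null(model, permuted$train, label_col)
    report$baseline <- list(splits = eval_one(null_model, permuted),
                            shuffled = TRUE)
  }
  structure(report, class = "evaluation_report")
}

# permute the label column in place (features untouched)
shuffle_labels <- function(x, label_col, seed) {
  df <- as.data.frame(as_profile_table(x))
  df[[label_col]] <- with_seed(seed, sample(df[[label_col]]))
  profile_table(df)
}

# retrain the full search procedure on (permuted) training data; the
# permutation null must include hyperparameter selection, or a winner tuned
# on real structure can degenerate into a constant predictor
refit_null <- function(model, train, label_col) {
  grid <- model$search$grid
  class(grid) <- c("search_grid", "data.frame")
  train_injury_classifier(train, grid = grid,
                          n_candidates = model$search$n_candidates,
                          cv_folds = model$search$cv_folds,
                          label_col = label_col,
                          class_weight = model$class_weight,
                          seed = model$seed)
}

#' @export
#' @method print evaluation_report
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report\n")
  for (nm in names(x$splits)) {
    s <- x$splits[[nm]]
    cat(sprintf("  %-18s n = %5d  macro-F1 = %.3f\n", nm,
                sum(s$confusion), s$macro_f1))
  }
  if (!is.null(x$baseline)) {
    cat("  shuffled baseline:\n")
    for (nm in names(x$baseline$splits)) {
      s <- x$baseline$splits[[nm]]
      cat(sprintf("  %-18s n = %5d  macro-F1 = %.3f\n",
                  paste0(nm, "*"), sum(s$confusion), s$macro_f1))
    }
  }
  invisible(x)
}

#' Write an evaluation report to JSON or CSV
#'
#' JSON keeps the full structure (metrics, confusion matrices, macro-F1 per
#' split, baseline included); CSV writes the per-class metrics in long form
#' with `split` and `shuffled` columns.
#'
#' @param report an `evaluation_report`.
#' @param path output path ending in `.json` or `.csv`.
#' @export
write_evaluation_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  long <- evaluation_metrics_long(report)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(long, path, row.names = FALSE)
  } else if (ext == "json") {
    obj <- list(classes = report$classes, metrics = long,
                macro_f1 = lapply(report$splits, `[[`, "macro_f1"),
                confusion = lapply(report$splits, function(s)
                  as.data.frame.matrix(s$confusion)))
    if (!is.null(report$baseline)) {
      obj$baseline_macro_f1 <- lapply(report$baseline$splits, `[[`, "macro_f1")
    }
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported report format: .", ext, call. = FALSE)
  }
  invisible(path)
}

evaluation_metrics_long <- function(report) {
  one <- function(splits, shuffled) {
    do.call(rbind, lapply(names(splits), function(nm) {
      m <- splits[[nm]]$metrics
      m$split <- nm
      m$shuffled <- shuffled
      m
    }))
  }
  out <- one(report$splits, FALSE)
  if (!is.null(report$baseline)) {
    out <- rbind(out, one(report$baseline$splits, TRUE))
  }
  out
}
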