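#' Hyperparameter grid for the injury classifier
#'
#' Expands the randomized-search grid for the class-weighted multinomial
#' logistic regression: penalty in {l1, l2, elasticnet}, regularization
#' strength C in {1e-4, 1e-2, 0.1, 1, 10, 100}, convergence tolerance in
#' {1e-6, 1e-3}, and, for elastic net only, the L1 ratio in
#' {0.1, 0.3, 0.5, 0.7, 0.9}. Only valid combinations are emitted (a ratio
#' is attached to the elastic-net penalty and to no other). The strength C
#' is the inverse of the penalty weight; internally it is mapped onto the
#' elastic-net path parameter as `lambda = 1 / (n * C)` with mixing
#' `alpha` = 1 (l1), 0 (l2) or the L1 ratio (elasticnet).
#'
#' @param penalties subset of `c("l1", "l2", "elasticnet")`.
#' @param strengths inverse regularization strengths C.
#' @param tolerances optimizer convergence tolerances.
#' @param elasticnet_ratios L1 ratios for the elastic-net penalty.
#' @return a `search_grid` data.frame of valid candidate combinations with
#'   columns `penalty`, `C`, `tol`, `ratio` (NA unless elastic net).
#' @export
search_grid <- function(penalties = c("l1", "l2", "elasticnet"),
                        strengths = c(1e-4, 1e-2, 0.1, 1, 10, 100),
                        tolerances = c(1e-6, 1e-3),
                        elasticnet_ratios = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  penalties <- match.arg(penalties, several.ok = TRUE)
  stopifnot(all(strengths > 0), all(tolerances > 0),
            all(elasticnet_ratios > 0 & elasticnet_ratios < 1))
  plain <- expand.grid(penalty = setdiff(penalties, "elasticnet"),
                       C = strengths, tol = tolerances, ratio = NA_real_,
                       stringsAsFactors = FALSE)
  en <- if ("elasticnet" %in% penalties) {
    expand.grid(penalty = "elasticnet", C = strengths, tol = tolerances,
                ratio = elasticnet_ratios, stringsAsFactors = FALSE)
  } else NULL
  grid <- rbind(plain, en)
  rownames(grid) <- NULL
  class(grid) <- c("search_grid", "data.frame")
  grid
}

# mixing parameter alpha for a grid row
grid_alpha <- function(cand) {
  switch(cand$penalty, l1 = 1, l2 = 0, elasticnet = cand$ratio,
         stop("unknown penalty '", cand$penalty, "'", call. = FALSE))
}

# balanced class weights: n / (n_classes * class count), per observation
balanced_weights <- function(y) {
  counts <- table(y)
  w <- length(y) / (length(counts) * as.numeric(counts[y]))
  as.numeric(w)
}

# Fit one penalized multinomial logistic regression and extract a dense
# coefficient matrix (classes x features) plus intercepts.
fit_multinomial <- function(xmat, y, cand, class_weight = "balanced") {
  classes <- levels(y)
  w <- if (identical(class_weight, "balanced")) balanced_weights(y)
       else rep(1, length(y))
  lambda <- 1 / (nrow(xmat) * cand$C)
  warn <- NULL
  fit <- withCallingHandlers(
    glmnet::glmnet(xmat, y, family = "multinomial", alpha = grid_alpha(cand),
                   lambda = lambda, thresh = cand$tol, weights = w,
                   standardize = FALSE, maxit = 1e5),
    warning = function(wc) {
      warn <<- conditionMessage(wc)
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)  # list per class of sparse (p+1) x 1
  beta <- t(vapply(cf, function(m) as.numeric(m), numeric(ncol(xmat) + 1L)))
  list(classes = classes,
       intercept = stats::setNames(beta[, 1L], classes),
       coefficients = matrix(beta[, -1L, drop = FALSE],
                             nrow = length(classes),
                             dimnames = list(classes, colnames(xmat))),
       warning = warn)
}

# class probabilities from a dense coefficient parameterization (softmax)
softmax_probabilities <- function(xmat, intercept, coefficients) {
  eta <- sweep(xmat %*% t(coefficients), 2L, -intercept)
  eta <- eta - apply(eta, 1L, max)
  e <- exp(eta)
  p <- e / rowSums(e)
  colnames(p) <- rownames(coefficients)
  p
}

# stratified fold assignment (1..k per row), deterministic given seed
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    rows <- which(y == cl)
    rows <- with_seed(derive_seed(seed, 17L + match(cl, levels(y))),
                      sample(rows))
    fold[rows] <- rep_len(seq_len(k), length(rows))
  }
  fold
}

#' Train the multi-class injury classifier
#'
#' Class-weighted multinomial logistic regression with randomized
#' hyperparameter search: `n_candidates` valid grid combinations are sampled
#' without replacement and scored by stratified `cv_folds`-fold
#' cross-validated macro-F1 on the training set; the winner is refit on the
#' full training data. Class weights are inversely proportional to class
#' frequencies, mitigating label imbalance. Remaining missing feature values
#' are imputed with training-set medians, which are stored in the bundle and
#' reapplied at prediction time.
#'
#' @param train labeled profile table (the training partition).
#' @param grid a [search_grid()].
#' @param n_candidates candidates sampled from the grid (default 50).
#' @param cv_folds cross-validation folds (default 5).
#' @param label_col label metadata column.
#' @param class_weight `"balanced"` (default) or `"none"`.
#' @param seed integer seed driving sampling, folds and the fit.
#' @return an `injury_model` bundle: `classes`, `coefficients`
#'   (classes x features), `intercept`, `hyperparameters`, `features`,
#'   `feature_medians`, `cv_results`, `seed`, `n_train`, and any
#'   convergence `warning` recorded during the final fit.
#' @export
train_injury_classifier <- function(train, grid = search_grid(),
                                    n_candidates = 50L, cv_folds = 5L,
                                    label_col = "Metadata_injury",
                                    class_weight = c("balanced", "none"),
                                    seed = 0L) {
  class_weight <- match.arg(class_weight)
  train <- as_profile_table(train)
  df <- as.data.frame(train)
  if (!label_col %in% names(df)) stop("label column '", label_col,
                                      "' not found", call. = FALSE)
  y <- factor(as.character(df[[label_col]]))
  if (nlevels(y) < 2L) stop("training needs at least 2 classes", call. = FALSE)
  if (any(table(y) < cv_folds)) {
    stop("every class needs at least cv_folds = ", cv_folds,
         " training wells", call. = FALSE)
  }
  feats <- feature_cols(train)
  xmat <- feature_matrix(train, feats)
  all_na <- feats[colSums(!is.na(xmat)) == 0L]
  if (length(all_na) > 0L) stop("all-missing feature column(s): ",
                                paste(all_na, collapse = ", "), call. = FALSE)
  medians <- apply(xmat, 2L, stats::median, na.rm = TRUE)
  xmat <- impute_medians(xmat, medians)

  stopifnot(inherits(grid, "search_grid"), nrow(grid) > 0L)
  n_candidates <- min(n_candidates, nrow(grid))
  cand_rows <- with_seed(derive_seed(seed, 7L),
                         sample(nrow(grid), n_candidates))
  folds <- stratified_folds(y, cv_folds, seed)
  cv_scores <- vapply(cand_rows, function(r) {
    cand <- grid[r, ]
    scores <- vapply(seq_len(cv_folds), function(k) {
      in_fold <- folds == k
      fit <- fit_multinomial(xmat[!in_fold, , drop = FALSE],
                             droplevels(y[!in_fold]), cand, class_weight)
      p <- softmax_probabilities(xmat[in_fold, , drop = FALSE],
                                 fit$intercept, fit$coefficients)
      pred <- colnames(p)[max.col(p, ties.method = "first")]
      macro_f1(as.character(y[in_fold]), pred, levels(y))
    }, numeric(1L))
    mean(scores)
  }, numeric(1L))
  best <- cand_rows[which.max(cv_scores)]
  winner <- grid[best, ]
  final <- fit_multinomial(xmat, y, winner, class_weight)

  cv_results <- cbind(grid[cand_rows, ],
                      data.frame(mean_cv_macro_f1 = cv_scores))
  rownames(cv_results) <- NULL
  structure(list(classes = levels(y),
                 coefficients = final$coefficients,
                 intercept = final$intercept,
                 hyperparameters = as.list(winner),
                 features = feats,
                 feature_medians = medians,
                 class_weight = class_weight,
                 search = list(grid = as.data.frame(grid),
                               n_candidates = n_candidates,
                               cv_folds = cv_folds),
                 cv_results = cv_results,
                 warning = final$warning,
                 seed = seed,
                 n_train = nrow(xmat)),
            class = "injury_model")
}

impute_medians <- function(xmat, medians) {
  for (j in seq_len(ncol(xmat))) {
    na <- is.na(xmat[, j])
    if (any(na)) xmat[na, j] <- medians[[j]]
  }
  xmat
}

#' @export
#' @method print injury_model
print.injury_model <- function(x, ...) {
  hp <- x$hyperparameters
  cat(sprintf("injury_model: %d classes, %d features (n_train = %d)\n",
              length(x$classes), length(x$features), x$n_train))
  cat(sprintf("  penalty %s, C = %g, tol = %g%s; class weights: %s\n",
              hp$penalty, hp$C, hp$tol,
              if (!is.na(hp$ratio)) sprintf(", l1 ratio %g", hp$ratio) else "",
              x$class_weight))
  cat(sprintf("  best CV macro-F1: %.3f over %d candidates\n",
              max(x$cv_results$mean_cv_macro_f1), nrow(x$cv_results)))
  if (!is.null(x$warning)) cat("  fit warning:", x$warning, "\n")
  invisible(x)
}

#' @export
#' @method summary injury_model
summary.injury_model <- function(object, ...) {
  print(object)
  cat("\ncross-validation results (top 5):\n")
  cv <- object$cv_results
  print(utils::head(cv[order(-cv$mean_cv_macro_f1), ], 5L), row.names = FALSE)
  invisible(object)
}

#' @export
coef.injury_model <- function(object, ...) {
  cbind(`(Intercept)` = object$intercept, object$coefficients)
}

#' Predict injury classes for profiles
#'
#' @param object an `injury_model`.
#' @param newdata profile table containing the model's features.
#' @param type `"prob"` for class probabilities, `"class"` for labels.
#' @param ... ignored.
#' @return matrix of probabilities (rows sum to 1) or character labels.
#' @export
predict.injury_model <- function(object, newdata,
                                 type = c("prob", "class"), ...) {
  type <- match.arg(type)
  newdata <- as_profile_table(newdata)
  absent <- setdiff(object$features, feature_cols(newdata))
  if (length(absent) > 0L) {
    stop("model feature(s) missing from profiles: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  xmat <- impute_medians(feature_matrix(newdata, object$features),
                         object$feature_medians)
  p <- softmax_probabilities(xmat, object$intercept, object$coefficients)
  if (type == "prob") p
  else colnames(p)[max.col(p, ties.method = "first")]
}

#' Probability table for an external profile set
#'
#' Applies a trained injury model to external profiles (after the feature
#' spaces have been reconciled with [intersect_features()]): returns the
#' metadata plus one probability column per class (`prob_<class>`, rows
#' summing to 1) and the argmax label in `predicted_injury`.
#'
#' @param model an `injury_model`.
#' @param external profile table containing the model's shared features.
#' @return a data.frame as described.
#' @export
predict_injury <- function(model, external) {
  external <- as_profile_table(external)
  p <- predict(model, external, type = "prob")
  meta <- as.data.frame(external)[metadata_cols(external)]
  probs <- as.data.frame(p)
  names(probs) <- paste0("prob_", gsub(" ", "_", colnames(p)))
  out <- cbind(meta, probs)
  out$predicted_injury <- colnames(p)[max.col(p, ties.method = "first")]
  rownames(out) <- NULL
  out
}

#' Serialize / restore an injury model as JSON
#'
#' @param model an `injury_model`.
#' @param path JSON path.
#' @export
write_injury_model <- function(model, path) {
  stopifnot(inherits(model, "injury_model"))
  obj <- unclass(model)
  obj$coefficients <- as.data.frame(obj$coefficients)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_injury_model
#' @export
read_injury_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$coefficients <- as.matrix(obj$coefficients)
  rownames(obj$coefficients) <- obj$classes
  obj$intercept <- stats::setNames(as.numeric(obj$intercept), obj$classes)
  obj$feature_medians <- stats::setNames(as.numeric(obj$feature_medians),
                                         obj$features)
  obj$hyperparameters$ratio <- obj$hyperparameters$ratio %||% NA_real_
  if (!is.null(obj$search)) {
    grid <- as.data.frame(obj$search$grid)
    if (is.null(grid$ratio)) grid$ratio <- NA_real_
    class(grid) <- c("search_grid", "data.frame")
    obj$search$grid <- grid
  }
  structure(obj, class = "injury_model")
}
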