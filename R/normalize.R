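#' Fit a normalization model on a reference population
#'
#' Fits per-feature location/scale parameters or a whitening transform on a
#' reference subpopulation -- typically the negative-control (DMSO) wells --
#' and records the reference used. Methods:
#'
#' * `standardize`: location = per-feature mean, scale = per-feature
#'   *population* standard deviation (denominator `n`).
#' * `mad_robustize`: location = per-feature median, scale = median absolute
#'   deviation times the Gaussian consistency constant 1.4826.
#' * `spherize`: ZCA whitening. Center = reference mean; the whitening matrix
#'   is `E diag(1/sqrt(lambda + regularization)) E'` from the
#'   eigendecomposition of the reference sample covariance (see
#'   [spherize_transform()]). Fitted on negative controls, sphering acts as a
#'   batch-effect correction: plate-level nuisance directions present in the
#'   controls are compressed to unit variance.
#'
#' All scales are floored at `epsilon`, so constant features get scale
#' `epsilon` rather than zero. Statistics are computed over non-missing
#' reference values only; a feature with no observed reference value is an
#' error.
#'
#' @param x a profile table.
#' @param method `"standardize"`, `"mad_robustize"` or `"spherize"`.
#' @param reference which rows form the reference population: `NULL` (all
#'   rows), a logical vector, or a character expression evaluated in the
#'   table's columns, e.g. `"Metadata_compound == 'DMSO'"`.
#' @param epsilon positive scale floor (default `1e-18`).
#' @param regularization eigenvalue ridge for `spherize` (default `1e-6`).
#' @return a `normalization_model` object recording method, parameters, the
#'   fitted feature columns in order, and a description of the reference.
#' @seealso [apply_normalization()], [spherize_transform()]
#' @export
#' @examples
#' pt <- profile_table(data.frame(Metadata_Well = c("A01", "A02", "A03"),
#'                                Cells_F1 = c(1, 2, 3)))
#' m <- fit_normalization(pt, "standardize")
#' m$location; m$scale  # 2 and sqrt(2/3)
fit_normalization <- function(x,
                              method = c("standardize", "mad_robustize", "spherize"),
                              reference = NULL, epsilon = 1e-18,
                              regularization = 1e-6) {
  method <- match.arg(method)
  stopifnot(is.numeric(epsilon), epsilon > 0)
  x <- as_profile_table(x)
  feats <- feature_cols(x)
  sel <- resolve_reference(x, reference)
  ref <- feature_matrix(x, feats)[sel, , drop = FALSE]
  if (nrow(ref) < 2L) {
    stop("normalization needs at least 2 reference rows (got ", nrow(ref), ")",
         call. = FALSE)
  }
  all_missing <- feats[colSums(!is.na(ref)) == 0L]
  if (length(all_missing) > 0L) {
    stop("feature(s) entirely missing in the reference: ",
         paste(all_missing, collapse = ", "), call. = FALSE)
  }
  model <- list(method = method,
                features = feats,
                epsilon = epsilon,
                reference = describe_reference(reference),
                n_reference = nrow(ref))
  if (method == "standardize") {
    model$location <- colMeans(ref, na.rm = TRUE)
    pop_sd <- apply(ref, 2L, function(v) {
      v <- v[!is.na(v)]
      sqrt(mean((v - mean(v))^2))
    })
    model$scale <- pmax(pop_sd, epsilon)
  } else if (method == "mad_robustize") {
    model$location <- apply(ref, 2L, stats::median, na.rm = TRUE)
    mads <- apply(ref, 2L, stats::mad, constant = 1.4826, na.rm = TRUE)
    model$scale <- pmax(mads, epsilon)
  } else {
    complete <- stats::complete.cases(ref)
    if (sum(complete) < 2L) {
      stop("spherize needs at least 2 complete reference rows", call. = FALSE)
    }
    refc <- ref[complete, , drop = FALSE]
    model$center <- colMeans(refc)
    model$whitening <- spherize_transform(stats::cov(refc), regularization)
    model$regularization <- regularization
  }
  structure(model, class = "normalization_model")
}

resolve_reference <- function(x, reference) {
  if (is.null(reference)) return(rep(TRUE, nrow(x)))
  if (is.logical(reference)) {
    if (length(reference) != nrow(x)) {
      stop("logical reference selector must have one entry per row", call. = FALSE)
    }
    return(reference & !is.na(reference))
  }
  if (is.character(reference) && length(reference) == 1L) {
    sel <- eval(parse(text = reference)[[1L]], envir = as.data.frame(x),
                enclos = parent.frame(2L))
    if (!is.logical(sel)) stop("reference expression must be logical", call. = FALSE)
    return(sel & !is.na(sel))
  }
  stop("reference must be NULL, a logical vector, or an expression string",
       call. = FALSE)
}

describe_reference <- function(reference) {
  if (is.null(reference)) "all rows"
  else if (is.character(reference)) reference
  else sprintf("logical selector (%d rows)", sum(reference, na.rm = TRUE))
}

#' ZCA whitening transform of a covariance matrix
#'
#' Returns `W = E diag(1/sqrt(lambda + regularization)) E'` where
#' `E, lambda` are the eigenvectors and eigenvalues of the (symmetric)
#' covariance. The ZCA orientation keeps transformed features aligned with
#' the originals, preserving interpretability. Negative eigenvalues from
#' numerical noise are clipped at zero before the ridge is added.
#'
#' @param covariance symmetric covariance matrix.
#' @param regularization non-negative eigenvalue ridge; must be positive when
#'   the covariance is rank deficient.
#' @return the symmetric whitening matrix `W`.
#' @export
spherize_transform <- function(covariance, regularization = 0) {
  covariance <- as.matrix(covariance)
  if (nrow(covariance) != ncol(covariance) ||
      max(abs(covariance - t(covariance))) >
      1e-8 * max(1, max(abs(covariance)))) {
    stop("covariance must be a symmetric square matrix", call. = FALSE)
  }
  stopifnot(regularization >= 0)
  eig <- eigen((covariance + t(covariance)) / 2, symmetric = TRUE)
  lam <- pmax(eig$values, 0) + regularization
  if (any(lam <= 0)) {
    stop("covariance is rank deficient; use a positive regularization",
         call. = FALSE)
  }
  w <- eig$vectors %*% (t(eig$vectors) / sqrt(lam))
  (w + t(w)) / 2
}

#' Apply a fitted normalization model
#'
#' Location-scale methods map each feature value `x` to
#' `(x - location) / scale`; sphering maps each row vector `v` to
#' `(v - center) %*% W`. Metadata columns are untouched and missing feature
#' values stay missing (for sphering, a row with any missing model feature
#' yields missing transformed values). Feature columns not known to the
#' model pass through unchanged; model features missing from the table are an
#' error.
#'
#' @param x a profile table containing all model features (any order).
#' @param model a `normalization_model` from [fit_normalization()].
#' @return the normalized [profile_table], columns in the input order.
#' @export
apply_normalization <- function(x, model) {
  stopifnot(inherits(model, "normalization_model"))
  x <- as_profile_table(x)
  absent <- setdiff(model$features, feature_cols(x))
  if (length(absent) > 0L) {
    stop("model feature(s) absent from profiles: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(x)
  m <- feature_matrix(x, model$features)
  if (model$method == "spherize") {
    centered <- sweep(m, 2L, model$center)
    out <- centered %*% model$whitening
  } else {
    out <- sweep(sweep(m, 2L, model$location), 2L, model$scale, `/`)
  }
  for (j in seq_along(model$features)) df[[model$features[j]]] <- out[, j]
  set_op_report(profile_table(df), NULL)
}

#' @export
#' @rdname apply_normalization
#' @param object a `normalization_model`.
#' @param newdata profile table to normalize.
#' @param ... ignored.
predict.normalization_model <- function(object, newdata, ...) {
  apply_normalization(newdata, object)
}

#' @export
#' @method print normalization_model
print.normalization_model <- function(x, ...) {
  cat(sprintf("normalization_model: %s over %d features\n", x$method,
              length(x$features)))
  cat(sprintf("  reference: %s (%d rows); epsilon %g\n", x$reference,
              x$n_reference, x$epsilon))
  if (x$method == "spherize") {
    cat(sprintf("  whitening matrix %dx%d, regularization %g\n",
                nrow(x$whitening), ncol(x$whitening), x$regularization))
  }
  invisible(x)
}

#' Serialize / restore a normalization model as JSON
#'
#' @param model a `normalization_model`.
#' @param path output (input) JSON path.
#' @return `write_normalization_model()` returns `path` invisibly;
#'   `read_normalization_model()` returns the restored model.
#' @export
write_normalization_model <- function(model, path) {
  stopifnot(inherits(model, "normalization_model"))
  obj <- unclass(model)
  if (!is.null(obj$whitening)) obj$whitening <- as.data.frame(obj$whitening)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_normalization_model
#' @export
read_normalization_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("location", "scale", "center")) {
    if (!is.null(obj[[f]])) obj[[f]] <- stats::setNames(as.numeric(obj[[f]]),
                                                        obj$features)
  }
  if (!is.null(obj$whitening)) obj$whitening <- as.matrix(obj$whitening)
  structure(obj, class = "normalization_model")
}
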