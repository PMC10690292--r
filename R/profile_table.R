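#' Profile tables
#'
#' A profile table is a rectangular table of observations -- single cells or
#' wells -- whose columns are partitioned into *metadata* columns
#' (identifiers and annotations: plate, well, treatment, ...) and numeric
#' *feature* columns (morphology measurements). The partition follows the
#' profiling community's naming convention: columns whose names start with
#' `"Metadata_"` (case sensitive) are metadata, all other columns are
#' features. Missing feature values are permitted; metadata columns are never
#' touched by numeric operations.
#'
#' `profile_table()` validates a data frame against the convention and tags
#' it with the `profile_table` class. All cytoprofile operations accept plain
#' data frames as well and apply the same convention internally.
#'
#' @param data a data.frame.
#' @param metadata_prefix prefix distinguishing metadata columns
#'   (default `"Metadata_"`).
#' @param allow_empty_features permit a table with no feature columns
#'   (used by filters that may drop every feature; default `FALSE`).
#' @return `data` classed as `profile_table`, with attributes
#'   `metadata_cols` and `feature_cols`.
#' @export
#' @examples
#' pt <- profile_table(data.frame(
#'   Metadata_Plate = "P1", Metadata_Well = "A01",
#'   Cells_AreaShape_Area = 120.5
#' ))
#' feature_cols(pt)
profile_table <- function(data, metadata_prefix = default_metadata_prefix(),
                          allow_empty_features = FALSE) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  parts <- split_columns(data, metadata_prefix)
  if (length(parts$features) == 0L && !allow_empty_features) {
    stop("no feature columns found with metadata prefix '", metadata_prefix,
         "'; check the prefix and the column names", call. = FALSE)
  }
  for (f in parts$features) {
    v <- data[[f]]
    if (!(is.numeric(v) || is.logical(v) && all(is.na(v)))) {
      stop("feature column '", f, "' is not numeric; metadata columns must ",
           "carry the '", metadata_prefix, "' prefix", call. = FALSE)
    }
    if (is.logical(v)) data[[f]] <- as.numeric(v)
  }
  structure(data,
            metadata_cols = parts$metadata,
            feature_cols = parts$features,
            metadata_prefix = metadata_prefix,
            class = c("profile_table", "data.frame"))
}

as_profile_table <- function(x, metadata_prefix = default_metadata_prefix()) {
  if (inherits(x, "profile_table")) x else profile_table(x, metadata_prefix)
}

#' @rdname profile_table
#' @param x a profile table or data.frame.
#' @export
metadata_cols <- function(x, metadata_prefix = default_metadata_prefix()) {
  split_columns(x, metadata_prefix)$metadata
}

#' @rdname profile_table
#' @export
feature_cols <- function(x, metadata_prefix = default_metadata_prefix()) {
  split_columns(x, metadata_prefix)$features
}

#' @export
#' @method print profile_table
print.profile_table <- function(x, ...) {
  parts <- split_columns(x)
  cat(sprintf("profile_table: %d observations, %d metadata + %d feature columns\n",
              nrow(x), length(parts$metadata), length(parts$features)))
  n_na <- sum(is.na(as.matrix(x[parts$features])))
  if (n_na > 0) cat(sprintf("  missing feature values: %d\n", n_na))
  show_cols <- utils::head(names(x), 6L)
  print(utils::head(as.data.frame(x)[show_cols], 4L))
  extra <- c(if (nrow(x) > 4L) sprintf("%d more rows", nrow(x) - 4L),
             if (ncol(x) > 6L) sprintf("%d more columns", ncol(x) - 6L))
  if (length(extra) > 0L) cat("  ...", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

# Numeric feature matrix of a profile table (rows kept in order).
feature_matrix <- function(x, features = feature_cols(x)) {
  m <- as.matrix(as.data.frame(x)[features])
  storage.mode(m) <- "double"
  m
}
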