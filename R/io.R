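#' Read a profile table from disk
#'
#' Reads well-level or single-cell profiles from CSV, TSV or Parquet and
#' partitions columns into metadata and features by the prefix convention.
#' Feature columns are coerced to numeric; in delimited files the tokens
#' `""`, `"NA"`, `"NaN"` and `"nan"` -- and any cell that fails numeric
#' parsing -- become missing values.
#'
#' @param path file path; format inferred from the extension
#'   (`.csv`, `.tsv`/`.txt`, `.parquet`) unless `format` is given.
#' @param metadata_prefix metadata column prefix (default `"Metadata_"`).
#' @param format one of `"auto"`, `"csv"`, `"tsv"`, `"parquet"`.
#' @return a [profile_table].
#' @seealso [write_profiles()]
#' @export
read_profiles <- function(path, metadata_prefix = default_metadata_prefix(),
                          format = c("auto", "csv", "tsv", "parquet")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file", call. = FALSE)
  format <- resolve_format(path, format)
  if (format == "parquet") {
    df <- as.data.frame(arrow::read_parquet(path))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            colClasses = "character", check.names = FALSE,
                            na.strings = c("", "NA", "NaN", "nan"),
                            quote = "\"", comment.char = "",
                            stringsAsFactors = FALSE)
    feats <- split_columns(df, metadata_prefix)$features
    for (f in feats) df[[f]] <- suppressWarnings(as.numeric(df[[f]]))
  }
  profile_table(df, metadata_prefix)
}

resolve_format <- function(path, format) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         csv = "csv",
         tsv = "tsv",
         txt = "tsv",
         parquet = "parquet",
         stop("cannot infer format from extension '.", ext,
              "'; pass format= explicitly", call. = FALSE))
}

#' Write a profile table to disk
#'
#' Writes CSV/TSV (missing values serialized as empty fields) or Parquet
#' (exact binary round-trip; a single fixed compression codec, snappy, for
#' bit-stable output). `read_profiles(write_profiles(x, p))` returns the
#' input table exactly for Parquet and within floating-point round-trip
#' tolerance for delimited text.
#'
#' @param table a profile table (or data.frame following the convention).
#' @param path output path; format inferred from extension unless forced.
#' @param format one of `"auto"`, `"csv"`, `"tsv"`, `"parquet"`.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(table, path,
                           format = c("auto", "csv", "tsv", "parquet")) {
  format <- match.arg(format)
  table <- as_profile_table(table)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write '", path, "': directory '", dir,
                             "' does not exist", call. = FALSE)
  format <- resolve_format(path, format)
  df <- as.data.frame(table)
  if (format == "parquet") {
    arrow::write_parquet(df, path, compression = "snappy")
  } else {
    sep <- if (format == "csv") "," else "\t"
    utils::write.table(df, path, sep = sep, na = "", row.names = FALSE,
                       quote = TRUE, qmethod = "double")
  }
  invisible(path)
}

#' Read a plate map
#'
#' A plate map assigns perturbation metadata (compound identifier, InChIKey,
#' concentration, perturbation type, ...) to each well position. The well
#' column is detected by name (`well`, `well_id`, `Metadata_Well`,
#' case-insensitive) unless given explicitly; an optional plate column is
#' detected likewise. Well identifiers are normalized with
#' [normalize_well_id()]. Duplicate (plate, well) keys and malformed well
#' identifiers are validation errors.
#'
#' @param path CSV or TSV file with a well identifier column and at least one
#'   annotation column.
#' @param well_col,plate_col optional explicit column names.
#' @return a data.frame of class `plate_map` with normalized `well` (and
#'   `plate`, when present) columns plus the annotation columns.
#' @export
read_platemap <- function(path, well_col = NULL, plate_col = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file", call. = FALSE)
  format <- resolve_format(path, "auto")
  if (format == "parquet") stop("plate maps must be delimited text", call. = FALSE)
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          na.strings = c("", "NA"), quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  as_platemap(df, well_col = well_col, plate_col = plate_col)
}

# Validate and normalize an in-memory plate map data.frame.
as_platemap <- function(df, well_col = NULL, plate_col = NULL) {
  if (inherits(df, "plate_map")) return(df)
  stopifnot(is.data.frame(df))
  nm <- names(df)
  find_col <- function(given, candidates, what, required) {
    if (!is.null(given)) {
      if (!given %in% nm) stop("column '", given, "' not found", call. = FALSE)
      return(given)
    }
    hit <- nm[tolower(nm) %in% candidates]
    if (length(hit) == 0L) {
      if (required) stop("no ", what, " column found; expected one of: ",
                         paste(candidates, collapse = ", "), call. = FALSE)
      return(NULL)
    }
    hit[[1L]]
  }
  wc <- find_col(well_col, c("well", "well_id", "metadata_well"), "well", TRUE)
  pc <- find_col(plate_col, c("plate", "plate_id", "metadata_plate"), "plate", FALSE)
  ann <- setdiff(nm, c(wc, pc))
  if (length(ann) == 0L) stop("plate map needs at least one annotation column",
                              call. = FALSE)
  out <- data.frame(well = normalize_well_id(df[[wc]]), stringsAsFactors = FALSE)
  if (!is.null(pc)) out$plate <- as.character(df[[pc]])
  key <- if (is.null(pc)) out$well else paste(out$plate, out$well, sep = "/")
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    stop("duplicate plate map entries for: ", paste(dups, collapse = ", "),
         call. = FALSE)
  }
  out <- cbind(out, df[ann])
  class(out) <- c("plate_map", "data.frame")
  out
}

#' @export
#' @method print plate_map
print.plate_map <- function(x, ...) {
  n_plates <- if ("plate" %in% names(x)) length(unique(x$plate)) else 1L
  cat(sprintf("plate_map: %d wells on %d plate(s); annotations: %s\n",
              nrow(x), n_plates,
              paste(setdiff(names(x), c("plate", "well")), collapse = ", ")))
  print(utils::head(as.data.frame(x), 4L))
  invisible(x)
}
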