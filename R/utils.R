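# Internal helpers: column partitioning, well-id normalization, seeded RNG
# scopes, and the per-operation report attribute.

default_metadata_prefix <- function() "Metadata_"

# Partition column names into metadata / feature sets by prefix convention.
split_columns <- function(x, metadata_prefix = default_metadata_prefix()) {
  nm <- names(x)
  meta <- nm[startsWith(nm, metadata_prefix)]
  list(metadata = meta, features = setdiff(nm, meta))
}

#' Normalize well identifiers
#'
#' Converts well identifiers to the canonical alphanumeric convention:
#' uppercase row letter followed by a zero-padded two-digit column
#' (`"a1"` becomes `"A01"`). Rows `A`--`P` and columns 1--24 are accepted,
#' covering 96- and 384-well plates.
#'
#' @param well character vector of well identifiers.
#' @return character vector of normalized well identifiers.
#' @export
#' @examples
#' normalize_well_id(c("a1", "H12", "p24"))
normalize_well_id <- function(well) {
  w <- toupper(trimws(as.character(well)))
  ok <- grepl("^[A-P](0?[1-9]|1[0-9]|2[0-4])$", w)
  if (any(!ok)) {
    stop("malformed well id(s): ", paste(unique(w[!ok]), collapse = ", "),
         call. = FALSE)
  }
  sprintf("%s%02d", substr(w, 1L, 1L), as.integer(substring(w, 2L)))
}

# Run code with a temporarily fixed RNG state; restores .Random.seed after.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# One global seed drives all sub-generators through this derivation rule:
# sub-seed k of seed s is (s * 48271 + k * 8191) mod (2^31 - 1).
derive_seed <- function(seed, stream) {
  s <- (as.double(seed) * 48271 + as.double(stream) * 8191) %% 2147483647
  as.integer(s)
}

#' Retrieve the report attached by a pipeline operation
#'
#' Several operations (single-cell merging, annotation, well labeling) attach
#' a small report (counts of orphans, unmatched rows, excluded wells) to their
#' result. `op_report()` retrieves it.
#'
#' @param x result of a cytoprofile operation.
#' @return the report list, or `NULL` when the operation attached none.
#' @export
op_report <- function(x) attr(x, "op_report", exact = TRUE)

set_op_report <- function(x, report) {
  attr(x, "op_report") <- report
  x
}

# md5 of an R object via its canonical JSON rendering (used for provenance).
object_md5 <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
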