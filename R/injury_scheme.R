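#' The cell-injury class vocabulary
#'
#' The fifteen phenotype classes used by the cell-injury classification
#' workflow: the vehicle-control class plus fourteen injury mechanisms.
#'
#' @return character vector of the 15 class labels.
#' @export
injury_classes <- function() {
  c("Control", "Cytoskeletal", "Hsp90", "Kinase", "Genotoxin",
    "Miscellaneous", "Redox", "HDAC", "mTOR", "Proteasome", "Saponin",
    "Mitochondria", "Ferroptosis", "Tannin", "Nonspecific Reactive")
}

#' Build an injury label scheme
#'
#' Maps compound identifiers (and optionally InChIKeys) to injury classes.
#' Control compounds (DMSO by default) always map to `"Control"`; every
#' mapped injury must belong to the [injury_classes()] vocabulary.
#'
#' @param compounds data.frame with columns `compound` and `injury`, and
#'   optionally `inchikey`. Control compounds may be included (mapped to
#'   `"Control"`) or omitted; they are added automatically.
#' @param control_compounds compounds labeled `"Control"` (default `"DMSO"`).
#' @return an `injury_label_scheme` object.
#' @export
#' @examples
#' sch <- injury_label_scheme(
#'   data.frame(compound = c("cytochalasin-b", "geldanamycin"),
#'              injury = c("Cytoskeletal", "Hsp90")))
#' sch$map[["cytochalasin-b"]]
injury_label_scheme <- function(compounds, control_compounds = "DMSO") {
  stopifnot(is.data.frame(compounds),
            all(c("compound", "injury") %in% names(compounds)))
  compounds$compound <- as.character(compounds$compound)
  compounds$injury <- as.character(compounds$injury)
  bad <- setdiff(unique(compounds$injury), injury_classes())
  if (length(bad) > 0L) {
    stop("injury label(s) outside the class vocabulary: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  wrong_ctl <- compounds$compound %in% control_compounds &
    compounds$injury != "Control"
  if (any(wrong_ctl)) {
    stop("control compound(s) mapped to a non-Control injury: ",
         paste(unique(compounds$compound[wrong_ctl]), collapse = ", "),
         call. = FALSE)
  }
  add <- setdiff(control_compounds, compounds$compound)
  if (length(add) > 0L) {
    extra <- data.frame(compound = add, injury = "Control",
                        stringsAsFactors = FALSE)
    if ("inchikey" %in% names(compounds)) extra$inchikey <- NA_character_
    compounds <- rbind(compounds[names(extra)], extra)
  }
  if (anyDuplicated(compounds$compound)) {
    dups <- unique(compounds$compound[duplicated(compounds$compound)])
    stop("compound(s) mapped more than once: ", paste(dups, collapse = ", "),
         call. = FALSE)
  }
  map <- stats::setNames(compounds$injury, compounds$compound)
  inchikey_map <- NULL
  if ("inchikey" %in% names(compounds)) {
    ok <- !is.na(compounds$inchikey)
    inchikey_map <- stats::setNames(compounds$injury[ok], compounds$inchikey[ok])
  }
  structure(list(classes = injury_classes(), map = map,
                 inchikey_map = inchikey_map,
                 control_compounds = control_compounds,
                 table = compounds),
            class = "injury_label_scheme")
}

#' @export
#' @method print injury_label_scheme
print.injury_label_scheme <- function(x, ...) {
  cat(sprintf("injury_label_scheme: %d compounds over %d classes (%d with InChIKey)\n",
              length(x$map), length(unique(x$map)),
              length(x$inchikey_map %||% character(0))))
  invisible(x)
}

#' Read an injury label scheme from a delimited file
#'
#' @param path CSV/TSV with columns `compound`, `injury` and optionally
#'   `inchikey`.
#' @param control_compounds passed to [injury_label_scheme()].
#' @export
read_injury_scheme <- function(path, control_compounds = "DMSO") {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  injury_label_scheme(df, control_compounds)
}

#' Label wells with their injury class
#'
#' Adds a `Metadata_injury` column from the scheme's compound-to-injury map.
#' Wells whose compound is absent from the scheme (no known injury
#' association) are removed from the output and counted in the attached
#' report.
#'
#' @param profiles a profile table annotated with compound identifiers.
#' @param scheme an [injury_label_scheme()].
#' @param compound_col metadata column holding the compound identifier.
#' @param label_col name of the added label column.
#' @return the labeled [profile_table]; [op_report()] gives `n_excluded`.
#' @export
label_wells <- function(profiles, scheme, compound_col = "Metadata_compound",
                        label_col = "Metadata_injury") {
  stopifnot(inherits(scheme, "injury_label_scheme"))
  profiles <- as_profile_table(profiles)
  if (!compound_col %in% metadata_cols(profiles)) {
    stop("compound column '", compound_col, "' not in profile metadata",
         call. = FALSE)
  }
  df <- as.data.frame(profiles)
  lab <- unname(scheme$map[as.character(df[[compound_col]])])
  keep <- !is.na(lab)
  if (!any(keep)) stop("no wells with a known injury treatment remain",
                       call. = FALSE)
  out <- df[keep, , drop = FALSE]
  out[[label_col]] <- lab[keep]
  # keep the label next to the other metadata, ahead of the features
  meta <- c(metadata_cols(profiles), label_col)
  out <- out[c(meta, feature_cols(profiles))]
  rownames(out) <- NULL
  set_op_report(profile_table(out), list(n_excluded = sum(!keep)))
}

#' Intersect two feature-name lists
#'
#' Returns the features present in both lists, in the first list's order --
#' the shared feature space used to train and apply a model across datasets
#' with different feature panels. An empty intersection is an error, since a
#' downstream model would be degenerate.
#'
#' @param a,b character vectors of feature names.
#' @export
intersect_features <- function(a, b) {
  shared <- a[a %in% b]
  if (length(shared) == 0L) stop("feature lists share no features", call. = FALSE)
  shared
}

#' Match external treatments to the injury scheme by InChIKey
#'
#' Selects the wells of an external plate map whose InChIKey maps to an
#' injury in the scheme, attaching that injury as ground truth. An empty
#' result is allowed and reported.
#'
#' @param scheme an [injury_label_scheme()] carrying InChIKeys.
#' @param platemap external `plate_map` with an InChIKey column
#'   (name matched case-insensitively against `inchikey`).
#' @return data.frame of matched plate-map rows plus an `injury` column;
#'   [op_report()] gives `n_matched`.
#' @export
match_treatments <- function(scheme, platemap) {
  stopifnot(inherits(scheme, "injury_label_scheme"))
  if (is.null(scheme$inchikey_map)) {
    stop("scheme carries no InChIKeys", call. = FALSE)
  }
  platemap <- as_platemap(platemap)
  ik_col <- names(platemap)[tolower(names(platemap)) %in%
                              c("inchikey", "metadata_inchikey")]
  if (length(ik_col) == 0L) stop("plate map has no InChIKey column", call. = FALSE)
  ik <- as.character(platemap[[ik_col[[1L]]]])
  injury <- unname(scheme$inchikey_map[ik])
  out <- as.data.frame(platemap)[!is.na(injury), , drop = FALSE]
  out$injury <- injury[!is.na(injury)]
  rownames(out) <- NULL
  set_op_report(out, list(n_matched = nrow(out)))
}
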