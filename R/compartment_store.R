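#' Single-cell compartment stores
#'
#' CellProfiler-style image analysis emits one relational table per cellular
#' compartment (cells, cytoplasm, nuclei) keyed by `(ImageNumber,
#' ObjectNumber)`, plus an image table keyed by `ImageNumber` carrying plate
#' and well metadata. cytoprofile persists this schema as a directory of
#' plain CSV tables: `image.csv` plus one `<compartment>.csv` per
#' compartment. The cytoplasm table carries explicit `Parent_Cells` /
#' `Parent_Nuclei` columns linking each cytoplasm object to its cell and
#' nucleus; merges use those parent links rather than assuming equal object
#' numbers. Image and object numbers are 1-based as produced upstream and are
#' never renumbered.
#'
#' @param path directory containing `image.csv` and compartment tables.
#' @return `read_compartment_store()` returns a `compartment_store` list with
#'   elements `image` (data.frame) and `compartments` (named list of
#'   data.frames).
#' @name compartment_store
NULL

#' @rdname compartment_store
#' @export
read_compartment_store <- function(path) {
  if (!dir.exists(path)) stop("no such store directory: ", path, call. = FALSE)
  img_path <- file.path(path, "image.csv")
  if (!file.exists(img_path)) stop("store at '", path, "' has no image.csv",
                                   call. = FALSE)
  read_tbl <- function(p) utils::read.table(p, header = TRUE, sep = ",",
                                            check.names = FALSE,
                                            na.strings = c("", "NA", "NaN", "nan"),
                                            stringsAsFactors = FALSE)
  image <- read_tbl(img_path)
  if (!"ImageNumber" %in% names(image)) {
    stop("image table lacks an ImageNumber column", call. = FALSE)
  }
  files <- setdiff(list.files(path, pattern = "\\.csv$"), "image.csv")
  compartments <- lapply(files, function(f) read_tbl(file.path(path, f)))
  names(compartments) <- tolower(tools::file_path_sans_ext(files))
  structure(list(image = image, compartments = compartments, path = path),
            class = "compartment_store")
}

#' @rdname compartment_store
#' @param store a `compartment_store` (or list with `image` and
#'   `compartments` elements).
#' @export
write_compartment_store <- function(store, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, p) utils::write.table(df, p, sep = ",", na = "",
                                           row.names = FALSE, quote = TRUE,
                                           qmethod = "double")
  wr(store$image, file.path(path, "image.csv"))
  for (nm in names(store$compartments)) {
    wr(store$compartments[[nm]], file.path(path, paste0(nm, ".csv")))
  }
  invisible(path)
}

#' @export
#' @method print compartment_store
print.compartment_store <- function(x, ...) {
  cat(sprintf("compartment_store: %d images; compartments: %s\n",
              nrow(x$image),
              paste(sprintf("%s (%d)", names(x$compartments),
                            vapply(x$compartments, nrow, 0L)), collapse = ", ")))
  invisible(x)
}

#' Merge compartment tables into a single-cell profile table
#'
#' Inner-joins the requested compartment tables into one row per cell.
#' When the cytoplasm compartment is among those requested, its
#' `Parent_Cells` / `Parent_Nuclei` columns provide the linkage to the cells
#' and nuclei tables; without cytoplasm, compartments are joined on equal
#' `(ImageNumber, ObjectNumber)`. Feature columns are prefixed with the
#' capitalized compartment name; image-level metadata is attached, and
#' `ImageNumber` / `ObjectNumber` become metadata columns. Cells missing from
#' any requested compartment are excluded and counted in the attached report
#' (see [op_report()]).
#'
#' @param store a `compartment_store` or a path to one.
#' @param compartments compartment names to merge
#'   (default `c("cells", "cytoplasm", "nuclei")`).
#' @return a [profile_table] of single cells, with an `op_report` attribute:
#'   `n_cells`, `n_excluded` (spine objects dropped by the joins) and
#'   per-compartment unmatched object counts.
#' @export
load_single_cells <- function(store,
                              compartments = c("cells", "cytoplasm", "nuclei")) {
  if (is.character(store)) store <- read_compartment_store(store)
  compartments <- tolower(compartments)
  missing_cmp <- setdiff(compartments, names(store$compartments))
  if (length(missing_cmp) > 0L) {
    stop("compartment table(s) missing from store: ",
         paste(missing_cmp, collapse = ", "), call. = FALSE)
  }
  tabs <- store$compartments[compartments]
  for (nm in compartments) {
    t <- tabs[[nm]]
    if (!all(c("ImageNumber", "ObjectNumber") %in% names(t))) {
      stop("compartment '", nm, "' lacks ImageNumber/ObjectNumber keys",
           call. = FALSE)
    }
  }
  cap <- function(s) paste0(toupper(substring(s, 1, 1)), substring(s, 2))

  use_parents <- "cytoplasm" %in% compartments && length(compartments) > 1L
  spine_name <- if (use_parents) "cytoplasm" else compartments[[1L]]
  spine <- tabs[[spine_name]]
  link_cols <- c("ImageNumber", "ObjectNumber",
                 grep("^Parent_", names(spine), value = TRUE))
  merged <- spine[intersect(link_cols, names(spine))]
  feats_of <- function(t, nm) {
    f <- setdiff(names(t), c("ImageNumber", "ObjectNumber",
                             grep("^Parent_", names(t), value = TRUE)))
    out <- t[c("ImageNumber", "ObjectNumber", f)]
    names(out)[-(1:2)] <- paste(cap(nm), f, sep = "_")
    out
  }
  sp_feats <- feats_of(spine, spine_name)
  merged <- cbind(merged, sp_feats[-(1:2)])

  unmatched <- stats::setNames(integer(length(compartments)), compartments)
  for (nm in setdiff(compartments, spine_name)) {
    t <- feats_of(tabs[[nm]], nm)
    if (use_parents) {
      parent_col <- paste0("Parent_", cap(nm))
      if (!parent_col %in% names(merged)) {
        stop("cytoplasm table lacks parent link column '", parent_col, "'",
             call. = FALSE)
      }
      by_x <- c("ImageNumber", parent_col)
    } else {
      by_x <- c("ImageNumber", "ObjectNumber")
    }
    before <- nrow(merged)
    merged$.row_order <- seq_len(nrow(merged))
    m <- merge(merged, t, by.x = by_x, by.y = c("ImageNumber", "ObjectNumber"),
               sort = FALSE)
    m <- m[order(m$.row_order), , drop = FALSE]
    m$.row_order <- NULL
    # objects of this compartment never matched by the spine
    key_t <- paste(t$ImageNumber, t$ObjectNumber)
    key_used <- paste(merged[[by_x[1L]]], merged[[by_x[2L]]])
    unmatched[[nm]] <- sum(!key_t %in% key_used)
    merged <- m
  }
  n_spine <- nrow(spine)
  if (nrow(merged) == 0L) {
    stop("compartment merge produced zero cells", call. = FALSE)
  }
  unmatched[[spine_name]] <- n_spine - nrow(merged)

  # attach image-level metadata
  img <- store$image
  img_meta <- setdiff(names(img), "ImageNumber")
  names(img)[match(img_meta, names(img))] <-
    ifelse(startsWith(img_meta, default_metadata_prefix()),
           img_meta, paste0(default_metadata_prefix(), img_meta))
  merged$.row_order <- seq_len(nrow(merged))
  out <- merge(img, merged, by = "ImageNumber", sort = FALSE)
  out <- out[order(out$.row_order), , drop = FALSE]
  out$.row_order <- NULL
  names(out)[names(out) == "ImageNumber"] <- "Metadata_ImageNumber"
  names(out)[names(out) == "ObjectNumber"] <- "Metadata_ObjectNumber"
  parent_cols <- grep("^Parent_", names(out), value = TRUE)
  names(out)[match(parent_cols, names(out))] <- paste0("Metadata_", parent_cols)
  rownames(out) <- NULL

  report <- list(n_cells = nrow(out),
                 n_excluded = n_spine - nrow(out),
                 unmatched_per_compartment = as.list(unmatched))
  set_op_report(profile_table(out), report)
}
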