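#' Aggregate single-cell profiles into group-level profiles
#'
#' Collapses observations to one row per distinct combination of the
#' stratification columns (typically plate and well), computing the chosen
#' statistic per feature over the group's non-missing values. Metadata
#' columns outside the strata are dropped; a per-group observation count is
#' appended as a metadata column. Output rows are ordered by first appearance
#' of each group.
#'
#' @param x a profile table of single cells (or any observations).
#' @param strata metadata columns defining the groups, e.g.
#'   `c("Metadata_Plate", "Metadata_Well")`.
#' @param statistic `"median"` (default; ties resolved as the mean of the two
#'   central order statistics) or `"mean"`.
#' @param count_col name of the appended count column.
#' @return a [profile_table] with one row per group.
#' @export
#' @examples
#' cells <- data.frame(Metadata_Well = c("A01", "A01", "B02"),
#'                     Cells_Area = c(2, 4, 10))
#' aggregate_profiles(cells, strata = "Metadata_Well", statistic = "mean")
aggregate_profiles <- function(x, strata, statistic = c("median", "mean"),
                               count_col = "Metadata_Object_Count") {
  statistic <- match.arg(statistic)
  x <- as_profile_table(x)
  if (length(strata) == 0L) stop("strata must name at least one metadata column",
                                 call. = FALSE)
  parts <- split_columns(x)
  bad <- setdiff(strata, parts$metadata)
  if (length(bad) > 0L) {
    stop("strata not among metadata columns: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x) == 0L) stop("cannot aggregate an empty table", call. = FALSE)
  df <- as.data.frame(x)
  key <- do.call(paste, c(df[strata], sep = "\r"))
  key <- factor(key, levels = unique(key))  # first-appearance order
  idx <- split(seq_len(nrow(df)), key)
  stat_fun <- if (statistic == "median") {
    function(v) stats::median(v, na.rm = TRUE)
  } else {
    function(v) mean(v, na.rm = TRUE)
  }
  fm <- feature_matrix(x, parts$features)
  agg <- t(vapply(idx, function(i) {
    apply(fm[i, , drop = FALSE], 2L, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0L) NA_real_ else stat_fun(v)
    })
  }, numeric(length(parts$features))))
  if (length(parts$features) == 1L) {
    agg <- matrix(agg, ncol = 1L, dimnames = list(NULL, parts$features))
  }
  meta <- df[vapply(idx, `[`, 0L, 1L), strata, drop = FALSE]
  meta[[count_col]] <- lengths(idx)
  out <- cbind(meta, as.data.frame(agg))
  rownames(out) <- NULL
  profile_table(out)
}

#' Annotate profiles with plate-map metadata
#'
#' Left join: every profile row is retained and matched rows gain the plate
#' map's annotation columns as new metadata columns (prefixed with
#' `"Metadata_"` to satisfy the column convention). Unmatched rows keep
#' missing annotations and are counted in the attached report. Well
#' identifiers on both sides are normalized for matching only; stored values
#' are untouched.
#'
#' @param profiles a profile table whose metadata contains the join columns.
#' @param platemap a `plate_map` (see [read_platemap()]) or data.frame.
#' @param plate_col,well_col metadata columns of `profiles` to join on;
#'   `plate_col` may be `NULL` for a single-plate map.
#' @return the annotated [profile_table]; [op_report()] gives
#'   `n_unmatched`.
#' @export
annotate_profiles <- function(profiles, platemap,
                              plate_col = "Metadata_Plate",
                              well_col = "Metadata_Well") {
  profiles <- as_profile_table(profiles)
  platemap <- as_platemap(platemap)
  parts <- split_columns(profiles)
  need <- c(plate_col, well_col)
  bad <- setdiff(need, parts$metadata)
  if (length(bad) > 0L) stop("join column(s) not in profile metadata: ",
                             paste(bad, collapse = ", "), call. = FALSE)
  use_plate <- !is.null(plate_col) && "plate" %in% names(platemap)
  ann_cols <- setdiff(names(platemap), c("plate", "well"))
  new_names <- ifelse(startsWith(ann_cols, default_metadata_prefix()),
                      ann_cols, paste0(default_metadata_prefix(), ann_cols))
  clash <- intersect(new_names, names(profiles))
  if (length(clash) > 0L) {
    stop("annotation column(s) collide with existing profile columns: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  pm <- as.data.frame(platemap)
  names(pm)[match(ann_cols, names(pm))] <- new_names
  df <- as.data.frame(profiles)
  df$.join_well <- normalize_well_id(df[[well_col]])
  pm$.join_well <- pm$well
  pm$well <- NULL
  by <- ".join_well"
  if (use_plate) {
    df$.join_plate <- as.character(df[[plate_col]])
    pm$.join_plate <- pm$plate
    pm$plate <- NULL
    by <- c(".join_plate", ".join_well")
  } else {
    pm$plate <- NULL
  }
  df$.row_order <- seq_len(nrow(df))
  out <- merge(df, pm, by = by, all.x = TRUE, sort = FALSE)
  out <- out[order(out$.row_order), , drop = FALSE]
  matched <- do.call(paste, df[by]) %in% do.call(paste, pm[by])
  n_unmatched <- sum(!matched)
  out <- out[c(names(profiles), new_names)]
  rownames(out) <- NULL
  set_op_report(profile_table(out), list(n_unmatched = n_unmatched))
}

#' Collapse replicate profiles into consensus profiles
#'
#' Groups well-level profiles by perturbation-level metadata (for example
#' compound id and concentration) and collapses replicates with the chosen
#' statistic -- the same machinery as [aggregate_profiles()] with a
#' replicate count column.
#'
#' @inheritParams aggregate_profiles
#' @export
consensus_profiles <- function(x, strata, statistic = c("median", "mean")) {
  aggregate_profiles(x, strata, statistic,
                     count_col = "Metadata_Replicate_Count")
}
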