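#' Construct plate, treatment and well holdouts
#'
#' Splits a labeled screen into three holdout sets and a modeling set, in
#' the fixed sequence plate, then treatment, then well:
#'
#' 1. *Plate holdout*: all wells of `n_plates` randomly selected plates.
#' 2. *Treatment holdout*: for every injury with strictly more than
#'    `min_treatments` distinct treatments, `treatments_per_injury` whole
#'    treatments (all their remaining wells) are held out. Injuries not
#'    meeting the criterion contribute nothing.
#' 3. *Well holdout*: from each plate not already held out, a random
#'    composition of wells -- by default 5 control wells and 10 injury wells
#'    (15 total). A plate lacking enough eligible wells contributes all it
#'    has; the shortfall is recorded.
#'
#' A well falling in an earlier holdout is never reassigned to a later one,
#' so the four sets are pairwise disjoint and cover all labeled wells.
#'
#' @param profiles labeled profile table (see [label_wells()]).
#' @param n_plates number of plates to hold out (default 10).
#' @param min_treatments an injury qualifies for the treatment holdout only
#'   with more than this many distinct treatments (default 10, strict).
#' @param treatments_per_injury whole treatments held out per qualifying
#'   injury (default 1).
#' @param wells_per_plate named vector `c(controls = 5, injury = 10)`: the
#'   per-plate well-holdout composition.
#' @param plate_col,label_col,treatment_col metadata column names.
#' @param seed integer seed; the same seed reproduces the same partition.
#' @return a `holdout_partition`: row-index vectors `plate_holdout`,
#'   `treatment_holdout`, `well_holdout`, `modeling`, plus `held_plates`,
#'   `held_treatments`, `shortfalls` and the seed.
#' @export
make_holdouts <- function(profiles, n_plates = 10L, min_treatments = 10L,
                          treatments_per_injury = 1L,
                          wells_per_plate = c(controls = 5L, injury = 10L),
                          plate_col = "Metadata_Plate",
                          label_col = "Metadata_injury",
                          treatment_col = "Metadata_compound",
                          seed = 0L) {
  profiles <- as_profile_table(profiles)
  df <- as.data.frame(profiles)
  for (col in c(plate_col, label_col, treatment_col)) {
    if (!col %in% names(df)) stop("column '", col, "' not found", call. = FALSE)
  }
  plates <- unique(as.character(df[[plate_col]]))
  if (length(plates) < n_plates) {
    stop("cannot hold out ", n_plates, " plates from ", length(plates),
         call. = FALSE)
  }
  n <- nrow(df)
  assigned <- rep(NA_character_, n)

  held_plates <- with_seed(derive_seed(seed, 1L),
                           sample(plates, n_plates))
  assigned[df[[plate_col]] %in% held_plates] <- "plate"

  # treatment holdout: qualification on the full labeled screen
  treated <- df[[label_col]] != "Control"
  t_by_injury <- tapply(as.character(df[[treatment_col]])[treated],
                        df[[label_col]][treated],
                        function(v) unique(v))
  qualifying <- names(t_by_injury)[lengths(t_by_injury) > min_treatments]
  held_treatments <- character(0)
  if (length(qualifying) > 0L) {
    held_treatments <- unlist(lapply(seq_along(qualifying), function(k) {
      with_seed(derive_seed(seed, 100L + k),
                sample(t_by_injury[[qualifying[k]]],
                       min(treatments_per_injury,
                           length(t_by_injury[[qualifying[k]]]))))
    }), use.names = FALSE)
    sel <- is.na(assigned) & df[[treatment_col]] %in% held_treatments
    assigned[sel] <- "treatment"
  }

  # well holdout: drawn only from plates not held out
  shortfalls <- list()
  open_plates <- setdiff(plates, held_plates)
  for (k in seq_along(open_plates)) {
    p <- open_plates[k]
    on_plate <- which(is.na(assigned) & df[[plate_col]] == p)
    ctl <- on_plate[df[[label_col]][on_plate] == "Control"]
    inj <- setdiff(on_plate, ctl)
    want_ctl <- wells_per_plate[["controls"]]
    want_inj <- wells_per_plate[["injury"]]
    take_ctl <- with_seed(derive_seed(seed, 1000L + k),
                          sample(ctl, min(want_ctl, length(ctl))))
    take_inj <- with_seed(derive_seed(seed, 2000L + k),
                          sample(inj, min(want_inj, length(inj))))
    if (length(take_ctl) < want_ctl || length(take_inj) < want_inj) {
      shortfalls[[p]] <- c(controls = want_ctl - length(take_ctl),
                           injury = want_inj - length(take_inj))
    }
    assigned[c(take_ctl, take_inj)] <- "well"
  }
  assigned[is.na(assigned)] <- "modeling"

  out <- structure(list(
    plate_holdout = which(assigned == "plate"),
    treatment_holdout = which(assigned == "treatment"),
    well_holdout = which(assigned == "well"),
    modeling = which(assigned == "modeling"),
    held_plates = held_plates,
    held_treatments = held_treatments,
    shortfalls = shortfalls,
    n = n, seed = seed), class = "holdout_partition")
  stopifnot(sum(lengths(out[c("plate_holdout", "treatment_holdout",
                              "well_holdout", "modeling")])) == n)
  out
}

#' @export
#' @method print holdout_partition
print.holdout_partition <- function(x, ...) {
  cat(sprintf(paste0("holdout_partition over %d wells (seed %d):\n",
                     "  plate holdout:     %5d wells (%d plates)\n",
                     "  treatment holdout: %5d wells (%d treatments)\n",
                     "  well holdout:      %5d wells\n",
                     "  modeling set:      %5d wells\n"),
              x$n, x$seed,
              length(x$plate_holdout), length(x$held_plates),
              length(x$treatment_holdout), length(x$held_treatments),
              length(x$well_holdout), length(x$modeling)))
  invisible(x)
}

#' Stratified train/test split
#'
#' Splits labeled profiles into train and test partitions, preserving the
#' class-label proportions. The overall test size is
#' `ceiling(test_fraction * n)`; per-class test counts are the floors of the
#' exact targets with the remainder distributed by largest fractional part,
#' so per-class proportions match the global ones within one well.
#'
#' @param x labeled profile table.
#' @param test_fraction fraction in (0, 1), default 0.2.
#' @param label_col label metadata column.
#' @param seed integer seed.
#' @return list with `train` and `test` profile tables; each carries an
#'   `indices` attribute with the source row indices.
#' @export
#' @examples
#' pt <- data.frame(Metadata_injury = rep(c("Control", "Hsp90"), c(8, 2)),
#'                  Cells_F1 = rnorm(10))
#' sp <- split_train_test(pt, 0.2, seed = 1)
#' nrow(sp$train); nrow(sp$test)  # 8 and 2
split_train_test <- function(x, test_fraction = 0.2,
                             label_col = "Metadata_injury", seed = 0L) {
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  x <- as_profile_table(x)
  df <- as.data.frame(x)
  if (!label_col %in% names(df)) stop("label column '", label_col,
                                      "' not found", call. = FALSE)
  y <- as.character(df[[label_col]])
  counts <- table(y)
  singletons <- names(counts)[counts < 2L]
  if (length(singletons) > 0L) {
    stop("class(es) with fewer than 2 wells cannot be stratified: ",
         paste(singletons, collapse = ", "), call. = FALSE)
  }
  n <- nrow(df)
  n_test <- ceiling(test_fraction * n)
  classes <- names(counts)
  exact <- test_fraction * as.numeric(counts)
  base <- floor(exact)
  rem <- n_test - sum(base)
  if (rem > 0L) {
    order_frac <- order(exact - base, decreasing = TRUE)
    bump <- order_frac[seq_len(rem)]
    base[bump] <- base[bump] + 1L
  }
  # never put a whole class into test
  base <- pmin(base, as.numeric(counts) - 1L)
  test_idx <- integer(0)
  for (k in seq_along(classes)) {
    rows <- which(y == classes[k])
    take <- with_seed(derive_seed(seed, 3000L + k),
                      sample(rows, base[k]))
    test_idx <- c(test_idx, take)
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(n), test_idx)
  train <- profile_table(df[train_idx, , drop = FALSE])
  test <- profile_table(df[test_idx, , drop = FALSE])
  attr(train, "indices") <- train_idx
  attr(test, "indices") <- test_idx
  list(train = train, test = test)
}
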