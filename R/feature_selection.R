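#' Feature selection filters
#'
#' Individual filters over the feature columns of a profile table. Each
#' filter returns an `fs_fragment` naming the features it would drop and the
#' per-feature statistic it computed; [feature_select()] chains filters and
#' assembles the auditable report.
#'
#' `variance_threshold()` implements the near-zero-variance rule: over the
#' non-missing entries of a feature, let `r` be the count of the
#' second-most-frequent value divided by the count of the most frequent
#' value, and `u` the number of distinct values divided by the number of
#' non-missing entries. The feature is dropped when `r <= freq_cut` (a
#' frequency ratio of `freq_cut` *and below* drops) or `u <= unique_cut`.
#'
#' `drop_na_columns()` drops a feature iff its missing fraction strictly
#' *exceeds* `na_cutoff` (a feature at exactly the cutoff is kept).
#'
#' `correlation_threshold()` computes pairwise-complete Pearson correlations
#' (pairs with fewer than `min_pairs` complete observations, or involving a
#' zero-variance feature, count as correlation 0) and then repeatedly takes
#' the pair with the largest `|r| >= corr_threshold` and drops the member
#' with the larger mean absolute correlation to all remaining features,
#' breaking exact ties by dropping the later column, until no pair reaches
#' the threshold.
#'
#' `blocklist()` drops features whose names match any of the glob-style
#' patterns (e.g. `"Cells_Correlation_*"`).
#'
#' @param x a profile table.
#' @param freq_cut drop when the second/first value-count ratio is at or
#'   below this fraction (default 0.05).
#' @param unique_cut drop when the distinct-value fraction is at or below
#'   this (default 0.01).
#' @param na_cutoff missing-fraction cutoff (default 0.05; strict `>` drops).
#' @param corr_threshold absolute-correlation bound (default 0.9).
#' @param min_pairs minimum complete pairs for a correlation to count.
#' @param patterns character vector of glob patterns.
#' @return an `fs_fragment`: list with `rule`, `drop` (character) and
#'   `statistic` (named numeric over all candidate features).
#' @name feature_filters
NULL

fs_fragment <- function(rule, drop, statistic) {
  structure(list(rule = rule, drop = drop, statistic = statistic),
            class = "fs_fragment")
}

#' @rdname feature_filters
#' @export
variance_threshold <- function(x, freq_cut = 0.05, unique_cut = 0.01) {
  stopifnot(freq_cut >= 0, freq_cut <= 1, unique_cut >= 0, unique_cut <= 1)
  x <- as_profile_table(x)
  if (nrow(x) < 2L) stop("variance_threshold needs at least 2 rows", call. = FALSE)
  feats <- feature_cols(x)
  m <- feature_matrix(x, feats)
  ratio <- numeric(length(feats))
  uniq <- numeric(length(feats))
  for (j in seq_along(feats)) {
    v <- m[, j]
    v <- v[!is.na(v)]
    if (length(v) == 0L) { ratio[j] <- 0; uniq[j] <- 0; next }
    counts <- sort(tabulate(factor(v)), decreasing = TRUE)
    ratio[j] <- if (length(counts) < 2L) 0 else counts[2L] / counts[1L]
    uniq[j] <- length(counts) / length(v)
  }
  drop <- feats[ratio <= freq_cut | uniq <= unique_cut]
  fs_fragment("variance_threshold", drop, stats::setNames(ratio, feats))
}

#' @rdname feature_filters
#' @export
drop_na_columns <- function(x, na_cutoff = 0.05) {
  stopifnot(na_cutoff >= 0, na_cutoff <= 1)
  x <- as_profile_table(x)
  feats <- feature_cols(x)
  frac <- colMeans(is.na(feature_matrix(x, feats)))
  fs_fragment("drop_na_columns", feats[frac > na_cutoff],
              stats::setNames(frac, feats))
}

# pairwise-complete |correlation| matrix with the low-overlap and
# zero-variance conventions applied
pairwise_abs_cor <- function(m, min_pairs = 3L) {
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- 0
  npairs <- crossprod(!is.na(m))
  r[npairs < min_pairs] <- 0
  a <- abs(r)
  diag(a) <- 0
  a
}

#' @rdname feature_filters
#' @export
correlation_threshold <- function(x, corr_threshold = 0.9, min_pairs = 3L) {
  stopifnot(corr_threshold >= 0, corr_threshold <= 1)
  x <- as_profile_table(x)
  if (nrow(x) < 3L) stop("correlation_threshold needs at least 3 rows",
                         call. = FALSE)
  feats <- feature_cols(x)
  if (length(feats) < 2L) {
    return(fs_fragment("correlation_threshold", character(0),
                       stats::setNames(rep(NA_real_, length(feats)), feats)))
  }
  a <- pairwise_abs_cor(feature_matrix(x, feats), min_pairs)
  keep <- seq_along(feats)
  dropped <- integer(0)
  stat <- stats::setNames(rep(NA_real_, length(feats)), feats)
  while (length(keep) >= 2L) {
    sub <- a[keep, keep, drop = FALSE]
    mx <- max(sub)
    if (mx < corr_threshold) break
    w <- which(sub == mx, arr.ind = TRUE)
    w <- w[w[, 1L] < w[, 2L], , drop = FALSE]
    w <- w[order(w[, 2L], w[, 1L]), , drop = FALSE]
    i <- keep[w[1L, 1L]]
    j <- keep[w[1L, 2L]]
    mi <- mean(a[i, setdiff(keep, i)])
    mj <- mean(a[j, setdiff(keep, j)])
    victim <- if (mi > mj) i else if (mj > mi) j else max(i, j)
    stat[victim] <- mx
    dropped <- c(dropped, victim)
    keep <- setdiff(keep, victim)
  }
  fs_fragment("correlation_threshold", feats[sort(dropped)], stat)
}

#' @rdname feature_filters
#' @export
blocklist <- function(x, patterns) {
  if (!is.character(patterns) || anyNA(patterns)) {
    stop("blocklist patterns must be a character vector without NAs",
         call. = FALSE)
  }
  x <- as_profile_table(x)
  feats <- feature_cols(x)
  hit <- rep(FALSE, length(feats))
  for (p in patterns) {
    rx <- tryCatch(utils::glob2rx(p), error = function(e) {
      stop("invalid blocklist pattern '", p, "': ", conditionMessage(e),
           call. = FALSE)
    })
    hit <- hit | grepl(rx, feats)
  }
  fs_fragment("blocklist", feats[hit],
              stats::setNames(as.numeric(hit), feats))
}

#' Run an ordered feature-selection pipeline
#'
#' Applies the configured filters in order, each operating on the survivors
#' of the previous one, and returns the filtered table (original column order
#' preserved among survivors) together with a per-feature report. A feature
#' that would fail several rules is attributed to the first rule that fired.
#'
#' The default order -- near-zero-variance, then missingness, then
#' correlation, then blocklist -- runs the cheap filters first. The defaults
#' `freq_cut = 0.05` and `na_cutoff = 0.05` are the thresholds used for
#' cell-injury profile reprocessing.
#'
#' @param x a profile table.
#' @param operations ordered character vector from `"variance_threshold"`,
#'   `"drop_na_columns"`, `"correlation_threshold"`, `"blocklist"`.
#' @inheritParams feature_filters
#' @param blocklist_patterns glob patterns for the blocklist step.
#' @return list with `profiles` (filtered [profile_table]) and `report`
#'   (a `feature_selection_report` data.frame: feature, status, rule,
#'   statistic, in original feature order).
#' @export
feature_select <- function(x,
                           operations = c("variance_threshold",
                                          "drop_na_columns",
                                          "correlation_threshold",
                                          "blocklist"),
                           freq_cut = 0.05, unique_cut = 0.01,
                           na_cutoff = 0.05, corr_threshold = 0.9,
                           min_pairs = 3L,
                           blocklist_patterns = character(0)) {
  known <- c("variance_threshold", "drop_na_columns",
             "correlation_threshold", "blocklist")
  if (length(operations) == 0L) {
    stop("operations must list at least one filter", call. = FALSE)
  }
  bad <- setdiff(operations, known)
  if (length(bad) > 0L) stop("unknown feature-selection operation(s): ",
                             paste(bad, collapse = ", "), call. = FALSE)
  x <- as_profile_table(x)
  all_feats <- feature_cols(x)
  report <- data.frame(feature = all_feats, status = "kept",
                       rule = NA_character_, statistic = NA_real_,
                       stringsAsFactors = FALSE)
  current <- x
  for (op in operations) {
    frag <- switch(op,
      variance_threshold = variance_threshold(current, freq_cut, unique_cut),
      drop_na_columns = drop_na_columns(current, na_cutoff),
      correlation_threshold = correlation_threshold(current, corr_threshold,
                                                    min_pairs),
      blocklist = blocklist(current, blocklist_patterns))
    if (length(frag$drop) > 0L) {
      i <- match(frag$drop, report$feature)
      report$status[i] <- "dropped"
      report$rule[i] <- frag$rule
      report$statistic[i] <- frag$statistic[frag$drop]
      keep_cols <- setdiff(names(current), frag$drop)
      current <- profile_table(as.data.frame(current)[keep_cols],
                               allow_empty_features = TRUE)
    }
  }
  class(report) <- c("feature_selection_report", "data.frame")
  attr(report, "counts") <- table(factor(report$rule[report$status == "dropped"],
                                         levels = operations))
  attr(report, "selected") <- report$feature[report$status == "kept"]
  list(profiles = current, report = report)
}

#' @export
#' @method print feature_selection_report
print.feature_selection_report <- function(x, ...) {
  n_kept <- sum(x$status == "kept")
  cat(sprintf("feature_selection_report: %d of %d features selected\n",
              n_kept, nrow(x)))
  counts <- attr(x, "counts")
  for (nm in names(counts)) {
    if (counts[[nm]] > 0) cat(sprintf("  dropped by %s: %d\n", nm, counts[[nm]]))
  }
  invisible(x)
}

#' Write a feature-selection report to CSV or JSON
#'
#' @param report a `feature_selection_report`.
#' @param path output path ending in `.csv` or `.json`.
#' @export
write_selection_report <- function(report, path) {
  stopifnot(inherits(report, "feature_selection_report"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE, na = "")
  } else if (ext == "json") {
    jsonlite::write_json(as.data.frame(report), path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  } else {
    stop("unsupported report format: .", ext, call. = FALSE)
  }
  invisible(path)
}
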