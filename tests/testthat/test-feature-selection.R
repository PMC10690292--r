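pt_from <- function(...) {
  cols <- list(...)
  n <- length(cols[[1]])
  profile_table(cbind(data.frame(Metadata_Well = sprintf("A%02d", seq_len(n))),
                      as.data.frame(cols)))
}

# independent greedy oracle over a plain correlation matrix
corr_oracle_survivors <- function(m, threshold) {
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- 0
  a <- abs(r)
  diag(a) <- 0
  keep <- seq_len(ncol(m))
  while (length(keep) >= 2) {
    sub <- a[keep, keep, drop = FALSE]
    mx <- max(sub)
    if (mx < threshold) break
    hit <- which(sub == mx, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 2], hit[, 1]), , drop = FALSE]
    i <- keep[hit[1, 1]]; j <- keep[hit[1, 2]]
    mi <- mean(a[i, setdiff(keep, i)]); mj <- mean(a[j, setdiff(keep, j)])
    drop <- if (mi > mj) i else if (mj > mi) j else max(i, j)
    keep <- setdiff(keep, drop)
  }
  colnames(m)[keep]
}

test_that("the near-zero-variance frequency ratio drops at the cutoff and below", {
  v <- c(rep(0, 100), rep(7, 5))
  frag <- variance_threshold(pt_from(Cells_A = v), freq_cut = 0.05)
  expect_equal(unname(frag$statistic["Cells_A"]), 0.05)
  expect_equal(frag$drop, "Cells_A")  # 0.05 "and below" is removed

  frag2 <- variance_threshold(pt_from(Cells_A = rep(1, 10)), freq_cut = 0.05)
  expect_equal(frag2$drop, "Cells_A")  # constant: no second value, r = 0

  frag3 <- variance_threshold(pt_from(Cells_A = rep(c(0, 1), 25)),
                              freq_cut = 0.05)
  expect_equal(unname(frag3$statistic["Cells_A"]), 1)
  expect_length(frag3$drop, 0L)

  expect_error(variance_threshold(pt_from(Cells_A = 1)), "2 rows")
})

test_that("the missingness filter drops strictly above the cutoff", {
  x6 <- c(rep(NA_real_, 6), rnorm(94))
  x5 <- c(rep(NA_real_, 5), rnorm(95))
  frag <- drop_na_columns(pt_from(Cells_Six = x6, Cells_Five = x5),
                          na_cutoff = 0.05)
  expect_equal(frag$drop, "Cells_Six")   # 6% exceeds 5%
  # exactly 5% is not "exceeded"
  expect_false("Cells_Five" %in% frag$drop)
  clean <- drop_na_columns(pt_from(Cells_A = rnorm(10)), 0.05)
  expect_length(clean$drop, 0L)
})

test_that("correlation filter drops one of a duplicated pair and spares orthogonal features", {
  set.seed(1)
  f1 <- rnorm(50)
  frag <- correlation_threshold(pt_from(Cells_A = f1, Cells_B = f1),
                                corr_threshold = 0.9)
  expect_length(frag$drop, 1L)

  f2 <- rnorm(50)
  frag2 <- correlation_threshold(pt_from(Cells_A = f1, Cells_B = f2),
                                 corr_threshold = 0.9)
  expect_length(frag2$drop, 0L)

  # f3 = f1 + tiny noise: the pair (f1, f3) fires; the brute-force oracle
  # decides which member goes
  f3 <- f1 + rnorm(50, sd = 1e-4)
  tab <- pt_from(Cells_A = f1, Cells_B = f2, Cells_C = f3)
  frag3 <- correlation_threshold(tab, corr_threshold = 0.9)
  expect_equal(setdiff(feature_cols(tab), frag3$drop),
               corr_oracle_survivors(feature_matrix(tab), 0.9))
})

test_that("correlation survivors match the exhaustive oracle on random small tables", {
  for (seed in 1:25) {
    set.seed(seed)
    p <- sample(3:8, 1)
    n <- 30
    m <- matrix(rnorm(n * p), n)
    # induce correlated blocks
    for (j in seq_len(p - 1)) {
      if (runif(1) < 0.5) m[, j + 1] <- m[, j] + rnorm(n, sd = runif(1, 0.01, 1))
    }
    colnames(m) <- sprintf("Cells_F%d", seq_len(p))
    tab <- profile_table(cbind(data.frame(Metadata_Well = sprintf("A%02d", 1:n)),
                               as.data.frame(m)))
    thr <- sample(c(0.7, 0.8, 0.9, 0.95), 1)
    frag <- correlation_threshold(tab, corr_threshold = thr)
    survivors <- setdiff(colnames(m), frag$drop)
    expect_equal(survivors, corr_oracle_survivors(m, thr))
    # no surviving pair may exceed the threshold
    if (length(survivors) >= 2) {
      a <- abs(stats::cor(m[, survivors]))
      diag(a) <- 0
      expect_lt(max(a), thr)
    }
  }
})

test_that("blocklist drops exactly the matching feature names", {
  tab <- pt_from(Cells_Correlation_X = rnorm(5), Cells_Area = rnorm(5),
                 Nuclei_Correlation_Y = rnorm(5))
  frag <- blocklist(tab, "Cells_Correlation_*")
  expect_equal(frag$drop, "Cells_Correlation_X")
  expect_length(blocklist(tab, character(0))$drop, 0L)
  expect_length(blocklist(tab, "Zebrafish_*")$drop, 0L)
  expect_error(blocklist(tab, c("ok", NA)), "character")
})

test_that("feature_select chains operations with first-rule-wins attribution", {
  set.seed(7)
  n <- 60
  good <- rnorm(n)
  tab <- pt_from(Cells_Good = good,
                 Cells_Const = rep(1, n),            # variance rule
                 Cells_Holey = ifelse(runif(n) < 0.3, NA, rnorm(n)),  # NA rule
                 Cells_Twin = good + rnorm(n, sd = 1e-6))  # correlation rule
  res <- feature_select(tab, operations = c("variance_threshold",
                                            "drop_na_columns",
                                            "correlation_threshold"))
  rep <- res$report
  expect_setequal(rep$feature,
                  c("Cells_Good", "Cells_Const", "Cells_Holey", "Cells_Twin"))
  expect_equal(rep$rule[rep$feature == "Cells_Const"], "variance_threshold")
  expect_equal(rep$rule[rep$feature == "Cells_Holey"], "drop_na_columns")
  expect_equal(sum(rep$status == "kept") + sum(rep$status == "dropped"),
               4L)  # report covers every feature exactly once
  expect_equal(feature_cols(res$profiles), rep$feature[rep$status == "kept"])
  expect_error(feature_select(tab, operations = character(0)), "at least one")
  expect_error(feature_select(tab, operations = "prune_by_vibes"), "unknown")
})

test_that("survivor sets respond monotonically to their thresholds", {
  for (seed in 1:3) {
    tab <- random_profile_table(n = 40L, p = 8L, na_rate = 0.12,
                                seed = seed)
    n_kept <- function(...) sum(feature_select(tab, ...)$report$status == "kept")
    expect_lte(n_kept(operations = "drop_na_columns", na_cutoff = 0.05),
               n_kept(operations = "drop_na_columns", na_cutoff = 0.2))
    expect_lte(n_kept(operations = "correlation_threshold",
                      corr_threshold = 0.5),
               n_kept(operations = "correlation_threshold",
                      corr_threshold = 0.95))
    expect_gte(n_kept(operations = "variance_threshold", freq_cut = 0.01),
               n_kept(operations = "variance_threshold", freq_cut = 0.5))
  }
})

test_that("row order does not affect the survivor set", {
  tab <- random_profile_table(n = 30L, p = 6L, na_rate = 0.1, seed = 11L)
  res1 <- feature_select(tab, operations = c("variance_threshold",
                                             "drop_na_columns",
                                             "correlation_threshold"))
  set.seed(2)
  perm <- profile_table(as.data.frame(tab)[sample(nrow(tab)), ])
  res2 <- feature_select(perm, operations = c("variance_threshold",
                                              "drop_na_columns",
                                              "correlation_threshold"))
  expect_equal(attr(res1$report, "selected"), attr(res2$report, "selected"))
})

test_that("selection reports serialize to CSV and JSON", {
  tab <- random_profile_table(n = 30L, p = 5L, na_rate = 0.2, seed = 13L)
  res <- feature_select(tab, operations = "drop_na_columns")
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_selection_report(res$report, csv)
  write_selection_report(res$report, js)
  expect_equal(nrow(utils::read.csv(csv)), nrow(res$report))
  expect_length(jsonlite::read_json(js), nrow(res$report))
})
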