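test_that("the hyperparameter grid contains exactly the valid combinations", {
  g <- search_grid()
  # 2 plain penalties x 6 strengths x 2 tolerances + elastic net x 5 ratios
  expect_equal(nrow(g), 2 * 6 * 2 + 6 * 2 * 5)
  expect_true(all(is.na(g$ratio[g$penalty != "elasticnet"])))
  expect_true(all(!is.na(g$ratio[g$penalty == "elasticnet"])))
  expect_setequal(unique(g$C), c(1e-4, 1e-2, 0.1, 1, 10, 100))
  expect_setequal(unique(g$tol), c(1e-6, 1e-3))
  expect_error(search_grid(strengths = -1))
})

test_that("well-separated classes are recovered almost perfectly", {
  classes <- c("Control", "Hsp90", "Kinase")
  train <- make_labeled(classes, rep(60, 3), n_features = 8, effect = 5,
                        seed = 1L)
  test <- make_labeled(classes, rep(30, 3), n_features = 8, effect = 5,
                       seed = 2L)
  model <- train_injury_classifier(train, n_candidates = 5L, cv_folds = 3L,
                                   seed = 4L)
  pred <- predict(model, test, type = "class")
  f1 <- macro_f1(test$Metadata_injury, pred, model$classes)
  expect_gt(f1, 0.95)
  expect_equal(model$classes, sort(classes))
  expect_equal(ncol(model$coefficients), length(model$features))
})

test_that("permuted training labels collapse performance to chance", {
  classes <- c("Control", "Hsp90", "Kinase")
  train <- make_labeled(classes, rep(60, 3), n_features = 8, effect = 5,
                        seed = 5L)
  test <- make_labeled(classes, rep(40, 3), n_features = 8, effect = 5,
                       seed = 6L)
  df <- as.data.frame(train)
  set.seed(9)
  df$Metadata_injury <- sample(df$Metadata_injury)
  null_model <- train_injury_classifier(profile_table(df), n_candidates = 4L,
                                        cv_folds = 3L, seed = 4L)
  f1 <- macro_f1(test$Metadata_injury,
                 predict(null_model, test, type = "class"),
                 null_model$classes)
  expect_lt(abs(f1 - 1 / 3), 0.1)
})

test_that("training validates its inputs", {
  one_class <- make_labeled("Control", 20, seed = 1L)
  expect_error(train_injury_classifier(one_class), "2 classes")
  small <- make_labeled(c("Control", "Hsp90"), c(3, 3), seed = 1L)
  expect_error(train_injury_classifier(small, cv_folds = 5L), "cv_folds")
})

test_that("balanced class weights raise minority recall on imbalanced data", {
  classes <- c("Control", "Tannin")
  # overlapping distributions, 95/5 imbalance
  train <- make_labeled(classes, c(380, 20), n_features = 4, effect = 1.2,
                        seed = 7L)
  test <- make_labeled(classes, c(190, 10), n_features = 4, effect = 1.2,
                       seed = 8L)
  grid <- search_grid(penalties = "l2", strengths = 1, tolerances = 1e-6)
  weighted <- train_injury_classifier(train, grid = grid, n_candidates = 1L,
                                      cv_folds = 3L, seed = 3L)
  unweighted <- train_injury_classifier(train, grid = grid, n_candidates = 1L,
                                        cv_folds = 3L, class_weight = "none",
                                        seed = 3L)
  recall_minority <- function(m) {
    cm <- class_metrics(test$Metadata_injury,
                        predict(m, test, type = "class"), m$classes)
    cm$recall[cm$class == "Tannin"]
  }
  expect_gt(recall_minority(weighted), recall_minority(unweighted))
})

test_that("predictions are normalized, deterministic and feature-checked", {
  train <- make_labeled(c("Control", "Hsp90"), c(30, 30), n_features = 5,
                        effect = 3, seed = 11L)
  model <- train_injury_classifier(train, n_candidates = 3L, cv_folds = 3L,
                                   seed = 1L)
  p <- predict(model, train, type = "prob")
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  dup <- profile_table(as.data.frame(train)[c(1, 1), ])
  pd <- predict(model, dup, type = "prob")
  expect_equal(pd[1, ], pd[2, ])
  stripped <- as.data.frame(train)
  stripped$Cells_Feature_01 <- NULL
  expect_error(predict(model, profile_table(stripped)), "Cells_Feature_01")
  # the probability-table surface carries metadata and the argmax label
  tab <- predict_injury(model, train)
  expect_true(all(c("prob_Control", "prob_Hsp90",
                    "predicted_injury") %in% names(tab)))
  expect_equal(tab$predicted_injury, predict(model, train, type = "class"))
})

test_that("a model bundle survives a JSON round trip", {
  train <- make_labeled(c("Control", "Hsp90"), c(30, 30), n_features = 5,
                        effect = 3, seed = 12L)
  model <- train_injury_classifier(train, n_candidates = 3L, cv_folds = 3L,
                                   seed = 2L)
  path <- withr::local_tempfile(fileext = ".json")
  write_injury_model(model, path)
  back <- read_injury_model(path)
  expect_equal(predict(back, train, type = "prob"),
               predict(model, train, type = "prob"), tolerance = 1e-12)
  expect_equal(back$hyperparameters$penalty, model$hyperparameters$penalty)
})

test_that("evaluation metrics match hand-computed confusion counts", {
  truth <- c("A", "A", "B", "B")
  pred <- c("A", "B", "B", "B")
  m <- class_metrics(truth, pred, c("A", "B"))
  expect_equal(m$precision[m$class == "B"], 2 / 3)
  expect_equal(m$recall[m$class == "B"], 1)
  expect_equal(m$f1[m$class == "B"], 0.8)
  expect_equal(m$recall[m$class == "A"], 0.5)

  perfect <- class_metrics(truth, truth, c("A", "B"))
  expect_equal(perfect$f1, c(1, 1))
  expect_equal(unname(diag(confusion_matrix(truth, truth, c("A", "B")))),
               c(2L, 2L))
  wrong <- class_metrics(truth, rev(truth), c("A", "B"))
  expect_equal(wrong$f1, c(0, 0))
})

test_that("evaluation reports cover each split and the shuffled baseline", {
  classes <- c("Control", "Hsp90", "Kinase")
  train <- make_labeled(classes, rep(40, 3), n_features = 6, effect = 4,
                        seed = 13L)
  test <- make_labeled(classes, rep(20, 3), n_features = 6, effect = 4,
                       seed = 14L)
  model <- train_injury_classifier(train, n_candidates = 3L, cv_folds = 3L,
                                   seed = 5L)
  rep <- evaluate_model(model, list(train = train, test = test),
                        shuffled_baseline = TRUE, seed = 3L)
  # confusion rows must sum to each split's true class counts
  expect_equal(unname(rowSums(rep$splits$train$confusion)),
               unname(as.vector(table(factor(train$Metadata_injury,
                                             levels = model$classes)))))
  expect_equal(unname(rowSums(rep$splits$test$confusion)),
               unname(as.vector(table(factor(test$Metadata_injury,
                                             levels = model$classes)))))
  expect_gt(rep$splits$test$macro_f1, 0.9)
  expect_lt(rep$baseline$splits$test$macro_f1, rep$splits$test$macro_f1)
  expect_true(rep$baseline$shuffled)
  path <- withr::local_tempfile(fileext = ".json")
  write_evaluation_report(rep, path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(js$macro_f1$test, rep$splits$test$macro_f1)
  expect_error(evaluate_model(model, list(test = test),
                              shuffled_baseline = TRUE), "train")
})
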