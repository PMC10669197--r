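test_that("evaluation metrics follow the four definitions", {
  # perfect predictions
  m <- evaluate_predictions(c(30, 40, 50, 70), c(30, 40, 50, 70))
  expect_equal(m$r, 1)
  expect_equal(m$rmse, 0)
  expect_equal(m$mape, 0)
  expect_equal(m$r2, 1)

  # hand-evaluated pair
  m <- evaluate_predictions(c(50, 60), c(55, 54))
  expect_equal(m$rmse, sqrt((25 + 36) / 2))
  expect_equal(m$mape, (5 / 50 + 6 / 60) / 2)

  # predicting the mean gives R2 = 0
  x <- c(30, 45, 60, 75)
  m <- evaluate_predictions(x, rep(mean(x), 4))
  expect_equal(m$r2, 0)
  expect_true(is.na(m$r))  # constant predictions: r undefined, noted
  expect_match(m$note, "constant")

  # zero age rejected (MAPE denominator)
  expect_error(evaluate_predictions(c(0, 50), c(10, 50)), "positive")

  # R2-RMSE identity and affine invariance of r on random pairs
  for (k in 1:20) {
    xy <- withr::with_seed(k, list(x = runif(30, 20, 80),
                                   y = runif(30, 20, 80)))
    m <- evaluate_predictions(xy$x, xy$y)
    expect_equal(m$r2, 1 - (m$rmse^2 * 30) / sum((xy$x - mean(xy$x))^2),
                 tolerance = 1e-12)
    m2 <- evaluate_predictions(xy$x, 2.5 * xy$y + 7)
    expect_equal(m2$r, m$r, tolerance = 1e-12)
  }
})

test_that("fold assignment is balanced, reproducible and guarded", {
  f <- assign_folds(sprintf("S%03d", 1:171), k = 4, seed = 9)
  expect_equal(sort(as.vector(table(f))), c(42, 43, 43, 43))
  expect_identical(f, assign_folds(sprintf("S%03d", 1:171), k = 4, seed = 9))
  expect_false(identical(f, assign_folds(sprintf("S%03d", 1:171), 4, 10)))

  f8 <- assign_folds(1:8, k = 4, seed = 1)
  expect_true(all(table(f8) == 2))
  expect_error(assign_folds(1:3, k = 4), "at least")
})

test_that("randomized search samples, scores and degenerates correctly", {
  tab <- simulate_tabular_cohort(cohort_spec(n_subjects = 40, seed = 1))
  # single-point space returns that point
  sp <- model_spec("random_forest",
                   search_space = list(n_estimators = 11L, max_depth = 3L))
  tuned <- randomized_search(sp, tab, n_iter = 3, seed = 1)
  expect_equal(tuned$params$n_estimators, 11L)
  expect_equal(tuned$params$max_depth, 3L)
  # empty space: unchanged with a warning
  expect_warning(out <- randomized_search(model_spec("linear"), tab),
                 "empty search space")
  expect_equal(out$family, "linear")
  # deterministic under seed
  sp <- model_spec("xgb_style_boosting",
                   search_space = list(max_depth = 2:4,
                                       learning_rate = c(0.1, 0.3)))
  t1 <- randomized_search(sp, tab, n_iter = 4, seed = 7)
  t2 <- randomized_search(sp, tab, n_iter = 4, seed = 7)
  expect_equal(t1$params, t2$params)
  # unknown search parameter rejected
  expect_error(model_spec("linear", search_space = list(bogus = 1)),
               "bogus")
})

test_that("hyperparameter registry validates names and seeds Table defaults", {
  expect_equal(model_spec("random_forest")$params$n_estimators, 74L)
  expect_equal(model_spec("adaboost")$params$learning_rate, 0.07)
  expect_equal(model_spec("gradient_boosting")$params$n_estimators, 198L)
  expect_equal(model_spec("bayesian_ridge")$params$alpha_1, 4e-4)
  expect_equal(model_spec("xgb_style_boosting")$params$colsample_bytree,
               0.95)
  expect_error(model_spec("random_forest", params = list(max_iter = 5)),
               "max_iter")
})

test_that("run_cv exactly recovers a noiseless linear world", {
  tab <- simulate_tabular_cohort(
    cohort_spec(n_subjects = 48, noise_sd = 0, seed = 3))
  cv <- run_cv(tab, list(linear = model_spec("linear")), k = 4, seed = 5)
  expect_lt(max(cv$fold_metrics$rmse), 1e-6)
  expect_equal(min(cv$fold_metrics$r), 1, tolerance = 1e-9)
})

test_that("run_cv produces six metric rows, retained predictions and importances", {
  tab <- simulate_tabular_cohort(cohort_spec(n_subjects = 60, seed = 4))
  specs <- default_model_specs()
  # shrink ensembles for speed; hyperparameters stay registry-valid
  specs$random_forest$params$n_estimators <- 20L
  specs$adaboost$params$n_estimators <- 20L
  specs$gradient_boosting$params$n_estimators <- 20L
  specs$xgb_style_boosting$params$n_estimators <- 20L
  cv <- run_cv(tab, specs, k = 4, seed = 6)
  expect_equal(nrow(cv$aggregated), 6L)
  expect_setequal(unique(cv$fold_metrics$model), names(specs))
  expect_setequal(unique(cv$predictions$set), c("training", "validation"))
  # folds partition the subjects
  expect_equal(sort(as.vector(table(cv$folds))), c(15, 15, 15, 15))
  # every tree family has importances summing to 1
  expect_setequal(names(cv$importances),
                  c("random_forest", "adaboost", "gradient_boosting",
                    "xgb_style_boosting"))
  for (imp in cv$importances) {
    expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
    expect_true(all(diff(imp$importance) <= 1e-12))
  }
  # determinism: identical rerun under the same seed
  cv2 <- run_cv(tab, specs, k = 4, seed = 6)
  expect_identical(cv$fold_metrics, cv2$fold_metrics)
})

test_that("a failing model is recorded per fold while others proceed", {
  tab <- simulate_tabular_cohort(cohort_spec(n_subjects = 24, seed = 8))
  bad <- model_spec("adaboost", params = list(loss = "no_such_loss",
                                              n_estimators = 5L))
  cv <- run_cv(tab, list(linear = model_spec("linear"), adaboost = bad),
               k = 4, seed = 2)
  expect_equal(nrow(cv$errors), 4L)
  expect_true(all(cv$errors$model == "adaboost"))
  expect_equal(sum(cv$fold_metrics$model == "linear"), 4L)
})

test_that("tree importance finds a single causal feature; non-tree rejects", {
  cs <- cohort_spec(n_subjects = 150,
                    coefficients = c("L-ICA_diam_mean" = 25),
                    noise_sd = 4, seed = 10)
  tab <- simulate_tabular_cohort(cs)
  X <- as.matrix(tab[, vm_feature_names()])
  m <- fit_model(model_spec("random_forest"), X, tab$age, seed = 3)
  imp <- feature_importance(m)
  expect_equal(imp$feature[1], "L-ICA_diam_mean")
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_length(feature_importance(m, top_n = 10)$feature, 10L)

  lin <- fit_model(model_spec("linear"), X, tab$age)
  expect_error(feature_importance(lin), "tree-based")

  # duplicated causal feature: split credit is shared, combined importance
  # comparable to the single-feature case
  X2 <- X
  X2[, "R-ICA_diam_mean"] <- X2[, "L-ICA_diam_mean"]
  m2 <- fit_model(model_spec("random_forest"), X2, tab$age, seed = 3)
  imp2 <- feature_importance(m2)
  pair <- sum(imp2$importance[imp2$feature %in%
                                c("L-ICA_diam_mean", "R-ICA_diam_mean")])
  single <- imp$importance[1]
  expect_gt(pair, 0.6 * single)
  expect_lt(abs(pair - single), 0.35)
})

test_that("bayesian ridge approaches least squares on strong-signal data", {
  cs <- cohort_spec(n_subjects = 200, noise_sd = 2, seed = 12)
  tab <- simulate_tabular_cohort(cs)
  X <- as.matrix(tab[, vm_feature_names()])
  br <- fit_model(model_spec("bayesian_ridge"), X, tab$age)
  ols <- fit_model(model_spec("linear"), X, tab$age)
  pb <- predict(br, X)
  po <- predict(ols, X)
  expect_lt(sqrt(mean((pb - po)^2)), 0.5)
})

test_that("shuffled ages break the age-feature link (leakage guard)", {
  rs <- vapply(1:20, function(k) {
    tab <- simulate_tabular_cohort(cohort_spec(n_subjects = 80, seed = 20))
    tab$age <- withr::with_seed(300 + k, sample(tab$age))
    cv <- run_cv(tab, list(linear = model_spec("linear")), k = 4,
                 seed = 400 + k)
    mean(abs(cv$fold_metrics$r))
  }, numeric(1))
  expect_lt(mean(rs), 2 / sqrt(20))  # validation folds hold 20 subjects
})

test_that("scatter plots are written with coordinate sidecars", {
  tmp <- withr::local_tempdir()
  x <- c(30, 40, 50, 60)
  y <- c(32, 41, 49, 58)
  path <- file.path(tmp, "sc.pdf")
  scatter_plot(x, y, path)
  expect_true(file.exists(path) && file.size(path) > 0)
  pts <- read.csv(file.path(tmp, "sc_points.csv"))
  expect_equal(pts$age, x)
  expect_equal(pts$predicted, y)
  expect_error(scatter_plot(numeric(), numeric(), path), "nonempty")
})
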