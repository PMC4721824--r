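test_that("stratified k-fold folds partition samples and preserve proportions", {
  labels <- rep(c("a", "b"), each = 50)
  folds <- stratified_kfold_split(labels, k = 10, seed = 1)
  expect_length(folds, 10)
  expect_setequal(unlist(folds), seq_along(labels))
  expect_equal(sum(lengths(folds)), 100)          # disjoint + exhaustive
  for (f in folds) {
    expect_length(f, 10)
    expect_equal(sum(labels[f] == "a"), 5)
  }

  # unbalanced case: per-fold class counts within 1 of proportional share
  lab2 <- rep(c("a", "b", "c"), c(23, 31, 46))
  folds2 <- stratified_kfold_split(lab2, k = 5, seed = 2)
  expect_setequal(unlist(folds2), seq_along(lab2))
  for (f in folds2)
    for (cl in c("a", "b", "c")) {
      share <- sum(lab2 == cl) / 5
      expect_lte(abs(sum(lab2[f] == cl) - share), 1)
    }

  expect_error(stratified_kfold_split(rep(c("a", "b"), c(3, 20)), k = 4),
               "a")
})

test_that("subject-wise folds isolate each subject's samples", {
  ids <- rep(sprintf("S%02d", 1:26), times = 3)
  folds <- subjectwise_split(ids)
  expect_length(folds, 26)
  expect_setequal(unlist(folds), seq_along(ids))
  for (nm in names(folds)) {
    expect_true(all(ids[folds[[nm]]] == nm))
    expect_false(any(ids[-folds[[nm]]] == nm))
  }
  # unequal fold sizes follow step counts
  ids2 <- rep(c("A", "B"), c(5, 7))
  expect_equal(unname(lengths(subjectwise_split(ids2))), c(5L, 7L))
  expect_error(subjectwise_split(rep("A", 5)), ">= 2 subjects")
})

test_that("confusion-matrix metrics follow the accuracy formula", {
  # binary: TP=9, TN=8, FP=2, FN=1 -> rate 17/20
  m <- matrix(c(9, 1, 2, 8), 2, 2, byrow = TRUE,
              dimnames = list(c("pos", "neg"), c("pos", "neg")))
  got <- compute_metrics(m)
  expect_equal(got$classification_rate, 0.85)
  # binary identities: sens = TP/(TP+FN), spec = TN/(TN+FP), macro-averaged
  expect_equal(got$sensitivity, mean(c(9 / 10, 8 / 10)))
  expect_equal(got$specificity, mean(c(8 / 10, 9 / 10)))
  expect_equal(unname(got$ppv_per_class), c(9 / 11, 8 / 9))

  # perfect diagonal
  d <- diag(c(4, 6, 5)); dimnames(d) <- list(letters[1:3], letters[1:3])
  perf <- compute_metrics(d)
  expect_equal(perf$classification_rate, 1)
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$specificity, 1)
  expect_equal(perf$avg_ppv, 1)

  # random matrices vs the per-cell oracle; invariance under permutation
  set.seed(3)
  for (rep in 1:200) {
    k <- sample(2:5, 1)
    m <- matrix(rpois(k * k, 4), k, k,
                dimnames = list(letters[1:k], letters[1:k]))
    if (sum(m) == 0) m[1, 1] <- 1
    got <- suppressWarnings(compute_metrics(m))
    want <- oracle_metrics(m)
    expect_equal(got$classification_rate, want$classification_rate,
                 tolerance = 1e-9)
    expect_equal(got$sensitivity, want$sensitivity, tolerance = 1e-9)
    expect_equal(got$specificity, want$specificity, tolerance = 1e-9)
    expect_equal(unname(got$ppv_per_class), want$ppv_per_class,
                 tolerance = 1e-9)
    expect_equal(got$avg_ppv, want$avg_ppv, tolerance = 1e-9)
    p <- sample(k)
    got_p <- suppressWarnings(compute_metrics(m[p, p]))
    expect_equal(got_p$classification_rate, got$classification_rate)
  }

  expect_error(compute_metrics(matrix(0, 2, 2,
    dimnames = list(c("a", "b"), c("a", "b")))), "empty")
  # class "b" never actual and never predicted
  expect_warning(compute_metrics(matrix(c(3, 0, 0, 0), 2, 2, byrow = TRUE,
    dimnames = list(c("a", "b"), c("a", "b")))), "never predicted")
})

test_that("run_task is deterministic and rejects single-class data", {
  set <- cohort_features(8, 10, gait_config(seed = 19), seed = 19,
                         demographics = gait_demographics(p_male = 0.5))
  rf <- rf_config(n_trees = 60, seed = 5)
  fit1 <- run_task(set$features, set$cohort, builtin_tasks()$gender,
                   rf = rf, plan = validation_plan("subject_wise", seed = 5))
  fit2 <- run_task(set$features, set$cohort, builtin_tasks()$gender,
                   rf = rf, plan = validation_plan("subject_wise", seed = 5))
  expect_identical(fit1$confusion, fit2$confusion)
  expect_identical(fit1$predictions, fit2$predictions)
  expect_equal(sum(fit1$confusion), nrow(fit1$predictions))
  expect_gte(fit1$classification_rate, 0)
  expect_lte(fit1$classification_rate, 1)

  # single class after filtering -> rejection
  one_class <- set$cohort
  one_class$sex <- "male"
  expect_error(run_task(set$features, one_class, builtin_tasks()$gender,
                        rf = rf), "single class")

  # mtry must fit the selected feature set
  expect_error(run_task(set$features, set$cohort, builtin_tasks()$gender,
                        rf = rf_config(max_features_split = 60)),
               "max_features_split")
})

test_that("shuffled training labels drive subject-wise accuracy to chance", {
  set <- cohort_features(10, 12, gait_config(seed = 29), seed = 29,
                         demographics = gait_demographics(p_male = 0.5))
  shuffled <- set$cohort
  set.seed(77)
  shuffled$sex <- sample(shuffled$sex)   # break the label-feature link
  fit <- run_task(set$features, shuffled, builtin_tasks()$gender,
                  rf = rf_config(n_trees = 100, seed = 7),
                  plan = validation_plan("subject_wise", seed = 7))
  # subject-level accuracy within the 99% binomial band around chance
  per_subj <- tapply(fit$predictions$predicted == fit$predictions$actual,
                     fit$predictions$subject_id, mean)
  acc <- mean(per_subj > 0.5)
  n <- length(per_subj)
  half <- stats::qnorm(0.995) * sqrt(0.5 * 0.5 / n)
  expect_lte(abs(acc - 0.5), half + 1e-9)
})

test_that("permutation importance: normalisation, dominance, degenerate case", {
  set.seed(41)
  n <- 150
  y <- factor(rep(c("u", "v"), length.out = n))
  x <- data.frame(perfect = as.numeric(y), n1 = rnorm(n), n2 = rnorm(n),
                  n3 = rnorm(n))
  rf <- rf_config(n_trees = 100, max_features_split = 2, seed = 3)
  model <- softgait:::fit_forest(x[1:100, ], y[1:100], rf, 3)
  imp <- permutation_importance(model, x[101:150, ], y[101:150], seed = 9)
  expect_equal(sum(imp), 100, tolerance = 1e-6)
  expect_true(all(imp >= 0))
  expect_equal(names(which.max(imp)), "perfect")
  expect_gt(imp[["perfect"]], max(imp[c("n1", "n2", "n3")]))

  # no informative feature at all -> uniform percentages with a warning
  x0 <- data.frame(a = rep(1, n), b = rep(2, n))
  m0 <- softgait:::fit_forest(x0[1:100, ], y[1:100],
                              rf_config(n_trees = 50,
                                        max_features_split = 1, seed = 2), 2)
  expect_warning(u <- permutation_importance(m0, x0[101:150, ], y[101:150],
                                             seed = 4), "uniform")
  expect_equal(unname(u), c(50, 50))
})

test_that("rf_regression pools out-of-fold predictions into an RMS error", {
  set <- cohort_features(8, 10, gait_config(seed = 37), seed = 37)
  reg <- rf_regression(set$features, set$cohort, "height",
                       rf = rf_config(n_trees = 80, seed = 1))
  expect_equal(reg$rms_error,
               sqrt(mean((reg$predictions$predicted -
                            reg$predictions$actual)^2)))
  expect_false(any(is.na(reg$predictions$predicted)))
  const <- set$cohort; const$height <- 170
  expect_error(rf_regression(set$features, const, "height"), "constant")
})

test_that("step consistency is the step-weighted modal-agreement fraction", {
  same <- data.frame(subject_id = "S1", sequence_id = rep(c("a", "b"), 3),
                     predicted = "CGF")
  expect_equal(step_consistency(same), 1)

  one <- data.frame(subject_id = "S1", sequence_id = "a",
                    predicted = c("A", "A", "B", "A"))
  expect_equal(step_consistency(one), 0.75)

  two <- data.frame(
    subject_id = "S1",
    sequence_id = rep(c("a", "b"), c(2, 6)),
    predicted = c("A", "B", rep("C", 6)))   # modal fractions 0.5 and 1.0
  expect_equal(step_consistency(two), (1 + 6) / 8)

  # tie broken toward the lexicographically first label
  tie <- data.frame(subject_id = "S1", sequence_id = "a",
                    predicted = c("B", "A", "B", "A"))
  expect_equal(step_consistency(tie), 0.5)
})
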