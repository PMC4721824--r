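# Random-forest classification and regression of soft-biometric attributes
# under stratified k-fold and subject-wise (leave-one-subject-out)
# cross-validation, with pooled confusion-matrix metrics, permutation feature
# importance, and within-sequence step-consistency.

#' Random-forest hyperparameters
#'
#' @param n_trees number of trees (default 400).
#' @param max_features_split number of candidate features at each split
#'   (default 7; must not exceed the number of features in the selected set).
#' @param seed integer seed for forest growing.
#' @return An object of class `rf_config`.
#' @export
rf_config <- function(n_trees = 400L, max_features_split = 7L, seed = 1L) {
  if (n_trees < 1L) stop("n_trees must be >= 1")
  if (max_features_split < 1L) stop("max_features_split must be >= 1")
  structure(list(n_trees = as.integer(n_trees),
                 max_features_split = as.integer(max_features_split),
                 seed = as.integer(seed)),
            class = "rf_config")
}

#' Cross-validation plan
#'
#' `stratified_kfold` partitions steps into `k` folds preserving class
#' proportions; `subject_wise` leaves all steps of one subject out per fold
#' (one fold per subject, unequal sizes), so no subject contributes to both
#' training and validation of any fold.
#'
#' @param scheme `"stratified_kfold"` or `"subject_wise"`.
#' @param k number of folds (k-fold only, default 10).
#' @param seed integer seed for the fold assignment.
#' @return An object of class `validation_plan`.
#' @export
validation_plan <- function(scheme = c("stratified_kfold", "subject_wise"),
                            k = 10L, seed = 1L) {
  scheme <- match.arg(scheme)
  if (scheme == "stratified_kfold" && k < 2L) stop("k must be >= 2")
  structure(list(scheme = scheme, k = as.integer(k), seed = as.integer(seed)),
            class = "validation_plan")
}

#' Stratified k-fold assignment
#'
#' Shuffles each class's samples and deals them round-robin into `k` folds,
#' so each fold's class counts differ from an exact proportional share by at
#' most one sample. The folds partition the samples.
#'
#' @param labels vector of class labels, one per sample.
#' @param k number of folds.
#' @param seed integer seed.
#' @return List of `k` integer vectors of validation-sample indices.
#' @export
stratified_kfold_split <- function(labels, k, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  tab <- table(labels)
  small <- names(tab)[tab < k]
  if (length(small) > 0L)
    stop("class(es) with fewer than k samples: ",
         paste(small, collapse = ", "))
  folds <- vector("list", k)
  with_seed(combine_seeds(seed, 23L), {
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))
      f <- rep(seq_len(k), length.out = length(idx))
      for (j in seq_len(k)) folds[[j]] <- c(folds[[j]], idx[f == j])
    }
  })
  lapply(folds, sort)
}

#' Subject-wise (leave-one-subject-out) fold assignment
#'
#' @param subject_ids vector of subject identifiers, one per sample.
#' @return Named list with one integer vector of validation indices per
#'   subject; all samples of that subject and no others.
#' @export
subjectwise_split <- function(subject_ids) {
  ids <- unique(subject_ids)
  if (length(ids) < 2L) stop("subject-wise validation needs >= 2 subjects")
  stats::setNames(lapply(ids, function(s) which(subject_ids == s)), ids)
}

make_folds <- function(labels, subject_ids, plan) {
  switch(plan$scheme,
         stratified_kfold = stratified_kfold_split(labels, plan$k, plan$seed),
         subject_wise = subjectwise_split(subject_ids))
}

fit_forest <- function(x, y, rf, fold_seed, regression = FALSE) {
  dat <- data.frame(x, check.names = FALSE)
  dat$.outcome <- y
  ranger::ranger(
    dependent.variable.name = ".outcome", data = dat,
    num.trees = rf$n_trees,
    mtry = rf$max_features_split,
    probability = FALSE,
    classification = !regression,
    seed = fold_seed, num.threads = 1)
}

# seed is passed through to predict so majority-vote ties (possible with an
# even tree count) break deterministically.
predict_forest <- function(model, x, seed = 1L) {
  stats::predict(model, data = data.frame(x, check.names = FALSE),
                 num.threads = 1, seed = seed)$predictions
}

#' Classification metrics from a confusion matrix
#'
#' The classification rate is `(TP + TN) / (TP + TN + FP + FN)` in the binary
#' case, generalised multi-class as `trace / total`. Sensitivity and
#' specificity are unweighted macro-averages of the per-class one-vs-rest
#' recall and true-negative rate; PPV is `TP / (TP + FP)` per class (0, with
#' a warning, for a class never predicted) and `avg_ppv` their unweighted
#' mean.
#'
#' @param confusion square integer matrix, rows = actual, columns = predicted,
#'   identical dimnames.
#' @return List: `classification_rate`, `sensitivity`, `specificity`,
#'   `ppv_per_class` (named), `avg_ppv`.
#' @export
compute_metrics <- function(confusion) {
  m <- as.matrix(confusion)
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    stop("confusion must be square with identical row/column names")
  total <- sum(m)
  if (total < 1) stop("empty confusion matrix")
  classes <- rownames(m)
  sens <- spec <- ppv <- stats::setNames(numeric(length(classes)), classes)
  for (i in seq_along(classes)) {
    tp <- m[i, i]
    fn <- sum(m[i, ]) - tp
    fp <- sum(m[, i]) - tp
    tn <- total - tp - fn - fp
    sens[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    spec[i] <- if (tn + fp > 0) tn / (tn + fp) else 0
    if (tp + fp > 0) {
      ppv[i] <- tp / (tp + fp)
    } else {
      ppv[i] <- 0
      if (tp + fn == 0)
        warning("class '", classes[i],
                "' never predicted and never actual: PPV set to 0")
    }
  }
  list(classification_rate = sum(diag(m)) / total,
       sensitivity = mean(sens),
       specificity = mean(spec),
       ppv_per_class = ppv,
       avg_ppv = mean(ppv))
}

#' Permutation feature importance on held-out data
#'
#' Importance of feature `j` is the mean decrease in classification rate over
#' `n_repeats` random permutations of column `j` of the held-out samples.
#' With `as_percentage = TRUE`, negative raw decreases are clipped to zero
#' and the values normalised to percentages summing to 100 (uniform, with a
#' warning, if every raw importance is zero).
#'
#' @param model a trained forest (from within [run_task()] or
#'   [ranger::ranger()]).
#' @param x held-out feature `data.frame`/matrix.
#' @param y held-out true labels.
#' @param seed integer seed for the permutations.
#' @param n_repeats permutations per feature (default 10).
#' @param as_percentage return percentages (default) or raw mean decreases.
#' @return Named numeric vector keyed by feature name.
#' @export
permutation_importance <- function(model, x, y, seed = 1L, n_repeats = 10L,
                                   as_percentage = TRUE) {
  x <- as.data.frame(x, check.names = FALSE)
  if (nrow(x) < 1L) stop("need at least 1 validation sample")
  baseline <- mean(predict_forest(model, x, seed = seed) == y)
  raw <- stats::setNames(numeric(ncol(x)), colnames(x))
  with_seed(combine_seeds(seed, 31L), {
    for (j in seq_len(ncol(x))) {
      acc <- numeric(n_repeats)
      for (r in seq_len(n_repeats)) {
        xp <- x
        xp[[j]] <- xp[[j]][sample(nrow(xp))]
        acc[r] <- mean(predict_forest(model, xp, seed = seed) == y)
      }
      raw[j] <- baseline - mean(acc)
    }
  })
  if (!as_percentage) return(raw)
  importance_percentages(raw)
}

importance_percentages <- function(raw) {
  clipped <- pmax(raw, 0)
  if (sum(clipped) == 0) {
    warning("all raw importances zero: returning uniform percentages")
    return(stats::setNames(rep(100 / length(raw), length(raw)), names(raw)))
  }
  100 * clipped / sum(clipped)
}

#' Train and cross-validate a random forest on one classification task
#'
#' Labels the feature table from the cohort metadata, drops excluded
#' subjects, restricts to the selected feature set, splits per the validation
#' plan, trains one forest per fold and pools the out-of-fold predictions
#' into a single confusion matrix (folds have unequal sizes under
#' subject-wise validation; pooling weights every step equally). Deterministic
#' given the seeds in `rf` and `plan`.
#'
#' @param features per-step feature table ([extract_feature_table()]).
#' @param cohort cohort metadata.
#' @param task a [task_spec()].
#' @param mode feature set: `"combined"`, `"accel_only"` or `"gyro_only"`.
#' @param rf an [rf_config()].
#' @param plan a [validation_plan()].
#' @param importance if `TRUE`, permutation importance is computed on each
#'   fold's held-out samples and aggregated into percentages.
#' @param importance_repeats permutations per feature and fold.
#' @return An object of class `gait_validation`: confusion matrix, Eq-style
#'   metrics, per-step out-of-fold predictions, and optionally an importance
#'   table.
#' @export
run_task <- function(features, cohort, task,
                     mode = c("combined", "accel_only", "gyro_only"),
                     rf = rf_config(), plan = validation_plan(),
                     importance = FALSE, importance_repeats = 10L) {
  mode <- match.arg(mode)
  stopifnot(inherits(task, "task_spec"), inherits(rf, "rf_config"),
            inherits(plan, "validation_plan"))
  labelled <- label_feature_table(features, cohort, task)
  classes <- task$class_names[task$class_names %in% unique(labelled$label)]
  if (length(classes) < 2L)
    stop("task '", task$name, "': labelled data contain a single class")
  feat_cols <- feature_names(mode)
  if (rf$max_features_split > length(feat_cols))
    stop("max_features_split exceeds the ", length(feat_cols),
         " features of mode '", mode, "'")
  x <- labelled[, feat_cols, drop = FALSE]
  y <- factor(labelled$label, levels = classes)
  folds <- make_folds(labelled$label, labelled$subject_id, plan)

  predicted <- factor(rep(NA_character_, nrow(x)), levels = classes)
  raw_imp <- stats::setNames(numeric(length(feat_cols)), feat_cols)
  for (f in seq_along(folds)) {
    val <- folds[[f]]
    fold_seed <- combine_seeds(rf$seed, plan$seed, f)
    model <- fit_forest(x[-val, , drop = FALSE], y[-val], rf, fold_seed)
    predicted[val] <- predict_forest(model, x[val, , drop = FALSE],
                                     seed = fold_seed)
    if (importance)
      raw_imp <- raw_imp + permutation_importance(
        model, x[val, , drop = FALSE], y[val],
        seed = combine_seeds(rf$seed, plan$seed, f, 17L),
        n_repeats = importance_repeats, as_percentage = FALSE)
  }

  confusion <- table(actual = y, predicted = predicted)
  confusion <- unclass(as.matrix(confusion))
  metrics <- compute_metrics(confusion)
  structure(list(
    task = task$name, mode = mode, scheme = plan$scheme,
    sensor_location = labelled$sensor_location[1],
    n_steps = nrow(labelled), n_subjects = length(unique(labelled$subject_id)),
    confusion = confusion,
    classification_rate = metrics$classification_rate,
    sensitivity = metrics$sensitivity,
    specificity = metrics$specificity,
    ppv_per_class = metrics$ppv_per_class,
    avg_ppv = metrics$avg_ppv,
    importance = if (importance) importance_percentages(raw_imp) else NULL,
    predictions = data.frame(
      subject_id = labelled$subject_id,
      sequence_id = labelled$sequence_id,
      actual = as.character(y),
      predicted = as.character(predicted),
      stringsAsFactors = FALSE),
    rf = rf, plan = plan
  ), class = "gait_validation")
}

#' @export
print.gait_validation <- function(x, ...) {
  cat(sprintf("<gait_validation> task=%s features=%s scheme=%s\n",
              x$task, x$mode, x$scheme))
  cat(sprintf("  %d steps, %d subjects\n", x$n_steps, x$n_subjects))
  cat(sprintf("  Class.Rate %.3f  Sens. %.3f  Spec. %.3f  Avg.PPV %.3f\n",
              x$classification_rate, x$sensitivity, x$specificity, x$avg_ppv))
  invisible(x)
}

#' @export
summary.gait_validation <- function(object, ...) {
  print(object)
  cat("\nConfusion matrix (actual x predicted):\n")
  print(object$confusion)
  cat("\nPer-class PPV:\n")
  print(round(object$ppv_per_class, 3))
  if (!is.null(object$importance)) {
    cat("\nTop 10 features by permutation importance (%):\n")
    print(round(sort(object$importance, decreasing = TRUE)[1:10], 2))
  }
  invisible(object)
}

#' Cross-validated random-forest regression of a numeric attribute
#'
#' Trains per-fold regression forests on the selected features and pools the
#' out-of-fold predictions; the reported error is the root-mean-square
#' residual in the target's units (years for age, cm for height).
#'
#' @inheritParams run_task
#' @param target `"age"` or `"height"`.
#' @return An object of class `gait_regression` with `rms_error` and the
#'   per-step out-of-fold predictions.
#' @export
rf_regression <- function(features, cohort, target = c("age", "height"),
                          mode = c("combined", "accel_only", "gyro_only"),
                          rf = rf_config(), plan = validation_plan("subject_wise")) {
  target <- match.arg(target); mode <- match.arg(mode)
  vals <- stats::setNames(cohort[[target]], cohort$subject_id)
  y <- unname(vals[features$subject_id])
  if (length(unique(y)) < 2L) stop("constant regression target")
  if (plan$scheme == "subject_wise" &&
      length(unique(features$subject_id)) < 2L)
    stop("subject-wise regression needs >= 2 subjects")
  x <- features[, feature_names(mode), drop = FALSE]
  folds <- make_folds(rep("all", nrow(x)), features$subject_id,
                      if (plan$scheme == "stratified_kfold")
                        validation_plan("stratified_kfold",
                                        k = min(plan$k, nrow(x)),
                                        seed = plan$seed)
                      else plan)
  pred <- rep(NA_real_, nrow(x))
  for (f in seq_along(folds)) {
    val <- folds[[f]]
    model <- fit_forest(x[-val, , drop = FALSE], y[-val], rf,
                        combine_seeds(rf$seed, plan$seed, f),
                        regression = TRUE)
    pred[val] <- predict_forest(model, x[val, , drop = FALSE],
                               seed = combine_seeds(rf$seed, plan$seed, f))
  }
  structure(list(target = target, mode = mode, scheme = plan$scheme,
                 rms_error = sqrt(mean((pred - y)^2)),
                 target_sd = stats::sd(y),
                 predictions = data.frame(
                   subject_id = features$subject_id,
                   actual = y, predicted = pred,
                   stringsAsFactors = FALSE)),
            class = "gait_regression")
}

#' @export
print.gait_regression <- function(x, ...) {
  cat(sprintf("<gait_regression> target=%s scheme=%s\n", x$target, x$scheme))
  cat(sprintf("  RMS error %.3f (target SD %.3f)\n", x$rms_error, x$target_sd))
  invisible(x)
}

#' Within-sequence step-label consistency
#'
#' For each walking sequence, the fraction of its steps whose predicted label
#' equals the sequence's modal predicted label (ties broken toward the
#' lexicographically first label); the returned value is the step-weighted
#' average over sequences, i.e. the overall fraction of steps agreeing with
#' their sequence's mode.
#'
#' @param predictions a `data.frame` with `subject_id`, `sequence_id` and
#'   `predicted` columns (e.g. `fit$predictions` from [run_task()]), or a
#'   `gait_validation` object.
#' @return A fraction in `[0, 1]`.
#' @export
step_consistency <- function(predictions) {
  if (inherits(predictions, "gait_validation"))
    predictions <- predictions$predictions
  stopifnot(all(c("subject_id", "sequence_id", "predicted") %in%
                  names(predictions)))
  key <- paste(predictions$subject_id, predictions$sequence_id, sep = "\r")
  groups <- split(as.character(predictions$predicted), key)
  matches <- vapply(groups, function(g) {
    tab <- table(g)                      # names sorted, which.max -> first tie
    max_label <- names(tab)[which.max(tab)]
    sum(g == max_label)
  }, numeric(1))
  sum(matches) / length(key)
}
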