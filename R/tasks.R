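# Classification task definitions: map subject metadata to class labels for
# the group tasks (gender, 3-class age, 3-class height) and the sex-subgroup
# age/height tasks.

#' Define a classification task
#'
#' A task names a target attribute, an optional population filter, and a
#' partition of the attribute's range into ordered classes. For numeric
#' targets the partition is given by ordered `edges` plus, per edge, whether
#' a subject exactly on the edge falls in the lower class
#' (`boundary_to_lower`); classes are therefore exhaustive and mutually
#' exclusive over the attribute's range.
#'
#' @param name task name.
#' @param target `"gender"`, `"age"` or `"height"`.
#' @param population_filter `"all"`, `"male_only"` or `"female_only"`.
#' @param edges increasing numeric thresholds (numeric targets only).
#' @param boundary_to_lower logical, one per edge: does equality with the
#'   edge map to the lower class?
#' @param class_names ordered class labels (`length(edges) + 1` for numeric
#'   targets; `c(female_label, male_label)` for gender).
#' @return An object of class `task_spec`.
#' @export
task_spec <- function(name, target = c("gender", "age", "height"),
                      population_filter = c("all", "male_only", "female_only"),
                      edges = numeric(0), boundary_to_lower = logical(0),
                      class_names) {
  target <- match.arg(target)
  population_filter <- match.arg(population_filter)
  if (target == "gender") {
    if (length(class_names) != 2L) stop("gender task needs 2 class names")
  } else {
    if (is.unsorted(edges, strictly = TRUE)) stop("edges must be increasing")
    if (length(boundary_to_lower) != length(edges))
      stop("boundary_to_lower must match edges")
    if (length(class_names) != length(edges) + 1L)
      stop("need length(edges) + 1 class names")
  }
  structure(list(name = name, target = target,
                 population_filter = population_filter,
                 edges = edges, boundary_to_lower = boundary_to_lower,
                 class_names = class_names),
            class = "task_spec")
}

#' The built-in group and subgroup classification tasks
#'
#' Seven tasks: gender (CGF/CGM); 3-class age (CA1: age < 40, CA2: 40 <= age
#' < 50, CA3: age >= 50); 3-class height (CH1: height <= 170 cm, CH2: 170 <
#' height < 180, CH3: height >= 180); and the sex-subgroup tasks male age
#' (<= 40 / > 40), female age (<= 50 / > 50), male height (<= 180 / > 180),
#' female height (<= 170 / > 170). Note the age-40 boundary maps to CA2
#' (the "40 <= age < 50" convention); an alternative source convention with
#' an open boundary at 40 exists, and users needing it can define their own
#' [task_spec()].
#'
#' @return Named list of 7 [task_spec()] objects.
#' @export
builtin_tasks <- function() {
  list(
    gender = task_spec("gender", "gender", "all",
                       class_names = c("CGF", "CGM")),
    age_group = task_spec("age_group", "age", "all",
                          edges = c(40, 50),
                          boundary_to_lower = c(FALSE, FALSE),
                          class_names = c("CA1", "CA2", "CA3")),
    height_group = task_spec("height_group", "height", "all",
                             edges = c(170, 180),
                             boundary_to_lower = c(TRUE, FALSE),
                             class_names = c("CH1", "CH2", "CH3")),
    age_male = task_spec("age_male", "age", "male_only",
                         edges = 40, boundary_to_lower = TRUE,
                         class_names = c("age<=40", "age>40")),
    age_female = task_spec("age_female", "age", "female_only",
                           edges = 50, boundary_to_lower = TRUE,
                           class_names = c("age<=50", "age>50")),
    height_male = task_spec("height_male", "height", "male_only",
                            edges = 180, boundary_to_lower = TRUE,
                            class_names = c("height<=180", "height>180")),
    height_female = task_spec("height_female", "height", "female_only",
                              edges = 170, boundary_to_lower = TRUE,
                              class_names = c("height<=170", "height>170")))
}

#' Assign a task's class label to subjects
#'
#' Pure function of the metadata: subjects failing the task's population
#' filter get `NA` (excluded); every other subject gets exactly one class.
#'
#' @param meta a cohort `data.frame` (or single row / list) with `sex` and
#'   the task's target attribute.
#' @param task a [task_spec()].
#' @return Character vector of class labels (`NA` = excluded).
#' @export
assign_label <- function(meta, task) {
  stopifnot(inherits(task, "task_spec"))
  meta <- as.data.frame(as.list(meta)[c("sex", "age", "height")],
                        stringsAsFactors = FALSE)
  keep <- switch(task$population_filter,
                 all = rep(TRUE, nrow(meta)),
                 male_only = meta$sex == "male",
                 female_only = meta$sex == "female")
  if (task$target == "gender") {
    lab <- ifelse(meta$sex == "female", task$class_names[1],
                  task$class_names[2])
  } else {
    x <- meta[[task$target]]
    idx <- rep(1L, length(x))
    for (e in seq_along(task$edges)) {
      above <- if (task$boundary_to_lower[e]) x > task$edges[e]
               else x >= task$edges[e]
      idx <- idx + as.integer(above)
    }
    lab <- task$class_names[idx]
  }
  lab[!keep] <- NA_character_
  lab
}

#' Attach task labels to a per-step feature table
#'
#' Joins subject labels onto the feature rows by `subject_id` and drops
#' excluded subjects' steps.
#'
#' @param features feature table with a `subject_id` column.
#' @param cohort cohort metadata (`subject_id`, `sex`, `age`, `height`).
#' @param task a [task_spec()].
#' @return The feature table with a `label` column, excluded rows removed.
#' @export
label_feature_table <- function(features, cohort, task) {
  lab <- assign_label(cohort, task)
  names(lab) <- cohort$subject_id
  features$label <- unname(lab[features$subject_id])
  features[!is.na(features$label), , drop = FALSE]
}
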