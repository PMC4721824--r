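# Plain-text file formats: recording CSV (one row per frame, 0-based
# frame_index, six channel columns, identity columns), per-step feature CSV
# with a fixed column order, boundary CSV, and JSON validation reports.

recording_csv_cols <- function()
  c("frame_index", imu_channels(),
    "subject_id", "sequence_id", "sensor_location", "sampling_rate_hz")

#' Write an IMU recording as CSV
#'
#' One row per frame: `frame_index` (0-based, contiguous), the six channel
#' columns, and constant identity columns (`subject_id`, `sequence_id`,
#' `sensor_location`, `sampling_rate_hz`). Full double precision is kept so a
#' write-then-read round trip is bit-identical.
#'
#' @param recording an [imu_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "imu_recording"))
  df <- data.frame(frame_index = seq_len(recording$n_frames) - 1L)
  for (ch in imu_channels())
    df[[ch]] <- sprintf("%.17g", recording$channels[[ch]])
  df$subject_id <- recording$subject_id
  df$sequence_id <- recording$sequence_id
  df$sensor_location <- recording$sensor_location
  df$sampling_rate_hz <- recording$sampling_rate
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an IMU recording from CSV
#'
#' Validates the recording CSV contract: all required columns present,
#' `frame_index` contiguous from 0, all channel values finite. Violations are
#' rejected with row/column diagnostics.
#'
#' @param path input file path.
#' @return An [imu_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(recording_csv_cols(), names(df))
  if (length(missing) > 0L)
    stop("recording CSV missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0L) stop("recording CSV has no frames")
  if (!identical(as.integer(df$frame_index), seq_len(nrow(df)) - 1L))
    stop("frame_index must be contiguous from 0; first violation at row ",
         which(as.integer(df$frame_index) != seq_len(nrow(df)) - 1L)[1])
  for (ch in imu_channels()) {
    bad <- which(!is.finite(df[[ch]]))
    if (length(bad) > 0L)
      stop("non-finite value in column ", ch, " at row ", bad[1])
  }
  imu_recording(
    channels = stats::setNames(lapply(imu_channels(), function(ch) df[[ch]]),
                               imu_channels()),
    sampling_rate = as.numeric(df$sampling_rate_hz[1]),
    subject_id = df$subject_id[1],
    sequence_id = df$sequence_id[1],
    sensor_location = df$sensor_location[1])
}

#' Write ground-truth step boundaries as a single-column CSV
#'
#' @param boundaries integer frame indices (1-based; written 0-based to match
#'   the recording CSV's `frame_index`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_boundaries <- function(boundaries, path) {
  utils::write.csv(data.frame(boundary_frame = as.integer(boundaries) - 1L),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a per-step feature table CSV
#'
#' The column order — identity columns followed by the 50 feature columns of
#' [feature_names()] — is part of the format contract and is validated on
#' read.
#'
#' @param features feature table ([extract_feature_table()]), optionally with
#'   a `label` column.
#' @param path file path.
#' @return `write_feature_table`: `path`, invisibly. `read_feature_table`:
#'   the feature `data.frame`.
#' @export
write_feature_table <- function(features, path) {
  id_cols <- c("subject_id", "sequence_id", "sensor_location", "step_index")
  cols <- c(id_cols, feature_names("combined"),
            intersect("label", names(features)))
  missing <- setdiff(cols, names(features))
  if (length(missing) > 0L)
    stop("feature table missing column(s): ", paste(missing, collapse = ", "))
  utils::write.csv(features[, cols, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sequence_id", "step_index",
            feature_names("combined"))
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop("feature CSV missing column(s): ", paste(missing, collapse = ", "))
  df
}

#' Serialize a validation report to JSON
#'
#' Writes the metrics, confusion counts and (when present) importance
#' percentages of a [run_task()] result, with the seeds and an optional
#' config hash for provenance.
#'
#' @param fit a `gait_validation` object.
#' @param path output path.
#' @param config_hash optional provenance string embedded in the report.
#' @return `path`, invisibly.
#' @export
write_report <- function(fit, path, config_hash = NA_character_) {
  stopifnot(inherits(fit, "gait_validation"))
  rep <- list(
    task = fit$task, feature_mode = fit$mode, scheme = fit$scheme,
    n_steps = fit$n_steps, n_subjects = fit$n_subjects,
    classification_rate = fit$classification_rate,
    sensitivity = fit$sensitivity, specificity = fit$specificity,
    ppv_per_class = as.list(fit$ppv_per_class), avg_ppv = fit$avg_ppv,
    step_consistency = step_consistency(fit),
    confusion = list(classes = rownames(fit$confusion),
                     counts = unname(apply(fit$confusion, 1, as.list))),
    importance = if (!is.null(fit$importance)) as.list(fit$importance),
    seeds = list(rf = fit$rf$seed, plan = fit$plan$seed),
    config_hash = config_hash)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Format a validation report as a text table
#'
#' One-line-per-report table with columns Class.Rate, Sens., Spec., per-class
#' PPV and Avg.PPV (percentages).
#'
#' @param fits a `gait_validation` object or list of them.
#' @return Character vector of table lines.
#' @export
format_report <- function(fits) {
  if (inherits(fits, "gait_validation")) fits <- list(fits)
  header <- sprintf("%-14s %-10s %-18s %10s %8s %8s %-24s %8s",
                    "Task", "Features", "Scheme", "Class.Rate", "Sens.",
                    "Spec.", "PPV per class", "Avg.PPV")
  rows <- vapply(fits, function(f) {
    sprintf("%-14s %-10s %-18s %10.2f %8.2f %8.2f %-24s %8.2f",
            f$task, f$mode, f$scheme,
            100 * f$classification_rate, 100 * f$sensitivity,
            100 * f$specificity,
            paste(sprintf("%.2f", 100 * f$ppv_per_class), collapse = " "),
            100 * f$avg_ppv)
  }, character(1))
  c(header, rows)
}
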