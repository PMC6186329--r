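#' @keywords internal
"_PACKAGE"

#' Feature columns used by the classifier
#'
#' The five gait-cadence series fed to the fuzzy model, in their fixed
#' input order: left/right stride interval, left/right stance interval and
#' double support interval (all in seconds).
#'
#' @format Character vector of length 5.
#' @export
MODEL_FEATURES <- c("left_stride", "right_stride",
                    "left_stance", "right_stance", "double_support")

#' Recognized cohort group labels
#' @format Character vector: ALS, PD, HD, CO (healthy control).
#' @export
GAIT_GROUPS <- c("ALS", "PD", "HD", "CO")

#' Construct a gait record
#'
#' A gait record holds one subject's stride-by-stride interval measurements:
#' an elapsed-time axis (seconds, strictly increasing) and a matrix of
#' per-stride interval features in seconds, plus the subject's group label
#' and optional severity covariate (disease duration for ALS, Hoehn & Yahr
#' for PD, total functional capacity for HD).
#'
#' @param subject_id Character scalar identifying the subject.
#' @param group One of `"ALS"`, `"PD"`, `"HD"`, `"CO"`, or `NA` if not yet
#'   known (e.g. a record read from disk before joining the manifest).
#' @param time Numeric vector of elapsed times (seconds), strictly increasing.
#' @param features Numeric matrix with one row per entry of `time` and named
#'   columns (a subset or superset of [MODEL_FEATURES]).
#' @param severity Optional numeric severity covariate.
#' @return An object of class `gait_record`.
#' @export
gait_record <- function(subject_id, group = NA_character_, time, features,
                        severity = NA_real_) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  if (!is.na(group)) group <- match.arg(group, GAIT_GROUPS)
  time <- as.numeric(time)
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (is.null(colnames(features)))
    stop("'features' must have named columns")
  if (length(time) != nrow(features))
    stop("'time' length (", length(time), ") does not match feature rows (",
         nrow(features), ")")
  if (length(time) > 1L && any(diff(time) <= 0))
    stop("'time' must be strictly increasing for subject ", subject_id)
  structure(
    list(subject_id = subject_id, group = group, time = time,
         features = features, severity = as.numeric(severity)[1L]),
    class = "gait_record")
}

#' @export
print.gait_record <- function(x, ...) {
  cat("<gait_record> subject:", x$subject_id,
      " group:", ifelse(is.na(x$group), "?", x$group),
      " strides:", nrow(x$features), "\n")
  cat("  features:", paste(colnames(x$features), collapse = ", "), "\n")
  if (!is.na(x$severity)) cat("  severity:", x$severity, "\n")
  invisible(x)
}

#' Number of strides in a record
#' @param record A [gait_record()].
#' @return Integer row count.
#' @export
n_strides <- function(record) nrow(record$features)

# Subset a record's rows, preserving metadata and attributes of interest.
record_rows <- function(record, idx) {
  gait_record(record$subject_id, record$group,
              record$time[idx], record$features[idx, , drop = FALSE],
              record$severity)
}
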