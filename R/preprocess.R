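#' Preprocessing configuration
#'
#' Bundles the signal-conditioning parameters applied to raw gait records
#' before classification.
#'
#' @param startup_cutoff_s Seconds of data discarded from the start of the
#'   walk to eliminate start-up transients (default 20; rows with
#'   `time >= cutoff` are kept).
#' @param outlier_k Multiple of the column standard deviation beyond the
#'   column median at which a stride is rejected as an artifact (default 3).
#' @param turn_rule How walking turns are detected: `"robust"` flags a
#'   stride whose left or right stride interval exceeds the column median
#'   plus `turn_k` standard deviations; `"absolute"` flags strides longer
#'   than `turn_threshold_s` seconds.
#' @param turn_k SD multiple for the robust turn rule (default 3).
#' @param turn_threshold_s Absolute stride-time threshold in seconds for
#'   the absolute turn rule (default 2).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(startup_cutoff_s = 20, outlier_k = 3,
                              turn_rule = c("robust", "absolute"),
                              turn_k = 3, turn_threshold_s = 2.0) {
  turn_rule <- match.arg(turn_rule)
  stopifnot(startup_cutoff_s >= 0, outlier_k > 0, turn_k > 0,
            turn_threshold_s > 0)
  structure(list(startup_cutoff_s = startup_cutoff_s, outlier_k = outlier_k,
                 turn_rule = turn_rule, turn_k = turn_k,
                 turn_threshold_s = turn_threshold_s),
            class = "preprocess_config")
}

#' Remove start-up strides
#'
#' Drops every stride recorded before `cutoff` seconds of walking; the
#' first strides of a trial reflect gait initiation rather than steady
#' walking. Rows with `time >= cutoff` are retained, order preserved.
#'
#' @param record A [gait_record()].
#' @param cutoff Cutoff in seconds (default 20).
#' @return The trimmed [gait_record()] (possibly with zero rows).
#' @export
remove_startup <- function(record, cutoff = 20) {
  record_rows(record, which(record$time >= cutoff))
}

#' Median-referenced outlier filter
#'
#' For each feature column, strides deviating from the column median by
#' more than `k` column standard deviations are treated as measurement
#' artifacts; a stride is removed if any column flags it. Medians and SDs
#' are computed once on the input segment. A column with zero SD flags any
#' value different from its median (no finite deviation exceeds 0 only if
#' the deviation is 0), so constant columns pass through unchanged.
#'
#' @param record A [gait_record()].
#' @param k SD multiple (default 3); `Inf` makes the filter the identity.
#' @param columns Columns to screen; defaults to the model features present
#'   in the record (all columns if none of them are).
#' @return The filtered [gait_record()]. Records with fewer than 3 rows are
#'   returned unchanged with a warning.
#' @export
median_outlier_filter <- function(record, k = 3,
                                  columns = intersect(colnames(record$features),
                                                      MODEL_FEATURES)) {
  if (n_strides(record) < 3L) {
    warning("fewer than 3 strides for subject ", record$subject_id,
            "; outlier filter skipped")
    return(record)
  }
  if (length(columns) == 0L) columns <- colnames(record$features)
  keep <- rep(TRUE, n_strides(record))
  for (cn in columns) {
    v <- record$features[, cn]
    dev <- abs(v - stats::median(v))
    lim <- if (is.infinite(k)) Inf else k * stats::sd(v)
    keep <- keep & (dev <= lim | dev == 0)
  }
  record_rows(record, which(keep))
}

# Indices of strides flagged as walking turns under the configured rule.
turn_flags <- function(record, rule = "robust", k = 3, threshold = 2.0) {
  cols <- intersect(c("left_stride", "right_stride"),
                    colnames(record$features))
  if (length(cols) == 0L) stop("record has no stride columns")
  flag <- rep(FALSE, n_strides(record))
  for (cn in cols) {
    v <- record$features[, cn]
    flag <- flag | switch(rule,
      robust   = v > stats::median(v) + k * stats::sd(v),
      absolute = v > threshold,
      stop("unknown turn rule: ", rule))
  }
  which(flag)
}

#' Extract the longest turn-free segment
#'
#' Subjects walked back and forth along a hallway, so the interval series
#' contains large stride-time spikes at each turn. Strides flagged as turns
#' split the series; only the longest contiguous run between two adjacent
#' flagged strides is kept (ties broken in favor of the earliest run).
#'
#' @param record A [gait_record()].
#' @param rule `"robust"` (stride exceeds column median + `k` SD) or
#'   `"absolute"` (stride exceeds `threshold` seconds).
#' @param k SD multiple for the robust rule.
#' @param threshold Absolute threshold in seconds.
#' @return The [gait_record()] restricted to the longest turn-free run,
#'   with attribute `"segment"` giving its first and last row index in the
#'   input record.
#' @export
longest_turn_free_segment <- function(record, rule = c("robust", "absolute"),
                                      k = 3, threshold = 2.0) {
  rule <- match.arg(rule)
  n <- n_strides(record)
  turns <- turn_flags(record, rule, k, threshold)
  is_turn <- rep(FALSE, n)
  is_turn[turns] <- TRUE
  r <- rle(!is_turn)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values)
  if (length(ok) == 0L || max(r$lengths[ok]) < 2L)
    stop("no turn-free segment of length >= 2 for subject ",
         record$subject_id)
  best <- ok[which.max(r$lengths[ok])]   # which.max returns earliest tie
  idx <- starts[best]:ends[best]
  out <- record_rows(record, idx)
  attr(out, "segment") <- c(starts[best], ends[best])
  out
}

#' Convert a preprocessed record to model observations
#'
#' Every stride of the retained segment is treated as an independent
#' observation: a 5-vector of left/right stride, left/right stance and
#' double support intervals, in that fixed order.
#'
#' @param record A fully preprocessed [gait_record()].
#' @return An object of class `observation_set` with elements `subject_id`,
#'   `group`, `X` (numeric matrix, one row per stride, columns
#'   [MODEL_FEATURES]) and `severity`.
#' @export
to_observations <- function(record) {
  missing_cols <- setdiff(MODEL_FEATURES, colnames(record$features))
  if (length(missing_cols))
    stop("record for subject ", record$subject_id,
         " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  observation_set(record$subject_id, record$group,
                  record$features[, MODEL_FEATURES, drop = FALSE],
                  record$severity)
}

#' Construct an observation set
#'
#' @param subject_id Subject identifier.
#' @param group Group label (any string; `gait_record` groups or derived
#'   labels such as severity strata).
#' @param X Numeric matrix with columns [MODEL_FEATURES].
#' @param severity Optional severity covariate.
#' @return An object of class `observation_set`.
#' @export
observation_set <- function(subject_id, group, X, severity = NA_real_) {
  X <- as.matrix(X)
  stopifnot(identical(colnames(X), MODEL_FEATURES))
  if (!all(is.finite(X)) || any(X <= 0))
    stop("observations for subject ", subject_id,
         " contain non-finite or non-positive values")
  structure(list(subject_id = subject_id, group = group, X = X,
                 severity = severity),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat("<observation_set> subject:", x$subject_id, " group:", x$group,
      " observations:", nrow(x$X), "\n")
  invisible(x)
}

#' Run the full preprocessing chain on a record
#'
#' Applies, in order: start-up removal, longest turn-free segment
#' extraction, and the median-referenced outlier filter within the
#' retained segment. Turns are detected before outlier filtering because
#' the turn spikes themselves exceed the outlier threshold: filtering
#' first would delete the very strides that mark the turns and splice
#' separate hallway traversals into one apparent segment.
#'
#' @param record A raw [gait_record()].
#' @param config A [preprocess_config()].
#' @return The preprocessed [gait_record()].
#' @export
preprocess_record <- function(record, config = preprocess_config()) {
  record <- remove_startup(record, config$startup_cutoff_s)
  record <- longest_turn_free_segment(record, config$turn_rule,
                                      k = config$turn_k,
                                      threshold = config$turn_threshold_s)
  median_outlier_filter(record, config$outlier_k)
}
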