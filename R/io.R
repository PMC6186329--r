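#' Default column layout of gaitndd-style record files
#'
#' PhysioNet-style gait files carry 13 whitespace-delimited numeric columns:
#' elapsed time, left/right stride interval, left/right swing interval
#' (seconds), left/right swing (% of stride), left/right stance interval
#' (seconds), left/right stance (%), double support interval (seconds) and
#' double support (%). The map names the column index holding each quantity
#' the package uses; percentage columns are redundant and not mapped.
#'
#' @return Named integer vector of 1-based column indices.
#' @export
gaitndd_columns <- function() {
  c(time = 1L, left_stride = 2L, right_stride = 3L,
    left_swing = 4L, right_swing = 5L,
    left_stance = 8L, right_stance = 9L, double_support = 12L)
}

#' Read a gaitndd-style gait record file
#'
#' Parses a plain-text, whitespace- or tab-delimited numeric table. Lines
#' starting with `#` are treated as comments. Rows whose mapped fields are
#' missing or non-numeric are dropped with a warning giving the count; row
#' order is never changed.
#'
#' @param path Path to the record file.
#' @param column_map Named integer vector mapping quantity names (must
#'   include `time`) to 1-based column indices; defaults to the gaitndd
#'   layout of [gaitndd_columns()].
#' @param subject_id Subject identifier; defaults to the file name without
#'   extension.
#' @param group,severity Optional group label and severity covariate
#'   (normally joined later from the cohort manifest).
#' @return A [gait_record()].
#' @export
read_gait_record <- function(path, column_map = gaitndd_columns(),
                             subject_id = sub("\\.[^.]*$", "", basename(path)),
                             group = NA_character_, severity = NA_real_) {
  if (!file.exists(path)) stop("gait record file not found: ", path)
  if (!("time" %in% names(column_map)))
    stop("column_map must include a 'time' entry")
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("cannot parse empty gait record file: ", path)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]

  need <- max(column_map)
  toks <- strsplit(trimws(lines), "[ \t]+")
  vals <- matrix(NA_real_, nrow = length(toks), ncol = length(column_map),
                 dimnames = list(NULL, names(column_map)))
  if (length(toks)) {
    width <- max(lengths(toks))
    if (width < need)
      stop("column_map references column ", need, " but '", basename(path),
           "' has only ", width, " columns")
    for (i in seq_along(toks)) {
      tk <- toks[[i]]
      if (length(tk) >= need)
        vals[i, ] <- suppressWarnings(as.numeric(tk[column_map]))
    }
  }
  bad <- apply(vals, 1L, function(r) any(!is.finite(r)))
  if (any(bad))
    warning("dropped ", sum(bad), " malformed row(s) while reading ",
            basename(path))
  vals <- vals[!bad, , drop = FALSE]
  gait_record(subject_id, group,
              time = vals[, "time"],
              features = vals[, setdiff(colnames(vals), "time"), drop = FALSE],
              severity = severity)
}

#' Write a gait record in the gaitndd 13-column layout
#'
#' Emits the canonical 13-column layout (see [gaitndd_columns()]) so the
#' file re-parses with the default column map. Swing intervals are taken
#' from the record when present, otherwise derived as stride minus stance;
#' percentage columns are expressed relative to the same foot's stride
#' (double support relative to the left stride). Values are printed with 6
#' decimal places, so a write/read round trip is exact to that precision
#' and a write/read/write cycle is byte-identical.
#'
#' @param record A [gait_record()] containing at least the five
#'   [MODEL_FEATURES] columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gait_record <- function(record, path) {
  f <- record$features
  missing_cols <- setdiff(MODEL_FEATURES, colnames(f))
  if (length(missing_cols))
    stop("record is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  # round the seconds quantities to the printed precision first, so the
  # derived percentage columns are stable under write/read/write cycles
  col <- function(nm) round(f[, nm], 6L)
  lsw <- if ("left_swing" %in% colnames(f)) col("left_swing")
         else col("left_stride") - col("left_stance")
  rsw <- if ("right_swing" %in% colnames(f)) col("right_swing")
         else col("right_stride") - col("right_stance")
  pct <- function(v, stride) ifelse(stride > 0, 100 * v / stride, 0)
  tab <- cbind(round(record$time, 6L),
               col("left_stride"), col("right_stride"),
               lsw, rsw,
               pct(lsw, col("left_stride")), pct(rsw, col("right_stride")),
               col("left_stance"), col("right_stance"),
               pct(col("left_stance"), col("left_stride")),
               pct(col("right_stance"), col("right_stride")),
               col("double_support"), pct(col("double_support"),
                                          col("left_stride")))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# gaitndd-style record  subject=", record$subject_id,
                    "  columns=time,l_stride,r_stride,l_swing,r_swing,",
                    "l_swing_pct,r_swing_pct,l_stance,r_stance,",
                    "l_stance_pct,r_stance_pct,double_support,ds_pct"), con)
  if (nrow(tab))
    writeLines(apply(tab, 1L, function(r)
      paste(sprintf("%.6f", r), collapse = "\t")), con)
  invisible(path)
}

#' Read a cohort manifest
#'
#' The manifest is a tab-delimited table with a header and columns
#' `file`, `subject`, `group`, `severity` mapping each record file to its
#' group label and severity covariate.
#'
#' @param path Manifest file path.
#' @return A data.frame with validated columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "#")
  required <- c("file", "subject", "group", "severity")
  if (!all(required %in% names(m)))
    stop("manifest must have columns: ", paste(required, collapse = ", "))
  if (anyDuplicated(m$subject))
    stop("manifest subject ids are not unique")
  if (!all(m$group %in% GAIT_GROUPS))
    stop("manifest contains unknown group label(s): ",
         paste(setdiff(m$group, GAIT_GROUPS), collapse = ", "))
  m$severity <- as.numeric(m$severity)
  m
}

#' Write a cohort manifest
#' @param manifest Data.frame with columns `file`, `subject`, `group`,
#'   `severity`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest[, c("file", "subject", "group", "severity")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort of gait records listed in a manifest
#'
#' @param manifest Data.frame as returned by [read_manifest()].
#' @param dir Directory containing the record files named in the manifest.
#' @param column_map Column layout, see [read_gait_record()].
#' @return Named list of [gait_record()] objects (names = subject ids).
#' @export
read_cohort <- function(manifest, dir, column_map = gaitndd_columns()) {
  recs <- lapply(seq_len(nrow(manifest)), function(i)
    read_gait_record(file.path(dir, manifest$file[i]), column_map,
                     subject_id = manifest$subject[i],
                     group = manifest$group[i],
                     severity = manifest$severity[i]))
  names(recs) <- manifest$subject
  recs
}
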