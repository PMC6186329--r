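#' Construct a confusion matrix
#'
#' @param tp,fn,tn,fp Non-negative integer counts of true positives, false
#'   negatives, true negatives and false positives.
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fn, tn, fp) {
  counts <- c(TP = tp, FN = fn, TN = tn, FP = fp)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion-matrix counts must be non-negative integers")
  structure(lapply(counts, as.integer), class = "confusion_matrix")
}

#' Tally a confusion matrix from labels
#'
#' @param truth,predicted Character vectors of `"positive"` /
#'   `"negative"` labels of equal length.
#' @return A [confusion_matrix()].
#' @export
confusion_from_labels <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted),
            all(truth %in% c("positive", "negative")),
            all(predicted %in% c("positive", "negative")))
  confusion_matrix(tp = sum(truth == "positive" & predicted == "positive"),
                   fn = sum(truth == "positive" & predicted == "negative"),
                   tn = sum(truth == "negative" & predicted == "negative"),
                   fp = sum(truth == "negative" & predicted == "positive"))
}

# Round half away from zero, as the reported percentages are conventionally
# formatted (base round() rounds half to even).
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Sensitivity, specificity and accuracy
#'
#' `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`,
#' `Ca = (TP+TN)/(TP+TN+FP+FN)`, reported as percentages rounded half-up
#' to 2 decimals. A statistic whose denominator is zero is undefined and
#' reported as `NA`, never as 0.
#'
#' @param cm A [confusion_matrix()].
#' @return Named numeric vector `c(sensitivity, specificity, accuracy)`
#'   in percent, with the unrounded values in attribute `"raw"`.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  raw <- c(sensitivity = ratio(cm$TP, cm$TP + cm$FN),
           specificity = ratio(cm$TN, cm$TN + cm$FP),
           accuracy = ratio(cm$TP + cm$TN, cm$TP + cm$TN + cm$FP + cm$FN))
  out <- round_half_up(raw, 2L)
  attr(out, "raw") <- raw
  out
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> TP:", x$TP, " FN:", x$FN,
      " TN:", x$TN, " FP:", x$FP, "\n")
  m <- compute_metrics(x)
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", v)
  cat("  sensitivity:", fmt(m["sensitivity"]),
      " specificity:", fmt(m["specificity"]),
      " accuracy:", fmt(m["accuracy"]), "\n")
  invisible(x)
}
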