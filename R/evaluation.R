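# Confusion-matrix summary and the three classification metrics.

#' Tally a 2x2 confusion matrix
#'
#' @param truth,predicted Label vectors over `{+1, -1}`, equal length >= 1.
#' @param positive Which label is the positive class (`+1` by default).
#' @return An object of class `confusion_counts` with fields `tp`, `fp`,
#'   `fn`, `tn` and the positive label.
#' @export
confusion <- function(truth, predicted, positive = 1L) {
  if (length(truth) != length(predicted))
    ewr_stop("`truth` and `predicted` must have equal length")
  if (length(truth) < 1L) ewr_stop("need at least one sample")
  if (!all(truth %in% c(-1L, 1L)) || !all(predicted %in% c(-1L, 1L)))
    ewr_stop("labels must take values +1 and -1")
  if (!positive %in% c(-1L, 1L)) ewr_stop("`positive` must be +1 or -1")
  pos <- truth == positive
  hit <- truth == predicted
  structure(
    list(tp = sum(pos & hit), fp = sum(!pos & !hit),
         fn = sum(pos & !hit), tn = sum(!pos & hit),
         positive = as.integer(positive)),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion (positive = %+d): TP=%d FP=%d FN=%d TN=%d\n",
              x$positive, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Classification accuracy
#'
#' Fraction of correctly identified samples, `(TP+TN)/(TP+FP+FN+TN)`.
#'
#' @param counts A [confusion()] object.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$tp + counts$fp + counts$fn + counts$tn
  if (total == 0L) ewr_stop("accuracy undefined: no samples", class = "undefined_metric")
  (counts$tp + counts$tn) / total
}

#' Sensitivity (true positive rate)
#'
#' Proportion of actual positive samples correctly identified, `TP/(TP+FN)`.
#' When no positive samples were evaluated the ratio is undefined and an
#' error of class `ewrsvmc_undefined_metric` is raised (never silently 0).
#'
#' @param counts A [confusion()] object.
#' @return Sensitivity in `[0, 1]`.
#' @export
sensitivity <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$tp + counts$fn == 0L)
    ewr_stop("sensitivity undefined: no actual positive samples",
             class = "undefined_metric")
  counts$tp / (counts$tp + counts$fn)
}

#' Specificity (true negative rate)
#'
#' Proportion of actual negative samples correctly identified, `TN/(TN+FP)`.
#'
#' @param counts A [confusion()] object.
#' @return Specificity in `[0, 1]`.
#' @export
specificity <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$tn + counts$fp == 0L)
    ewr_stop("specificity undefined: no actual negative samples",
             class = "undefined_metric")
  counts$tn / (counts$tn + counts$fp)
}

metric_or_na <- function(f, counts) {
  tryCatch(f(counts), ewrsvmc_undefined_metric = function(e) NA_real_)
}

#' Full metric report for a set of predictions
#'
#' @inheritParams confusion
#' @param positive_name Human-readable name of the positive class, echoed in
#'   all outputs so reports are unambiguous about which class sensitivity
#'   refers to.
#' @return Object of class `metric_report` with accuracy, sensitivity,
#'   specificity (NA where undefined, flagged in `undefined`), the counts and
#'   the positive-class name.
#' @export
metric_report <- function(truth, predicted, positive = 1L,
                          positive_name = as.character(positive)) {
  counts <- confusion(truth, predicted, positive)
  metrics <- list(
    accuracy = metric_or_na(accuracy, counts),
    sensitivity = metric_or_na(sensitivity, counts),
    specificity = metric_or_na(specificity, counts)
  )
  structure(
    c(metrics,
      list(counts = counts, positive_name = positive_name,
           undefined = names(metrics)[vapply(metrics, is.na, logical(1))])),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "not applicable" else sprintf("%.2f%%", 100 * v)
  cat(sprintf("positive class: %s\n", x$positive_name))
  cat(sprintf("  accuracy:    %s\n", fmt(x$accuracy)))
  cat(sprintf("  sensitivity: %s\n", fmt(x$sensitivity)))
  cat(sprintf("  specificity: %s\n", fmt(x$specificity)))
  print(x$counts)
  invisible(x)
}
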