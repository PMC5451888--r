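# Confusion counting and the three performance measures.  Accuracy is on the
# percent scale, precision and recall on the unit scale, matching the mixed
# convention of the result tables.  Undefined measures (zero denominator)
# propagate as NA, never as 0, so they stay visible and drop out of argmax.

CLASSES <- c("negative", "positive")

#' Confusion counts for a binary detector
#'
#' Partitions paired true/predicted labels into the four confusion counts.
#' Labels must come from `{"positive", "negative"}`.
#'
#' @param truth,predicted character vectors of equal positive length.
#' @return A list of class `confusion_counts` with integer `TP`, `FN`, `FP`,
#'   `TN`.
#' @examples
#' confusion(c("positive", "positive", "negative", "negative"),
#'           c("positive", "negative", "negative", "positive"))
#' @export
confusion <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) == 0L)
    stop("empty label collections", call. = FALSE)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length", call. = FALSE)
  if (!all(truth %in% CLASSES) || !all(predicted %in% CLASSES))
    stop("labels must be 'positive' or 'negative'", call. = FALSE)
  structure(list(
    TP = sum(truth == "positive" & predicted == "positive"),
    FN = sum(truth == "positive" & predicted == "negative"),
    FP = sum(truth == "negative" & predicted == "positive"),
    TN = sum(truth == "negative" & predicted == "negative")
  ), class = "confusion_counts")
}

#' Performance measures from confusion counts
#'
#' `accuracy()` returns `100 * (TP + TN) / (TP + FN + TN + FP)` (percent
#' scale); `precision()` returns `TP / (TP + FP)` and `recall()`
#' `TP / (TP + FN)` (unit scale).  A zero denominator yields `NA`, an
#' explicit undefined-measure signal.
#'
#' @param counts a [confusion()] result, or a list with `TP`, `FN`, `FP`, `TN`.
#' @return A single numeric value, or `NA_real_` when undefined.
#' @export
accuracy <- function(counts) {
  n <- counts$TP + counts$FN + counts$FP + counts$TN
  if (n == 0) return(NA_real_)
  100 * (counts$TP + counts$TN) / n
}

#' @rdname accuracy
#' @export
precision <- function(counts) {
  d <- counts$TP + counts$FP
  if (d == 0) return(NA_real_)
  counts$TP / d
}

#' @rdname accuracy
#' @export
recall <- function(counts) {
  d <- counts$TP + counts$FN
  if (d == 0) return(NA_real_)
  counts$TP / d
}

measure_fun <- function(name) {
  switch(name,
    accuracy = accuracy, precision = precision, recall = recall,
    stop("unknown measure: ", name, call. = FALSE))
}

#' Ordered measure set with priorities
#'
#' A non-empty, duplicate-free vector of measure names in strictly decreasing
#' priority; the first entry is the primary measure used to break
#' disagreements during global selection.
#'
#' @param measures character vector from
#'   `{"accuracy", "precision", "recall"}`.
#' @return A character vector of class `measure_set`.
#' @export
measure_set <- function(measures = c("accuracy", "recall", "precision")) {
  measures <- as.character(measures)
  if (length(measures) == 0L)
    stop("measure set must be non-empty", call. = FALSE)
  if (anyDuplicated(measures))
    stop("measure set must not contain duplicates", call. = FALSE)
  ok <- measures %in% c("accuracy", "precision", "recall")
  if (!all(ok))
    stop("unknown measures: ", paste(measures[!ok], collapse = ", "),
         call. = FALSE)
  structure(measures, class = "measure_set")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("confusion counts: TP =", x$TP, " FN =", x$FN,
      " FP =", x$FP, " TN =", x$TN, "\n")
  acc <- accuracy(x)
  cat(sprintf("  accuracy %s  precision %s  recall %s\n",
              if (is.na(acc)) "NA" else sprintf("%.2f%%", acc),
              format(precision(x), digits = 4),
              format(recall(x), digits = 4)))
  invisible(x)
}
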