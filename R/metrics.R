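#' Confusion counts of binary predictions
#'
#' @param predicted Integer vector of predicted classes in `{0, 1}`.
#' @param actual Integer vector of true classes in `{0, 1}`.
#' @return A `confusion_counts` object: named integer vector with `TP`,
#'   `FP`, `FN`, `TN` (positive class = disease = 1).
#' @export
confusion_counts <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual),
            all(predicted %in% c(0L, 1L)), all(actual %in% c(0L, 1L)))
  structure(c(TP = sum(predicted == 1L & actual == 1L),
              FP = sum(predicted == 1L & actual == 0L),
              FN = sum(predicted == 0L & actual == 1L),
              TN = sum(predicted == 0L & actual == 0L)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy is the proportion of correctly classified records; precision
#' the proportion of true positives among predicted positives; recall the
#' proportion of true positives among actual positives; F1 the harmonic
#' mean of precision and recall. A ratio with a zero denominator is
#' reported as 0 and the metric's name is listed under `undefined`.
#'
#' @param counts A [confusion_counts()] object or named vector with `TP`,
#'   `FP`, `FN`, `TN`.
#' @return List with `accuracy`, `precision`, `recall`, `f1` and
#'   `undefined` (character vector of zero-denominator metrics).
#' @examples
#' compute_metrics(c(TP = 8, FP = 2, FN = 1, TN = 9))
#' @export
compute_metrics <- function(counts) {
  cc <- counts[c("TP", "FP", "FN", "TN")]
  stopifnot(!anyNA(cc), all(cc >= 0))
  total <- sum(cc)
  if (total == 0)
    stop("empty evaluation: all confusion counts are zero", call. = FALSE)
  undefined <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); 0 } else num / den
  }
  accuracy <- (cc[["TP"]] + cc[["TN"]]) / total
  precision <- safe(cc[["TP"]], cc[["TP"]] + cc[["FP"]], "precision")
  recall <- safe(cc[["TP"]], cc[["TP"]] + cc[["FN"]], "recall")
  f1 <- safe(2 * precision * recall, precision + recall, "f1")
  list(accuracy = accuracy, precision = precision, recall = recall,
       f1 = f1, undefined = undefined)
}
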