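#' Per-pixel confusion counts
#'
#' Tally of true/false positives and negatives between a predicted and a
#' ground-truth binary mask, with lung (1) as the positive class.
#'
#' @param pred,truth binary 0/1 matrices of identical shape.
#' @return list with integer \code{TP}, \code{TN}, \code{FP}, \code{FN}.
#' @examples
#' a <- matrix(c(1, 0, 1, 0), 2); b <- matrix(c(1, 1, 0, 0), 2)
#' confusionCounts(a, b)
#' @export
confusionCounts <- function(pred, truth) {
  assertBinaryMask(pred); assertBinaryMask(truth)
  if (!all(dim(pred) == dim(truth))) stop("mask shapes differ")
  tp <- sum(pred == 1 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

#' Segmentation scores from confusion counts
#'
#' Accuracy \code{(TP+TN)/total}, sensitivity \code{TP/(TP+FN)} and
#' specificity \code{TN/(TN+FP)}. A zero denominator (one class absent from
#' the ground truth) yields \code{NA}, which aggregate reports exclude.
#'
#' @param counts list from \code{\link{confusionCounts}}.
#' @return numeric in [0,1], or \code{NA} when undefined.
#' @export
accuracy <- function(counts) {
  tot <- counts$TP + counts$TN + counts$FP + counts$FN
  if (tot == 0) return(NA_real_)
  (counts$TP + counts$TN) / tot
}

#' @rdname accuracy
#' @export
sensitivity <- function(counts) {
  d <- counts$TP + counts$FN
  if (d == 0) return(NA_real_)
  counts$TP / d
}

#' @rdname accuracy
#' @export
specificity <- function(counts) {
  d <- counts$TN + counts$FP
  if (d == 0) return(NA_real_)
  counts$TN / d
}

#' Dice coefficient between two binary masks
#'
#' \code{DI(e, f) = 2 |e intersect f| / (|e| + |f|)}, equivalently
#' \code{2 TP / (2 TP + FP + FN)}. Two empty masks have Dice 1 by
#' convention (perfect agreement on "no lung").
#'
#' @inheritParams confusionCounts
#' @return numeric in [0,1].
#' @examples
#' diceCoef(matrix(c(1, 1, 1, 0), 2), matrix(c(1, 1, 0, 0), 2))  # 0.8
#' @export
diceCoef <- function(pred, truth) {
  assertBinaryMask(pred); assertBinaryMask(truth)
  if (!all(dim(pred) == dim(truth))) stop("mask shapes differ")
  denom <- sum(pred) + sum(truth)
  if (denom == 0) return(1)
  2 * sum(pred == 1 & truth == 1) / denom
}

#' Full per-image metrics report
#'
#' @inheritParams confusionCounts
#' @return named numeric vector with \code{AC}, \code{SE}, \code{SP},
#'   \code{DI}.
#' @export
metricsReport <- function(pred, truth) {
  cc <- confusionCounts(pred, truth)
  c(AC = accuracy(cc), SE = sensitivity(cc), SP = specificity(cc),
    DI = diceCoef(pred, truth))
}

#' Write per-image metrics to CSV and JSON
#'
#' @param report data.frame with columns id, AC, SE, SP, DI (e.g. from
#'   \code{\link{evaluateSplit}}).
#' @param path output path without extension; writes \code{path.csv} and
#'   \code{path.json} (the JSON also carries the aggregate means).
#' @return invisibly, the aggregate means.
#' @export
writeMetrics <- function(report, path) {
  utils::write.csv(report, paste0(path, ".csv"), row.names = FALSE)
  agg <- colMeans(report[, c("AC", "SE", "SP", "DI"), drop = FALSE],
                  na.rm = TRUE)
  jsonlite::write_json(list(per_image = report, aggregate = as.list(agg)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(agg)
}
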