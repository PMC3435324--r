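#' Pixelwise precision and recall of a segmentation
#'
#' Compares an automatic binary mask against a manual ground-truth mask:
#' `precision = 100 * TP / (TP + FP)` measures how many chosen pixels lie
#' outside the true lesion, `recall = 100 * TP / (TP + FN)` how many lesion
#' pixels the algorithm missed. If the automatic mask is empty while the
#' manual one is not, precision is undefined and reported as 0 with a flag;
#' if both are empty, both scores are 100 with a flag.
#'
#' @param auto logical matrix: the automatic segmentation.
#' @param manual logical matrix of the same dimensions: the ground truth.
#' @return an object of class `segmentation_score`: list with `TP`, `FP`,
#'   `FN`, `precision`, `recall` (0--100), and `flagged`.
#' @export
precision_recall <- function(auto, manual) {
  stopifnot(all(dim(auto) == dim(manual)))
  auto <- auto > 0; manual <- manual > 0
  TP <- sum(auto & manual)
  FP <- sum(auto & !manual)
  FN <- sum(!auto & manual)
  flagged <- FALSE
  if (TP + FP == 0L) {
    flagged <- TRUE
    if (FN == 0L) {
      precision <- 100; recall <- 100
    } else {
      precision <- 0
      recall <- 0
    }
  } else {
    precision <- 100 * TP / (TP + FP)
    recall <- if (TP + FN == 0L) {flagged <- TRUE; 100} else 100 * TP / (TP + FN)
  }
  structure(list(TP = TP, FP = FP, FN = FN,
                 precision = precision, recall = recall, flagged = flagged),
            class = "segmentation_score")
}

#' @export
print.segmentation_score <- function(x, ...) {
  cat(sprintf("precision %.1f, recall %.1f (TP %d, FP %d, FN %d)%s\n",
              x$precision, x$recall, x$TP, x$FP, x$FN,
              if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Summarize per-image segmentation scores
#'
#' Median, mean and interquartile range (75th minus 25th percentile,
#' linear-interpolation percentiles) of precision and recall over a set of
#' per-image scores, in the layout of a dataset summary table (dataset name,
#' N, medians). Flagged scores (degenerate masks) are counted separately.
#'
#' @param scores list of `segmentation_score` objects, or a data.frame with
#'   `precision` and `recall` columns.
#' @param dataset label for the score set.
#' @return an object of class `score_summary`: data.frame with one row per
#'   metric (metric, n, median, mean, iqr) plus attributes `dataset` and
#'   `n_flagged`.
#' @export
summarize_scores <- function(scores, dataset = "dataset") {
  if (is.data.frame(scores)) {
    df <- scores
    n_flagged <- if ("flagged" %in% names(df)) sum(df$flagged) else 0L
  } else {
    stopifnot(is.list(scores), length(scores) >= 1L)
    df <- data.frame(precision = vapply(scores, `[[`, numeric(1), "precision"),
                     recall = vapply(scores, `[[`, numeric(1), "recall"))
    n_flagged <- sum(vapply(scores, `[[`, logical(1), "flagged"))
  }
  if (nrow(df) == 0L) stop("no scores to summarize", call. = FALSE)
  one <- function(v, metric) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(metric = metric, n = length(v), median = q[2], mean = mean(v),
               iqr = q[3] - q[1])
  }
  out <- rbind(one(df$precision, "precision"), one(df$recall, "recall"))
  attr(out, "dataset") <- dataset
  attr(out, "n_flagged") <- n_flagged
  class(out) <- c("score_summary", class(out))
  out
}

#' @export
print.score_summary <- function(x, ...) {
  cat(sprintf("%s (N = %d images, %d flagged)\n",
              attr(x, "dataset"), x$n[1], attr(x, "n_flagged")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
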