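#' Tversky loss hyperparameters
#'
#' The Tversky loss \code{TL = 1 - (TP + e) / (TP + a*FN + b*FP + e)}
#' generalizes the Dice loss: \code{alpha} weights false negatives and
#' \code{beta} false positives, with \code{alpha + beta = 1}. Raising
#' \code{alpha} above 0.5 penalizes missed lodged pixels more than false
#' alarms, the usual choice when the positive class (lodged canopy) is rare.
#' At \code{alpha = beta = 0.5} the loss reduces to \code{1 - Dice}.
#'
#' @param alpha false-negative weight in \[0, 1\] (default 0.7).
#' @param beta false-positive weight; must equal \code{1 - alpha}.
#' @param epsilon small positive smoothing constant (default 1e-6).
#' @return an object of class \code{tversky_params}.
#' @export
tversky_params <- function(alpha = 0.7, beta = 1 - alpha, epsilon = 1e-6) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1)
    stop("tversky_params: alpha must be in [0, 1]")
  if (abs(alpha + beta - 1) > 1e-12)
    stop("tversky_params: alpha + beta must equal 1 (got ",
         alpha + beta, ")")
  if (epsilon <= 0) stop("tversky_params: epsilon must be > 0")
  structure(list(alpha = alpha, beta = beta, epsilon = epsilon),
            class = "tversky_params")
}

#' Tversky loss between a score map and a binary mask
#'
#' Uses differentiable soft counts: \code{TP} is the sum of predicted
#' probabilities over truly lodged pixels, \code{FN} the probability mass
#' those pixels miss, \code{FP} the probability mass assigned to standing
#' canopy.
#'
#' @param pred numeric array of predicted probabilities in \[0, 1\].
#' @param truth binary \{0, 1\} array of the same shape (1 = lodged).
#' @param params a [tversky_params()].
#' @return scalar loss in \[0, 1\].
#' @examples
#' truth <- matrix(c(1, 1, 0, 0), 2)
#' tversky_loss(truth, truth, tversky_params())  # ~0: perfect prediction
#' @export
tversky_loss <- function(pred, truth, params = tversky_params()) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    stop("tversky_loss: pred and truth shapes differ (",
         paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(truth), collapse = "x"), ")")
  p <- as.numeric(pred)
  t <- as.numeric(truth)
  if (any(p < -1e-9 | p > 1 + 1e-9)) stop("tversky_loss: pred not in [0, 1]")
  TP <- sum(p * t)
  FN <- sum((1 - p) * t)
  FP <- sum(p * (1 - t))
  1 - (TP + params$epsilon) /
    (TP + params$alpha * FN + params$beta * FP + params$epsilon)
}

#' Pixel confusion counts between two binary masks
#'
#' @param pred_mask predicted \{0, 1\} mask.
#' @param truth reference \{0, 1\} mask of the same shape.
#' @return object of class \code{confusion_counts} with fields
#'   \code{tp, fp, fn, tn}; the four tallies are exhaustive and mutually
#'   exclusive (they sum to the pixel count).
#' @export
confusion <- function(pred_mask, truth) {
  if (!identical(dim(pred_mask), dim(truth)) ||
      length(pred_mask) != length(truth))
    stop("confusion: mask shapes differ")
  p <- as.numeric(pred_mask)
  t <- as.numeric(truth)
  if (!all(p %in% c(0, 1)) || !all(t %in% c(0, 1)))
    stop("confusion: masks must be binary {0, 1}")
  structure(list(tp = sum(p == 1 & t == 1),
                 fp = sum(p == 1 & t == 0),
                 fn = sum(p == 0 & t == 1),
                 tn = sum(p == 0 & t == 0)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP=%g FP=%g FN=%g TN=%g\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Combine confusion counts by summation
#'
#' Pooling counts first and computing metrics once is the aggregation used
#' for multi-image reports.
#'
#' @param ... \code{confusion_counts} objects (or a single list of them).
#' @return pooled \code{confusion_counts}.
#' @export
pool_confusion <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1]], "confusion_counts"))
    xs <- xs[[1]]
  structure(list(tp = sum(vapply(xs, `[[`, 0, "tp")),
                 fp = sum(vapply(xs, `[[`, 0, "fp")),
                 fn = sum(vapply(xs, `[[`, 0, "fn")),
                 tn = sum(vapply(xs, `[[`, 0, "tn"))),
            class = "confusion_counts")
}

metric_ratio <- function(num, den, err) {
  # zero-denominator convention: vacuous perfection scores 1, else 0
  if (den == 0) return(if (err == 0) 1 else 0)
  num / den
}

#' Segmentation quality metrics from confusion counts
#'
#' Precision \code{TP/(TP+FP)}, Dice \code{2TP/(2TP+FP+FN)} (the harmonic
#' mean of precision and recall), Recall \code{TP/(TP+FN)} and Accuracy
#' \code{(TP+TN)/(TP+TN+FP+FN)}. A metric whose denominator is zero returns
#' 1 when the total error count \code{FP + FN} is also zero (two empty
#' masks agree vacuously) and 0 otherwise (e.g. precision when nothing was
#' predicted but lodged pixels exist).
#'
#' @param counts a \code{confusion_counts} object (or list with
#'   \code{tp, fp, fn, tn}).
#' @return named list \code{precision, dice, recall, accuracy}, all in
#'   \[0, 1\].
#' @examples
#' seg_metrics(list(tp = 8, fp = 2, fn = 2, tn = 88))
#' @export
seg_metrics <- function(counts) {
  with(counts, {
    if (tp + fp + fn + tn == 0) stop("seg_metrics: empty input (no pixels)")
    err <- fp + fn
    list(
      precision = metric_ratio(tp, tp + fp, err),
      dice = metric_ratio(2 * tp, 2 * tp + fp + fn, err),
      recall = metric_ratio(tp, tp + fn, err),
      accuracy = (tp + tn) / (tp + tn + fp + fn)
    )
  })
}

#' Format a metrics report as a plain-text table
#'
#' @param metrics named list as returned by [seg_metrics()].
#' @param digits digits to print.
#' @return character vector of formatted lines (invisibly printed).
#' @export
format_metrics <- function(metrics, digits = 4) {
  lines <- sprintf("%-10s %.*f", names(metrics), digits,
                   unlist(metrics))
  lines
}
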