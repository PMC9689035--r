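#' Pixel-wise confusion matrix
#'
#' Entry (i, j) counts pixels whose true class is i and predicted class is j
#' (0-based class values).
#'
#' @param true_mask,pred_mask integer matrices/vectors of equal shape with
#'   values in \code{0:(n_classes-1)}.
#' @param n_classes number of classes.
#' @return an n x n count matrix (rows = true, columns = predicted).
#' @export
confusion_matrix <- function(true_mask, pred_mask, n_classes = 2) {
  if (length(true_mask) != length(pred_mask))
    stop("mask shapes differ")
  tv <- as.integer(true_mask)
  pv <- as.integer(pred_mask)
  if (any(tv < 0 | tv >= n_classes) || any(pv < 0 | pv >= n_classes))
    stop("mask values outside [0, n_classes)")
  counts <- tabulate(tv * n_classes + pv + 1L, nbins = n_classes^2)
  matrix(counts, n_classes, n_classes, byrow = TRUE)
}

#' Segmentation metrics from a confusion matrix
#'
#' Pixel accuracy is the trace over the total. Per-class IoU is
#' \code{TP / (FP + FN + TP)} and per-class Dice is
#' \code{2*TP / (FP + 2*TP + FN)}; both are averaged over classes without
#' weighting. A class absent from both the reference and the prediction scores
#' 1 for IoU and Dice; absent from only one scores 0.
#'
#' @param confusion an n x n count matrix (rows = true, columns = predicted).
#' @return object of class \code{metrics_report}: list with \code{confusion},
#'   \code{pa}, \code{mean_iou}, \code{dice}, \code{per_class_iou},
#'   \code{per_class_dice}, \code{n_classes}.
#' @export
compute_metrics <- function(confusion) {
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion),
            all(confusion >= 0))
  n <- nrow(confusion)
  total <- sum(confusion)
  tp <- diag(confusion)
  fn <- rowSums(confusion) - tp   # true i predicted elsewhere
  fp <- colSums(confusion) - tp   # predicted i but true elsewhere
  iou <- numeric(n)
  dice <- numeric(n)
  for (i in seq_len(n)) {
    denom_iou <- tp[i] + fp[i] + fn[i]
    denom_dc <- fp[i] + 2 * tp[i] + fn[i]
    if (denom_iou == 0) {            # class absent everywhere
      iou[i] <- 1
      dice[i] <- 1
    } else {
      iou[i] <- tp[i] / denom_iou
      dice[i] <- 2 * tp[i] / denom_dc
    }
  }
  structure(list(confusion = confusion,
                 pa = if (total > 0) sum(tp) / total else NA_real_,
                 mean_iou = mean(iou), dice = mean(dice),
                 per_class_iou = iou, per_class_dice = dice,
                 n_classes = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Segmentation metrics (", x$n_classes, " classes)\n", sep = "")
  cat(sprintf("  pixel accuracy: %.4f\n", x$pa))
  cat(sprintf("  mean IoU:       %.4f\n", x$mean_iou))
  cat(sprintf("  mean Dice:      %.4f\n", x$dice))
  cat("  confusion matrix (rows = true, cols = predicted):\n")
  print(x$confusion)
  invisible(x)
}

#' Evaluate a model on a labelled dataset
#'
#' Predicts every image, pools the pixel-wise confusion matrix across the
#' dataset and computes the metrics.
#'
#' @param model a fitted \code{rgc_snn} segmentation model.
#' @param data list of labelled images (see \code{\link{labeled_image}}).
#' @return a \code{metrics_report}.
#' @export
evaluate_segmentation <- function(model, data) {
  n <- model$config$n_classes
  conf <- matrix(0, n, n)
  for (item in data) {
    pred <- predict(model, item$image, type = "mask")
    conf <- conf + confusion_matrix(item$mask, pred, n)
  }
  compute_metrics(conf)
}
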