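#' Dice overlap of two masks
#'
#' `2 |A n B| / (|A| + |B|)` on the binarized foregrounds (any positive
#' label is foreground). Two empty masks score 1 by convention.
#'
#' @param mask_a,mask_b [label_mask()] objects or 0/positive matrices of
#'   identical shape.
#' @return Dice score in \[0, 1\].
#' @export
dice <- function(mask_a, mask_b) {
  a <- if (inherits(mask_a, "label_mask")) mask_a$labels else mask_a
  b <- if (inherits(mask_b, "label_mask")) mask_b$labels else mask_b
  if (!all(dim(a) == dim(b))) stop("mask shapes differ")
  fa <- a > 0; fb <- b > 0
  denom <- sum(fa) + sum(fb)
  if (denom == 0L) return(1)
  2 * sum(fa & fb) / denom
}

#' Match predicted and ground-truth instances
#'
#' Greedy one-to-one matching of instances by descending pairwise
#' intersection-over-union, accepting pairs with IoU >= `iou_min`.
#' Returns detection counts and the F1/recall/precision triplet
#' (`F1 = 2TP / (2TP + FP + FN)`). With no predictions, precision is
#' reported as 0 and flagged.
#'
#' @param pred,gt Labeled [label_mask()] objects of identical shape.
#' @param iou_min Acceptance threshold in (0, 1\] (default 0.5).
#' @return List of class `"detection_match"`: `tp`, `fp`, `fn`, `f1`,
#'   `recall`, `precision`, `precision_defined`, `iou_min`, `pairs`
#'   (matched label pairs with their IoU).
#' @export
match_instances <- function(pred, gt, iou_min = 0.5) {
  stopifnot(inherits(pred, "label_mask"), inherits(gt, "label_mask"))
  if (!all(dim(pred$labels) == dim(gt$labels))) stop("mask shapes differ")
  if (iou_min <= 0 || iou_min > 1) stop("'iou_min' must be in (0, 1]")
  pa <- instance_pixel_counts(pred)
  ga <- instance_pixel_counts(gt)
  np <- length(pa); ng <- length(ga)
  both <- pred$labels > 0L & gt$labels > 0L
  pairs <- NULL
  if (any(both)) {
    inter <- table(pred = pred$labels[both], gt = gt$labels[both])
    idx <- which(inter > 0, arr.ind = TRUE)
    pl <- rownames(inter)[idx[, 1L]]
    gl <- colnames(inter)[idx[, 2L]]
    ov <- inter[idx]
    iou <- ov / (pa[pl] + ga[gl] - ov)
    keep <- iou >= iou_min
    pairs <- data.frame(pred = as.integer(pl[keep]), gt = as.integer(gl[keep]),
                        iou = as.numeric(iou[keep]))
    pairs <- pairs[order(-pairs$iou, pairs$pred, pairs$gt), , drop = FALSE]
  }
  matched <- NULL
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    used_p <- integer(0); used_g <- integer(0); keep_rows <- integer(0)
    for (i in seq_len(nrow(pairs))) {
      if (!(pairs$pred[i] %in% used_p) && !(pairs$gt[i] %in% used_g)) {
        used_p <- c(used_p, pairs$pred[i]); used_g <- c(used_g, pairs$gt[i])
        keep_rows <- c(keep_rows, i)
      }
    }
    matched <- pairs[keep_rows, , drop = FALSE]
    rownames(matched) <- NULL
  }
  tp <- if (is.null(matched)) 0L else nrow(matched)
  fp <- np - tp
  fn <- ng - tp
  precision_defined <- np > 0L
  precision <- if (precision_defined) tp / np else 0
  recall <- if (ng > 0L) tp / ng else NA_real_
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn, f1 = f1, recall = recall,
                 precision = precision, precision_defined = precision_defined,
                 iou_min = iou_min, pairs = matched),
            class = "detection_match")
}

#' @export
print.detection_match <- function(x, ...) {
  cat(sprintf("detection_match (IoU >= %.2f): TP=%d FP=%d FN=%d | F1=%.3f recall=%.3f precision=%.3f%s\n",
              x$iou_min, x$tp, x$fp, x$fn, x$f1, x$recall, x$precision,
              if (!x$precision_defined) " [precision undefined: no predictions]" else ""))
  invisible(x)
}

#' Root mean squared error between paired image-level measurements
#'
#' @param estimates,truth Numeric vectors of the same length (one entry per
#'   image); pairs with a missing value on either side are skipped.
#' @return List with `rmse`, `n_used`, and `n_skipped`.
#' @export
parameter_rmse <- function(estimates, truth) {
  if (length(estimates) != length(truth)) stop("vectors must be paired")
  ok <- is.finite(estimates) & is.finite(truth)
  if (!any(ok)) stop("no valid pairs")
  list(rmse = sqrt(mean((estimates[ok] - truth[ok])^2)),
       n_used = sum(ok), n_skipped = sum(!ok))
}
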