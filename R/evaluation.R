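# Detection evaluation: IoU matching of predictions to ground truth and
# precision / recall / F1, confidence-threshold curves, and mask-level
# (polygon IoU) agreement.

#' Intersection over union of two axis-aligned boxes
#'
#' Boxes are `c(x, y, w, h)` in the half-open pixel convention
#' `[x, x+w) x [y, y+h)`.
#'
#' @param a,b Numeric vectors `c(x, y, w, h)` or one-row box data frames.
#' @return IoU in \[0, 1\].
#' @export
box_iou <- function(a, b) {
  if (is.data.frame(a)) a <- as.numeric(a[1, c("x", "y", "w", "h")])
  if (is.data.frame(b)) b <- as.numeric(b[1, c("x", "y", "w", "h")])
  ix <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  union <- a[3] * a[4] + b[3] * b[4] - inter
  if (union <= 0) return(0)
  inter / union
}

# IoU matrix between two box data frames (rows of gt x rows of pred).
box_iou_matrix <- function(gt, pred) {
  m <- matrix(0, nrow(gt), nrow(pred))
  for (i in seq_len(nrow(gt))) {
    a <- as.numeric(gt[i, c("x", "y", "w", "h")])
    for (j in seq_len(nrow(pred))) {
      m[i, j] <- box_iou(a, as.numeric(pred[j, c("x", "y", "w", "h")]))
    }
  }
  m
}

#' Match predicted boxes to ground truth by greedy confidence-ordered IoU
#'
#' Predictions are processed in descending confidence (ties: higher best
#' available IoU, then input order); each is matched to the unmatched
#' ground-truth box of highest IoU and the pair is accepted iff its IoU
#' reaches `iou_threshold`. Unmatched predictions become false positives,
#' unmatched ground truth false negatives. This greedy confidence-ordered
#' rule is the standard detector-evaluation protocol; see
#' [compute_metrics()] for the derived precision / recall / F1.
#'
#' @param gt Ground-truth box data frame (columns `x, y, w, h`; an optional
#'   `id` column names the ground-truth objects).
#' @param preds Detection-box data frame with `confidence`.
#' @param iou_threshold Minimum IoU for an accepted pair (default 0.5).
#' @return An object of class `match_result`: list with `pairs` (data frame
#'   `gt_id, pred_id, iou`), `false_positives` (pred ids), `false_negatives`
#'   (gt ids), `iou_threshold`, and counts `n_gt`, `n_pred`.
#' @export
match_detections <- function(gt, preds, iou_threshold = 0.5) {
  n_gt <- nrow(gt)
  n_pred <- nrow(preds)
  gt_ids <- if (!is.null(gt$id)) gt$id else seq_len(n_gt)
  pred_ids <- seq_len(n_pred)
  pairs <- data.frame(gt_id = gt_ids[0], pred_id = pred_ids[0],
                      iou = numeric(0))
  if (n_gt > 0L && n_pred > 0L) {
    iom <- box_iou_matrix(gt, preds)
    conf <- if (!is.null(preds$confidence)) preds$confidence else rep(1, n_pred)
    best_iou <- apply(iom, 2, max)
    ord <- order(-conf, -best_iou, seq_len(n_pred))
    gt_free <- rep(TRUE, n_gt)
    for (j in ord) {
      ious <- iom[, j]
      ious[!gt_free] <- -1
      i <- which.max(ious)
      if (ious[i] >= iou_threshold) {
        gt_free[i] <- FALSE
        pairs <- rbind(pairs, data.frame(gt_id = gt_ids[i], pred_id = j,
                                         iou = iom[i, j]))
      }
    }
  }
  structure(
    list(pairs = pairs,
         false_positives = setdiff(pred_ids, pairs$pred_id),
         false_negatives = setdiff(gt_ids, pairs$gt_id),
         iou_threshold = iou_threshold,
         n_gt = n_gt, n_pred = n_pred),
    class = "match_result"
  )
}

#' Precision, recall and F1 from a match result
#'
#' Precision is the fraction of detected stomata that are true positives;
#' recall the fraction of all ground-truth stomata that were detected; the
#' F1 score is their harmonic mean, `2 * p * r / (p + r)`. With zero
#' predictions precision is defined as 1 (no false claims were made); with
#' zero ground truth recall is defined as 1; F1 is 0 when `p + r = 0`.
#'
#' @param match A `match_result` from [match_detections()], or `NULL` when
#'   passing counts directly.
#' @param tp,fp,fn Optional explicit counts (used when `match` is `NULL`).
#' @return List of class `detection_metrics`:
#'   `tp, fp, fn, precision, recall, f1`.
#' @export
compute_metrics <- function(match = NULL, tp = NULL, fp = NULL, fn = NULL) {
  if (!is.null(match)) {
    stopifnot(inherits(match, "match_result"))
    tp <- nrow(match$pairs)
    fp <- length(match$false_positives)
    fn <- length(match$false_negatives)
  }
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  p <- if (tp + fp == 0) 1 else tp / (tp + fp)
  r <- if (tp + fn == 0) 1 else tp / (tp + fn)
  structure(
    list(tp = tp, fp = fp, fn = fn,
         precision = p, recall = r, f1 = f1_score(p, r)),
    class = "detection_metrics"
  )
}

#' F1 score: the harmonic mean of precision and recall
#'
#' `f1 = 2 * precision * recall / (precision + recall)`, defined as 0 when
#' both are 0. Vectorised.
#'
#' @param precision,recall Values in \[0, 1\].
#' @return F1 in \[0, 1\].
#' @export
f1_score <- function(precision, recall) {
  s <- precision + recall
  ifelse(s == 0, 0, 2 * precision * recall / s)
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf(
    "<detection_metrics: tp %d fp %d fn %d | precision %.3f recall %.3f f1 %.3f>\n",
    x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Precision / recall / F1 across confidence thresholds
#'
#' For each threshold on an even grid over \[0, 1\], keeps predictions with
#' confidence >= threshold, re-matches against ground truth and computes
#' metrics. `best_threshold` is the threshold maximising F1 (ties: lowest
#' threshold).
#'
#' @inheritParams match_detections
#' @param grid_size Number of grid points (default 101).
#' @return Object of class `confidence_curve`: data frame `threshold,
#'   precision, recall, f1` plus attribute `best_threshold`.
#' @export
confidence_curve <- function(gt, preds, iou_threshold = 0.5,
                             grid_size = 101L) {
  thr <- seq(0, 1, length.out = grid_size)
  rows <- lapply(thr, function(t) {
    keep <- preds[preds$confidence >= t, , drop = FALSE]
    m <- compute_metrics(match_detections(gt, keep, iou_threshold))
    data.frame(threshold = t, precision = m$precision, recall = m$recall,
               f1 = m$f1)
  })
  curve <- do.call(rbind, rows)
  best <- curve$threshold[which.max(curve$f1)]
  structure(curve, best_threshold = best,
            class = c("confidence_curve", "data.frame"))
}

poly_to_pc <- function(poly) list(x = poly[, 1], y = poly[, 2])

pc_area <- function(pl) {
  sum(vapply(pl, function(p) {
    abs(polygon_area(cbind(p$x, p$y)))
  }, numeric(1)))
}

#' Polygon intersection-over-union
#'
#' Geometric IoU of two simple polygons, computed by exact polygon clipping.
#'
#' @param polyA,polyB n x 2 coordinate matrices.
#' @return IoU in \[0, 1\].
#' @export
polygon_iou <- function(polyA, polyB) {
  if (is.null(polyA) || is.null(polyB) ||
      nrow(polyA) < 3L || nrow(polyB) < 3L) {
    stop_stomapipe("polygon_iou needs two polygons with >= 3 vertices",
                   "stomapipe_geometry_error")
  }
  A <- list(poly_to_pc(polyA))
  B <- list(poly_to_pc(polyB))
  inter <- pc_area(polyclip::polyclip(A, B, op = "intersection"))
  aA <- abs(polygon_area(polyA))
  aB <- abs(polygon_area(polyB))
  union <- aA + aB - inter
  if (union <= 0) return(0)
  inter / union
}

#' Mask-level agreement between two stoma masks
#'
#' Computes the polygon IoU of the complex outlines and, when both masks
#' carry an aperture, of the aperture outlines.
#'
#' @param maskA,maskB `stoma_mask` objects (see [stoma_mask()]), on the same
#'   image frame.
#' @return List `complex_iou`, `aperture_iou` (`NA` if either aperture is
#'   absent).
#' @export
mask_agreement <- function(maskA, maskB) {
  ci <- polygon_iou(maskA$complex_polygon, maskB$complex_polygon)
  ai <- if (!is.null(maskA$aperture_polygon) &&
            !is.null(maskB$aperture_polygon)) {
    polygon_iou(maskA$aperture_polygon, maskB$aperture_polygon)
  } else {
    NA_real_
  }
  list(complex_iou = ci, aperture_iou = ai)
}

#' Per-image evaluation report
#'
#' Matches predictions to ground truth image by image and tabulates counts
#' and metrics, with a pooled (micro-averaged) aggregate row computed from
#' the summed tp/fp/fn.
#'
#' @param gt_by_image Named list of ground-truth box data frames.
#' @param preds_by_image Named list of detection-box data frames (missing
#'   names count as zero predictions).
#' @param iou_threshold Matching threshold.
#' @return Data frame `image_id, n_gt, n_pred, tp, fp, fn, precision,
#'   recall, f1`; last row `image_id = "pooled"`.
#' @export
evaluation_report <- function(gt_by_image, preds_by_image,
                              iou_threshold = 0.5) {
  ids <- names(gt_by_image)
  rows <- lapply(ids, function(id) {
    preds <- preds_by_image[[id]]
    if (is.null(preds)) preds <- empty_boxes()
    m <- compute_metrics(match_detections(gt_by_image[[id]], preds,
                                          iou_threshold))
    data.frame(image_id = id, n_gt = nrow(gt_by_image[[id]]),
               n_pred = nrow(preds), tp = m$tp, fp = m$fp, fn = m$fn,
               precision = m$precision, recall = m$recall, f1 = m$f1)
  })
  rep <- do.call(rbind, rows)
  agg <- compute_metrics(tp = sum(rep$tp), fp = sum(rep$fp),
                         fn = sum(rep$fn))
  rbind(rep, data.frame(image_id = "pooled", n_gt = sum(rep$n_gt),
                        n_pred = sum(rep$n_pred), tp = agg$tp, fp = agg$fp,
                        fn = agg$fn, precision = agg$precision,
                        recall = agg$recall, f1 = agg$f1))
}
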