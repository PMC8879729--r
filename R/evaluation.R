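#' Euclidean distance between two centroids
#'
#' Distance in millimeters between a ground-truth and a predicted centroid;
#' `pixel_spacing_mm` converts pixels to millimeters (default 1, i.e.
#' report in pixels).
#'
#' @param gt,pred Numeric `c(x, y)` points.
#' @param pixel_spacing_mm Pixel pitch in mm/pixel (> 0).
#' @return Distance in mm.
#' @export
euclidean_distance <- function(gt, pred, pixel_spacing_mm = 1) {
  stopifnot(pixel_spacing_mm > 0)
  pixel_spacing_mm * sqrt((pred[[1]] - gt[[1]])^2 + (pred[[2]] - gt[[2]])^2)
}

#' Mean centroid distance (MEU)
#'
#' @param distances Non-empty numeric vector of centroid distances.
#' @return Arithmetic mean.
#' @export
mean_eu <- function(distances) {
  if (length(distances) == 0) stop("no distances to average")
  mean(distances)
}

#' Intersection over union of two axis-aligned boxes
#'
#' Area of overlap divided by area of union, on continuous coordinates.
#' Disjoint boxes give 0; boxes of zero area give 0.
#'
#' @param a,b Single-row bounding-box data frames (or lists with `xmin`,
#'   `ymin`, `xmax`, `ymax`).
#' @return IOU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  ix <- max(0, min(a$xmax, b$xmax) - max(a$xmin, b$xmin))
  iy <- max(0, min(a$ymax, b$ymax) - max(a$ymin, b$ymin))
  inter <- ix * iy
  area_a <- (a$xmax - a$xmin) * (a$ymax - a$ymin)
  area_b <- (b$xmax - b$xmin) * (b$ymax - b$ymin)
  union <- area_a + area_b - inter
  if (union <= 0) return(0)
  inter / union
}

#' Mean absolute angle error (ME)
#'
#' Mean of `|predicted - ground truth|` over paired angle lists, degrees.
#'
#' @param pred_angles,orig_angles Equal-length non-empty numeric vectors.
#' @return Mean absolute error in degrees.
#' @export
mean_error <- function(pred_angles, orig_angles) {
  if (length(pred_angles) != length(orig_angles))
    stop("angle lists differ in length")
  if (length(pred_angles) == 0) stop("empty angle lists")
  mean(abs(pred_angles - orig_angles))
}

# Greedy non-maximum suppression: order by confidence descending, drop any
# box overlapping a kept box above `nms_iou`.
nms_filter <- function(boxes, nms_iou) {
  if (nrow(boxes) <= 1) return(boxes)
  ord <- order(-boxes$confidence)
  boxes <- boxes[ord, , drop = FALSE]
  keep <- integer(0)
  for (i in seq_len(nrow(boxes))) {
    drop_i <- FALSE
    for (k in keep) {
      if (box_iou(boxes[k, ], boxes[i, ]) > nms_iou) { drop_i <- TRUE; break }
    }
    if (!drop_i) keep <- c(keep, i)
  }
  boxes[keep, , drop = FALSE]
}

#' Match predicted boxes to ground truth
#'
#' Post-processes detections the way the localization stage is evaluated:
#' predictions below `conf_threshold` (default 0.65) are dropped, greedy
#' non-maximum suppression at `nms_iou` (default 0.3) removes duplicate
#' detections, and the survivors are matched to ground truth greedily in
#' descending confidence, each to its highest-IOU still-free ground-truth
#' box with IOU at least `match_iou`.
#'
#' @param gt Ground-truth bounding-box data frame.
#' @param pred Predicted boxes with a `confidence` column.
#' @param conf_threshold,nms_iou,match_iou Post-filter parameters.
#' @return A list of class `"detection_match"`: `pairs` (data frame
#'   `gt_idx`, `pred_idx`, `iou` into the input frames), `unmatched_gt`,
#'   `unmatched_pred` (row indices), and `params`.
#' @export
match_detections <- function(gt, pred, conf_threshold = 0.65,
                             nms_iou = 0.3, match_iou = 0.5) {
  validate_boxes(gt)
  validate_boxes(pred)
  if (nrow(pred) > 0 && any(is.na(pred$confidence)))
    stop("predictions must carry confidences")
  pred$.row <- seq_len(nrow(pred))
  kept <- pred[pred$confidence >= conf_threshold, , drop = FALSE]
  kept <- nms_filter(kept, nms_iou)
  gt_free <- rep(TRUE, nrow(gt))
  pairs <- list()
  matched_pred <- integer(0)
  if (nrow(kept) > 0) {
    kept <- kept[order(-kept$confidence), , drop = FALSE]
    for (i in seq_len(nrow(kept))) {
      ious <- vapply(seq_len(nrow(gt)), function(g)
        if (gt_free[g]) box_iou(gt[g, ], kept[i, ]) else -1, 0)
      if (length(ious) == 0) next
      g <- which.max(ious)
      if (ious[g] >= match_iou) {
        gt_free[g] <- FALSE
        pairs[[length(pairs) + 1]] <-
          data.frame(gt_idx = g, pred_idx = kept$.row[i], iou = ious[g])
        matched_pred <- c(matched_pred, kept$.row[i])
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gt_idx = integer(0), pred_idx = integer(0), iou = numeric(0))
  structure(list(pairs = pairs,
                 unmatched_gt = which(gt_free),
                 unmatched_pred = setdiff(kept$.row, matched_pred),
                 params = list(conf_threshold = conf_threshold,
                               nms_iou = nms_iou, match_iou = match_iou)),
            class = "detection_match")
}

#' Precision and recall of a detection match
#'
#' `P = TP / (TP + FP)` (1 by convention when there are no predictions, so
#' precision-recall curves start at (0, 1)) and `R = TP / (TP + FN)`.
#'
#' @param match A [match_detections()] result.
#' @return Named numeric vector `c(precision, recall)`.
#' @export
precision_recall <- function(match) {
  stopifnot(inherits(match, "detection_match"))
  tp <- nrow(match$pairs)
  fp <- length(match$unmatched_pred)
  fn <- length(match$unmatched_gt)
  p <- if (tp + fp == 0) 1 else tp / (tp + fp)
  r <- if (tp + fn == 0) 1 else tp / (tp + fn)
  c(precision = p, recall = r)
}

#' Average precision over a detection dataset
#'
#' Pools all predictions across images, ranks them by confidence
#' descending (ties by image order, then row), marks each as true positive
#' if it matches a still-free ground-truth box of its image with IOU at
#' least `iou_threshold`, and integrates the all-point interpolated
#' (monotone-envelope) precision-recall curve. Detections enter the curve
#' unfiltered — confidence and NMS cuts belong to deployment, not to AP.
#'
#' @param gt_sets,pred_sets Lists of bounding-box data frames, one element
#'   per image; predictions carry confidences.
#' @param iou_threshold Match threshold (default 0.5).
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(gt_sets, pred_sets, iou_threshold = 0.5) {
  stopifnot(length(gt_sets) == length(pred_sets))
  n_gt <- sum(vapply(gt_sets, nrow, 0L))
  if (n_gt == 0) stop("average precision undefined without ground truth")
  recs <- list()
  for (img in seq_along(pred_sets)) {
    p <- pred_sets[[img]]
    if (nrow(p) == 0) next
    recs[[length(recs) + 1]] <-
      data.frame(img = img, row = seq_len(nrow(p)), conf = p$confidence)
  }
  if (length(recs) == 0) return(0)
  all_pred <- do.call(rbind, recs)
  all_pred <- all_pred[order(-all_pred$conf, all_pred$img, all_pred$row), ,
                       drop = FALSE]
  gt_free <- lapply(gt_sets, function(g) rep(TRUE, nrow(g)))
  tp <- logical(nrow(all_pred))
  for (i in seq_len(nrow(all_pred))) {
    img <- all_pred$img[i]
    g <- gt_sets[[img]]
    if (nrow(g) == 0) next
    box <- pred_sets[[img]][all_pred$row[i], ]
    ious <- vapply(seq_len(nrow(g)), function(k)
      if (gt_free[[img]][k]) box_iou(g[k, ], box) else -1, 0)
    best <- which.max(ious)
    if (ious[best] >= iou_threshold) {
      tp[i] <- TRUE
      gt_free[[img]][best] <- FALSE
    }
  }
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  precision <- cum_tp / (cum_tp + cum_fp)
  recall <- cum_tp / n_gt
  # monotone envelope from the right, integrate over recall increments
  env <- rev(cummax(rev(precision)))
  rec_prev <- c(0, recall[-length(recall)])
  sum((recall - rec_prev) * env)
}

#' Mean average precision over a range of IOU thresholds
#'
#' `mAP@0.5` is [average_precision()] at threshold 0.5; `mAP@0.5:0.95` is
#' the mean AP over thresholds 0.50, 0.55, ..., 0.95.
#'
#' @param gt_sets,pred_sets As in [average_precision()].
#' @param thresholds IOU thresholds to average over.
#' @return List with `thresholds`, per-threshold `ap`, and their mean
#'   `map`.
#' @export
map_over_thresholds <- function(gt_sets, pred_sets,
                                thresholds = seq(0.5, 0.95, by = 0.05)) {
  ap <- vapply(thresholds, function(t)
    average_precision(gt_sets, pred_sets, t), 0)
  list(thresholds = thresholds, ap = ap, map = mean(ap))
}

#' Three-class confusion matrix and accuracy for lordosis grades
#'
#' Rows are true grades, columns predicted, both ordered (hypo, normal,
#' hyper); accuracy is the trace over the total.
#'
#' @param true_grades,pred_grades Equal-length grade vectors.
#' @return List of class `"grade_confusion"` with `confusion` (3x3 integer
#'   matrix), `accuracy` and `n`.
#' @export
confusion_and_accuracy <- function(true_grades, pred_grades) {
  if (length(true_grades) != length(pred_grades))
    stop("grade vectors differ in length")
  lv <- c("hypo", "normal", "hyper")
  if (!all(true_grades %in% lv) || !all(pred_grades %in% lv))
    stop("grades must be 'hypo', 'normal' or 'hyper'")
  cm <- table(factor(true_grades, levels = lv),
              factor(pred_grades, levels = lv))
  cm <- matrix(as.integer(cm), 3, 3, dimnames = list(true = lv, pred = lv))
  structure(list(confusion = cm,
                 accuracy = sum(diag(cm)) / sum(cm), n = sum(cm)),
            class = "grade_confusion")
}

#' @export
print.grade_confusion <- function(x, ...) {
  cat("Lordosis grading confusion matrix (rows = true):\n")
  print(x$confusion)
  cat(sprintf("Accuracy: %.3f (%d/%d)\n", x$accuracy,
              sum(diag(x$confusion)), x$n))
  invisible(x)
}
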