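test_that("centroid distances follow Euclid and scale with pixel spacing", {
  expect_equal(euclidean_distance(c(3, 4), c(3, 4)), 0)
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(c(0, 0), c(3, 4), pixel_spacing_mm = 0.5),
               2.5)
  expect_equal(mean_eu(c(2, 2, 2)), 2)
  expect_equal(mean_eu(0), 0)
  set.seed(8)
  v <- runif(1000)
  expect_equal(mean_eu(v), sum(v) / length(v), tolerance = 1e-9)
  expect_error(mean_eu(numeric(0)), "no distances")
})

test_that("IOU matches a fine-grid pixel-count oracle", {
  a <- bounding_box(0, 0, 2, 2)
  b <- bounding_box(1, 1, 3, 3)
  expect_equal(box_iou(a, a), 1)
  expect_equal(box_iou(a, bounding_box(5, 5, 6, 6)), 0)
  expect_equal(box_iou(a, b), 1 / 7)

  # fine-grid oracle: count sub-pixels inside either/both boxes
  g <- expand.grid(x = seq(0.005, 3, by = 0.01), y = seq(0.005, 3, by = 0.01))
  in_a <- g$x < 2 & g$y < 2
  in_b <- g$x > 1 & g$y > 1
  expect_equal(box_iou(a, b), sum(in_a & in_b) / sum(in_a | in_b),
               tolerance = 1e-2)

  # symmetry and translation invariance
  set.seed(10)
  for (i in 1:20) {
    p <- bounding_box(runif(1, 0, 5), runif(1, 0, 5),
                      runif(1, 5, 10), runif(1, 5, 10))
    q <- bounding_box(runif(1, 0, 5), runif(1, 0, 5),
                      runif(1, 5, 10), runif(1, 5, 10))
    expect_equal(box_iou(p, q), box_iou(q, p))
    ps <- p; qs <- q
    for (col in c("xmin", "xmax")) { ps[[col]] <- ps[[col]] + 3
                                     qs[[col]] <- qs[[col]] + 3 }
    expect_equal(box_iou(ps, qs), box_iou(p, q))
    expect_gte(box_iou(p, q), 0); expect_lte(box_iou(p, q), 1)
  }
  expect_equal(box_iou(bounding_box(2, 2, 2, 2), bounding_box(2, 2, 2, 2)),
               0)  # zero-area boxes
})

test_that("mean angle error is a brute-force mean of absolute deviations", {
  expect_equal(mean_error(c(40, 50), c(40, 50)), 0)
  expect_equal(mean_error(c(40, 50), c(39, 51)), 1)
  set.seed(12)
  p <- runif(200, 0, 90); o <- runif(200, 0, 90)
  acc <- 0
  for (i in seq_along(p)) acc <- acc + abs(p[i] - o[i])
  expect_equal(mean_error(p, o), acc / length(p), tolerance = 1e-12)
  expect_error(mean_error(1:3, 1:2), "length")
  expect_gte(mean_error(p, o), 0)
})

test_that("detection matching applies confidence, NMS and IOU rules", {
  gt <- generate_phantom(phantom_spec(seed = 1))$boxes

  perfect <- gt; perfect$confidence <- 1
  m <- match_detections(gt, perfect)
  expect_equal(nrow(m$pairs), 6)
  expect_length(m$unmatched_gt, 0)
  expect_length(m$unmatched_pred, 0)
  expect_equal(precision_recall(m), c(precision = 1, recall = 1))

  low <- gt; low$confidence <- 0.5
  m2 <- match_detections(gt, low)
  expect_equal(nrow(m2$pairs), 0)
  expect_length(m2$unmatched_gt, 6)
  expect_equal(precision_recall(m2), c(precision = 1, recall = 0))

  # duplicate detections on one object: NMS keeps the stronger one
  one_gt <- bounding_box(10, 10, 30, 30)
  dup <- bounding_box(xmin = c(10, 12), ymin = c(10, 10),
                      xmax = c(30, 32), ymax = c(30, 30),
                      confidence = c(0.9, 0.8))
  expect_gt(box_iou(dup[1, ], dup[2, ]), 0.3)
  m3 <- match_detections(one_gt, dup)
  expect_equal(nrow(m3$pairs), 1)
  expect_equal(m3$pairs$pred_idx, 1)
  expect_length(m3$unmatched_pred, 0)
  expect_equal(precision_recall(m3), c(precision = 1, recall = 1))

  # 3 TP, 1 FP, 1 FN arithmetic
  gt4 <- bounding_box(xmin = c(0, 40, 80, 120), ymin = 0,
                      xmax = c(20, 60, 100, 140), ymax = 20)
  pred <- bounding_box(xmin = c(0, 40, 80, 200), ymin = 0,
                       xmax = c(20, 60, 100, 220), ymax = 20,
                       confidence = 0.9)
  pr <- precision_recall(match_detections(gt4, pred))
  expect_equal(unname(pr), c(0.75, 0.75))
})

test_that("average precision equals exhaustive staircase enumeration", {
  boxes_at <- function(xs, conf = NA_real_)
    bounding_box(xmin = xs, ymin = 0, xmax = xs + 10, ymax = 10,
                 confidence = conf)
  # 3 images, 6 gt; detections: 4 hits, one duplicate, one far miss,
  # one gt never detected
  gt_sets <- list(boxes_at(c(0, 20)), boxes_at(c(0, 20)), boxes_at(c(0, 20)))
  pred_sets <- list(
    boxes_at(c(0, 20), conf = c(0.95, 0.9)),
    boxes_at(c(0, 1, 20), conf = c(0.85, 0.8, 0.7)),   # dup on gt 1
    boxes_at(c(0, 100), conf = c(0.6, 0.5)))           # miss on gt 2
  # ranked by confidence: TP TP TP FP(dup) TP TP FP(far)
  flags <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  ap <- average_precision(gt_sets, pred_sets, 0.5)
  expect_equal(ap, staircase_ap(flags, 6), tolerance = 1e-9)

  expect_equal(average_precision(gt_sets, gt_then_conf(gt_sets), 0.5), 1)
  expect_equal(average_precision(gt_sets, list(boxes_at(numeric(0)),
                                               boxes_at(numeric(0)),
                                               boxes_at(numeric(0)))), 0)
  expect_error(average_precision(list(boxes_at(numeric(0))),
                                 list(boxes_at(numeric(0)))),
               "without ground truth")
})

test_that("mAP is 1 for perfect detections and non-increasing in IOU", {
  cohort <- lapply(1:3, function(s)
    generate_phantom(phantom_spec(seed = s, boundary_jitter_px = 1)))
  gt_sets <- lapply(cohort, `[[`, "boxes")
  pred_sets <- gt_then_conf(gt_sets)
  res <- map_over_thresholds(gt_sets, pred_sets)
  expect_equal(res$map, 1)
  expect_equal(average_precision(gt_sets, pred_sets, 0.5), 1)

  # perturbed predictions: AP cannot grow as the threshold tightens
  pert <- lapply(pred_sets, function(p) {
    p$xmin <- p$xmin + c(2, 4, 1, 6, 3, 8)
    p$confidence <- seq(0.95, 0.7, length.out = 6)
    p
  })
  aps <- map_over_thresholds(gt_sets, pert)$ap
  expect_true(all(diff(aps) <= 1e-12))
})

test_that("AP is invariant to the ordering of images", {
  set.seed(33)
  gt_sets <- lapply(1:4, function(i)
    bounding_box(xmin = runif(3, 0, 80), ymin = runif(3, 0, 80),
                 xmax = runif(3, 90, 160), ymax = runif(3, 90, 160)))
  pred_sets <- lapply(gt_sets, function(g) {
    g$xmin <- g$xmin + rnorm(3, 0, 6); g$ymin <- g$ymin + rnorm(3, 0, 6)
    g$confidence <- runif(3, 0.3, 1); g
  })
  a <- average_precision(gt_sets, pred_sets, 0.5)
  perm <- c(3, 1, 4, 2)
  b <- average_precision(gt_sets[perm], pred_sets[perm], 0.5)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("confusion matrices reproduce their printed accuracies", {
  # perfect corner-method matrix: diagonal (6, 19, 26)
  t4 <- c(rep("hypo", 6), rep("normal", 19), rep("hyper", 26))
  cm4 <- confusion_and_accuracy(t4, t4)
  expect_equal(cm4$confusion,
               matrix(as.integer(diag(c(6, 19, 26))), 3, 3,
                      dimnames = list(true = c("hypo", "normal", "hyper"),
                                      pred = c("hypo", "normal", "hyper"))))
  expect_equal(cm4$accuracy, 1)

  # region-area matrix: rows (6,0,0), (6,11,2), (0,5,21) -> 38/51
  pred6 <- c(rep("hypo", 6),
             rep("hypo", 6), rep("normal", 11), rep("hyper", 2),
             rep("normal", 5), rep("hyper", 21))
  cm6 <- confusion_and_accuracy(t4, pred6)
  expect_equal(unname(cm6$confusion),
               matrix(as.integer(c(6, 0, 0, 6, 11, 2, 0, 5, 21)), 3, 3,
                      byrow = TRUE))
  expect_equal(cm6$accuracy, 38 / 51, tolerance = 1e-12)
  expect_equal(cm6$n, 51)

  # accuracy identity: trace/total equals the mean agreement indicator
  set.seed(19)
  a <- sample(c("hypo", "normal", "hyper"), 200, replace = TRUE)
  b <- sample(c("hypo", "normal", "hyper"), 200, replace = TRUE)
  expect_equal(confusion_and_accuracy(a, b)$accuracy, mean(a == b))
  expect_error(confusion_and_accuracy(a, b[-1]), "length")
  expect_error(confusion_and_accuracy(c("hypo"), c("weird")), "grades")
})
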