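test_that("box IoU follows the half-open convention", {
  a <- c(0, 0, 10, 10)
  expect_equal(box_iou(a, a), 1)
  expect_equal(box_iou(a, c(20, 20, 5, 5)), 0)
  expect_equal(box_iou(a, c(5, 0, 10, 10)), 1 / 3)
})

test_that("greedy matching pairs predictions to ground truth correctly", {
  gt <- data.frame(x = c(0, 30, 60), y = 0, w = 10, h = 10)
  preds <- detection_boxes(x = c(0, 30, 60), y = c(0, 0, 0), w = 10, h = 10,
                           confidence = c(0.9, 0.8, 0.7))
  m <- match_detections(gt, preds, 0.5)
  expect_identical(nrow(m$pairs), 3L)
  expect_length(m$false_positives, 0)
  expect_length(m$false_negatives, 0)

  # 10 GT, preds = 8 of them plus 2 disjoint -> tp 8, fp 2, fn 2
  gt10 <- data.frame(x = seq(0, 180, by = 20), y = 0, w = 10, h = 10)
  preds8 <- detection_boxes(x = c(gt10$x[1:8], 500, 550), y = 0, w = 10,
                            h = 10, confidence = seq(0.95, 0.5,
                                                     length.out = 10))
  met <- compute_metrics(match_detections(gt10, preds8, 0.5))
  expect_identical(c(met$tp, met$fp, met$fn), c(8L, 2L, 2L))

  # two predictions on one GT: the more confident one pairs
  gt1 <- data.frame(x = 0, y = 0, w = 10, h = 10)
  duo <- detection_boxes(x = c(0.5, -0.5), y = 0, w = 10, h = 10,
                         confidence = c(0.8, 0.7))
  m2 <- match_detections(gt1, duo, 0.5)
  expect_identical(m2$pairs$pred_id, 1L)
  expect_identical(m2$false_positives, 2L)
})

test_that("precision, recall and F1 satisfy their defining identities", {
  # worked examples from published detector operating points
  ops <- detector_operating_points()
  expect_equal(round(ops$f1, 3), c(0.995, 0.907, 0.889, 0.896, 0.873))
  # harmonic-mean identity
  for (x in c(0.1, 0.5, 0.815, 1)) expect_equal(f1_score(x, x), x)
  expect_equal(f1_score(0, 0), 0)
  # degenerate conventions
  none <- compute_metrics(tp = 0, fp = 0, fn = 5)
  expect_equal(none$precision, 1)
  expect_equal(none$recall, 0)
  no_gt <- compute_metrics(tp = 0, fp = 3, fn = 0)
  expect_equal(no_gt$recall, 1)
  expect_equal(no_gt$precision, 0)
})

test_that("match results satisfy the partition identities on random instances", {
  set.seed(7)
  for (rep in 1:25) {
    inst <- random_match_instance(sample(0:6, 1), sample(0:6, 1))
    m <- match_detections(inst$gt, inst$pred, 0.5)
    expect_identical(nrow(m$pairs) + length(m$false_positives), m$n_pred)
    expect_identical(nrow(m$pairs) + length(m$false_negatives), m$n_gt)
    expect_true(all(m$pairs$iou >= 0.5))
    expect_identical(anyDuplicated(m$pairs$gt_id), 0L)
    expect_identical(anyDuplicated(m$pairs$pred_id), 0L)
    # metrics are permutation-invariant given distinct confidences
    if (m$n_pred > 1) {
      perm <- sample(m$n_pred)
      m_p <- match_detections(inst$gt, inst$pred[perm, ], 0.5)
      expect_identical(nrow(m_p$pairs), nrow(m$pairs))
    }
  }
})

test_that("greedy matching tracks the brute-force optimal matching", {
  set.seed(20)
  n_exact <- 0L
  n_unambiguous <- 0L
  for (rep in 1:300) {
    inst <- random_match_instance(sample(1:6, 1), sample(1:6, 1))
    m <- match_detections(inst$gt, inst$pred, 0.5)
    iom <- stomapipe:::box_iou_matrix(inst$gt, inst$pred)
    opt <- brute_force_max_matching(iom, 0.5)
    expect_gte(nrow(m$pairs), opt - 1L)
    expect_lte(nrow(m$pairs), opt)
    # when no prediction is IoU-feasible for two GT boxes the greedy walk is
    # unambiguous and must equal the optimum
    if (all(colSums(iom >= 0.5) <= 1)) {
      n_unambiguous <- n_unambiguous + 1L
      expect_identical(nrow(m$pairs), opt)
    }
    if (nrow(m$pairs) == opt) n_exact <- n_exact + 1L
  }
  expect_gt(n_unambiguous, 50)
  expect_gt(n_exact / 300, 0.95)
})

test_that("confidence curves sweep thresholds with non-increasing recall", {
  sc <- cached_scene("dicot", 3)
  det <- detect_classical(sc$image, get_profile("400x"),
                          detector_config_for("dicot"))
  curve <- confidence_curve(sc$truth$boxes, det, 0.5, grid_size = 21)
  expect_identical(nrow(curve), 21L)
  expect_true(all(diff(curve$recall) <= 1e-12))
  expect_equal(attr(curve, "best_threshold"),
               curve$threshold[which.max(curve$f1)])
  # above the maximum confidence recall drops to 0
  expect_equal(curve$recall[curve$threshold > max(det$confidence)],
               rep(0, sum(curve$threshold > max(det$confidence))))

  # constant confidences: curve flat until the confidence value
  preds <- detection_boxes(x = c(0, 30), y = 0, w = 10, h = 10,
                           confidence = 1)
  gt <- data.frame(x = c(0, 30), y = 0, w = 10, h = 10)
  cc <- confidence_curve(gt, preds, 0.5, grid_size = 11)
  expect_true(all(cc$f1 == 1))
})

test_that("mask agreement computes polygon IoU geometrically", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  m1 <- stoma_mask(sq * 10)
  expect_equal(mask_agreement(m1, m1)$complex_iou, 1)

  shifted <- stoma_mask(sq * 10 + cbind(rep(5, 4), rep(0, 4)))
  expect_equal(mask_agreement(m1, shifted)$complex_iou, 1 / 3)

  far <- stoma_mask(sq * 10 + 100)
  expect_equal(mask_agreement(m1, far)$complex_iou, 0)
  expect_true(is.na(mask_agreement(m1, far)$aperture_iou))

  # with apertures on both masks the aperture term is computed too
  ap <- sq * 2 + 3
  m_ap <- stoma_mask(sq * 10, ap)
  both <- mask_agreement(m_ap, m_ap)
  expect_equal(both$aperture_iou, 1)
  expect_error(polygon_iou(sq[1:2, ], sq), class = "stomapipe_geometry_error")
})

test_that("evaluation reports pool counts across images", {
  gt <- list(a = data.frame(x = c(0, 30), y = 0, w = 10, h = 10),
             b = data.frame(x = 0, y = 0, w = 10, h = 10))
  preds <- list(a = detection_boxes(x = c(0, 100), y = 0, w = 10, h = 10,
                                    confidence = c(0.9, 0.8)))
  rep_ <- evaluation_report(gt, preds, 0.5)
  expect_identical(nrow(rep_), 3L)
  pooled <- rep_[rep_$image_id == "pooled", ]
  expect_identical(c(pooled$tp, pooled$fp, pooled$fn), c(1L, 1L, 2L))
  expect_equal(pooled$precision, 0.5)
  expect_equal(pooled$recall, 1 / 3)
})
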