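test_that("box IoU follows area arithmetic", {
  expect_equal(box_iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(box_iou(c(0, 0, 2, 2), c(5, 5, 7, 7)), 0)
  expect_equal(box_iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)
  # symmetry on random pairs
  set.seed(1)
  for (i in 1:25) {
    a <- random_boxes(1); b <- random_boxes(1)
    expect_equal(box_iou(a, b), box_iou(b, a))
    expect_true(box_iou(a, b) >= 0 && box_iou(a, b) <= 1)
  }
})

test_that("matcher applies confidence threshold and greedy assignment", {
  gt <- box(0, 0, 10, 10)
  pred <- box(1, 0, 11, 10, confidence = 0.9)
  m <- match_detections(gt, pred, 0.13, 0.5)
  expect_equal(nrow(m$pairs), 1)
  expect_length(m$unmatched_gt, 0)
  expect_length(m$unmatched_pred, 0)

  # a prediction below the 13% threshold is discarded, not a false positive
  low <- box(1, 0, 11, 10, confidence = 0.10)
  m2 <- match_detections(gt, low, 0.13, 0.5)
  expect_equal(nrow(m2$pairs), 0)
  expect_equal(m2$unmatched_gt, 1L)
  expect_length(m2$unmatched_pred, 0)
  expect_equal(m2$n_discarded, 1L)

  # two predictions over one gt: higher confidence wins even at lower IoU
  gt3 <- box(0, 0, 10, 10)
  preds3 <- rbind(box(0, 3, 10, 13, confidence = 0.8),   # IoU = 7/13
                  box(0, 1, 10, 11, confidence = 0.6))   # IoU = 9/11
  m3 <- match_detections(gt3, preds3, 0.13, 0.5)
  expect_equal(m3$pairs$pred_idx, 1L)
  expect_equal(m3$unmatched_pred, 2L)
})

test_that("image-level confusion-matrix metrics handle edge cases", {
  perfect <- image_classification_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$ppv, 1)

  none <- image_classification_metrics(c(1, 1, 0), c(0, 0, 0))
  expect_equal(none$sensitivity, 0)
  expect_equal(none$specificity, 1)
  expect_true(is.na(none$ppv))
})

test_that("detection precision/recall aggregates match results", {
  gt <- box(0, 0, 10, 10)
  pred <- box(0, 0, 10, 10, confidence = 0.9)
  m <- match_detections(gt, pred)
  pr <- detection_pr(m)
  expect_equal(pr$precision, 1)
  expect_equal(pr$recall, 1)

  m0 <- match_detections(gt, pred[0, ])
  pr0 <- detection_pr(m0)
  expect_true(is.na(pr0$precision))
  expect_equal(pr0$recall, 0)
})

test_that("average precision reproduces the interpolated envelope", {
  gt <- rbind(box(0, 0, 10, 10), box(50, 50, 60, 60))
  hit1 <- box(0, 0, 10, 10, confidence = 0.9)
  miss <- box(80, 80, 90, 90, confidence = 0.8)
  hit2 <- box(50, 50, 60, 60, confidence = 0.7)
  preds <- rbind(hit1, miss, hit2)
  expect_equal(average_precision_50(gt, preds), 5 / 6)

  expect_equal(average_precision_50(gt, rbind(hit1, hit2)), 1)
  expect_equal(average_precision_50(box(0, 0, 10, 10), miss), 0)
  expect_true(is.na(average_precision_50(gt[0, ], preds)))
})

test_that("AP is invariant to monotone transforms of confidence", {
  set.seed(11)
  fx <- generate_detection_fixtures(n_images = 40, seed = 11)
  ap1 <- average_precision_50(fx$annotations, fx$predictions)
  tr <- fx$predictions
  tr$confidence <- sqrt(tr$confidence)  # strictly monotone
  expect_equal(average_precision_50(fx$annotations, tr), ap1)
})

test_that("lowering the confidence threshold never decreases recall", {
  fx <- generate_detection_fixtures(n_images = 60, seed = 13)
  ids <- fx$image_ids
  recalls <- sapply(c(0.9, 0.7, 0.5, 0.3, 0.15), function(thr) {
    ms <- lapply(ids, function(id) {
      match_detections(fx$annotations[fx$annotations$image_id == id, ],
                       fx$predictions[fx$predictions$image_id == id, ],
                       conf_threshold = thr)
    })
    detection_pr(ms)$recall
  })
  expect_true(all(diff(recalls) >= 0))
})

test_that("confidence-threshold tuning follows the balanced objective", {
  gt <- box(0, 0, 10, 10, image_id = "a")
  pred <- box(0, 0, 10, 10, confidence = 0.9, image_id = "a")
  # perfect detector: tie across the grid, lowest threshold wins
  expect_equal(tune_confidence_threshold(gt, pred, c(0.1, 0.3, 0.5),
                                         image_ids = c("a", "b")), 0.1)
  expect_equal(tune_confidence_threshold(gt, pred, 0.4,
                                         image_ids = c("a", "b")), 0.4)

  # fixture where 0.13 uniquely maximizes the mean of the three metrics:
  # a true-positive at 0.14 and a false-positive at 0.12
  gt2 <- box(0, 0, 10, 10, image_id = "a")
  preds2 <- rbind(box(0, 0, 10, 10, confidence = 0.14, image_id = "a"),
                  box(0, 0, 10, 10, confidence = 0.12, image_id = "b"))
  grid <- c(0.05, 0.13, 0.2)
  # oracle: exhaustive scan of the objective
  obj <- sapply(grid, function(thr) {
    pp <- c("a", "b", "c") %in% preds2$image_id[preds2$confidence >= thr]
    m <- image_classification_metrics(c(TRUE, FALSE, FALSE), pp)
    mean(c(m$accuracy, m$sensitivity, m$specificity))
  })
  expect_equal(grid[which.max(obj)], 0.13)
  expect_equal(tune_confidence_threshold(gt2, preds2, grid,
                                         image_ids = c("a", "b", "c")), 0.13)
})

test_that("phenotype aggregation prioritizes plaque-positive images", {
  imgs <- data.frame(
    id = c(1, 1, 2, 2, 2),
    artery = c("left", "right", "left", "left", "right"),
    image_id = c("a", "b", "c", "d", "e"),
    n_boxes = c(2, 0, 0, 1, 0))
  ph <- aggregate_phenotypes(imgs, seed = 1)
  p1 <- ph[ph$id == 1, ]
  expect_equal(p1$plaque_count, 2L)
  expect_equal(p1$count_left, 2L)
  expect_equal(p1$count_right, 0L)
  expect_equal(p1$plaque_present, 1L)
  # the positive left image (1 box) is selected for individual 2
  p2 <- ph[ph$id == 2, ]
  expect_equal(p2$count_left, 1L)
  expect_equal(p2$plaque_present, 1L)

  empty <- data.frame(id = 3, artery = "left", image_id = "f", n_boxes = 0)
  ph3 <- aggregate_phenotypes(empty)
  expect_equal(ph3$plaque_present, 0L)
  expect_equal(ph3$plaque_count, 0L)
  expect_error(aggregate_phenotypes(imgs[0, ]), "zero images")
})
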