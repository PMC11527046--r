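#' Intersection-over-union of two boxes
#'
#' Boxes are axis-aligned rectangles in pixel coordinates with origin at the
#' top-left and half-open `[min, max)` intervals, so area is
#' `(x_max - x_min) * (y_max - y_min)` with no +1 correction.
#'
#' @param a,b boxes: numeric vectors `c(x_min, y_min, x_max, y_max)` or
#'   single-row data.frames with those columns.
#' @return IoU in \[0, 1\]; 0 for disjoint boxes.
#' @export
box_iou <- function(a, b) {
  a <- as_box(a); b <- as_box(b)
  inter_w <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  inter_h <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- inter_w * inter_h
  area <- function(x) (x[3] - x[1]) * (x[4] - x[2])
  union <- area(a) + area(b) - inter
  if (union <= 0) return(0)
  inter / union
}

as_box <- function(x) {
  if (is.data.frame(x)) {
    x <- as.numeric(x[1, c("x_min", "y_min", "x_max", "y_max")])
  }
  stopifnot(length(x) == 4, x[3] > x[1], x[4] > x[2])
  x
}

# IoU matrix between rows of two box data.frames (vectorized)
iou_matrix <- function(gt, preds) {
  ng <- nrow(gt); np <- nrow(preds)
  if (ng == 0 || np == 0) return(matrix(0, ng, np))
  gx1 <- gt$x_min; gy1 <- gt$y_min; gx2 <- gt$x_max; gy2 <- gt$y_max
  px1 <- preds$x_min; py1 <- preds$y_min; px2 <- preds$x_max; py2 <- preds$y_max
  iw <- pmax(0, outer(gx2, px2, pmin) - outer(gx1, px1, pmax))
  ih <- pmax(0, outer(gy2, py2, pmin) - outer(gy1, py1, pmax))
  inter <- iw * ih
  ga <- (gx2 - gx1) * (gy2 - gy1)
  pa <- (px2 - px1) * (py2 - py1)
  inter / (outer(ga, pa, `+`) - inter)
}

#' Match predicted boxes to ground truth within one image
#'
#' Predictions below the confidence threshold are discarded. Survivors are
#' visited in descending confidence order and each is matched greedily to
#' its highest-IoU still-unmatched ground-truth box, provided the IoU
#' reaches `iou_threshold` (the COCO-style matching rule).
#'
#' @param gt ground-truth box data.frame (possibly 0 rows).
#' @param preds predicted box data.frame with a `confidence` column.
#' @param conf_threshold minimum confidence retained (default 0.13).
#' @param iou_threshold minimum IoU for a match (default 0.5).
#' @return a `match_result` list: `pairs` (data.frame `gt_idx`, `pred_idx`,
#'   `iou`, indices into the input frames), `unmatched_gt` (false
#'   negatives), `unmatched_pred` (false positives among retained
#'   predictions), `n_discarded` (predictions below threshold).
#' @export
match_detections <- function(gt, preds, conf_threshold = 0.13,
                             iou_threshold = 0.5) {
  stopifnot(conf_threshold > 0, conf_threshold < 1,
            iou_threshold > 0, iou_threshold < 1)
  keep <- which(preds$confidence >= conf_threshold)
  n_discarded <- nrow(preds) - length(keep)
  kept <- preds[keep, , drop = FALSE]
  ord <- if (length(keep)) keep[order(-kept$confidence)] else integer()
  iou <- iou_matrix(gt, preds)
  matched_gt <- rep(FALSE, nrow(gt))
  pairs <- list()
  fps <- integer()
  for (p in ord) {
    cand <- which(!matched_gt & iou[, p] >= iou_threshold)
    if (length(cand)) {
      best <- cand[which.max(iou[cand, p])]
      matched_gt[best] <- TRUE
      pairs[[length(pairs) + 1L]] <-
        data.frame(gt_idx = best, pred_idx = p, iou = iou[best, p])
    } else {
      fps <- c(fps, p)
    }
  }
  res <- list(
    pairs = if (length(pairs)) do.call(rbind, pairs) else
      data.frame(gt_idx = integer(), pred_idx = integer(), iou = numeric()),
    unmatched_gt = which(!matched_gt),
    unmatched_pred = sort(fps),
    n_discarded = n_discarded)
  class(res) <- "match_result"
  res
}

#' Image-level plaque classification metrics
#'
#' An image counts as predicted positive when the prediction set contains
#' any bounding box (after confidence thresholding); true positive means
#' both annotation and prediction contain a box.
#'
#' @param gt_positive logical/0-1 vector: image contains a true box.
#' @param pred_positive logical/0-1 vector: image has any predicted box.
#' @return list with `accuracy`, `sensitivity`, `specificity`, `ppv` and a
#'   `counts` vector (tp, fp, fn, tn). Metrics with empty denominators are
#'   `NA`, not 0.
#' @export
image_classification_metrics <- function(gt_positive, pred_positive) {
  stopifnot(length(gt_positive) >= 1,
            length(gt_positive) == length(pred_positive))
  g <- as.logical(gt_positive); p <- as.logical(pred_positive)
  tp <- sum(g & p); fp <- sum(!g & p); fn <- sum(g & !p); tn <- sum(!g & !p)
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  list(accuracy = frac(tp + tn, length(g)),
       sensitivity = frac(tp, tp + fn),
       specificity = frac(tn, tn + fp),
       ppv = frac(tp, tp + fp),
       counts = c(tp = tp, fp = fp, fn = fn, tn = tn))
}

#' Box-level detection precision and recall
#'
#' Aggregates one or more [match_detections()] results: precision is
#' matched pairs over pairs plus false-positive boxes, recall is matched
#' pairs over pairs plus missed ground-truth boxes.
#'
#' @param matches a `match_result` or a list of them.
#' @return list with `precision`, `recall` and the aggregated `counts`.
#' @export
detection_pr <- function(matches) {
  if (inherits(matches, "match_result")) matches <- list(matches)
  pairs <- sum(vapply(matches, function(m) nrow(m$pairs), integer(1)))
  fp <- sum(vapply(matches, function(m) length(m$unmatched_pred), integer(1)))
  fn <- sum(vapply(matches, function(m) length(m$unmatched_gt), integer(1)))
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  list(precision = frac(pairs, pairs + fp),
       recall = frac(pairs, pairs + fn),
       counts = c(pairs = pairs, fp = fp, fn = fn))
}

#' Average precision at a fixed IoU threshold (single class)
#'
#' Predictions across all images are ranked by confidence; each is a true
#' positive if it matches a still-unmatched ground-truth box in its image at
#' IoU >= `iou_threshold`. AP is the area under the precision-recall curve
#' using all-point interpolation (the running-maximum precision envelope).
#' No confidence threshold is applied.
#'
#' @param gt ground-truth boxes with `image_id`.
#' @param preds predicted boxes with `image_id` and `confidence`.
#' @param iou_threshold match threshold, default 0.5 (AP@50).
#' @return AP in \[0, 1\]; `NA` when there are no ground-truth boxes.
#' @export
average_precision_50 <- function(gt, preds, iou_threshold = 0.5) {
  n_gt <- nrow(gt)
  if (n_gt == 0) return(NA_real_)
  if (nrow(preds) == 0) return(0)
  ord <- order(-preds$confidence)
  matched <- new.env(parent = emptyenv())
  tp <- logical(length(ord))
  for (i in seq_along(ord)) {
    p <- preds[ord[i], , drop = FALSE]
    g_idx <- which(gt$image_id == p$image_id)
    taken <- get0(p$image_id, envir = matched, ifnotfound = integer())
    g_idx <- setdiff(g_idx, taken)
    if (length(g_idx)) {
      ious <- iou_matrix(gt[g_idx, , drop = FALSE], p)[, 1]
      if (max(ious) >= iou_threshold) {
        best <- g_idx[which.max(ious)]
        matched[[p$image_id]] <- c(taken, best)
        tp[i] <- TRUE
      }
    }
  }
  cum_tp <- cumsum(tp)
  recall <- cum_tp / n_gt
  precision <- cum_tp / seq_along(tp)
  # precision envelope (running max from the right), all-point interpolation
  env <- rev(cummax(rev(precision)))
  r_prev <- c(0, recall[-length(recall)])
  sum((recall - r_prev) * env)
}

#' Tune the detector confidence threshold at the image level
#'
#' Scans a grid of confidence thresholds; at each, an image is predicted
#' positive when any predicted box survives the threshold. Returns the grid
#' value maximizing the unweighted mean of accuracy, sensitivity and
#' specificity; ties are broken toward the lowest threshold.
#'
#' @param gt ground-truth boxes with `image_id`.
#' @param preds predicted boxes with `image_id` and `confidence`.
#' @param grid candidate thresholds (non-empty).
#' @param image_ids full image universe (negative images carry no box rows).
#' @return the selected threshold.
#' @export
tune_confidence_threshold <- function(gt, preds, grid,
                                      image_ids = NULL) {
  stopifnot(length(grid) >= 1)
  ids <- image_ids %||% sort(unique(c(gt$image_id, preds$image_id)))
  gt_pos <- ids %in% gt$image_id
  grid <- sort(grid)
  score <- vapply(grid, function(thr) {
    pp <- ids %in% preds$image_id[preds$confidence >= thr]
    m <- image_classification_metrics(gt_pos, pp)
    mean(c(m$accuracy, m$sensitivity, m$specificity))
  }, numeric(1))
  grid[which.max(score)]
}

#' Aggregate per-image detections into per-individual plaque phenotypes
#'
#' For each individual and artery, one image is selected: plaque-positive
#' images are prioritized; among several positives one is chosen at random
#' (seeded). The plaque count of the selected image is taken per artery, the
#' individual's count is the left+right sum, and presence means count >= 1.
#'
#' @param image_boxes data.frame with columns `id` (individual), `artery`
#'   ("left"/"right"), `image_id`, `n_boxes`.
#' @param seed optional seed for the random choice among positive images.
#' @return data.frame with `id`, `plaque_present`, `plaque_count`,
#'   `count_left`, `count_right`. Individuals with zero images error.
#' @export
aggregate_phenotypes <- function(image_boxes, seed = NULL) {
  stopifnot(all(c("id", "artery", "image_id", "n_boxes") %in%
                  names(image_boxes)))
  if (nrow(image_boxes) == 0) stop("individual with zero images")
  if (!is.null(seed)) set.seed(seed)
  pick_count <- function(counts) {
    pos <- which(counts >= 1)
    if (!length(pos)) return(0L)
    if (length(pos) == 1L) return(counts[pos])
    counts[pos[sample.int(length(pos), 1L)]]
  }
  ids <- unique(image_boxes$id)
  out <- lapply(ids, function(i) {
    rows <- image_boxes[image_boxes$id == i, , drop = FALSE]
    cl <- pick_count(rows$n_boxes[rows$artery == "left"])
    cr <- pick_count(rows$n_boxes[rows$artery == "right"])
    data.frame(id = i, plaque_present = as.integer(cl + cr >= 1),
               plaque_count = as.integer(cl + cr),
               count_left = as.integer(cl), count_right = as.integer(cr))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' End-to-end detector evaluation on an annotated image set
#'
#' Convenience wrapper combining the image-level confusion matrix, box-level
#' precision/recall and AP@50 for a ground-truth/prediction pair.
#'
#' @inheritParams tune_confidence_threshold
#' @param conf_threshold confidence threshold for matching and image
#'   classification (default 0.13).
#' @param iou_threshold IoU threshold for box matching (default 0.5).
#' @return list with `image_metrics`, `detection` (precision/recall),
#'   `ap50` and the per-image `matches`.
#' @export
detect_eval <- function(gt, preds, image_ids = NULL,
                        conf_threshold = 0.13, iou_threshold = 0.5) {
  ids <- image_ids %||% sort(unique(c(gt$image_id, preds$image_id)))
  matches <- lapply(ids, function(id) {
    match_detections(gt[gt$image_id == id, , drop = FALSE],
                     preds[preds$image_id == id, , drop = FALSE],
                     conf_threshold, iou_threshold)
  })
  gt_pos <- ids %in% gt$image_id
  pred_pos <- ids %in% preds$image_id[preds$confidence >= conf_threshold]
  list(image_metrics = image_classification_metrics(gt_pos, pred_pos),
       detection = detection_pr(matches),
       ap50 = average_precision_50(gt, preds, iou_threshold),
       matches = matches)
}
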