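# shared fixture builders and independent oracles used across test files

box <- function(x_min, y_min, x_max, y_max, confidence = NULL,
                image_id = "img_0001") {
  b <- data.frame(image_id = image_id, x_min = x_min, y_min = y_min,
                  x_max = x_max, y_max = y_max)
  if (!is.null(confidence)) b$confidence <- confidence
  b
}

# exhaustive maximum-cardinality matching between gt and pred boxes at an
# IoU threshold; independent oracle for the greedy matcher
exhaustive_max_matching <- function(gt, preds, iou_threshold) {
  ng <- nrow(gt); np <- nrow(preds)
  if (ng == 0 || np == 0) return(0L)
  iou <- matrix(0, ng, np)
  for (i in seq_len(ng)) {
    for (j in seq_len(np)) {
      iou[i, j] <- box_iou(as.numeric(gt[i, c("x_min", "y_min", "x_max", "y_max")]),
                           as.numeric(preds[j, c("x_min", "y_min", "x_max", "y_max")]))
    }
  }
  feas <- iou >= iou_threshold
  best <- 0L
  recurse <- function(j, used) {
    if (j > np) return(0L)
    skip <- recurse(j + 1, used)
    take <- 0L
    for (i in which(feas[, j])) {
      if (!used[i]) {
        used2 <- used; used2[i] <- TRUE
        take <- max(take, 1L + recurse(j + 1, used2))
      }
    }
    max(skip, take)
  }
  recurse(1L, rep(FALSE, ng))
}

random_boxes <- function(k, canvas = c(width = 100, height = 100)) {
  if (k == 0) {
    return(data.frame(image_id = character(), x_min = numeric(),
                      y_min = numeric(), x_max = numeric(),
                      y_max = numeric()))
  }
  w <- runif(k, 10, 60); h <- runif(k, 10, 60)
  x0 <- runif(k, 0, canvas[["width"]] - w)
  y0 <- runif(k, 0, canvas[["height"]] - h)
  data.frame(image_id = "img_0001", x_min = x0, y_min = y0,
             x_max = x0 + w, y_max = y0 + h)
}

# small survival data set with known structure
uncensored_cohort <- function(n, seed = 1, t0 = 60) {
  set.seed(seed)
  risk_old <- runif(n, 0.01, 0.4)
  risk_new <- pmin(pmax(risk_old + rnorm(n, 0, 0.05), 0.001), 0.999)
  rate <- -log(1 - risk_old) / t0
  times <- rexp(n, rate)
  # everyone observed to the event or past the horizon: no censoring by t0
  events <- as.integer(times <= t0 + 20)
  times <- pmin(times, t0 + 20)
  data.frame(risk_old = risk_old, risk_new = risk_new,
             times = times, events = events)
}
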