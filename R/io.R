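#' Read and write cohort tables as TSV
#'
#' The on-disk format is plain tab-separated text with a header row using
#' the column names documented in [generate_cohort()]; lipids are stored in
#' mmol/L and follow-up in months.
#'
#' @param cohort a cohort table.
#' @param path file path.
#' @return `read_cohort_tsv` returns a `cohort_table` data.frame.
#' @export
write_cohort_tsv <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  class(d) <- c("cohort_table", "data.frame")
  d
}

#' Read and write cohort generator parameters as YAML
#'
#' @param params a [cohort_params()] object.
#' @param path file path.
#' @return `read_params_yaml` returns a `cohort_params` object.
#' @export
write_params_yaml <- function(params, path) {
  stopifnot(inherits(params, "cohort_params"))
  x <- unclass(params)
  x$covariate_means <- as.list(x$covariate_means)
  x$covariate_sds <- as.list(x$covariate_sds)
  x$fractions <- as.list(x$fractions)
  x$count_levels <- as.list(x$count_levels)
  x$event_type_probs <- as.list(x$event_type_probs)
  x$plaque_model$coef <- as.list(x$plaque_model$coef)
  x$hazard_model$log_hr <- as.list(x$hazard_model$log_hr)
  x$hazard_model$centers <- as.list(x$hazard_model$centers)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_params_yaml
#' @export
read_params_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  cohort_params(
    n_participants = x$n_participants,
    covariate_means = unlist(x$covariate_means),
    covariate_sds = unlist(x$covariate_sds),
    fractions = unlist(x$fractions),
    plaque_model = list(intercept = x$plaque_model$intercept,
                        coef = unlist(x$plaque_model$coef)),
    count_levels = unlist(x$count_levels),
    hazard_model = list(base_rate = x$hazard_model$base_rate,
                        log_hr = unlist(x$hazard_model$log_hr),
                        centers = unlist(x$hazard_model$centers)),
    admin_censor_months = x$admin_censor_months,
    followup_spread_months = x$followup_spread_months,
    event_type_probs = unlist(x$event_type_probs),
    seed = x$seed)
}

#' Read and write per-image bounding boxes as JSON
#'
#' One JSON record per image: `{image_id, boxes: [{x_min, y_min, x_max,
#' y_max, confidence?}]}`. Ground-truth boxes carry no confidence.
#'
#' @param boxes data.frame with `image_id`, corner columns and optionally
#'   `confidence`.
#' @param path file path.
#' @param image_ids optional image universe to serialize, so that images
#'   without boxes are represented with an empty box list.
#' @return `read_boxes_json` returns a list with `boxes` (data.frame) and
#'   `image_ids`.
#' @export
write_boxes_json <- function(boxes, path, image_ids = NULL) {
  ids <- image_ids %||% unique(boxes$image_id)
  cols <- intersect(c("x_min", "y_min", "x_max", "y_max", "confidence"),
                    names(boxes))
  recs <- lapply(ids, function(id) {
    b <- boxes[boxes$image_id == id, cols, drop = FALSE]
    rownames(b) <- NULL
    list(image_id = id, boxes = b)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_boxes_json
#' @export
read_boxes_json <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  ids <- vapply(recs, function(r) r$image_id, character(1))
  rows <- lapply(recs, function(r) {
    if (!length(r$boxes)) return(NULL)
    b <- do.call(rbind, lapply(r$boxes, function(bx)
      as.data.frame(bx, stringsAsFactors = FALSE)))
    b$image_id <- r$image_id
    b
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  boxes <- if (length(rows)) {
    out <- do.call(rbind, rows)
    front <- c("image_id", "x_min", "y_min", "x_max", "y_max")
    out[c(front, setdiff(names(out), front))]
  } else {
    data.frame(image_id = character(), x_min = numeric(), y_min = numeric(),
               x_max = numeric(), y_max = numeric())
  }
  rownames(boxes) <- NULL
  list(boxes = boxes, image_ids = ids)
}

#' Convert between pixel boxes and YOLO-format text lines
#'
#' YOLO text lines are `class x_center y_center width height` normalized to
#' the canvas, with an optional trailing confidence for predictions. The
#' single plaque class is written as class 0.
#'
#' @param boxes data.frame of boxes for one image (corner columns and
#'   optionally `confidence`).
#' @param canvas named vector `c(width=, height=)` in pixels.
#' @return `boxes_to_yolo` returns a character vector of lines;
#'   `yolo_to_boxes` returns a box data.frame in pixel corner coordinates.
#' @export
boxes_to_yolo <- function(boxes, canvas = c(width = 480, height = 448)) {
  if (!nrow(boxes)) return(character())
  w <- canvas[["width"]]; h <- canvas[["height"]]
  cx <- (boxes$x_min + boxes$x_max) / 2 / w
  cy <- (boxes$y_min + boxes$y_max) / 2 / h
  bw <- (boxes$x_max - boxes$x_min) / w
  bh <- (boxes$y_max - boxes$y_min) / h
  if ("confidence" %in% names(boxes)) {
    sprintf("0 %.8f %.8f %.8f %.8f %.8f", cx, cy, bw, bh, boxes$confidence)
  } else {
    sprintf("0 %.8f %.8f %.8f %.8f", cx, cy, bw, bh)
  }
}

#' @rdname boxes_to_yolo
#' @param lines character vector of YOLO lines.
#' @param image_id id to attach to the parsed boxes.
#' @export
yolo_to_boxes <- function(lines, canvas = c(width = 480, height = 448),
                          image_id = NA_character_) {
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(image_id = character(), x_min = numeric(),
                      y_min = numeric(), x_max = numeric(),
                      y_max = numeric()))
  }
  parts <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  w <- canvas[["width"]]; h <- canvas[["height"]]
  out <- data.frame(
    image_id = image_id,
    x_min = (parts[, 2] - parts[, 4] / 2) * w,
    y_min = (parts[, 3] - parts[, 5] / 2) * h,
    x_max = (parts[, 2] + parts[, 4] / 2) * w,
    y_max = (parts[, 3] + parts[, 5] / 2) * h)
  if (ncol(parts) >= 6) out$confidence <- parts[, 6]
  out
}

#' Write or read a directory of YOLO-format box files
#'
#' One `<image_id>.txt` per image; images without boxes get an empty file,
#' so the image universe round-trips.
#'
#' @param boxes box data.frame with `image_id`.
#' @param dir directory (created if needed).
#' @inheritParams boxes_to_yolo
#' @param image_ids image universe to write.
#' @return `read_boxes_yolo` returns a list with `boxes` and `image_ids`.
#' @export
write_boxes_yolo <- function(boxes, dir, canvas = c(width = 480, height = 448),
                             image_ids = NULL) {
  ids <- image_ids %||% unique(boxes$image_id)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in ids) {
    b <- boxes[boxes$image_id == id, , drop = FALSE]
    writeLines(boxes_to_yolo(b, canvas), file.path(dir, paste0(id, ".txt")))
  }
  invisible(dir)
}

#' @rdname write_boxes_yolo
#' @export
read_boxes_yolo <- function(dir, canvas = c(width = 480, height = 448)) {
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  ids <- sub("\\.txt$", "", basename(files))
  rows <- mapply(function(f, id) yolo_to_boxes(readLines(f), canvas, id),
                 files, ids, SIMPLIFY = FALSE)
  rows <- rows[vapply(rows, nrow, integer(1)) > 0]
  boxes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(image_id = character(), x_min = numeric(), y_min = numeric(),
               x_max = numeric(), y_max = numeric())
  rownames(boxes) <- NULL
  list(boxes = boxes, image_ids = ids)
}
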