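#' Convert between pixel and normalized bounding boxes
#'
#' Pixel boxes use 0-based inclusive min/max indices with
#' `width = xmax - xmin + 1`; normalized boxes are YOLO-style
#' `(cx, cy, w, h)` relative to image width/height. The two conversions are
#' mutually inverse for finite inputs.
#'
#' @param bbox_px Named vector `(xmin, ymin, xmax, ymax)` (0-based inclusive).
#' @param image_shape `(H, W)` in px.
#' @return `pixel_bbox_to_norm`: one-row data frame
#'   `(class, cx, cy, w, h)`; `norm_bbox_to_pixel`: numeric
#'   `(xmin, ymin, xmax, ymax)` (continuous).
#' @export
pixel_bbox_to_norm <- function(bbox_px, image_shape, class_id = 0L) {
  H <- image_shape[1]; W <- image_shape[2]
  data.frame(class = as.integer(class_id),
             cx = (bbox_px[["xmin"]] + bbox_px[["xmax"]] + 1) / 2 / W,
             cy = (bbox_px[["ymin"]] + bbox_px[["ymax"]] + 1) / 2 / H,
             w = (bbox_px[["xmax"]] - bbox_px[["xmin"]] + 1) / W,
             h = (bbox_px[["ymax"]] - bbox_px[["ymin"]] + 1) / H,
             row.names = NULL)
}

#' @rdname pixel_bbox_to_norm
#' @param bbox_norm One row of `(cx, cy, w, h)` (list or data frame row).
#' @param class_id Integer class id (always 0 = worm here).
#' @export
norm_bbox_to_pixel <- function(bbox_norm, image_shape) {
  H <- image_shape[1]; W <- image_shape[2]
  wpx <- bbox_norm$w * W; hpx <- bbox_norm$h * H
  xmin <- bbox_norm$cx * W - (wpx + 1) / 2 + 0.5
  ymin <- bbox_norm$cy * H - (hpx + 1) / 2 + 0.5
  c(xmin = xmin, ymin = ymin, xmax = xmin + wpx - 1, ymax = ymin + hpx - 1)
}

#' Tight bounding box of a binary mask
#'
#' Scans foreground indices for the tight 0-based inclusive pixel box and
#' converts it to a normalized YOLO row. A single foreground pixel yields a
#' box of width `1/W` — the inclusive convention guarantees every non-empty
#' mask a box of positive area.
#'
#' @param mask Logical matrix (or `worm_mask`).
#' @param image_shape `(H, W)`; defaults to `dim(mask)`.
#' @return One-row data frame `(class, cx, cy, w, h)`.
#' @export
mask_to_bbox <- function(mask, image_shape = NULL) {
  m <- if (inherits(mask, "worm_mask")) mask$raster else mask
  if (!any(m)) stop("cannot compute a bounding box of an empty mask")
  if (is.null(image_shape)) image_shape <- dim(m)
  pixel_bbox_to_norm(ws_mask_pixel_bbox(m), image_shape)
}

ws_validate_rows <- function(df, path, conf = FALSE) {
  bad <- function(i, msg)
    stop(sprintf("%s: line %d: %s", path, i, msg), call. = FALSE)
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (r$class < 0 || r$class != round(r$class)) bad(i, "invalid class id")
    if (!all(is.finite(as.numeric(r[c("cx", "cy", "w", "h")]))))
      bad(i, "non-finite box values")
    if (r$cx < 0 || r$cx > 1 || r$cy < 0 || r$cy > 1)
      bad(i, "box centre outside [0, 1]")
    if (r$w <= 0 || r$w > 1 || r$h <= 0 || r$h > 1)
      bad(i, "box size outside (0, 1]")
    if (conf && (!is.finite(r$conf) || r$conf < 0 || r$conf > 1))
      bad(i, "confidence outside [0, 1]")
  }
  invisible(TRUE)
}

ws_parse_yolo <- function(path, n_fields_ok, what) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (!(length(f) %in% n_fields_ok))
      stop(sprintf("%s: line %d: expected %s fields, got %d", path, i,
                   paste(n_fields_ok, collapse = " or "), length(f)),
           call. = FALSE)
    v <- suppressWarnings(as.numeric(f))
    if (any(is.na(v)))
      stop(sprintf("%s: line %d: non-numeric field", path, i), call. = FALSE)
    v
  })
  rows
}

#' Write / read YOLO-format label files
#'
#' One object per line, `class cx cy w h` space-separated at 6 decimal
#' places; an empty file denotes zero objects. Reading validates every row
#' (field count, finiteness, ranges) and reports the offending line number.
#' The write/read round trip is lossless at 6 decimals.
#'
#' @param labels Data frame with columns `class, cx, cy, w, h`.
#' @param path File path.
#' @return `read_yolo_labels` returns a data frame of the same shape.
#' @export
write_yolo_labels <- function(labels, path) {
  lines <- if (nrow(labels) == 0) character(0) else
    sprintf("%d %.6f %.6f %.6f %.6f", labels$class,
            labels$cx, labels$cy, labels$w, labels$h)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_yolo_labels
#' @export
read_yolo_labels <- function(path) {
  rows <- ws_parse_yolo(path, 5L, "label")
  df <- if (!length(rows))
    data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
               w = numeric(0), h = numeric(0))
  else {
    m <- do.call(rbind, rows)
    data.frame(class = as.integer(m[, 1]), cx = m[, 2], cy = m[, 3],
               w = m[, 4], h = m[, 5])
  }
  ws_validate_rows(df, path)
  df
}

#' Write / read YOLO-format detection files
#'
#' Detections use the 6-column inference dialect `class cx cy w h conf`.
#' Files whose rows lack the confidence column are accepted: confidences are
#' assumed 1.0 and the result carries the attribute
#' `missing_confidence = TRUE` plus a warning.
#'
#' @param detections Data frame with columns `class, cx, cy, w, h, conf`.
#' @param path File path.
#' @return `read_detections` returns a data frame
#'   `(class, cx, cy, w, h, conf)`.
#' @export
write_detections <- function(detections, path) {
  lines <- if (nrow(detections) == 0) character(0) else
    sprintf("%d %.6f %.6f %.6f %.6f %.6f", detections$class,
            detections$cx, detections$cy, detections$w, detections$h,
            detections$conf)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_yolo_labels
#' @export
read_detections <- function(path) {
  rows <- ws_parse_yolo(path, c(5L, 6L), "detection")
  missing_conf <- FALSE
  df <- if (!length(rows))
    data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
               w = numeric(0), h = numeric(0), conf = numeric(0))
  else {
    rows <- lapply(rows, function(v) {
      if (length(v) == 5) {
        missing_conf <<- TRUE
        v <- c(v, 1.0)
      }
      v
    })
    m <- do.call(rbind, rows)
    data.frame(class = as.integer(m[, 1]), cx = m[, 2], cy = m[, 3],
               w = m[, 4], h = m[, 5], conf = m[, 6])
  }
  ws_validate_rows(df, path, conf = TRUE)
  if (missing_conf) {
    warning(path, ": confidence column absent; assuming 1.0")
    attr(df, "missing_confidence") <- TRUE
  }
  df
}

#' Read a directory of YOLO label / detection files
#'
#' @param dir Directory containing `.txt` files, one per image; the file
#'   stem is the image id.
#' @return Named list of data frames, keyed by image id.
#' @export
read_label_dir <- function(dir) {
  fs <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  out <- lapply(fs, read_yolo_labels)
  names(out) <- sub("\\.txt$", "", basename(fs))
  out
}

#' @rdname read_label_dir
#' @export
read_detection_dir <- function(dir) {
  fs <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  out <- lapply(fs, read_detections)
  names(out) <- sub("\\.txt$", "", basename(fs))
  out
}
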