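#' Intersection over union of two boxes
#'
#' Boxes are continuous pixel rectangles `(xmin, ymin, xmax, ymax)` where
#' the box spans `[xmin, xmax + 1) x [ymin, ymax + 1)` (inclusive-pixel
#' convention), or normalized YOLO rows converted via
#' [norm_bbox_to_pixel()]. Disjoint boxes score 0; identical boxes 1.
#'
#' @param a,b Named numeric vectors `(xmin, ymin, xmax, ymax)`.
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(a, b) {
  wa <- a[["xmax"]] - a[["xmin"]] + 1; ha <- a[["ymax"]] - a[["ymin"]] + 1
  wb <- b[["xmax"]] - b[["xmin"]] + 1; hb <- b[["ymax"]] - b[["ymin"]] + 1
  if (wa <= 0 || ha <= 0 || wb <= 0 || hb <= 0)
    stop("degenerate (zero-area) box")
  iw <- min(a[["xmax"]], b[["xmax"]]) - max(a[["xmin"]], b[["xmin"]]) + 1
  ih <- min(a[["ymax"]], b[["ymax"]]) - max(a[["ymin"]], b[["ymin"]]) + 1
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (wa * ha + wb * hb - inter)
}

# IoU matrix between normalized detection rows and ground-truth rows
ws_iou_matrix <- function(det, gt, image_shape) {
  db <- lapply(seq_len(nrow(det)), function(i)
    norm_bbox_to_pixel(det[i, ], image_shape))
  gb <- lapply(seq_len(nrow(gt)), function(j)
    norm_bbox_to_pixel(gt[j, ], image_shape))
  m <- matrix(0, nrow(det), nrow(gt))
  for (i in seq_len(nrow(det)))
    for (j in seq_len(nrow(gt)))
      m[i, j] <- iou(db[[i]], gb[[j]])
  m
}

#' Match detections to ground truth
#'
#' Greedy confidence-ordered matching (the PASCAL-VOC convention):
#' detections are processed in decreasing confidence (ties broken by row
#' order), each matched to the unmatched ground-truth box of highest IoU at
#' or above the threshold. Matched detections are true positives, the rest
#' false positives; unmatched ground truths count as false negatives.
#'
#' @param detections Data frame `(class, cx, cy, w, h, conf)`.
#' @param ground_truths Data frame `(class, cx, cy, w, h)`.
#' @param iou_threshold IoU threshold in `(0, 1]`; default 0.5.
#' @param image_shape `(H, W)` used to denormalize boxes; IoU is invariant
#'   to it when both inputs share it, default `c(1000, 1000)`.
#' @return An object of class `match_result`: list with `tp` (logical flags
#'   in confidence order), `conf` (the ordered confidences), `fn`, `n_gt`
#'   and `iou_threshold`.
#' @export
match_detections <- function(detections, ground_truths, iou_threshold = 0.5,
                             image_shape = c(1000, 1000)) {
  if (!is.finite(iou_threshold) || iou_threshold <= 0 || iou_threshold > 1)
    stop("iou_threshold must lie in (0, 1]")
  nd <- nrow(detections); ng <- nrow(ground_truths)
  ord <- if (nd) order(-detections$conf) else integer(0)
  det <- detections[ord, , drop = FALSE]
  tp <- logical(nd)
  if (nd && ng) {
    m <- ws_iou_matrix(det, ground_truths, image_shape)
    taken <- logical(ng)
    for (i in seq_len(nd)) {
      ious <- m[i, ]
      ious[taken] <- -1
      j <- which.max(ious)
      if (ious[j] >= iou_threshold) {
        tp[i] <- TRUE
        taken[j] <- TRUE
      }
    }
  }
  structure(list(tp = tp, conf = if (nd) det$conf else numeric(0),
                 fn = ng - sum(tp), n_gt = ng,
                 iou_threshold = iou_threshold),
            class = "match_result")
}

#' Precision and recall
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`. A zero
#' denominator returns 0 with the attribute `degenerate = TRUE` rather than
#' failing, so batch evaluation is robust.
#'
#' @param tp,fp,fn Counts.
#' @return A number in `[0, 1]`, possibly flagged `degenerate`.
#' @export
precision <- function(tp, fp) {
  if (tp + fp == 0) return(structure(0, degenerate = TRUE))
  tp / (tp + fp)
}

#' @rdname precision
#' @export
recall <- function(tp, fn) {
  if (tp + fn == 0) return(structure(0, degenerate = TRUE))
  tp / (tp + fn)
}

#' Precision-recall curve from pooled matches
#'
#' Pools the TP/FP flags of one or more [match_detections()] results,
#' orders them by decreasing confidence (ties by input order) and
#' accumulates precision and recall after each detection.
#'
#' @param matches A `match_result` or list of them.
#' @return An object of class `pr_curve`: data frame
#'   `(conf, tp, precision, recall)` plus attributes `n_gt`.
#' @export
pr_curve <- function(matches) {
  if (inherits(matches, "match_result")) matches <- list(matches)
  conf <- unlist(lapply(matches, `[[`, "conf"))
  tp <- unlist(lapply(matches, `[[`, "tp"))
  n_gt <- sum(vapply(matches, `[[`, numeric(1), "n_gt"))
  ord <- order(-conf)
  conf <- conf[ord]; tp <- tp[ord]
  ctp <- cumsum(tp); cfp <- cumsum(!tp)
  prec <- if (length(tp)) ctp / (ctp + cfp) else numeric(0)
  rec <- if (n_gt > 0) ctp / n_gt else rep(0, length(tp))
  structure(data.frame(conf = conf, tp = tp, precision = prec, recall = rec),
            n_gt = n_gt, class = c("pr_curve", "data.frame"))
}

#' Average precision
#'
#' Area under the precision-recall curve, `AP = integral of P(R) dR` over
#' recall in `[0, 1]`. The default integrates the monotone (right-maximum)
#' precision envelope exactly over all curve points; `method = "interp101"`
#' instead averages the envelope at 101 equally spaced recall values, the
#' convention of the YOLO tooling, for comparability (differences are below
#' 0.01 on realistic curves).
#'
#' @param curve A [pr_curve()] object.
#' @param method `"exact"` (all-points envelope area) or `"interp101"`.
#' @return AP in `[0, 1]`; 0 when there are no detections or no ground
#'   truths.
#' @export
average_precision <- function(curve, method = c("exact", "interp101")) {
  method <- match.arg(method)
  n_gt <- attr(curve, "n_gt")
  if (!nrow(curve) || is.null(n_gt) || n_gt == 0) return(0)
  mrec <- c(0, curve$recall, 1)
  mpre <- c(1, curve$precision, 0)
  # right-maximum envelope
  for (i in (length(mpre) - 1):1) mpre[i] <- max(mpre[i], mpre[i + 1])
  if (method == "exact") {
    sum(diff(mrec) * mpre[-1])
  } else {
    r <- seq(0, 1, length.out = 101)
    env <- vapply(r, function(x) {
      j <- which(mrec >= x)
      if (length(j)) mpre[j[1]] else 0
    }, numeric(1))
    mean(env)
  }
}

#' Evaluate a detection set against ground truth
#'
#' Matches detections per image at the IoU threshold, pools all detections
#' across images with a global confidence ranking, and reports precision and
#' recall at the end of the ranked list together with the average precision
#' of the pooled curve (AP@0.5 at the default threshold).
#'
#' @param detections Named list of detection data frames, keyed by image id.
#' @param labels Named list of label data frames with the same keys.
#' @param iou_threshold IoU threshold, default 0.5.
#' @param image_shape `(H, W)` for denormalization (shared by all images).
#' @param method AP integration method, see [average_precision()].
#' @return An object of class `ap_result`: list with `precision`, `recall`,
#'   `ap`, counts `tp/fp/fn`, `per_image` data frame, and the pooled
#'   `curve`.
#' @export
evaluate_dataset <- function(detections, labels, iou_threshold = 0.5,
                             image_shape = c(1000, 1000),
                             method = "exact") {
  ids <- names(labels)
  extra <- setdiff(names(detections), ids)
  if (length(extra))
    stop("detections refer to unknown image ids: ",
         paste(utils::head(extra, 5), collapse = ", "))
  matches <- lapply(ids, function(id) {
    det <- detections[[id]]
    if (is.null(det))
      det <- data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                        w = numeric(0), h = numeric(0), conf = numeric(0))
    match_detections(det, labels[[id]], iou_threshold, image_shape)
  })
  per_image <- data.frame(
    image = ids,
    tp = vapply(matches, function(m) sum(m$tp), numeric(1)),
    fp = vapply(matches, function(m) sum(!m$tp), numeric(1)),
    fn = vapply(matches, `[[`, numeric(1), "fn"))
  curve <- pr_curve(matches)
  tp <- sum(per_image$tp); fp <- sum(per_image$fp); fn <- sum(per_image$fn)
  structure(list(precision = precision(tp, fp), recall = recall(tp, fn),
                 ap = average_precision(curve, method), tp = tp, fp = fp,
                 fn = fn, iou_threshold = iou_threshold,
                 per_image = per_image, curve = curve),
            class = "ap_result")
}

#' @export
print.ap_result <- function(x, ...) {
  cat(sprintf("Detection evaluation (IoU >= %.2f)\n", x$iou_threshold))
  cat(sprintf("  images: %d   TP: %d   FP: %d   FN: %d\n",
              nrow(x$per_image), x$tp, x$fp, x$fn))
  cat(sprintf("  Precision: %.3f   Recall: %.3f   AP: %.3f\n",
              as.numeric(x$precision), as.numeric(x$recall), x$ap))
  invisible(x)
}
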