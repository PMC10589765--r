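# Independent oracles used to cross-check package computations.
# These deliberately use different algorithms / data paths than the package.

# IoU of two inclusive integer pixel boxes by explicit lattice counting.
oracle_iou_pixels <- function(a, b) {
  ax <- a["xmin"]:a["xmax"]; ay <- a["ymin"]:a["ymax"]
  bx <- b["xmin"]:b["xmax"]; by <- b["ymin"]:b["ymax"]
  inter <- length(intersect(ax, bx)) * length(intersect(ay, by))
  union <- length(ax) * length(ay) + length(bx) * length(by) - inter
  inter / union
}

# Greedy best-first matching recomputed naively from integer pixel boxes.
# Returns the TP count.
oracle_match_tp <- function(det_boxes, det_conf, gt_boxes, thr) {
  ord <- order(-det_conf)
  taken <- rep(FALSE, length(gt_boxes))
  tp <- 0
  for (i in ord) {
    best <- 0; bj <- 0
    for (j in seq_along(gt_boxes)) {
      if (taken[j]) next
      v <- oracle_iou_pixels(det_boxes[[i]], gt_boxes[[j]])
      if (v > best) { best <- v; bj <- j }
    }
    if (bj > 0 && best >= thr) { tp <- tp + 1; taken[bj] <- TRUE }
  }
  tp
}

# AP by dense numerical integration of the interpolated precision envelope
# p(r) = max{ precision(k) : recall(k) >= r }, evaluated on a fine grid.
oracle_ap <- function(conf, tp, n_gt, grid_n = 20000) {
  if (!length(conf) || n_gt == 0) return(0)
  ord <- order(-conf)
  tp <- tp[ord]
  ctp <- cumsum(tp)
  prec <- ctp / seq_along(tp)
  rec <- ctp / n_gt
  r <- (seq_len(grid_n) - 0.5) / grid_n
  env <- vapply(r, function(x) {
    ok <- rec >= x
    if (any(ok)) max(prec[ok]) else 0
  }, numeric(1))
  mean(env)
}

# Tight bbox of a mask by a raw per-pixel index scan.
oracle_mask_bbox <- function(mask) {
  hits <- which(mask)
  rr <- ((hits - 1) %% nrow(mask)) + 1
  cc <- ((hits - 1) %/% nrow(mask)) + 1
  c(xmin = min(cc) - 1, ymin = min(rr) - 1, xmax = max(cc) - 1, ymax = max(rr) - 1)
}

# Does segment (p1,p2) properly intersect segment (p3,p4)?
oracle_seg_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p1, p2, p3); d2 <- d(p1, p2, p4)
  d3 <- d(p3, p4, p1); d4 <- d(p3, p4, p2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

# O(n^2) loop over all non-adjacent segment pairs of a polyline.
oracle_polyline_selfintersects <- function(pts) {
  n <- nrow(pts) - 1
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (oracle_seg_intersect(pts[i, ], pts[i + 1, ], pts[j, ], pts[j + 1, ]))
        return(TRUE)
    }
  }
  FALSE
}

# random normalized YOLO boxes that survive 6-decimal serialization exactly
random_yolo_labels <- function(n) {
  cx <- round(runif(n, 0.2, 0.8), 6)
  cy <- round(runif(n, 0.2, 0.8), 6)
  w <- round(runif(n, 0.01, 0.3), 6)
  h <- round(runif(n, 0.01, 0.3), 6)
  data.frame(class = rep(0L, n), cx = cx, cy = cy, w = w, h = h)
}
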