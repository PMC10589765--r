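box <- function(xmin, ymin, xmax, ymax)
  c(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax)

test_that("IoU matches analytic cases", {
  a <- box(0, 0, 9, 9)           # 10 x 10 box (inclusive pixels)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, box(20, 20, 29, 29)), 0)
  # half-overlapping equal boxes: 50 / 150 = 1/3
  expect_equal(iou(box(0, 0, 9, 9), box(5, 0, 14, 9)), 1 / 3)
  expect_error(iou(a, box(5, 5, 3, 3)), "degenerate")
})

test_that("matching is greedy in confidence with single-use ground truths", {
  gt <- data.frame(class = 0L, cx = 0.3, cy = 0.3, w = 0.2, h = 0.2)
  # two detections on one ground truth: one TP, one FP
  det <- data.frame(class = 0L, cx = c(0.3, 0.31), cy = c(0.3, 0.3),
                    w = 0.2, h = 0.2, conf = c(0.9, 0.8))
  m <- match_detections(det, gt)
  expect_equal(m$tp, c(TRUE, FALSE))
  expect_equal(m$fn, 0)
  # perfect one-to-one: all TP
  m2 <- match_detections(cbind(gt, conf = 1), gt)
  expect_true(all(m2$tp))
  expect_error(match_detections(det, gt, iou_threshold = 0), "0, 1")
})

test_that("matching TP count agrees with a naive best-first oracle", {
  withr::with_seed(13, {
    for (rep in 1:40) {
      n_gt <- sample(0:6, 1); n_det <- sample(0:6, 1)
      mk <- function(n) lapply(seq_len(n), function(i) {
        x <- sample(0:40, 1); y <- sample(0:40, 1)
        box(x, y, x + sample(5:20, 1), y + sample(5:20, 1))
      })
      gtb <- mk(n_gt); detb <- mk(n_det)
      conf <- runif(n_det)
      shape <- c(64, 64)
      gt_df <- if (n_gt) do.call(rbind, lapply(gtb, pixel_bbox_to_norm, shape)) else
        data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                   w = numeric(0), h = numeric(0))
      det_df <- if (n_det) {
        d <- do.call(rbind, lapply(detb, pixel_bbox_to_norm, shape))
        d$conf <- conf
        d
      } else data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                        w = numeric(0), h = numeric(0), conf = numeric(0))
      m <- match_detections(det_df, gt_df, 0.5, shape)
      expect_equal(sum(m$tp), oracle_match_tp(detb, conf, gtb, 0.5))
      expect_equal(sum(m$tp) + m$fn, n_gt)
    }
  })
})

test_that("precision and recall handle the degenerate zero denominator", {
  expect_equal(precision(8, 2), 0.8)
  expect_equal(recall(8, 8), 0.5)
  p0 <- precision(0, 0)
  expect_equal(as.numeric(p0), 0)
  expect_true(isTRUE(attr(p0, "degenerate")))
})

test_that("AP reproduces hand-computed curves", {
  # 2 GTs; confidences .9 TP, .8 FP, .7 TP -> envelope 1 on [0,.5], 2/3 after
  m <- structure(list(tp = c(TRUE, FALSE, TRUE), conf = c(0.9, 0.8, 0.7),
                      fn = 0, n_gt = 2, iou_threshold = 0.5),
                 class = "match_result")
  curve <- pr_curve(m)
  expect_true(all(diff(curve$recall) >= 0))
  expect_equal(average_precision(curve), 0.5 + 0.5 * 2 / 3, tolerance = 1e-12)
  # single GT, single TP -> AP 1; no detections -> AP 0
  m1 <- structure(list(tp = TRUE, conf = 1, fn = 0, n_gt = 1,
                       iou_threshold = 0.5), class = "match_result")
  expect_equal(average_precision(pr_curve(m1)), 1)
  m0 <- structure(list(tp = logical(0), conf = numeric(0), fn = 1, n_gt = 1,
                       iou_threshold = 0.5), class = "match_result")
  expect_equal(average_precision(pr_curve(m0)), 0)
})

test_that("AP equals the threshold-sweep oracle on all small instances", {
  withr::with_seed(31, {
    for (rep in 1:60) {
      n_det <- sample(0:10, 1)
      n_gt <- sample(1:10, 1)
      tp <- rep(FALSE, n_det)
      if (n_det) tp[runif(n_det) < 0.5] <- TRUE
      # at most n_gt TPs
      if (sum(tp) > n_gt) tp[which(tp)[-seq_len(n_gt)]] <- FALSE
      conf <- runif(n_det)
      m <- structure(list(tp = tp[order(-conf)], conf = sort(conf, decreasing = TRUE),
                          fn = n_gt - sum(tp), n_gt = n_gt,
                          iou_threshold = 0.5), class = "match_result")
      got <- average_precision(pr_curve(m))
      expect_equal(got, oracle_ap(conf, tp, n_gt), tolerance = 1e-3)
    }
  })
})

test_that("AP is invariant to monotone confidence transforms and to added FPs", {
  withr::with_seed(7, {
    conf <- sort(runif(8), decreasing = TRUE)
    tp <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE)
    mk <- function(conf, tp, n_gt = 5)
      structure(list(tp = tp, conf = conf, fn = n_gt - sum(tp), n_gt = n_gt,
                     iou_threshold = 0.5), class = "match_result")
    base <- average_precision(pr_curve(mk(conf, tp)))
    for (f in list(function(x) x^3, function(x) exp(x), function(x) 0.1 + 0.5 * x))
      expect_equal(average_precision(pr_curve(mk(f(conf), tp))), base)
    # appending a lowest-confidence FP never increases AP
    worse <- average_precision(pr_curve(mk(c(conf, min(conf) / 2), c(tp, FALSE))))
    expect_lte(worse, base)
    # the 101-point interpolated variant stays close to the exact area
    expect_equal(average_precision(pr_curve(mk(conf, tp)), method = "interp101"),
                 base, tolerance = 0.01)
  })
})

test_that("dataset evaluation pools detections globally", {
  ds <- cached_scene_set(20, seed = 31)
  # ground truth re-fed as perfect unit-confidence detections
  perfect <- lapply(ds$labels, function(l) cbind(l, conf = 1))
  ev <- evaluate_dataset(perfect, ds$labels, image_shape = c(640, 640))
  expect_equal(as.numeric(ev$precision), 1)
  expect_equal(as.numeric(ev$recall), 1)
  expect_equal(ev$ap, 1)
  # empty detections: degenerate precision, zero recall and AP
  none <- lapply(ds$labels, function(l) perfect[[1]][0, ])
  ev0 <- evaluate_dataset(none, ds$labels, image_shape = c(640, 640))
  expect_true(isTRUE(attr(ev0$precision, "degenerate")))
  expect_equal(as.numeric(ev0$recall), 0)
  expect_equal(ev0$ap, 0)
  expect_error(evaluate_dataset(list(zzz = perfect[[1]]), ds$labels),
               "unknown image ids")
})

test_that("pooled AP agrees with an independently coded single pass", {
  ds <- cached_scene_set(20, seed = 31)
  dets <- lapply(seq_along(ds$scenes), function(i) {
    l <- ds$labels[[i]]
    withr::with_seed(1000 + i, {
      keep <- runif(nrow(l)) < 0.8           # drop some -> FNs
      d <- l[keep, , drop = FALSE]
      if (nrow(d)) {                          # perturb some boxes -> FPs
        d$cx <- pmin(pmax(d$cx + rnorm(nrow(d), 0, 0.01), 0), 1)
        d$conf <- runif(nrow(d))
      } else d$conf <- numeric(0)
      d
    })
  })
  names(dets) <- names(ds$labels)
  ev <- evaluate_dataset(dets, ds$labels, image_shape = c(640, 640))
  # oracle: flatten per-image flags, then integrate the envelope densely
  flags <- lapply(names(ds$labels), function(id)
    match_detections(dets[[id]], ds$labels[[id]], 0.5, c(640, 640)))
  conf <- unlist(lapply(flags, `[[`, "conf"))
  tp <- unlist(lapply(flags, `[[`, "tp"))
  n_gt <- sum(vapply(ds$labels, nrow, numeric(1)))
  expect_equal(ev$ap, oracle_ap(conf, tp, n_gt), tolerance = 1e-3)
})
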