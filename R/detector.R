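#' Baseline detector parameters
#'
#' A classical, training-free worm detector used to exercise the
#' self-labeling and evaluation pipelines end to end on a CPU. The pipeline
#' is: background flattening (subtract a large-kernel Gaussian estimate of
#' the background) -> polarity-resolved residual -> Otsu threshold, floored
#' at a robust noise level -> connected components -> area and elongation
#' filters -> component bounding boxes. Component confidence is its
#' normalized mean absolute residual.
#'
#' @param flatten_kernel_px Gaussian sigma (px) of the background estimate;
#'   must be much larger than the worm half-width. Default 25.
#' @param polarity `"auto"` (resolved from the residual skew sign),
#'   `"dark"` (dark worms) or `"light"`.
#' @param min_area_px,max_area_px Component area bounds in px
#'   (`min < max`).
#' @param min_elongation Minimum major/minor second-moment axis ratio;
#'   suppresses round speckle that is not worm-shaped. Default 1.3: round
#'   blobs sit at 1 while even a tightly curled worm scores above ~1.3.
#' @param max_detections Per-image cap on the number of emitted boxes,
#'   highest confidence first (`Inf` = unlimited). Mirrors the
#'   `--max-detect` inference cap of detector toolkits.
#' @return An object of class `detector_params`.
#' @export
detector_params <- function(flatten_kernel_px = 25,
                            polarity = c("auto", "dark", "light"),
                            min_area_px = 150, max_area_px = 1e6,
                            min_elongation = 1.3, max_detections = Inf) {
  polarity <- match.arg(polarity)
  if (min_area_px >= max_area_px) stop("min_area_px must be < max_area_px")
  if (flatten_kernel_px <= 0) stop("flatten_kernel_px must be positive")
  structure(list(flatten_kernel_px = flatten_kernel_px, polarity = polarity,
                 min_area_px = min_area_px, max_area_px = max_area_px,
                 min_elongation = min_elongation,
                 max_detections = max_detections),
            class = "detector_params")
}

# major/minor axis ratio from second moments of pixel coordinates
ws_elongation <- function(ys, xs) {
  if (length(xs) < 2) return(1)
  cxx <- stats::var(xs); cyy <- stats::var(ys); cxy <- stats::cov(xs, ys)
  tr <- cxx + cyy
  det <- cxx * cyy - cxy^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  if (l2 <= 1e-9) return(Inf)
  sqrt(l1 / l2)
}

#' Detect worms in an image
#'
#' @param image Grayscale matrix or RGB array with values in `[0, 1]`
#'   (RGB is averaged to luminance).
#' @param params A [detector_params()] object.
#' @return Detection data frame `(class, cx, cy, w, h, conf)` sorted by
#'   decreasing confidence, normalized to the image size.
#' @examples
#' sc <- generate_scene(seed = 3, spec = scene_spec(n_worms = 2))
#' detect_worms(sc$image)
#' @export
detect_worms <- function(image, params = detector_params()) {
  ws_stopifnot_image(image)
  img <- if (is.matrix(image)) image else
    (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  empty <- data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0), conf = numeric(0))
  bg <- ws_gblur(img, sigma = params$flatten_kernel_px)
  residual <- img - bg
  pol <- params$polarity
  if (pol == "auto") {
    # dark worms leave a negative-skewed residual
    rv <- as.vector(residual)
    m3 <- mean((rv - mean(rv))^3)
    pol <- if (m3 <= 0) "dark" else "light"
  }
  signal <- if (pol == "dark") pmax(-residual, 0) else pmax(residual, 0)
  smax <- max(signal)
  if (smax < 5e-3) return(empty)
  # Otsu picks the worm/background split when worms are present; the robust
  # noise floor (6 x MAD of the flattened residual) stops pure-noise images
  # from being segmented into spurious blobs
  noise_floor <- 6 * stats::mad(as.vector(residual), center = 0)
  thr <- max(EBImage::otsu(signal, range = c(0, smax)), noise_floor)
  if (thr >= smax) return(empty)
  bw <- signal > thr
  lab <- ws_label8(bw)
  n <- max(lab)
  if (n == 0) return(empty)
  idx <- which(lab > 0, arr.ind = TRUE)
  comp <- lab[lab > 0]
  dets <- list()
  H <- nrow(img); W <- ncol(img)
  for (k in seq_len(n)) {
    sel <- comp == k
    ys <- idx[sel, 1]; xs <- idx[sel, 2]
    area <- length(xs)
    if (area < params$min_area_px || area > params$max_area_px) next
    if (ws_elongation(ys, xs) < params$min_elongation) next
    bb <- c(xmin = min(xs) - 1L, ymin = min(ys) - 1L,
            xmax = max(xs) - 1L, ymax = max(ys) - 1L)
    conf_raw <- mean(signal[cbind(ys, xs)])
    row <- pixel_bbox_to_norm(bb, c(H, W))
    row$conf <- conf_raw
    dets[[length(dets) + 1]] <- row
  }
  if (!length(dets)) return(empty)
  out <- do.call(rbind, dets)
  out$conf <- out$conf / max(out$conf)  # normalize into (0, 1]
  out <- out[order(-out$conf), , drop = FALSE]
  if (is.finite(params$max_detections) && nrow(out) > params$max_detections)
    out <- out[seq_len(params$max_detections), , drop = FALSE]
  rownames(out) <- NULL
  out
}
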