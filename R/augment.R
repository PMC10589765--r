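#' Augmentation configuration
#'
#' Defaults follow the standard single-stage-detector training recipe:
#' HSV gains H = 0.015, S = 0.7, V = 0.4, translation 0.1, scale 0.5,
#' horizontal-flip probability 0.5 and mosaic probability 1.
#'
#' @param hsv_h,hsv_s,hsv_v Per-channel HSV gain half-ranges (`>= 0`).
#' @param translate Maximum translation as a fraction of each dimension.
#' @param scale Scale half-range; scale factors are drawn in
#'   `[1 - scale, 1 + scale]`.
#' @param fliplr_p Horizontal flip probability.
#' @param mosaic_p Mosaic probability.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(hsv_h = 0.015, hsv_s = 0.7, hsv_v = 0.4,
                           translate = 0.1, scale = 0.5, fliplr_p = 0.5,
                           mosaic_p = 1.0) {
  for (g in c(hsv_h, hsv_s, hsv_v, translate, scale))
    if (!is.finite(g) || g < 0) stop("gains must be >= 0")
  for (p in c(fliplr_p, mosaic_p))
    if (!is.finite(p) || p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  structure(list(hsv_h = hsv_h, hsv_s = hsv_s, hsv_v = hsv_v,
                 translate = translate, scale = scale, fliplr_p = fliplr_p,
                 mosaic_p = mosaic_p),
            class = "augment_config")
}

# numeric HSV -> RGB (h, s, v in [0, 1]); inverse of grDevices::rgb2hsv
ws_hsv2rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- g <- b <- v
  m <- i == 0; r[m] <- v[m]; g[m] <- t[m]; b[m] <- p[m]
  m <- i == 1; r[m] <- q[m]; g[m] <- v[m]; b[m] <- p[m]
  m <- i == 2; r[m] <- p[m]; g[m] <- v[m]; b[m] <- t[m]
  m <- i == 3; r[m] <- p[m]; g[m] <- q[m]; b[m] <- v[m]
  m <- i == 4; r[m] <- t[m]; g[m] <- p[m]; b[m] <- v[m]
  m <- i >= 5; r[m] <- v[m]; g[m] <- p[m]; b[m] <- q[m]
  list(r = r, g = g, b = b)
}

#' HSV colour jitter
#'
#' Draws one multiplicative gain per channel, `r ~ U(1 - g, 1 + g)`,
#' converts to HSV, applies the gains (hue wraps around, saturation and
#' value clip to `[0, 1]`) and converts back. Grayscale images carry no hue
#' or saturation, so they receive the value gain only. All-zero gains leave
#' the image untouched.
#'
#' @param image Matrix (grayscale) or `H x W x 3` RGB array, values in
#'   `[0, 1]`.
#' @param gains Numeric `(h, s, v)` gain half-ranges.
#' @param seed Optional integer seed.
#' @return Image of the same shape, values in `[0, 1]`.
#' @export
hsv_jitter <- function(image, gains = c(0.015, 0.7, 0.4), seed = NULL) {
  ws_stopifnot_image(image)
  if (all(gains == 0)) return(image)
  ws_with_seed(seed, {
    r <- 1 + runif(3, -1, 1) * gains
    if (is.matrix(image)) return(ws_clip01(image * r[3]))
    rgb <- matrix(c(image[, , 1], image[, , 2], image[, , 3]), nrow = 3,
                  byrow = TRUE)
    hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
    h <- (hsv[1, ] * r[1]) %% 1
    s <- ws_clip01(hsv[2, ] * r[2])
    v <- ws_clip01(hsv[3, ] * r[3])
    out <- ws_hsv2rgb(h, s, v)
    array(c(out$r, out$g, out$b), dim = dim(image))
  })
}

# transform continuous pixel box corners by x' = a*x + tx (per axis),
# with optional horizontal flip over width W
ws_transform_boxes <- function(labels, image_shape, sc, tx, ty, flip,
                               out_shape = image_shape, min_area_px = 8) {
  if (nrow(labels) == 0) return(labels)
  H <- image_shape[1]; W <- image_shape[2]
  oH <- out_shape[1]; oW <- out_shape[2]
  cxp <- labels$cx * W; cyp <- labels$cy * H
  wp <- labels$w * W; hp <- labels$h * H
  x1 <- cxp - wp / 2; x2 <- cxp + wp / 2
  y1 <- cyp - hp / 2; y2 <- cyp + hp / 2
  cx0 <- (W - 1) / 2; cy0 <- (H - 1) / 2
  x1 <- sc * (x1 - cx0) + cx0 + tx; x2 <- sc * (x2 - cx0) + cx0 + tx
  y1 <- sc * (y1 - cy0) + cy0 + ty; y2 <- sc * (y2 - cy0) + cy0 + ty
  if (flip) {
    fx1 <- W - x2; fx2 <- W - x1
    x1 <- fx1; x2 <- fx2
  }
  # clip to output canvas, drop boxes with too little visible area
  x1c <- pmax(x1, 0); x2c <- pmin(x2, oW)
  y1c <- pmax(y1, 0); y2c <- pmin(y2, oH)
  vis <- pmax(x2c - x1c, 0) * pmax(y2c - y1c, 0)
  keep <- vis >= min_area_px
  data.frame(class = labels$class[keep],
             cx = ((x1c + x2c) / 2 / oW)[keep],
             cy = ((y1c + y2c) / 2 / oH)[keep],
             w = ((x2c - x1c) / oW)[keep],
             h = ((y2c - y1c) / oH)[keep])
}

#' Geometric augmentation (scale, translate, horizontal flip)
#'
#' Draws a uniform scale in `[1 - scale, 1 + scale]` about the image centre,
#' a translation up to `+/- translate` of each dimension, and a horizontal
#' flip with probability `fliplr_p`; applies the same affine map to the
#' image (bilinear, out-of-canvas filled with the image median) and to the
#' labels. Boxes are clipped to the canvas and dropped when their visible
#' area falls below 8 px^2. With `translate = 0`, `scale = 0`, `fliplr_p = 0`
#' the operation is the identity.
#'
#' @param image Grayscale matrix or RGB array, values in `[0, 1]`.
#' @param labels Normalized label data frame `(class, cx, cy, w, h)`.
#' @param translate,scale,fliplr_p See [augment_config()].
#' @param seed Optional integer seed.
#' @return List `(image, labels)`.
#' @export
geometric_augment <- function(image, labels, translate = 0.1, scale = 0.5,
                              fliplr_p = 0.5, seed = NULL) {
  ws_stopifnot_image(image)
  dims <- if (is.matrix(image)) dim(image) else dim(image)[1:2]
  H <- dims[1]; W <- dims[2]
  ws_with_seed(seed, {
    sc <- if (scale > 0) runif(1, 1 - scale, 1 + scale) else 1
    tx <- if (translate > 0) runif(1, -translate, translate) * W else 0
    ty <- if (translate > 0) runif(1, -translate, translate) * H else 0
    flip <- runif(1) < fliplr_p
    if (sc == 1 && tx == 0 && ty == 0 && !flip)
      return(list(image = image, labels = labels))
    warp1 <- function(m) {
      fill <- median(m)
      xs <- rep(0:(W - 1), each = H)
      ys <- rep(0:(H - 1), times = W)
      xi <- if (flip) (W - 1) - xs else xs
      cx0 <- (W - 1) / 2; cy0 <- (H - 1) / 2
      sx <- (xi - cx0 - tx) / sc + cx0
      sy <- (ys - cy0 - ty) / sc + cy0
      matrix(ws_bilinear(m, sx, sy, fill = fill), H, W)
    }
    out_img <- ws_per_channel(image, warp1)
    out_lab <- ws_transform_boxes(labels, dims, sc, tx, ty, flip)
    list(image = out_img, labels = out_lab)
  })
}

#' Horizontal flip (exact)
#'
#' Mirrors the image and its labels about the vertical centre line. Applying
#' it twice restores the original exactly.
#'
#' @inheritParams geometric_augment
#' @return List `(image, labels)`.
#' @export
flip_horizontal <- function(image, labels) {
  flip1 <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
  out <- ws_per_channel(image, flip1)
  lab <- labels
  if (nrow(lab)) lab$cx <- 1 - lab$cx
  list(image = out, labels = lab)
}

#' Mosaic augmentation
#'
#' Composes one training image from four sources on a 2x2 grid around a
#' split point drawn uniformly in the central 50% of each dimension. Each
#' tile is filled by uniformly scaling its source to cover the tile and
#' cropping from the top-left; labels are remapped, clipped to their tile,
#' and dropped when less than 8 px^2 remain visible.
#'
#' @param scenes List of four `(image, labels)` lists (grayscale images).
#' @param out_canvas `(H, W)` of the mosaic.
#' @param seed Optional integer seed.
#' @return List `(image, labels)`.
#' @export
mosaic <- function(scenes, out_canvas = c(640, 640), seed = NULL) {
  if (length(scenes) != 4) stop("mosaic requires exactly 4 source scenes")
  H <- out_canvas[1]; W <- out_canvas[2]
  ws_with_seed(seed, {
    sy <- round(runif(1, 0.25, 0.75) * H)
    sx <- round(runif(1, 0.25, 0.75) * W)
    tiles <- list(c(1, 1, sy, sx), c(1, sx + 1, sy, W),
                  c(sy + 1, 1, H, sx), c(sy + 1, sx + 1, H, W))
    img <- matrix(0, H, W)
    labs <- list()
    for (k in 1:4) {
      t <- tiles[[k]]
      th <- t[3] - t[1] + 1; tw <- t[4] - t[2] + 1
      src <- scenes[[k]]$image
      sh <- nrow(src); sw <- ncol(src)
      f <- max(th / sh, tw / sw)
      rs <- ws_resize(src, ceiling(sh * f), ceiling(sw * f))
      img[t[1]:t[3], t[2]:t[4]] <- rs[1:th, 1:tw]
      sl <- scenes[[k]]$labels
      if (nrow(sl)) {
        # scale by f, shift to tile origin, clip to tile
        cxp <- sl$cx * sw * f + (t[2] - 1); cyp <- sl$cy * sh * f + (t[1] - 1)
        wp <- sl$w * sw * f; hp <- sl$h * sh * f
        x1 <- pmax(cxp - wp / 2, t[2] - 1); x2 <- pmin(cxp + wp / 2, t[4])
        y1 <- pmax(cyp - hp / 2, t[1] - 1); y2 <- pmin(cyp + hp / 2, t[3])
        vis <- pmax(x2 - x1, 0) * pmax(y2 - y1, 0)
        keep <- vis >= 8
        if (any(keep))
          labs[[length(labs) + 1]] <- data.frame(
            class = sl$class[keep],
            cx = ((x1 + x2) / 2 / W)[keep], cy = ((y1 + y2) / 2 / H)[keep],
            w = ((x2 - x1) / W)[keep], h = ((y2 - y1) / H)[keep])
      }
    }
    labels <- if (length(labs)) do.call(rbind, labs) else
      data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                 w = numeric(0), h = numeric(0))
    list(image = img, labels = labels)
  })
}

#' Letterbox resize to a square multiple of 32
#'
#' Aspect-preserving resize so that the long side equals
#' `target_long_side`, followed by symmetric padding to a square. The pad
#' value is the image median (so no artificial high-contrast border is
#' introduced). Normalized labels are recomputed, and the returned
#' `transform` record allows exact inverse mapping of boxes back to the
#' original image.
#'
#' @param image Grayscale matrix or RGB array.
#' @param labels Normalized label data frame.
#' @param target_long_side Output side length in px; must be a multiple
#'   of 32 (the detector stride). Default 1728.
#' @return List `(image, labels, transform)`; `transform` holds
#'   `scale`, `pad_x`, `pad_y` (left/top padding) and the original shape.
#' @export
letterbox_resize <- function(image, labels, target_long_side = 1728) {
  if (target_long_side %% 32 != 0)
    stop("target_long_side must be a multiple of 32")
  ws_stopifnot_image(image)
  dims <- if (is.matrix(image)) dim(image) else dim(image)[1:2]
  H <- dims[1]; W <- dims[2]
  s <- target_long_side / max(H, W)
  nh <- round(H * s); nw <- round(W * s)
  pad_y <- (target_long_side - nh) %/% 2
  pad_x <- (target_long_side - nw) %/% 2
  fill <- median(if (is.matrix(image)) image else image[, , 1])
  emb1 <- function(m) {
    rs <- ws_resize(m, nh, nw)
    out <- matrix(fill, target_long_side, target_long_side)
    out[pad_y + seq_len(nh), pad_x + seq_len(nw)] <- rs
    out
  }
  out_img <- ws_per_channel(image, emb1)
  lab <- labels
  if (nrow(lab)) {
    lab$cx <- (lab$cx * W * s + pad_x) / target_long_side
    lab$cy <- (lab$cy * H * s + pad_y) / target_long_side
    lab$w <- lab$w * W * s / target_long_side
    lab$h <- lab$h * H * s / target_long_side
  }
  tr <- list(scale = s, pad_x = pad_x, pad_y = pad_y, orig = c(H, W),
             target = target_long_side)
  list(image = out_img, labels = lab, transform = tr)
}

#' Invert a letterbox transform on labels
#'
#' Maps normalized boxes in letterboxed coordinates back to normalized
#' boxes in the original image; exact inverse of the label mapping of
#' [letterbox_resize()].
#'
#' @param labels Normalized label data frame in letterbox coordinates.
#' @param transform The `transform` record from [letterbox_resize()].
#' @return Normalized label data frame in original-image coordinates.
#' @export
letterbox_invert <- function(labels, transform) {
  lab <- labels
  if (nrow(lab)) {
    t <- transform
    H <- t$orig[1]; W <- t$orig[2]
    lab$cx <- (lab$cx * t$target - t$pad_x) / t$scale / W
    lab$cy <- (lab$cy * t$target - t$pad_y) / t$scale / H
    lab$w <- lab$w * t$target / t$scale / W
    lab$h <- lab$h * t$target / t$scale / H
  }
  lab
}
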