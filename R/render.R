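#' Procedural appearance parameters
#'
#' Describes how a worm body and the agar background are shaded. This is a
#' procedural appearance model: bodies are rendered as noisy, edge-darkened
#' silhouettes over a vignetted, mottled background, emulating the dominant
#' photometric character of plate microscopy (dark worms on bright agar, or
#' the inverted polarity of darkfield-style setups).
#'
#' @param polarity `"dark-on-light"` or `"light-on-dark"`.
#' @param fg_mean,fg_std Body intensity mean / spread, in `[0, 1]`.
#' @param edge_gain Strength of body-outline darkening (lightening for
#'   inverted polarity), `>= 0`.
#' @param texture_scale Correlation length of body texture in px (0 = white
#'   noise).
#' @param blur_sigma Gaussian blur of the rendered crop in px (0 = none).
#' @param bg_mean,bg_std Background intensity mean / noise, in `[0, 1]`.
#' @param vignette_strength Radial darkening toward canvas corners, `[0, 1]`.
#' @param speckle_density Per-pixel probability of a salt speckle (dust/
#'   debris spot).
#' @return An object of class `appearance_params`.
#' @export
appearance_params <- function(polarity = c("dark-on-light", "light-on-dark"),
                              fg_mean = 0.25, fg_std = 0.04, edge_gain = 0.25,
                              texture_scale = 6, blur_sigma = 0.8,
                              bg_mean = 0.78, bg_std = 0.02,
                              vignette_strength = 0.10,
                              speckle_density = 2e-5) {
  polarity <- match.arg(polarity)
  for (v in c(fg_mean, fg_std, bg_mean, bg_std, vignette_strength))
    if (!is.finite(v) || v < 0 || v > 1)
      stop("intensity parameters must lie in [0, 1]")
  if (blur_sigma < 0) stop("blur_sigma must be >= 0")
  if (edge_gain < 0) stop("edge_gain must be >= 0")
  if (speckle_density < 0 || speckle_density > 1)
    stop("speckle_density must be a probability")
  structure(list(polarity = polarity, fg_mean = fg_mean, fg_std = fg_std,
                 edge_gain = edge_gain, texture_scale = texture_scale,
                 blur_sigma = blur_sigma, bg_mean = bg_mean, bg_std = bg_std,
                 vignette_strength = vignette_strength,
                 speckle_density = speckle_density),
            class = "appearance_params")
}

# Band-limited unit-variance noise field: white noise smoothed at `scale` px
# and re-standardized. scale = 0 returns white noise.
ws_noise_field <- function(h, w, scale) {
  z <- matrix(rnorm(h * w), h, w)
  if (scale > 0) {
    z <- ws_gblur(z, sigma = scale)
    s <- sd(as.vector(z))
    if (s > 0) z <- z / s
  }
  z
}

#' Synthesize a worm-free background
#'
#' Base intensity plus Gaussian grain, a radial vignette, low-frequency
#' mottle (uneven agar/illumination) and sparse salt speckle, clipped to
#' `[0, 1]`. With all noise terms at zero the result is a constant image at
#' `bg_mean`.
#'
#' @param appearance An [appearance_params()] object.
#' @param canvas `(H, W)` in px.
#' @param seed Optional integer seed.
#' @return Numeric matrix in `[0, 1]`.
#' @export
make_background <- function(appearance, canvas = c(640, 640), seed = NULL) {
  h <- as.integer(canvas[1]); w <- as.integer(canvas[2])
  a <- appearance
  ws_with_seed(seed, {
    img <- matrix(a$bg_mean, h, w)
    if (a$bg_std > 0) {
      img <- img + matrix(rnorm(h * w, 0, a$bg_std), h, w)
      # low-frequency mottle: coarse grid upsampled to canvas size
      g <- matrix(rnorm(64, 0, 2 * a$bg_std), 8, 8)
      img <- img + ws_resize(g, h, w)
    }
    if (a$vignette_strength > 0) {
      cy <- (h - 1) / 2; cx <- (w - 1) / 2
      r2 <- outer(((seq_len(h) - 1) - cy)^2, ((seq_len(w) - 1) - cx)^2, "+")
      img <- img * (1 - a$vignette_strength * r2 / max(r2))
    }
    if (a$speckle_density > 0) {
      n <- length(img)
      hit <- runif(n) < a$speckle_density
      if (any(hit)) {
        delta <- if (a$polarity == "dark-on-light") -0.5 else 0.5
        img[hit] <- img[hit] + delta
      }
    }
    ws_clip01(img)
  })
}

#' Render a worm crop from a mask
#'
#' Paints the body with intensity `N(fg_mean, fg_std)` modulated by
#' band-limited texture at `texture_scale` px, darkens (dark-on-light) or
#' lightens (light-on-dark) a 1 px outline band by `edge_gain`, then blurs
#' patch and alpha by `blur_sigma`. With blur off, the alpha channel equals
#' the input mask exactly.
#'
#' @param worm_mask A `worm_mask` or logical matrix.
#' @param appearance An [appearance_params()] object.
#' @param seed Optional integer seed.
#' @return List with `patch` (intensity matrix), `alpha` (compositing weight
#'   in `[0, 1]`) and `mask` (the binary input mask).
#' @export
render_worm <- function(worm_mask, appearance, seed = NULL) {
  m <- if (inherits(worm_mask, "worm_mask")) worm_mask$raster else worm_mask
  a <- appearance
  ws_with_seed(seed, {
    h <- nrow(m); w <- ncol(m)
    body <- matrix(a$fg_mean, h, w)
    if (a$fg_std > 0)
      body <- body + a$fg_std * ws_noise_field(h, w, a$texture_scale)
    if (a$edge_gain > 0) {
      interior <- EBImage::erode(m, EBImage::makeBrush(3, "box")) > 0
      band <- m & !interior
      body[band] <- if (a$polarity == "dark-on-light")
        body[band] * (1 - a$edge_gain)
      else
        body[band] + a$edge_gain * (1 - body[band])
    }
    patch <- ws_clip01(body) * m
    alpha <- m * 1
    if (a$blur_sigma > 0) {
      patch <- ws_gblur(patch, sigma = a$blur_sigma)
      alpha <- ws_clip01(ws_gblur(alpha, sigma = a$blur_sigma))
    }
    list(patch = ws_clip01(patch), alpha = alpha, mask = m)
  })
}

#' Scene composition parameters
#'
#' @param canvas `(H, W)` px, each `>= 64`.
#' @param n_worms Number of worms to place (`>= 0`).
#' @param max_overlap_frac Maximum allowed pairwise mask overlap, as a
#'   fraction of the smaller mask's area (0 = worms must not touch).
#' @param brightness_range,contrast_range Per-worm photometric jitter applied
#'   before compositing.
#' @param placement_tries Rejection-sampling budget per worm.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(canvas = c(640, 640), n_worms = 3,
                       max_overlap_frac = 0,
                       brightness_range = c(-0.03, 0.03),
                       contrast_range = c(0.9, 1.1),
                       placement_tries = 60) {
  if (any(canvas < 64)) stop("canvas dimensions must be >= 64")
  if (n_worms < 0) stop("n_worms must be >= 0")
  if (max_overlap_frac < 0 || max_overlap_frac > 1)
    stop("max_overlap_frac must lie in [0, 1]")
  structure(list(canvas = as.integer(canvas), n_worms = as.integer(n_worms),
                 max_overlap_frac = max_overlap_frac,
                 brightness_range = brightness_range,
                 contrast_range = contrast_range,
                 placement_tries = as.integer(placement_tries)),
            class = "scene_spec")
}

# tight 0-based inclusive pixel bbox of a logical matrix
ws_mask_pixel_bbox <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  c(xmin = min(idx[, 2]) - 1L, ymin = min(idx[, 1]) - 1L,
    xmax = max(idx[, 2]) - 1L, ymax = max(idx[, 1]) - 1L)
}

#' Place rendered worms onto a background
#'
#' Rejection-samples a position and an exact quarter-turn rotation for each
#' crop until the pairwise mask-overlap constraint is met, applies per-worm
#' brightness/contrast jitter, alpha-composites, and records each placed
#' mask together with its tight pixel bounding box — the auto-generated
#' label. If a worm cannot be placed within the budget the scene is returned
#' with fewer worms and `placement_ok = FALSE` (with a warning).
#'
#' @param background Background matrix from [make_background()].
#' @param crops List of rendered crops from [render_worm()].
#' @param spec A [scene_spec()].
#' @param seed Optional integer seed.
#' @return An object of class `synthetic_scene`: list with `image`,
#'   `placements` (per worm: id, offset, mask, pixel bbox), `labels`
#'   (normalized YOLO boxes, see [mask_to_bbox()]), `n_requested`,
#'   `n_placed`, `placement_ok`, `spec`.
#' @export
place_worms <- function(background, crops, spec, seed = NULL) {
  H <- nrow(background); W <- ncol(background)
  img <- background
  ws_with_seed(seed, {
    placements <- list()
    placed_masks <- list()
    for (i in seq_along(crops)) {
      crop <- crops[[i]]
      ok <- FALSE
      for (try in seq_len(spec$placement_tries)) {
        k <- sample.int(4L, 1L) - 1L
        patch <- ws_rot90(crop$patch, k)
        alpha <- ws_rot90(crop$alpha, k)
        mask <- ws_rot90(crop$mask, k)
        ch <- nrow(mask); cw <- ncol(mask)
        if (ch > H || cw > W) next
        y0 <- sample.int(H - ch + 1L, 1L) - 1L
        x0 <- sample.int(W - cw + 1L, 1L) - 1L
        # overlap constraint against every already-placed mask
        feasible <- TRUE
        for (pm in placed_masks) {
          ix0 <- max(x0, pm$x0); iy0 <- max(y0, pm$y0)
          ix1 <- min(x0 + cw, pm$x0 + ncol(pm$mask))
          iy1 <- min(y0 + ch, pm$y0 + nrow(pm$mask))
          if (ix1 <= ix0 || iy1 <= iy0) next
          sub_a <- mask[(iy0 - y0 + 1):(iy1 - y0), (ix0 - x0 + 1):(ix1 - x0), drop = FALSE]
          sub_b <- pm$mask[(iy0 - pm$y0 + 1):(iy1 - pm$y0),
                           (ix0 - pm$x0 + 1):(ix1 - pm$x0), drop = FALSE]
          inter <- sum(sub_a & sub_b)
          if (inter > spec$max_overlap_frac * min(sum(mask), sum(pm$mask))) {
            feasible <- FALSE
            break
          }
        }
        if (!feasible) next
        # photometric jitter, then alpha compositing
        gain <- runif(1, spec$contrast_range[1], spec$contrast_range[2])
        bright <- runif(1, spec$brightness_range[1], spec$brightness_range[2])
        patch <- ws_clip01(gain * (patch - 0.5) + 0.5 + bright)
        ys <- y0 + seq_len(ch); xs <- x0 + seq_len(cw)
        img[ys, xs] <- img[ys, xs] * (1 - alpha) + patch * alpha
        bb <- ws_mask_pixel_bbox(mask)
        bb <- bb + c(x0, y0, x0, y0)
        placed_masks[[length(placed_masks) + 1]] <-
          list(x0 = x0, y0 = y0, mask = mask)
        placements[[length(placements) + 1]] <-
          list(id = i, x0 = x0, y0 = y0, mask = mask, bbox_px = bb)
        ok <- TRUE
        break
      }
      if (!ok) next
    }
    n_placed <- length(placements)
    if (n_placed < length(crops))
      warning(sprintf("placed %d of %d worms (placement budget exhausted)",
                      n_placed, length(crops)))
    labels <- scene_labels(placements, c(H, W))
    structure(list(image = img, placements = placements, labels = labels,
                   n_requested = length(crops), n_placed = n_placed,
                   placement_ok = n_placed == length(crops), spec = spec),
              class = "synthetic_scene")
  })
}

# normalized YOLO label rows (class cx cy w h) from placement records
scene_labels <- function(placements, canvas) {
  if (!length(placements))
    return(data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0)))
  do.call(rbind, lapply(placements, function(p)
    pixel_bbox_to_norm(p$bbox_px, canvas)))
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic_scene: %d x %d, %d/%d worms placed%s\n",
              nrow(x$image), ncol(x$image), x$n_placed, x$n_requested,
              if (x$placement_ok) "" else " [INCOMPLETE]"))
  invisible(x)
}

#' Generate one labelled synthetic scene
#'
#' End-to-end convenience wrapper: samples `n_worms` masks from a strain
#' preset, renders them under one appearance, synthesizes a background and
#' composes the scene. The whole result is a pure function of
#' `(arguments, seed)`.
#'
#' @param preset Strain preset name or `strain_params`.
#' @param appearance An [appearance_params()] object.
#' @param spec A [scene_spec()].
#' @param seed Integer seed.
#' @return A `synthetic_scene`.
#' @examples
#' sc <- generate_scene(seed = 1, spec = scene_spec(n_worms = 2))
#' sc$labels
#' @export
generate_scene <- function(preset = "wild-type",
                           appearance = appearance_params(),
                           spec = scene_spec(), seed = 1) {
  crops <- lapply(seq_len(spec$n_worms), function(i) {
    wm <- generate_worm_mask(preset, seed = derive_seed(seed, 10L, i))
    render_worm(wm, appearance, seed = derive_seed(seed, 11L, i))
  })
  bg <- make_background(appearance, spec$canvas, seed = derive_seed(seed, 12L))
  place_worms(bg, crops, spec, seed = derive_seed(seed, 13L))
}
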