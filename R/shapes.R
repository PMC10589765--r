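#' Strain shape presets
#'
#' Parameter ranges describing the body geometry of a worm strain. Worm bodies
#' are modelled as a sinusoidally undulating centerline with a power-law
#' tapered width profile. The `"wild-type"` preset corresponds to a typical
#' adult hermaphrodite at plate-microscopy scale; `"dpy-like"` (dumpy: short
#' and wide) and `"lon-like"` (long and narrow) presets emulate the two
#' classic mutant morphologies used to probe detector robustness to strain
#' change.
#'
#' @param name One of `"wild-type"`, `"dpy-like"`, `"lon-like"`.
#' @return An object of class `strain_params`: a list of ranges
#'   (`length_px`, `max_halfwidth_px`, `undulation_amplitude_frac`,
#'   `undulation_wavelength_frac`) and the scalar `taper_exponent`.
#' @examples
#' strain_preset("dpy-like")
#' @export
strain_preset <- function(name = c("wild-type", "dpy-like", "lon-like")) {
  name <- match.arg(name)
  base <- list(
    name = "wild-type",
    length_px = c(200, 400),
    max_halfwidth_px = c(8, 14),
    undulation_amplitude_frac = c(0.05, 0.20),
    undulation_wavelength_frac = c(0.4, 1.0),
    taper_exponent = 0.8
  )
  p <- switch(name,
    "wild-type" = base,
    "dpy-like" = {
      b <- base
      b$name <- "dpy-like"
      b$length_px <- base$length_px * 0.5
      b$max_halfwidth_px <- base$max_halfwidth_px * 1.8
      b
    },
    "lon-like" = {
      b <- base
      b$name <- "lon-like"
      b$length_px <- base$length_px * 1.5
      b$max_halfwidth_px <- base$max_halfwidth_px * 0.7
      b
    }
  )
  structure(p, class = "strain_params")
}

#' Construct a user-defined strain preset
#'
#' @param name Label for the strain.
#' @param length_px,max_halfwidth_px Positive `(min, max)` ranges in pixels.
#' @param undulation_amplitude_frac,undulation_wavelength_frac `(min, max)`
#'   ranges expressed as fractions of body length.
#' @param taper_exponent Positive exponent of the width taper
#'   `w(s) = w_max * (4 s (1 - s))^tau`.
#' @return A `strain_params` object.
#' @export
strain_params <- function(name, length_px, max_halfwidth_px,
                          undulation_amplitude_frac = c(0.05, 0.20),
                          undulation_wavelength_frac = c(0.4, 1.0),
                          taper_exponent = 0.8) {
  p <- list(name = name, length_px = as.numeric(length_px),
            max_halfwidth_px = as.numeric(max_halfwidth_px),
            undulation_amplitude_frac = as.numeric(undulation_amplitude_frac),
            undulation_wavelength_frac = as.numeric(undulation_wavelength_frac),
            taper_exponent = as.numeric(taper_exponent))
  validate_strain_params(p)
  structure(p, class = "strain_params")
}

validate_strain_params <- function(p) {
  for (f in c("length_px", "max_halfwidth_px", "undulation_amplitude_frac",
              "undulation_wavelength_frac")) {
    r <- p[[f]]
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2] || r[1] <= 0)
      stop("range '", f, "' must satisfy 0 < min <= max")
  }
  if (!is.finite(p$taper_exponent) || p$taper_exponent <= 0)
    stop("taper_exponent must be positive")
  invisible(TRUE)
}

#' @export
print.strain_params <- function(x, ...) {
  cat("Strain preset:", x$name, "\n")
  cat(sprintf("  length       %g-%g px\n", x$length_px[1], x$length_px[2]))
  cat(sprintf("  halfwidth    %g-%g px\n", x$max_halfwidth_px[1], x$max_halfwidth_px[2]))
  cat(sprintf("  undulation   amplitude %g-%g, wavelength %g-%g (of length)\n",
              x$undulation_amplitude_frac[1], x$undulation_amplitude_frac[2],
              x$undulation_wavelength_frac[1], x$undulation_wavelength_frac[2]))
  cat(sprintf("  taper        %g\n", x$taper_exponent))
  invisible(x)
}

#' Draw one realization of a strain's shape parameters
#'
#' Samples each scalar shape parameter uniformly from its preset range.
#' A fixed seed gives an identical realization.
#'
#' @param preset A preset name (see [strain_preset()]) or a `strain_params`
#'   object.
#' @param seed Optional integer seed.
#' @return A list of scalar parameters (class `worm_params`) with fields
#'   `name`, `length_px`, `max_halfwidth_px`, `undulation_amplitude_frac`,
#'   `undulation_wavelength_frac`, `taper_exponent`.
#' @examples
#' sample_strain("dpy-like", seed = 1)
#' @export
sample_strain <- function(preset = "wild-type", seed = NULL) {
  p <- if (inherits(preset, "strain_params")) preset else strain_preset(preset)
  ws_with_seed(seed, {
    r <- list(
      name = p$name,
      length_px = runif(1, p$length_px[1], p$length_px[2]),
      max_halfwidth_px = runif(1, p$max_halfwidth_px[1], p$max_halfwidth_px[2]),
      undulation_amplitude_frac = runif(1, p$undulation_amplitude_frac[1],
                                        p$undulation_amplitude_frac[2]),
      undulation_wavelength_frac = runif(1, p$undulation_wavelength_frac[1],
                                         p$undulation_wavelength_frac[2]),
      taper_exponent = p$taper_exponent
    )
    structure(r, class = "worm_params")
  })
}

# Does an open polyline intersect itself? Brute-force O(n^2) segment test,
# vectorized; adjacent segments (sharing an endpoint) are excluded.
polyline_self_intersects <- function(pts) {
  n <- nrow(pts) - 1
  if (n < 3) return(FALSE)
  x1 <- pts[1:n, 1]; y1 <- pts[1:n, 2]
  x2 <- pts[2:(n + 1), 1]; y2 <- pts[2:(n + 1), 2]
  idx <- which(outer(seq_len(n), seq_len(n), function(i, j) j > i + 1), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  d1 <- (x2[i] - x1[i]) * (y1[j] - y1[i]) - (y2[i] - y1[i]) * (x1[j] - x1[i])
  d2 <- (x2[i] - x1[i]) * (y2[j] - y1[i]) - (y2[i] - y1[i]) * (x2[j] - x1[i])
  d3 <- (x2[j] - x1[j]) * (y1[i] - y1[j]) - (y2[j] - y1[j]) * (x1[i] - x1[j])
  d4 <- (x2[j] - x1[j]) * (y2[i] - y1[j]) - (y2[j] - y1[j]) * (x2[i] - x1[j])
  any(d1 * d2 < 0 & d3 * d4 < 0)
}

#' Sample a worm centerline
#'
#' Builds a sinusoidally undulating centerline of the requested arclength:
#' a sinusoid `y = A sin(2 pi x / lambda + phase)` is traced until its
#' arclength reaches the body length, resampled to (approximately) equal
#' arclength spacing, then rigidly rotated about its centroid. Amplitude `A`
#' and wavelength `lambda` come from the parameter realization (fractions of
#' body length); phase and rotation are drawn uniformly. If the polyline
#' self-intersects it is redrawn, up to `max_retries` times.
#'
#' @param params A `worm_params` realization from [sample_strain()].
#' @param seed Optional integer seed.
#' @param rotation Rotation angle in radians; `NULL` (default) draws it
#'   uniformly in `[0, 2 pi)`.
#' @param n_points Number of polyline points; default scales with length
#'   (roughly one point per 2.5 px, at least 17).
#' @param max_retries Redraw budget on self-intersection.
#' @return An object of class `centerline`: list with `points` (n x 2 matrix
#'   of continuous 0-based `(x, y)` pixel coordinates, x right / y down,
#'   centred on the centroid) and `arclength`.
#' @export
sample_centerline <- function(params, seed = NULL, rotation = NULL,
                              n_points = NULL, max_retries = 20) {
  L <- params$length_px
  A <- params$undulation_amplitude_frac * L
  lambda <- params$undulation_wavelength_frac * L
  if (is.null(n_points)) n_points <- max(17L, as.integer(round(L / 2.5)) + 1L)
  if (n_points < 16) stop("n_points must be >= 16")
  ws_with_seed(seed, {
    for (attempt in seq_len(max_retries)) {
      phase <- runif(1, 0, 2 * pi)
      theta <- if (is.null(rotation)) runif(1, 0, 2 * pi) else rotation
      # trace the sinusoid densely until cumulative arclength reaches L
      dx <- min(lambda / 64, 0.5)
      xmax <- 4 * L
      x <- seq(0, xmax, by = dx)
      y <- if (A == 0) rep(0, length(x)) else A * sin(2 * pi * x / lambda + phase)
      seglen <- sqrt(diff(x)^2 + diff(y)^2)
      s <- c(0, cumsum(seglen))
      if (s[length(s)] < L)
        stop("infeasible shape parameters: cannot reach requested arclength")
      targets <- seq(0, L, length.out = n_points)
      px <- approx(s, x, xout = targets)$y
      py <- approx(s, y, xout = targets)$y
      pts <- cbind(x = px, y = py)
      # rigid motion: rotate about centroid, re-centre on the centroid
      ctr <- colMeans(pts)
      pts <- sweep(pts, 2, ctr)
      R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
      pts <- pts %*% t(R)
      colnames(pts) <- c("x", "y")
      if (!polyline_self_intersects(pts)) {
        arclen <- sum(sqrt(rowSums(diff(pts)^2)))
        return(structure(list(points = pts, arclength = arclen,
                              phase = phase, rotation = theta),
                         class = "centerline"))
      }
      if (!is.null(rotation) && attempt == max_retries) break
    }
    stop("centerline retry budget exhausted (self-intersecting geometry); ",
         "amplitude is likely too large relative to wavelength")
  })
}

#' Tapered half-width profile along the body
#'
#' Evaluates `w(s) = w_max * (4 s (1 - s))^tau` at `n_points` equally spaced
#' positions `s` in `[0, 1]`. The profile is zero at both body tips and
#' reaches `w_max` exactly at mid-body.
#'
#' @param params A `worm_params` realization (uses `max_halfwidth_px` and
#'   `taper_exponent`).
#' @param n_points Number of evaluation points (>= 16), normally the number
#'   of centerline points.
#' @return Numeric vector of half-widths in pixels.
#' @export
width_profile <- function(params, n_points) {
  if (n_points < 16) stop("n_points must be >= 16")
  s <- seq(0, 1, length.out = n_points)
  params$max_halfwidth_px * (4 * s * (1 - s))^params$taper_exponent
}

#' Rasterize a worm body to a binary mask
#'
#' The body is the union of disks centred on a densified centerline (0.5 px
#' arclength spacing, half-widths linearly interpolated), i.e. a stroked
#' variable-width tube. The mask is guaranteed to be a single 8-connected
#' component with at least a 2 px background margin on every canvas border.
#'
#' @param centerline A `centerline` object.
#' @param halfwidths Per-point half-widths from [width_profile()].
#' @param canvas_shape Optional `(H, W)`; if `NULL` the canvas is sized
#'   tightly around the body plus margin. If given, the body is centred and
#'   an error is raised when it does not fit with the margin.
#' @param margin Background margin in px (default 2).
#' @return An object of class `worm_mask`: list with `raster` (logical
#'   matrix), `strain`, `params_used`, and the realized geometry.
#' @export
rasterize_worm <- function(centerline, halfwidths, canvas_shape = NULL,
                           margin = 2) {
  pts <- centerline$points
  if (length(halfwidths) != nrow(pts))
    stop("halfwidths must match the number of centerline points")
  # densify to 0.5 px spacing along arclength
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  sd_ <- seq(0, s[length(s)], by = 0.5)
  xd <- approx(s, pts[, 1], xout = sd_)$y
  yd <- approx(s, pts[, 2], xout = sd_)$y
  rd <- approx(s, halfwidths, xout = sd_)$y
  xmin <- min(xd - rd); xmax <- max(xd + rd)
  ymin <- min(yd - rd); ymax <- max(yd + rd)
  bw <- xmax - xmin; bh <- ymax - ymin
  if (is.null(canvas_shape)) {
    W <- as.integer(ceiling(bw)) + 2L * as.integer(margin) + 2L
    H <- as.integer(ceiling(bh)) + 2L * as.integer(margin) + 2L
    ox <- margin + 0.5 - xmin
    oy <- margin + 0.5 - ymin
  } else {
    H <- as.integer(canvas_shape[1]); W <- as.integer(canvas_shape[2])
    if (bw > W - 2 * margin - 1 || bh > H - 2 * margin - 1)
      stop("worm does not fit inside the canvas with the required margin")
    ox <- (W - 1) / 2 - (xmin + xmax) / 2
    oy <- (H - 1) / 2 - (ymin + ymax) / 2
  }
  xd <- xd + ox; yd <- yd + oy
  mask <- matrix(FALSE, H, W)
  # trace the centerline itself so thin tip disks can never leave
  # disconnected fragments: consecutive dense points are <= 0.5 px apart,
  # hence their rounded pixels are 8-adjacent
  body <- rd > 0
  if (any(body)) {
    ti <- pmin(pmax(round(yd[body]), 0), H - 1) + 1
    tj <- pmin(pmax(round(xd[body]), 0), W - 1) + 1
    mask[cbind(ti, tj)] <- TRUE
  }
  for (i in seq_along(xd)) {
    r <- rd[i]
    if (r <= 0) next
    cx <- xd[i]; cy <- yd[i]
    jx <- max(0, floor(cx - r)):min(W - 1, ceiling(cx + r))
    jy <- max(0, floor(cy - r)):min(H - 1, ceiling(cy + r))
    if (!length(jx) || !length(jy)) next
    d2 <- outer((jy - cy)^2, (jx - cx)^2, "+")
    hit <- d2 <= r^2
    if (any(hit)) {
      sub <- mask[jy + 1, jx + 1, drop = FALSE]
      mask[jy + 1, jx + 1] <- sub | hit
    }
  }
  if (!any(mask)) stop("rasterization produced an empty mask")
  if (any(mask[1, ]) || any(mask[H, ]) || any(mask[, 1]) || any(mask[, W]))
    stop("worm touches the canvas border")
  ncomp <- max(ws_label8(mask))
  if (ncomp != 1)
    stop("rasterization produced ", ncomp, " connected components")
  structure(list(raster = mask, strain = NULL, seed = NULL,
                 params_used = NULL, centerline = centerline,
                 halfwidths = halfwidths),
            class = "worm_mask")
}

#' Generate a complete worm mask from a strain preset
#'
#' Convenience wrapper chaining [sample_strain()], [sample_centerline()],
#' [width_profile()] and [rasterize_worm()]. Identical `(preset, seed)`
#' always give a bit-identical mask.
#'
#' @inheritParams sample_strain
#' @param canvas_shape,margin Passed to [rasterize_worm()].
#' @return A `worm_mask` with `strain`, `seed` and `params_used` filled in.
#' @examples
#' m <- generate_worm_mask("wild-type", seed = 7)
#' dim(m$raster)
#' @export
generate_worm_mask <- function(preset = "wild-type", seed = NULL,
                               canvas_shape = NULL, margin = 2) {
  params <- sample_strain(preset, seed = seed)
  cl_seed <- if (is.null(seed)) NULL else derive_seed(seed, 1L)
  cl <- sample_centerline(params, seed = cl_seed)
  hw <- width_profile(params, nrow(cl$points))
  wm <- rasterize_worm(cl, hw, canvas_shape = canvas_shape, margin = margin)
  wm$strain <- params$name
  wm$seed <- seed
  wm$params_used <- params
  wm
}

#' @export
print.worm_mask <- function(x, ...) {
  d <- dim(x$raster)
  cat(sprintf("worm_mask: %s, %d x %d canvas, %d foreground px\n",
              if (is.null(x$strain)) "(no strain)" else x$strain,
              d[1], d[2], sum(x$raster)))
  invisible(x)
}

#' Write / read a binary mask as 8-bit PNG
#'
#' Foreground is stored as 255, background as 0.
#'
#' @param mask A `worm_mask` or logical matrix.
#' @param path Output / input file path.
#' @return `read_mask_png` returns a logical matrix.
#' @export
write_mask_png <- function(mask, path) {
  m <- if (inherits(mask, "worm_mask")) mask$raster else mask
  png::writePNG(m * 1, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}
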