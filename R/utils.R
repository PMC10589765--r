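#' @importFrom stats approx median rnorm runif sd pt quantile
#' @importFrom utils read.delim write.table
NULL

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# state; seed = NULL uses the current stream.
ws_with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  withr::with_seed(as.integer(seed), code)
}

#' Derive a child seed from a root seed
#'
#' Deterministically maps a root seed and one or more integer stream indices
#' to a new seed in `[0, 2^31 - 2]`, so that every stage of a pipeline gets
#' its own reproducible RNG stream from a single root seed.
#'
#' @param seed Integer root seed.
#' @param ... One or more integer stream indices.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  ks <- c(...)
  s <- as.numeric(seed) %% 2147483647
  for (k in ks) {
    s <- (s * 48271 + as.numeric(k) * 7919 + 1) %% 2147483647
  }
  as.integer(s)
}

ws_clip01 <- function(x) pmin(pmax(x, 0), 1)

# Exact k*90-degree counter-clockwise rotation of a matrix (image convention:
# rows = y down, cols = x right).
ws_rot90 <- function(m, k = 1L) {
  k <- ((k %% 4L) + 4L) %% 4L
  if (k == 0L) return(m)
  for (i in seq_len(k)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  m
}

# Bilinear sampling of `img` at continuous (x, y) positions (0-based pixel
# index coordinates: pixel [i, j] has centre (x = j - 1, y = i - 1)).
ws_bilinear <- function(img, x, y, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  get_px <- function(yy, xx) {
    ok <- yy >= 0 & yy <= h - 1 & xx >= 0 & xx <= w - 1
    v <- rep(fill, length(xx))
    v[ok] <- img[cbind(yy[ok] + 1, xx[ok] + 1)]
    v
  }
  v00 <- get_px(y0, x0);     v01 <- get_px(y0, x0 + 1)
  v10 <- get_px(y0 + 1, x0); v11 <- get_px(y0 + 1, x0 + 1)
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

# Bilinear resize of a matrix to out_h x out_w, mapping pixel centres so that
# the image corners align (the convention used for letterboxing).
ws_resize <- function(img, out_h, out_w) {
  h <- nrow(img); w <- ncol(img)
  if (out_h == h && out_w == w) return(img)
  xs <- (seq_len(out_w) - 0.5) * w / out_w - 0.5
  ys <- (seq_len(out_h) - 0.5) * h / out_h - 0.5
  xg <- rep(xs, each = out_h)
  yg <- rep(ys, times = out_w)
  xg <- pmin(pmax(xg, 0), w - 1)
  yg <- pmin(pmax(yg, 0), h - 1)
  matrix(ws_bilinear(img, xg, yg), out_h, out_w)
}

# Apply a function to a grayscale matrix or channelwise to an H x W x C array.
ws_per_channel <- function(img, f) {
  if (is.matrix(img)) return(f(img))
  out <- img
  for (k in seq_len(dim(img)[3])) out[, , k] <- f(img[, , k])
  out
}

# Gaussian blur whose kernel is clamped to fit inside the image
# (EBImage::filter2 requires the filter to be no larger than the image).
ws_gblur <- function(x, sigma) {
  r <- 2 * ceiling(3 * sigma) + 1
  rmax <- min(dim(x))
  if (rmax %% 2 == 0) rmax <- rmax - 1
  EBImage::gblur(x, sigma = sigma, radius = min(r, rmax))
}

# 8-connected component labelling: 4-connected labels from EBImage::bwlabel,
# then labels touching diagonally are merged with a union-find pass.
ws_label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n <= 1) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]   # down-right diagonal
  a2 <- lab[-h, -1]; b2 <- lab[-1, -w]   # down-left diagonal
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  remap <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

ws_stopifnot_image <- function(img) {
  if (!(is.matrix(img) || (is.array(img) && length(dim(img)) == 3)))
    stop("image must be a matrix or an H x W x C array")
  if (length(img) == 0) stop("empty image")
  if (any(!is.finite(img))) stop("image contains non-finite pixels")
  invisible(TRUE)
}
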