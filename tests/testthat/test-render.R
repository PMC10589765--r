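test_that("background with all noise off is constant at bg_mean", {
  app <- test_appearance()
  bg <- make_background(app, c(80, 120), seed = 1)
  expect_equal(dim(bg), c(80, 120))
  expect_true(all(bg == 0.8))
})

test_that("speckle count matches its binomial expectation", {
  app <- test_appearance(speckle_density = 0.001)
  bg <- make_background(app, c(512, 512), seed = 7)
  n_speckle <- sum(bg != 0.8)
  expected <- 0.001 * 512^2            # 262.1
  sigma <- sqrt(512^2 * 0.001 * 0.999)
  expect_lt(abs(n_speckle - expected), 3 * sigma)
})

test_that("backgrounds are reproducible under a fixed seed", {
  app <- appearance_params()
  expect_identical(make_background(app, c(100, 100), seed = 3),
                   make_background(app, c(100, 100), seed = 3))
})

test_that("worm rendering honours its degenerate and polarity contracts", {
  wm <- generate_worm_mask("wild-type", seed = 2)
  app <- test_appearance()
  cr <- render_worm(wm, app, seed = 1)
  # flat shading: constant silhouette at fg_mean
  expect_true(all(cr$patch[wm$raster] == 0.2))
  expect_true(all(cr$patch[!wm$raster] == 0))
  # blur off: alpha identical to the mask
  expect_identical(cr$alpha, wm$raster * 1)
  # dark-on-light: body darker than background
  app2 <- appearance_params()
  cr2 <- render_worm(wm, app2, seed = 1)
  expect_lt(mean(cr2$patch[wm$raster]), app2$bg_mean)
})

test_that("scene placement respects counts, overlap and bbox tightness", {
  app <- test_appearance()
  crops <- lapply(1:5, function(i)
    render_worm(generate_worm_mask("wild-type", seed = i), app,
                seed = 100 + i))
  bg <- make_background(app, c(640, 640), seed = 1)
  spec <- scene_spec(canvas = c(640, 640), n_worms = 5, max_overlap_frac = 0)
  sc <- place_worms(bg, crops, spec, seed = 9)
  expect_equal(sc$n_placed, 5)
  expect_equal(nrow(sc$labels), 5)
  expect_true(sc$placement_ok)
  # masks pairwise disjoint in scene coordinates
  full <- lapply(sc$placements, function(p) {
    m <- matrix(FALSE, 640, 640)
    m[p$y0 + seq_len(nrow(p$mask)), p$x0 + seq_len(ncol(p$mask))] <- p$mask
    m
  })
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(sum(full[[i]] & full[[j]]), 0)
  # recorded bbox equals the per-pixel oracle on the composited mask
  for (k in 1:5)
    expect_equal(unname(sc$placements[[k]]$bbox_px),
                 unname(oracle_mask_bbox(full[[k]])))
})

test_that("an empty scene is exactly the background", {
  app <- test_appearance()
  bg <- make_background(app, c(128, 128), seed = 2)
  sc <- place_worms(bg, list(), scene_spec(canvas = c(128, 128), n_worms = 0),
                    seed = 1)
  expect_identical(sc$image, bg)
  expect_equal(nrow(sc$labels), 0)
})

test_that("exported labels denormalize to the tight mask bbox", {
  ds <- cached_scene_set(20, seed = 31)
  for (sc in ds$scenes) {
    expect_equal(nrow(sc$labels), sc$n_placed)  # label conservation
    expect_true(all(sc$labels$cx >= 0 & sc$labels$cx <= 1))
    expect_true(all(sc$labels$w > 0 & sc$labels$w <= 1))
    for (k in seq_len(sc$n_placed)) {
      px <- norm_bbox_to_pixel(sc$labels[k, ], dim(sc$image))
      expect_equal(unname(px), unname(sc$placements[[k]]$bbox_px),
                   tolerance = 1e-9)
    }
  }
})

test_that("HSV jitter is identity at zero gain and bounded otherwise", {
  img <- array(runif(40 * 40 * 3), dim = c(40, 40, 3))
  expect_identical(hsv_jitter(img, c(0, 0, 0), seed = 1), img)
  out <- hsv_jitter(img, c(0.015, 0.7, 0.4), seed = 5)
  expect_true(all(out >= 0 & out <= 1))
  expect_identical(out, hsv_jitter(img, c(0.015, 0.7, 0.4), seed = 5))
  # grayscale degrades to a value-only gain
  g <- matrix(runif(100), 10, 10)
  out_g <- hsv_jitter(g, c(0.015, 0.7, 0.4), seed = 2)
  ratio <- out_g[g > 0 & out_g < 1] / g[g > 0 & out_g < 1]
  expect_lt(diff(range(ratio)), 1e-12)
})

test_that("geometric augmentation: identity, involution and label fidelity", {
  sc <- cached_scene_set(20, seed = 31)$scenes[[1]]
  # identity configuration changes nothing
  out <- geometric_augment(sc$image, sc$labels, translate = 0, scale = 0,
                           fliplr_p = 0, seed = 1)
  expect_identical(out$image, sc$image)
  expect_identical(out$labels, sc$labels)
  # flipping twice restores the original exactly
  f1 <- flip_horizontal(sc$image, sc$labels)
  f2 <- flip_horizontal(f1$image, f1$labels)
  expect_identical(f2$image, sc$image)
  expect_equal(f2$labels, sc$labels, tolerance = 1e-12)
  # transformed bbox equals bbox of the transformed mask (flip case)
  for (k in seq_len(sc$n_placed)) {
    p <- sc$placements[[k]]
    full <- matrix(FALSE, nrow(sc$image), ncol(sc$image))
    full[p$y0 + seq_len(nrow(p$mask)), p$x0 + seq_len(ncol(p$mask))] <- p$mask
    flipped_mask <- full[, rev(seq_len(ncol(full)))]
    bb <- mask_to_bbox(flipped_mask)
    lab <- f1$labels[k, ]
    expect_equal(lab$cx, bb$cx, tolerance = 1e-9)
    expect_equal(lab$w, bb$w, tolerance = 1e-9)
  }
})

test_that("geometric augmentation transforms labels with the image", {
  # a scaled/translated mask-backed worm: label must match the bbox of the
  # identically transformed mask
  app <- test_appearance()
  wm <- generate_worm_mask("wild-type", seed = 12)
  bg <- make_background(app, c(400, 400), seed = 1)
  cr <- render_worm(wm, app)
  sc <- place_worms(bg, list(cr), scene_spec(canvas = c(400, 400), n_worms = 1),
                    seed = 3)
  out <- geometric_augment(sc$image, sc$labels, translate = 0.1, scale = 0.3,
                           fliplr_p = 1, seed = 77)
  # recover the transform by re-running the RNG draws
  draws <- withr::with_seed(77L, runif(4))
  scf <- 1 - 0.3 + draws[1] * 0.6
  tx <- (draws[2] * 2 - 1) * 0.1 * 400
  ty <- (draws[3] * 2 - 1) * 0.1 * 400
  # rasterize-then-box oracle: warp the binary mask with the same affine map
  full <- matrix(0, 400, 400)
  p <- sc$placements[[1]]
  full[p$y0 + seq_len(nrow(p$mask)), p$x0 + seq_len(ncol(p$mask))] <- p$mask
  xs <- rep(0:399, each = 400); ys <- rep(0:399, times = 400)
  xi <- 399 - xs  # flip
  sx <- (xi - 199.5 - tx) / scf + 199.5
  sy <- (ys - 199.5 - ty) / scf + 199.5
  ok <- sx >= 0 & sx <= 399 & sy >= 0 & sy <= 399
  warped <- matrix(FALSE, 400, 400)
  warped[cbind(ys + 1, xs + 1)[ok, ]] <-
    full[cbind(round(sy) + 1, round(sx) + 1)[ok, ]] > 0.5
  bb <- mask_to_bbox(warped)
  expect_equal(out$labels$cx, bb$cx, tolerance = 0.01)
  expect_equal(out$labels$cy, bb$cy, tolerance = 0.01)
  expect_equal(out$labels$w, bb$w, tolerance = 0.03)
  expect_equal(out$labels$h, bb$h, tolerance = 0.03)
})

test_that("mosaic composes four scenes with clipped, conserved labels", {
  ds <- cached_scene_set(20, seed = 31)
  quads <- lapply(ds$scenes[1:4], function(s)
    list(image = s$image, labels = s$labels))
  mo <- mosaic(quads, out_canvas = c(640, 640), seed = 5)
  expect_equal(dim(mo$image), c(640, 640))
  n_src <- sum(vapply(quads, function(q) nrow(q$labels), numeric(1)))
  expect_lte(nrow(mo$labels), n_src)
  expect_gt(nrow(mo$labels), 0)
  x1 <- mo$labels$cx - mo$labels$w / 2
  x2 <- mo$labels$cx + mo$labels$w / 2
  expect_true(all(x1 >= -1e-9 & x2 <= 1 + 1e-9))
  # four one-worm scenes, centred worms: nothing is lost
  one <- lapply(c(41, 42, 43, 44), function(s) {
    sc <- generate_scene(seed = s, appearance = test_appearance(),
                         spec = scene_spec(canvas = c(320, 320), n_worms = 1))
    list(image = sc$image, labels = sc$labels)
  })
  mo1 <- mosaic(one, out_canvas = c(640, 640), seed = 1)
  expect_equal(nrow(mo1$labels), 4)
})

test_that("letterbox resize follows the exact arithmetic and inverts", {
  img <- matrix(runif(500 * 1000), 500, 1000)
  labs <- random_yolo_labels(5)
  out <- letterbox_resize(img, labs, 1728)
  expect_equal(dim(out$image), c(1728, 1728))
  expect_equal(out$transform$scale, 1.728)
  expect_equal(out$transform$pad_y, 432)  # (1728 - 500 * 1.728) / 2
  expect_equal(out$transform$pad_x, 0)
  back <- letterbox_invert(out$labels, out$transform)
  expect_equal(back$cx, labs$cx, tolerance = 1e-6)
  expect_equal(back$w, labs$w, tolerance = 1e-6)
  # square input at target size: identity transform
  sq <- matrix(runif(64 * 64), 64, 64)
  out2 <- letterbox_resize(sq, random_yolo_labels(2), 64)
  expect_equal(out2$transform$scale, 1)
  expect_equal(out2$transform$pad_x + out2$transform$pad_y, 0)
  expect_equal(out2$image, sq)
  expect_error(letterbox_resize(img, labs, 1000), "multiple of 32")
})

test_that("generation is a pure function of (config, seed)", {
  a <- generate_scene(seed = 17, spec = scene_spec(n_worms = 3))
  b <- generate_scene(seed = 17, spec = scene_spec(n_worms = 3))
  expect_identical(a$image, b$image)
  expect_identical(a$labels, b$labels)
})
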