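# Shared, lazily built scene fixtures (generated in code, cached per run).
ws_test_cache <- new.env(parent = emptyenv())

cached_scene_set <- function(n, seed = 42, key = sprintf("set_%d_%d", n, seed)) {
  if (is.null(ws_test_cache[[key]]))
    ws_test_cache[[key]] <- generate_dataset(n, seed = seed)
  ws_test_cache[[key]]
}

# a crisp, high-contrast appearance used by small unit tests
test_appearance <- function(...) {
  args <- utils::modifyList(
    list(fg_mean = 0.2, fg_std = 0, edge_gain = 0, texture_scale = 0,
         blur_sigma = 0, bg_mean = 0.8, bg_std = 0, vignette_strength = 0,
         speckle_density = 0),
    list(...))
  do.call(appearance_params, args)
}

straight_centerline <- function(length_px = 300, n = 121, y = 0) {
  structure(list(points = cbind(x = seq(0, length_px, length.out = n),
                                y = rep(y, n)),
                 arclength = length_px, phase = 0, rotation = 0),
            class = "centerline")
}
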