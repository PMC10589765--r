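#' Default run configuration
#'
#' Nested configuration covering every pipeline stage. A YAML file with the
#' same structure can override any subset of values; unknown keys are
#' rejected with the full key path, so typos never silently fall back to
#' defaults.
#'
#' @return Nested list of per-stage settings.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    shapes = list(preset = "wild-type"),
    render = list(
      polarity = "dark-on-light", fg_mean = 0.25, fg_std = 0.04,
      edge_gain = 0.25, texture_scale = 6, blur_sigma = 0.8,
      bg_mean = 0.78, bg_std = 0.02, vignette_strength = 0.10,
      speckle_density = 2e-5,
      canvas = c(640L, 640L), n_worms_range = c(1L, 5L),
      max_overlap_frac = 0
    ),
    detector = list(
      flatten_kernel_px = 25, polarity = "auto", min_area_px = 150,
      max_area_px = 1e6, min_elongation = 1.3
    ),
    selflabel = list(seconds_per_worm = 5),
    evaluate = list(iou_threshold = 0.5, ap_method = "exact"),
    augment = list(hsv_h = 0.015, hsv_s = 0.7, hsv_v = 0.4,
                   translate = 0.1, scale = 0.5, fliplr_p = 0.5,
                   mosaic_p = 1.0)
  )
}

ws_merge_config <- function(base, override, path = character(0)) {
  for (k in names(override)) {
    here <- paste(c(path, k), collapse = ".")
    if (!k %in% names(base))
      stop("unknown config key: ", here)
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      if (!is.list(override[[k]]))
        stop("config key ", here, " must be a mapping")
      base[[k]] <- ws_merge_config(base[[k]], override[[k]], c(path, k))
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Load and validate a run configuration
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Validated configuration list (defaults merged with overrides).
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    ov <- yaml::read_yaml(path)
    cfg <- ws_merge_config(cfg, ov)
  }
  cfg
}

cfg_appearance <- function(cfg) {
  r <- cfg$render
  appearance_params(polarity = r$polarity, fg_mean = r$fg_mean,
                    fg_std = r$fg_std, edge_gain = r$edge_gain,
                    texture_scale = r$texture_scale, blur_sigma = r$blur_sigma,
                    bg_mean = r$bg_mean, bg_std = r$bg_std,
                    vignette_strength = r$vignette_strength,
                    speckle_density = r$speckle_density)
}

cfg_detector <- function(cfg) {
  d <- cfg$detector
  detector_params(flatten_kernel_px = d$flatten_kernel_px,
                  polarity = d$polarity, min_area_px = d$min_area_px,
                  max_area_px = d$max_area_px,
                  min_elongation = d$min_elongation)
}

#' Generate a labelled synthetic dataset
#'
#' Generates `n_images` scenes (worm count drawn uniformly from
#' `n_worms_range`), optionally writing `images/*.png`, `labels/*.txt` and
#' a `manifest.tsv` (image id, seed, strain, worm count) under `out_dir`.
#' The dataset is a pure function of `(config, seed)`.
#'
#' @param n_images Number of scenes.
#' @param config Configuration from [load_config()].
#' @param seed Integer root seed.
#' @param out_dir Optional output directory.
#' @return Invisible list with `scenes` (list of `synthetic_scene`),
#'   `labels` (named list of label data frames) and `manifest`.
#' @export
generate_dataset <- function(n_images, config = default_config(), seed = 1,
                             out_dir = NULL) {
  app <- cfg_appearance(config)
  canvas <- config$render$canvas
  nr <- config$render$n_worms_range
  scenes <- vector("list", n_images)
  labels <- vector("list", n_images)
  ids <- sprintf("img_%04d", seq_len(n_images))
  manifest <- data.frame(id = ids, seed = integer(n_images),
                         strain = character(n_images),
                         n_worms = integer(n_images))
  for (i in seq_len(n_images)) {
    si <- derive_seed(seed, 100L, i)
    n_worms <- ws_with_seed(derive_seed(si, 1L),
                            sample(seq(nr[1], nr[2]), 1))
    spec <- scene_spec(canvas = canvas, n_worms = n_worms,
                       max_overlap_frac = config$render$max_overlap_frac)
    sc <- generate_scene(preset = config$shapes$preset, appearance = app,
                         spec = spec, seed = si)
    scenes[[i]] <- sc
    labels[[i]] <- sc$labels
    manifest$seed[i] <- si
    manifest$strain[i] <- config$shapes$preset
    manifest$n_worms[i] <- sc$n_placed
  }
  names(scenes) <- ids
  names(labels) <- ids
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "labels"), recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n_images)) {
      png::writePNG(scenes[[i]]$image,
                    file.path(out_dir, "images", paste0(ids[i], ".png")))
      write_yolo_labels(labels[[i]],
                        file.path(out_dir, "labels", paste0(ids[i], ".txt")))
    }
    write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  invisible(list(scenes = scenes, labels = labels, manifest = manifest))
}

#' Run the full demonstration pipeline
#'
#' Chains all stages on a small seeded dataset: generate labelled scenes,
#' run the baseline detector, evaluate (precision / recall / AP@0.5),
#' perform one self-labeling round on a pool (capped inference +
#' count-filter, with an accept-all stand-in for the manual review), and
#' compute the bundled replicate-statistics comparison. Deterministic for a
#' fixed `(config, seed)`.
#'
#' @param seed Integer root seed.
#' @param n_images Number of evaluation scenes.
#' @param pool_size Number of scenes in the self-labeling pool.
#' @param config Configuration list.
#' @param out Optional path for the JSON summary report.
#' @return The summary as a list (invisibly if `out` is given).
#' @export
run_demo <- function(seed = 1, n_images = 200, pool_size = 100,
                     config = default_config(), out = NULL) {
  ds <- generate_dataset(n_images, config, seed = derive_seed(seed, 1L))
  det_params <- cfg_detector(config)
  detections <- lapply(ds$scenes, function(sc) detect_worms(sc$image, det_params))
  ev <- evaluate_dataset(detections, ds$labels,
                         iou_threshold = config$evaluate$iou_threshold,
                         image_shape = config$render$canvas,
                         method = config$evaluate$ap_method)
  # self-labeling round on a fresh pool
  pool_idx <- seq_len(min(pool_size, n_images))
  pds <- generate_dataset(pool_size, config, seed = derive_seed(seed, 2L))
  pool <- image_pool(names(pds$scenes),
                     vapply(pds$scenes, function(s) s$n_placed, numeric(1)))
  images <- lapply(pds$scenes, `[[`, "image")
  capped <- capped_inference(images, pool, det_params)
  report <- filter_by_count(capped, pool)
  decisions <- data.frame(id = report$id[report$kept], accept = TRUE)
  accepted <- apply_review(report, decisions)
  n_worms_acc <- sum(vapply(accepted, nrow, numeric(1)))
  stats <- compare_methods()
  summary <- list(
    seed = seed,
    n_images = n_images,
    evaluation = list(precision = as.numeric(ev$precision),
                      recall = as.numeric(ev$recall), ap50 = ev$ap,
                      tp = ev$tp, fp = ev$fp, fn = ev$fn),
    selflabel = list(pool_size = nrow(pool), kept = sum(report$kept),
                     deleted_zero = sum(report$reason == "zero-detections"),
                     deleted_undercount = sum(report$reason == "undercount"),
                     accepted_worms = n_worms_acc,
                     est_hours_saved = estimate_time_saved(
                       n_worms_acc, config$selflabel$seconds_per_worm)),
    method_comparison = lapply(seq_len(nrow(stats)), function(i)
      list(method = stats$method[i], p_value = stats$p_value[i]))
  )
  if (!is.null(out)) {
    dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(summary))
  }
  summary
}
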