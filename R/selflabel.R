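#' Image pool for self-labeling
#'
#' The supervised self-labeling workflow starts from a pool of unlabeled
#' images whose per-image worm counts are known (e.g. frames from videos of
#' plates seeded with a known number of animals). The pool manifest makes
#' those expected counts an explicit input.
#'
#' @param ids Character vector of unique image ids.
#' @param expected_counts Integer vector of expected worm counts (`>= 0`).
#' @return An object of class `image_pool`: data frame
#'   `(id, expected_count)`.
#' @export
image_pool <- function(ids, expected_counts) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("image ids must be unique")
  if (length(ids) != length(expected_counts))
    stop("ids and expected_counts must have the same length")
  ec <- as.integer(expected_counts)
  if (any(is.na(ec)) || any(ec < 0))
    stop("expected counts must be non-negative integers")
  structure(data.frame(id = ids, expected_count = ec),
            class = c("image_pool", "data.frame"))
}

#' Read / write a pool manifest
#'
#' Tab-separated text with columns `id` and `expected_count`.
#'
#' @param path File path.
#' @param pool An `image_pool`.
#' @export
read_pool <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  image_pool(df$id, df$expected_count)
}

#' @rdname read_pool
#' @export
write_pool <- function(pool, path) {
  write.table(pool, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Group pool images by expected worm count
#'
#' First step of the self-labeling procedure: images are separated by the
#' number of worms each is known to contain, so inference can be capped per
#' group.
#'
#' @param pool An [image_pool()].
#' @return Named list mapping each distinct count (as character) to the
#'   vector of image ids with that count; the groups partition the pool.
#' @export
group_by_count <- function(pool) {
  if (nrow(pool) == 0) return(structure(list(), names = character(0)))
  split(pool$id, pool$expected_count)
}

#' Capped inference over a pool
#'
#' Runs a detector on every image with the per-image detection cap set to
#' the image's expected count (the `--max-detect` idea): the detector can
#' never report more worms than are known to be present, which makes
#' overcounting impossible and undercounting detectable.
#'
#' @param images Named list of image matrices keyed by pool id.
#' @param pool An [image_pool()].
#' @param params Base [detector_params()]; `max_detections` is overridden
#'   per image.
#' @return Named list of detection data frames keyed by image id.
#' @export
capped_inference <- function(images, pool, params = detector_params()) {
  missing_imgs <- setdiff(pool$id, names(images))
  if (length(missing_imgs))
    stop("no image supplied for pool ids: ",
         paste(utils::head(missing_imgs, 5), collapse = ", "))
  out <- lapply(seq_len(nrow(pool)), function(i) {
    p <- params
    p$max_detections <- pool$expected_count[i]
    detect_worms(images[[pool$id[i]]], p)
  })
  names(out) <- pool$id
  out
}

#' Filter images by detection count
#'
#' Third step of the self-labeling procedure: an image is kept if and only
#' if the number of detected worms equals its expected count. Deleted images
#' are tagged with the reason (`zero-detections` when nothing was found,
#' `undercount` otherwise). Overcounts are impossible under capped
#' inference and raise an error if encountered. "Deleted" is a logical flag
#' in the report, not file removal, so every run is auditable.
#'
#' @param detections Named list of detection data frames keyed by image id.
#' @param pool An [image_pool()].
#' @return An object of class `filter_report`: data frame
#'   `(id, expected, detected, kept, reason)` plus the detections as an
#'   attribute.
#' @export
filter_by_count <- function(detections, pool) {
  unknown <- setdiff(names(detections), pool$id)
  if (length(unknown))
    stop("detections for unknown image ids: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  missing_det <- setdiff(pool$id, names(detections))
  if (length(missing_det))
    stop("missing detections for pool ids: ",
         paste(utils::head(missing_det, 5), collapse = ", "))
  detected <- vapply(pool$id, function(id) nrow(detections[[id]]), numeric(1))
  over <- detected > pool$expected_count
  if (any(over))
    stop("detected more worms than expected for: ",
         paste(utils::head(pool$id[over], 5), collapse = ", "),
         " (was inference capped?)")
  kept <- detected == pool$expected_count
  reason <- ifelse(kept, "kept",
                   ifelse(detected == 0, "zero-detections", "undercount"))
  # an expected 0 image with 0 detections is a correct (kept) image
  rep <- data.frame(id = pool$id, expected = pool$expected_count,
                    detected = as.integer(detected), kept = kept,
                    reason = reason)
  structure(rep, detections = detections,
            class = c("filter_report", "data.frame"))
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Self-labeling filter: %d images, %d kept, %d deleted (%d zero, %d undercount)\n",
              nrow(x), sum(x$kept), sum(!x$kept),
              sum(x$reason == "zero-detections"),
              sum(x$reason == "undercount")))
  invisible(x)
}

#' Apply manual review decisions
#'
#' Fourth step: kept images are reviewed by a human and only the accepted
#' ones enter the training set. Decisions may only refer to kept images.
#' The accepted detection files are re-emitted as 5-column label files
#' (confidence stripped), ready for training ingestion.
#'
#' @param report A [filter_by_count()] report.
#' @param decisions Data frame `(id, accept)` with logical `accept`,
#'   covering a subset of the kept images; omitted kept images count as
#'   rejected.
#' @return Named list of label data frames `(class, cx, cy, w, h)` for the
#'   accepted images.
#' @export
apply_review <- function(report, decisions) {
  kept_ids <- report$id[report$kept]
  bad <- setdiff(decisions$id, kept_ids)
  if (length(bad))
    stop("review decisions refer to images that were not kept: ",
         paste(utils::head(bad, 5), collapse = ", "))
  acc <- decisions$id[as.logical(decisions$accept)]
  dets <- attr(report, "detections")
  out <- lapply(acc, function(id)
    dets[[id]][, c("class", "cx", "cy", "w", "h"), drop = FALSE])
  names(out) <- acc
  out
}

#' Estimate manual-labeling time saved
#'
#' Hours of manual annotation avoided by auto-labeling `n_worms` worms,
#' assuming a constant manual speed (default 5 s per worm). Reported at one
#' decimal place.
#'
#' @param n_worms Number of worms labeled automatically.
#' @param seconds_per_worm Manual labeling speed, default 5.
#' @return Hours, rounded to 1 decimal.
#' @examples
#' estimate_time_saved(10468)  # 14.5 hours
#' @export
estimate_time_saved <- function(n_worms, seconds_per_worm = 5) {
  if (n_worms < 0) stop("n_worms must be >= 0")
  round(n_worms * seconds_per_worm / 3600, 1)
}

#' Iteration bookkeeping for self-labeling rounds
#'
#' The self-labeling loop is repeated with a retrained (here: reconfigured)
#' detector; each round can only add accepted images, so the cumulative
#' totals are non-decreasing.
#'
#' @return `new_iteration_log()`: an empty log (class `iteration_log`).
#' @export
new_iteration_log <- function() {
  structure(data.frame(iteration = integer(0), pool_size = integer(0),
                       kept = integer(0), accepted = integer(0),
                       cum_accepted = integer(0), cum_worms = integer(0)),
            class = c("iteration_log", "data.frame"))
}

#' @rdname new_iteration_log
#' @param log An `iteration_log`.
#' @param pool_size,kept,accepted,worms This round's pool size, kept-image
#'   count, accepted-image count and accepted worm count.
#' @export
log_iteration <- function(log, pool_size, kept, accepted, worms) {
  prev_a <- if (nrow(log)) log$cum_accepted[nrow(log)] else 0L
  prev_w <- if (nrow(log)) log$cum_worms[nrow(log)] else 0L
  row <- data.frame(iteration = nrow(log) + 1L,
                    pool_size = as.integer(pool_size),
                    kept = as.integer(kept), accepted = as.integer(accepted),
                    cum_accepted = prev_a + as.integer(accepted),
                    cum_worms = prev_w + as.integer(worms))
  out <- rbind(as.data.frame(log), row)
  structure(out, class = c("iteration_log", "data.frame"))
}
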