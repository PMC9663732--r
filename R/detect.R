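#' Reference detector configuration
#'
#' The reference per-slice detector is a deterministic stand-in for a trained
#' 2D detection network: it thresholds the normalized slice inside the brain
#' mask, takes connected components, and gates them by area and circularity.
#' The circularity gate (`4 * pi * area / perimeter^2`) rejects elongated
#' residues of insufficiently suppressed vessels, the dominant false-positive
#' class on black-blood contrast; enhancing metastases present as compact,
#' near-circular cross-sections.
#'
#' Area gate defaults derive from the 5 mm lesion floor at the current pixel
#' size: the minimum is the area of a 1 mm-radius disc (the smallest
#' cross-section the phantom guarantees visible on two slices) and the
#' maximum is 1.2 times the equatorial area of a 25 mm lesion.
#'
#' @param intensity_threshold cutoff on normalized intensity in (0, 1).
#' @param min_area_px,max_area_px connected-component area gates in pixels.
#' @param min_circularity lower gate on `4 * pi * area / perimeter^2`
#'   (clamped to `[0, 1]`; the perimeter estimate is a boundary-pixel count).
#' @param pixel_size_mm pixel spacing used to derive the default area gates.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(intensity_threshold = 0.6,
                            min_area_px = NULL, max_area_px = NULL,
                            min_circularity = 0.4,
                            pixel_size_mm = c(0.9, 0.9)) {
  px_area <- prod(pixel_size_mm)
  if (is.null(min_area_px)) min_area_px <- max(3L, floor(pi * 1.0^2 / px_area))
  if (is.null(max_area_px)) max_area_px <- ceiling(1.2 * pi * 12.5^2 / px_area)
  if (intensity_threshold <= 0 || intensity_threshold >= 1)
    stop("intensity_threshold must be in (0, 1)")
  if (min_area_px > max_area_px) stop("min_area_px must be <= max_area_px")
  if (min_circularity < 0 || min_circularity > 1)
    stop("min_circularity must be in [0, 1]")
  structure(list(intensity_threshold = as.numeric(intensity_threshold),
                 min_area_px = as.numeric(min_area_px),
                 max_area_px = as.numeric(max_area_px),
                 min_circularity = as.numeric(min_circularity)),
            class = "detector_config")
}

#' Run the reference detector on every slice
#'
#' Per slice: threshold the normalized intensities, intersect with the brain
#' mask, label connected components (4-connectivity), apply the area and
#' circularity gates, and emit the tight bounding box of each surviving
#' component. The score is the component's mean normalized intensity times
#' its circularity, clamped to `[0, 1]`. Fully deterministic.
#'
#' @param v a [bm_volume] normalized to `[0, 1]` (see [normalize_slices()]).
#' @param mask logical brain mask congruent with `v`.
#' @param cfg a [detector_config].
#' @return A box table with `score` filled and `lesion_id` empty.
#' @export
detect_slices <- function(v, mask, cfg = detector_config()) {
  stopifnot(inherits(v, "bm_volume"), inherits(cfg, "detector_config"))
  rng <- range(v$data)
  if (rng[1] < 0 || rng[2] > 1)
    stop("detect_slices expects a volume normalized to [0, 1]")
  nr <- dim(v$data)[1]
  acc <- list()
  for (s in seq_len(dim(v$data)[3])) {
    sl <- v$data[, , s]
    bin <- (sl > cfg$intensity_threshold) & mask[, , s]
    if (!any(bin)) next
    labs <- EBImage::bwlabel(bin * 1)
    nz <- which(labs > 0)
    lb <- as.integer(labs[nz])
    nlab <- max(lb)
    areas <- tabulate(lb, nbins = nlab)
    cand <- which(areas >= cfg$min_area_px & areas <= cfg$max_area_px)
    if (!length(cand)) next
    shp <- EBImage::computeFeatures.shape(labs)
    circ <- pmin(1, 4 * pi * shp[, "s.area"] / pmax(shp[, "s.perimeter"], 1)^2)
    cand <- cand[circ[cand] >= cfg$min_circularity]
    if (!length(cand)) next
    sel <- lb %in% cand
    sp <- split(nz[sel], factor(lb[sel], levels = cand))
    rr0 <- lapply(sp, function(i) (i - 1L) %% nr)        # 0-based rows
    cc0 <- lapply(sp, function(i) (i - 1L) %/% nr)       # 0-based cols
    ymin <- vapply(rr0, min, 0); ymax <- vapply(rr0, max, 0)
    xmin <- vapply(cc0, min, 0); xmax <- vapply(cc0, max, 0)
    score <- pmin(1, vapply(sp, function(i) mean(sl[i]), 0) * circ[cand])
    acc[[length(acc) + 1L]] <- data.frame(
      slice_index = s - 1L, x = xmin, y = ymin,
      w = xmax - xmin + 1, h = ymax - ymin + 1, score = score)
  }
  if (!length(acc)) return(boxes_df())
  res <- do.call(rbind, acc)
  boxes_df(v$scan_id, res$slice_index, res$x, res$y, res$w, res$h,
           res$score, NA_integer_)
}

#' Augment a slice image and its boxes by a rotation/flip isometry
#'
#' Rotations of 0, 90, 180 or 270 degrees (clockwise, with row 1 displayed on
#' top) followed optionally by a left-right flip, the augmentation group used
#' to compensate for scarce training data. Boxes are mapped by the same
#' isometry; e.g. 180 degrees in a W x H image sends `(x, y, w, h)` to
#' `(W - x - w, H - y - h, w, h)`.
#'
#' @param image 2D numeric matrix (rows x cols).
#' @param boxes box table whose boxes lie within the image.
#' @param rot one of 0, 90, 180, 270 (degrees clockwise).
#' @param flip_lr flip left-right after rotating?
#' @return A list with `image` and `boxes`.
#' @export
augment <- function(image, boxes, rot = 0L, flip_lr = FALSE) {
  if (!rot %in% c(0L, 90L, 180L, 270L))
    stop("rot must be one of 0, 90, 180, 270")
  validate_boxes(boxes)
  b <- boxes
  for (q in seq_len(rot / 90)) {
    H <- nrow(image)
    image <- t(image[H:1, , drop = FALSE])
    b2 <- b
    b2$x <- H - b$y - b$h
    b2$y <- b$x
    b2$w <- b$h
    b2$h <- b$w
    b <- b2
  }
  if (flip_lr) {
    W <- ncol(image)
    image <- image[, W:1, drop = FALSE]
    b$x <- W - b$x - b$w
  }
  validate_boxes(b)
  list(image = image, boxes = b)
}

#' Estimate anchor boxes by IoU k-means
#'
#' Clusters label box shapes `(w, h)` into `k` prototype anchors with Lloyd
#' iterations under the distance `1 - IoU` of centered boxes (the standard
#' practice for single-shot detectors), with farthest-point initialization
#' from a seeded random start. Anchors are returned sorted by area.
#'
#' @param boxes box table with at least `k` rows.
#' @param k number of anchors; 7 by default.
#' @param seed RNG seed for the initialization.
#' @param max_iter Lloyd iteration cap.
#' @return A data.frame of class `anchor_set` with columns `w`, `h`.
#' @export
estimate_anchors <- function(boxes, k = 7L, seed = 1L, max_iter = 100L) {
  validate_boxes(boxes)
  wh <- cbind(boxes$w, boxes$h)
  if (nrow(wh) < k) stop(sprintf("need at least k = %d boxes, got %d", k, nrow(wh)))
  centered_iou <- function(wh1, anchors) {
    # wh1: n x 2, anchors: k x 2 -> n x k IoU of co-centered rectangles
    iw <- outer(wh1[, 1], anchors[, 1], pmin)
    ih <- outer(wh1[, 2], anchors[, 2], pmin)
    inter <- iw * ih
    inter / (outer(wh1[, 1] * wh1[, 2], anchors[, 1] * anchors[, 2], `+`) - inter)
  }
  anchors <- with_seed(seed, {
    a <- wh[sample.int(nrow(wh), 1L), , drop = FALSE]
    while (nrow(a) < k) {
      d <- 1 - centered_iou(wh, a)
      nearest <- apply(d, 1, min)
      a <- rbind(a, wh[which.max(nearest), , drop = FALSE])
    }
    a
  })
  assign_prev <- rep(0L, nrow(wh))
  for (it in seq_len(max_iter)) {
    d <- 1 - centered_iou(wh, anchors)
    assign_now <- max.col(-d, ties.method = "first")
    for (j in seq_len(k)) {
      members <- wh[assign_now == j, , drop = FALSE]
      if (nrow(members) == 0) {  # re-seed an empty cluster deterministically
        worst <- which.max(d[cbind(seq_len(nrow(wh)), assign_now)])
        anchors[j, ] <- wh[worst, ]
        assign_now[worst] <- j
      } else {
        anchors[j, ] <- colMeans(members)
      }
    }
    if (identical(assign_now, assign_prev)) break
    assign_prev <- assign_now
  }
  anchors <- anchors[order(anchors[, 1] * anchors[, 2]), , drop = FALSE]
  structure(data.frame(w = anchors[, 1], h = anchors[, 2]),
            class = c("anchor_set", "data.frame"))
}

#' Default calibration grid for the reference detector
#'
#' The search space stands in for network training: the intensity threshold
#' governs how far into the noise tail the detector reaches, and the
#' circularity gate how aggressively elongated vessel residues are rejected.
#'
#' @param pixel_size_mm pixel spacing forwarded to [detector_config()].
#' @return A list of `detector_config` objects.
#' @export
default_detector_grid <- function(pixel_size_mm = c(0.9, 0.9)) {
  g <- expand.grid(intensity_threshold = c(0.55, 0.7),
                   min_circularity = c(0.35, 0.5, 0.65))
  lapply(seq_len(nrow(g)), function(i)
    detector_config(intensity_threshold = g$intensity_threshold[i],
                    min_circularity = g$min_circularity[i],
                    pixel_size_mm = pixel_size_mm))
}

# Lesion-level counts for one preprocessed scan under one detector config.
detect_and_count <- function(scan, cfg, linker, eval_cfg) {
  det <- detect_slices(scan$norm, scan$mask, cfg)
  pred <- link_boxes(det, linker)
  match_lesions(scan$gt_linked, pred, eval_cfg, scan_id = scan$norm$scan_id)
}

# Shared selection rule: maximize pooled F1, ties -> lower FP_avg,
# then lower intensity threshold, then grid order.
select_detector_config <- function(counts_by_config, grid) {
  stats <- lapply(counts_by_config, function(cnt) {
    tp <- sum(cnt$TP); fn <- sum(cnt$FN); fp <- sum(cnt$FP)
    f1 <- if (2 * tp + fn + fp == 0) -Inf else 100 * 2 * tp / (2 * tp + fn + fp)
    c(f1 = f1, fp_avg = fp / max(nrow(cnt), 1))
  })
  f1s <- vapply(stats, `[[`, 0, "f1")
  fps <- vapply(stats, `[[`, 0, "fp_avg")
  thr <- vapply(grid, `[[`, 0, "intensity_threshold")
  best <- order(-f1s, fps, thr, seq_along(grid))[1]
  list(index = best, config = grid[[best]], f1 = f1s[best], fp_avg = fps[best])
}

#' Calibrate the reference detector on training scans
#'
#' Exhaustive grid search standing in for network training inside the
#' cross-validation harness: every candidate configuration is run on every
#' training scan (detect, link, lesion-level match against the linked ground
#' truth) and the configuration maximizing the pooled lesion-level F1 is
#' returned; ties are broken by lower false positives per scan, then by lower
#' intensity threshold. Deterministic given fixed inputs.
#'
#' @param train_scans list of preprocessed scans, each a list with `norm`
#'   (normalized [bm_volume]), `mask` (brain mask) and `gt_linked` (linked
#'   ground-truth box table).
#' @param grid list of [detector_config] objects (non-empty).
#' @param linker a [linker_config] applied to predictions.
#' @param eval_cfg an [eval_config].
#' @return The selected `detector_config`, with attributes `train_f1` and
#'   `train_fp_avg`.
#' @export
calibrate_detector <- function(train_scans, grid = default_detector_grid(),
                               linker = linker_config(),
                               eval_cfg = eval_config()) {
  if (length(grid) == 0) stop("calibration grid is empty")
  if (length(train_scans) == 0) stop("need at least one training scan")
  counts <- lapply(grid, function(cfg)
    do.call(rbind, lapply(train_scans, detect_and_count,
                          cfg = cfg, linker = linker, eval_cfg = eval_cfg)))
  sel <- select_detector_config(counts, grid)
  out <- sel$config
  attr(out, "train_f1") <- sel$f1
  attr(out, "train_fp_avg") <- sel$fp_avg
  out
}
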