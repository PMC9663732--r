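# A normalized synthetic stack: background 0, structures painted at 1.
paint_volume <- function(painter, dims = c(64, 64, 3)) {
  a <- array(0, dims)
  a <- painter(a)
  list(v = bm_volume(a, pixel_size_mm = c(0.9, 0.9), scan_id = "synth"),
       mask = array(TRUE, dims))
}

disk_mask <- function(dims, cy, cx, r) {
  idx <- expand.grid(row = seq_len(dims[1]), col = seq_len(dims[2]))
  m <- matrix(FALSE, dims[1], dims[2])
  m[as.matrix(idx[(idx$row - cy)^2 + (idx$col - cx)^2 <= r^2, ])] <- TRUE
  m
}

test_that("a bright disk yields exactly one tight detection", {
  dm <- disk_mask(c(64, 64), 32, 30, 8)
  pv <- paint_volume(function(a) { a[, , 2][dm] <- 1; a })
  det <- detect_slices(pv$v, pv$mask)
  expect_equal(nrow(det), 1L)
  idx <- which(dm, arr.ind = TRUE)
  expect_lte(abs(det$x - (min(idx[, 2]) - 1)), 1)
  expect_lte(abs(det$y - (min(idx[, 1]) - 1)), 1)
  expect_lte(abs(det$w - diff(range(idx[, 2])) - 1), 1)
  expect_lte(abs(det$h - diff(range(idx[, 1])) - 1), 1)
  expect_equal(det$slice_index, 1L)
  expect_true(det$score > 0 && det$score <= 1)
})

test_that("all-zero slices yield no detections and thin lines are rejected", {
  pv <- paint_volume(function(a) a)
  expect_equal(nrow(detect_slices(pv$v, pv$mask)), 0L)
  pv <- paint_volume(function(a) { a[10:11, 3:62, 2] <- 1; a },
                     dims = c(64, 64, 3))
  expect_equal(nrow(detect_slices(pv$v, pv$mask)), 0L)
  # the same line passes when the circularity gate is disabled
  cfg <- detector_config(min_circularity = 0)
  expect_equal(nrow(detect_slices(pv$v, pv$mask, cfg)), 1L)
})

test_that("unnormalized input violates the detector contract", {
  pv <- paint_volume(function(a) { a[30, 30, 1] <- 2; a })
  expect_error(detect_slices(pv$v, pv$mask), "normalized")
})

test_that("detection is unchanged by scan relabeling and zero-slice padding", {
  dm <- disk_mask(c(64, 64), 20, 40, 6)
  pv <- paint_volume(function(a) { a[, , 2][dm] <- 0.9; a })
  det1 <- detect_slices(pv$v, pv$mask)
  v2 <- pv$v; v2$scan_id <- "other"
  det2 <- detect_slices(v2, pv$mask)
  expect_equal(det2[setdiff(names(det2), "scan_id")],
               det1[setdiff(names(det1), "scan_id")])
  padded <- array(0, c(64, 64, 5))
  padded[, , 2:4] <- pv$v$data
  det3 <- detect_slices(bm_volume(padded, c(0.9, 0.9), scan_id = "synth"),
                        array(TRUE, c(64, 64, 5)))
  expect_equal(det3$slice_index, det1$slice_index + 1L)
  expect_equal(det3[c("x", "y", "w", "h")], det1[c("x", "y", "w", "h")])
})

test_that("rotations and flips map boxes by the same isometry", {
  img <- matrix(seq_len(100 * 100), 100, 100)
  boxes <- b(0, 0, 0, 10, 20)
  out <- augment(img, boxes, rot = 180L)
  expect_equal(out$boxes[c("x", "y", "w", "h")],
               data.frame(x = 90, y = 80, w = 10, h = 20), ignore_attr = TRUE)
  id <- augment(img, boxes, rot = 0L, flip_lr = FALSE)
  expect_identical(id$image, img)
  expect_equal(id$boxes, boxes)
  expect_error(augment(img, boxes, rot = 45L), "rot")
})

test_that("four quarter-turns and double flips are the identity", {
  set.seed(2)
  img <- matrix(rnorm(80 * 60), 80, 60)
  boxes <- rbind(b(0, 3, 5, 10, 20), b(0, 40, 50, 12, 8), b(1, 0, 0, 60, 80))
  cur <- list(image = img, boxes = boxes)
  for (i in 1:4) cur <- augment(cur$image, cur$boxes, rot = 90L)
  expect_identical(cur$image, img)
  expect_equal(cur$boxes, boxes, ignore_attr = TRUE)
  flipped2 <- augment(augment(img, boxes, flip_lr = TRUE)$image,
                      augment(img, boxes, flip_lr = TRUE)$boxes,
                      flip_lr = TRUE)
  expect_identical(flipped2$image, img)
  expect_equal(flipped2$boxes, boxes, ignore_attr = TRUE)
})

test_that("pairwise IoU is invariant under any augmentation isometry", {
  set.seed(3)
  img <- matrix(0, 70, 90)
  for (i in 1:20) {
    b1 <- b(0, runif(1, 0, 40), runif(1, 0, 30), runif(1, 2, 20), runif(1, 2, 20))
    b2 <- b(0, runif(1, 0, 40), runif(1, 0, 30), runif(1, 2, 20), runif(1, 2, 20))
    both <- rbind(b1, b2)
    for (rot in c(0L, 90L, 180L, 270L)) for (fl in c(FALSE, TRUE)) {
      out <- augment(img, both, rot = rot, flip_lr = fl)
      expect_equal(box_iou(out$boxes[1, ], out$boxes[2, ]),
                   box_iou(b1, b2), tolerance = 1e-12)
    }
  }
})

test_that("anchor clustering recovers exact two-point structure", {
  wh <- rbind(matrix(rep(c(10, 10), 50), ncol = 2, byrow = TRUE),
              matrix(rep(c(30, 30), 50), ncol = 2, byrow = TRUE))
  boxes <- boxes_df("s", 0, 0, 0, wh[, 1], wh[, 2])
  anch <- estimate_anchors(boxes, k = 2, seed = 1)
  expect_equal(as.matrix(anch), matrix(c(10, 10, 30, 30), 2, byrow = TRUE),
               ignore_attr = TRUE)
  one <- estimate_anchors(boxes_df("s", 0, 0, 0, rep(12, 5), rep(12, 5)),
                          k = 1, seed = 1)
  expect_equal(unlist(one), c(w = 12, h = 12))
  expect_error(estimate_anchors(boxes[1:3, ], k = 7), "at least k")
})

test_that("anchor sets always have k members, sorted by area, deterministically", {
  set.seed(9)
  boxes <- random_boxes(60, n_slices = 3)
  for (k in c(2L, 5L, 7L)) {
    a1 <- estimate_anchors(boxes, k = k, seed = 11)
    a2 <- estimate_anchors(boxes, k = k, seed = 11)
    expect_equal(nrow(a1), k)
    expect_identical(a1, a2)
    expect_true(all(diff(a1$w * a1$h) >= 0))
  }
})

test_that("calibration returns the planted-truth optimum deterministically", {
  cfg <- small_config(n_lesions = 2L, seed = 55L)
  scans <- lapply(1:3, function(i) {
    c2 <- cfg; c2$seed <- cfg$seed + i
    sc <- generate_scan(c2)
    ex <- extract_brain(sc$volume)
    list(norm = normalize_slices(ex$stripped, ex$mask), mask = ex$mask,
         gt_linked = link_boxes(sc$truth$gt_boxes))
  })
  single <- list(detector_config(intensity_threshold = 0.7,
                                 pixel_size_mm = cfg$pixel_size_mm))
  expect_equal(calibrate_detector(scans, single), single[[1]],
               ignore_attr = TRUE)
  grid <- default_detector_grid(cfg$pixel_size_mm)
  best1 <- calibrate_detector(scans, grid)
  best2 <- calibrate_detector(scans, grid)
  expect_equal(best1, best2, ignore_attr = TRUE)
  # the selected config achieves full sensitivity on its own training scans
  counts <- do.call(rbind, lapply(scans, function(s)
    match_lesions(s$gt_linked,
                  link_boxes(detect_slices(s$norm, s$mask, best1)))))
  expect_equal(sum(counts$FN), 0L)
  expect_error(calibrate_detector(scans, list()), "empty")
})

test_that("noise-free phantoms yield >= 2 detected slices per planted lesion", {
  cfg <- phantom_config(grid = c(16L, 96L, 96L), pixel_size_mm = c(0.9, 0.9),
                        n_lesions = 2L, lesion_diameter_range_mm = c(5, 12),
                        n_vessels = 2L, noise_sigma = 0, seed = 83L)
  sc <- generate_scan(cfg)
  ex <- extract_brain(sc$volume)
  norm <- normalize_slices(ex$stripped, ex$mask)
  det <- detect_slices(norm, ex$mask,
                       detector_config(pixel_size_mm = cfg$pixel_size_mm))
  gt <- sc$truth$gt_boxes
  for (id in unique(gt$lesion_id)) {
    gb <- gt[gt$lesion_id == id, ]
    hit_slices <- vapply(seq_len(nrow(gb)), function(r) {
      d1 <- det[det$slice_index == gb$slice_index[r], , drop = FALSE]
      nrow(d1) > 0 && max(bmdetect:::iou_matrix(gb[r, ], d1)) > 0.5
    }, TRUE)
    expect_gte(sum(hit_slices), 2L)
  }
})
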