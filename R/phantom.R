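#' Phantom configuration
#'
#' Describes one synthetic black-blood-like contrast-enhanced scan: a smooth
#' ellipsoidal brain of unit tissue intensity surrounded by a dark CSF gap and
#' a bright skull rim, hyperintense spherical metastasis-like lesions, and
#' curvilinear vessel-like tubes whose signal is largely suppressed (the
#' black-blood situation) except for residual bright segments — the dominant
#' false-positive source on this contrast. Additive Gaussian noise is applied
#' last.
#'
#' The default geometry is a 256 x 256 matrix with 0.9 x 0.9 mm pixels and
#' 3 mm slices — half the clinical 512 x 512 / 0.45 mm matrix with identical
#' physical field of view, preserving the relation that every lesion of
#' diameter >= 5 mm crosses two or more 3 mm slices. `clinical_geometry = TRUE`
#' restores the full 512 x 512 / 0.45 mm matrix.
#'
#' @param grid integer triple (n_slices, n_rows, n_cols).
#' @param pixel_size_mm in-plane (row, col) spacing, mm.
#' @param slice_thickness_mm slice thickness, mm.
#' @param n_lesions number of lesions to plant (>= 0); the default 5 matches
#'   the mean lesion burden of a metastasis work-up cohort (~5 per scan).
#' @param lesion_diameter_range_mm min/max lesion diameter; the floor must be
#'   >= 5 mm so every lesion is observable on two or more slices.
#' @param lesion_intensity lesion intensity as a multiple of tissue mean.
#' @param n_vessels number of vessel-like tubes.
#' @param vessel_suppression fraction in `[0, 1]` of each vessel's length
#'   rendered at tissue intensity (signal suppressed); the remainder stays
#'   bright. The `"bb"` preset uses 0.85, `"gre"` 0 (all vessels bright).
#' @param noise_sigma standard deviation of additive Gaussian noise, in units
#'   of the tissue mean.
#' @param seed RNG seed for this scan.
#' @param preset `"bb"` (black-blood, vessels mostly suppressed) or `"gre"`
#'   (gradient-echo-like, vessels fully bright); sets `vessel_suppression`
#'   unless that is given explicitly.
#' @param clinical_geometry logical; use the clinical 512 x 512 / 0.45 mm matrix.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid = c(40L, 256L, 256L),
                           pixel_size_mm = c(0.9, 0.9),
                           slice_thickness_mm = 3.0,
                           n_lesions = 5L,
                           lesion_diameter_range_mm = c(5, 25),
                           lesion_intensity = 3.0,
                           n_vessels = 6L,
                           vessel_suppression = NULL,
                           noise_sigma = 0.05,
                           seed = 1L,
                           preset = c("bb", "gre"),
                           clinical_geometry = FALSE) {
  preset <- match.arg(preset)
  if (clinical_geometry) {
    grid <- c(grid[1], 512L, 512L)
    pixel_size_mm <- c(0.45, 0.45)
  }
  if (is.null(vessel_suppression))
    vessel_suppression <- if (preset == "bb") 0.85 else 0.0
  if (length(grid) != 3L || any(grid < 1)) stop("grid must be three dims >= 1")
  if (n_lesions < 0) stop("n_lesions must be >= 0")
  if (lesion_diameter_range_mm[1] < 5)
    stop("lesion diameters below 5 mm are out of scope: the minimum must be >= 5 mm")
  if (diff(lesion_diameter_range_mm) < 0) stop("invalid lesion diameter range")
  if (vessel_suppression < 0 || vessel_suppression > 1)
    stop("vessel_suppression must be in [0, 1]")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(grid = as.integer(grid),
                 pixel_size_mm = as.numeric(pixel_size_mm),
                 slice_thickness_mm = as.numeric(slice_thickness_mm),
                 n_lesions = as.integer(n_lesions),
                 lesion_diameter_range_mm = as.numeric(lesion_diameter_range_mm),
                 lesion_intensity = as.numeric(lesion_intensity),
                 n_vessels = as.integer(n_vessels),
                 vessel_suppression = as.numeric(vessel_suppression),
                 noise_sigma = as.numeric(noise_sigma),
                 seed = as.integer(seed),
                 preset = preset),
            class = "phantom_config")
}

# Intensities relative to tissue mean 1.0.
PHANTOM_TISSUE <- 1.0
PHANTOM_SKULL <- 2.0
PHANTOM_VESSEL <- 3.0

# Normalized ellipsoid radius field and brain mask for a config.
phantom_geometry <- function(cfg) {
  nr <- cfg$grid[2]; nc <- cfg$grid[3]; ns <- cfg$grid[1]
  ps <- cfg$pixel_size_mm; th <- cfg$slice_thickness_mm
  y_mm <- (seq_len(nr) - 0.5) * ps[1]
  x_mm <- (seq_len(nc) - 0.5) * ps[2]
  z_mm <- (seq_len(ns) - 0.5) * th
  center <- c(max(y_mm) / 2 + ps[1] / 4, max(x_mm) / 2 + ps[2] / 4,
              max(z_mm) / 2 + th / 4)
  semi <- c(0.42 * nr * ps[1], 0.40 * nc * ps[2], 0.42 * ns * th)
  uy <- ((y_mm - center[1]) / semi[1])^2
  ux <- ((x_mm - center[2]) / semi[2])^2
  uz <- ((z_mm - center[3]) / semi[3])^2
  rnorm2 <- outer(outer(uy, ux, `+`), uz, `+`)  # squared normalized radius
  # skull rim: shell between ellipsoids offset 5 mm and 9 mm outward in
  # metric units, so the dark CSF gap is >= 5 mm everywhere and the rim can
  # never touch brain tissue across a 3 mm slice step
  shell_field <- function(off) {
    s <- semi + off
    outer(outer(((y_mm - center[1]) / s[1])^2, ((x_mm - center[2]) / s[2])^2, `+`),
          ((z_mm - center[3]) / s[3])^2, `+`)
  }
  skull <- shell_field(5) > 1 & shell_field(9) <= 1
  list(rnorm2 = rnorm2, skull = skull, center = center, semi = semi,
       y_mm = y_mm, x_mm = x_mm, z_mm = z_mm)
}

# Voxelize a ball; returns integer index vector into the volume array.
ball_voxels <- function(geom, dims, center_mm, radius_mm) {
  ri <- which(abs(geom$y_mm - center_mm[1]) <= radius_mm)
  ci <- which(abs(geom$x_mm - center_mm[2]) <= radius_mm)
  si <- which(abs(geom$z_mm - center_mm[3]) <= radius_mm)
  if (!length(ri) || !length(ci) || !length(si)) return(integer())
  gg <- expand.grid(r = ri, c = ci, s = si)
  d2 <- (geom$y_mm[gg$r] - center_mm[1])^2 + (geom$x_mm[gg$c] - center_mm[2])^2 +
    (geom$z_mm[gg$s] - center_mm[3])^2
  keep <- d2 <= radius_mm^2
  (gg$s[keep] - 1L) * (dims[1] * dims[2]) + (gg$c[keep] - 1L) * dims[1] + gg$r[keep]
}

#' Generate one phantom scan with ground truth
#'
#' Deterministic given `config$seed`. Ground-truth boxes are the tight
#' per-slice bounding boxes of each lesion's voxelized cross-section, computed
#' on the noiseless lesion mask; every lesion is guaranteed to present a
#' cross-section of radius >= 1 mm on at least two slices (lesion centers are
#' resampled until this visibility criterion holds), the phantom counterpart
#' of the clinical rule that a metastasis >= 5 mm is observed on two or more
#' 3 mm slices.
#'
#' @param config a [phantom_config].
#' @param scan_id scan identifier stored in the volume and truth tables.
#' @return A list with elements `volume` (a [bm_volume]), and `truth`: a list
#'   with `lesions` (data.frame: lesion_id, center_y/x/z_mm, diameter_mm),
#'   `gt_boxes` (box table with `lesion_id` filled), `brain_mask` (logical
#'   array), `lesion_mask` and `vessel_mask` (logical arrays, disjoint).
#' @export
generate_scan <- function(config, scan_id = sprintf("phantom%06d", config$seed)) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed, {
    dims <- c(config$grid[2], config$grid[3], config$grid[1])  # row, col, slice
    geom <- phantom_geometry(config)
    brain <- geom$rnorm2 <= 1
    if (!any(brain)) stop("degenerate geometry: empty brain mask")
    vol <- array(0, dims)
    vol[brain] <- PHANTOM_TISSUE
    vol[geom$skull] <- PHANTOM_SKULL

    min_semi <- min(geom$semi)
    interior <- which(geom$rnorm2 <= 0.8^2)
    lesion_mask <- array(FALSE, dims)
    lesions <- NULL
    placed <- list()
    if (config$n_lesions > 0) {
      if (!length(interior)) stop("cannot place lesions: brain interior empty")
      for (i in seq_len(config$n_lesions)) {
        ok <- FALSE
        for (try in seq_len(200L)) {
          d <- runif(1, config$lesion_diameter_range_mm[1],
                     config$lesion_diameter_range_mm[2])
          r <- d / 2
          idx <- interior[sample.int(length(interior), 1L)]
          s <- (idx - 1L) %/% (dims[1] * dims[2])
          rem <- (idx - 1L) %% (dims[1] * dims[2])
          cc <- rem %/% dims[1]; rr <- rem %% dims[1]
          ctr <- c(geom$y_mm[rr + 1L], geom$x_mm[cc + 1L], geom$z_mm[s + 1L]) +
            runif(3, -0.5, 0.5) * c(config$pixel_size_mm, config$slice_thickness_mm)
          # whole ball well inside the brain
          u <- sqrt(((ctr[1] - geom$center[1]) / geom$semi[1])^2 +
                      ((ctr[2] - geom$center[2]) / geom$semi[2])^2 +
                      ((ctr[3] - geom$center[3]) / geom$semi[3])^2)
          if (u > 0.92 - r / min_semi) next
          # pairwise non-overlap with a 2 mm clearance
          clash <- FALSE
          for (p in placed)
            if (sqrt(sum((ctr - p$ctr)^2)) <= r + p$r + 2) { clash <- TRUE; break }
          if (clash) next
          # visibility: on >= 2 slices the cross-section radius must reach
          # both 1 mm and half the in-plane pixel diagonal, so a voxel
          # center falls inside the cross-section at any resolution
          r_vis <- max(1, sqrt(sum(config$pixel_size_mm^2)) / 2)
          vis <- sum(abs(geom$z_mm - ctr[3]) <= sqrt(max(r^2 - r_vis^2, 0)))
          if (vis < 2) next
          placed[[i]] <- list(ctr = ctr, r = r)
          ok <- TRUE
          break
        }
        if (!ok)
          stop(sprintf("could not place lesion %d without overlap after bounded retries", i))
      }
      lesions <- data.frame(
        lesion_id = seq_along(placed),
        center_y_mm = vapply(placed, function(p) p$ctr[1], 0),
        center_x_mm = vapply(placed, function(p) p$ctr[2], 0),
        center_z_mm = vapply(placed, function(p) p$ctr[3], 0),
        diameter_mm = vapply(placed, function(p) 2 * p$r, 0))
    }

    # vessels: random-walk tubes inside the brain, one contiguous bright
    # (unsuppressed) run per vessel, remainder at tissue intensity
    vessel_mask <- array(FALSE, dims)
    if (config$n_vessels > 0 && length(interior)) {
      step_mm <- 2.0
      n_steps <- 64L
      for (vsl in seq_len(config$n_vessels)) {
        idx <- interior[sample.int(length(interior), 1L)]
        s <- (idx - 1L) %/% (dims[1] * dims[2])
        rem <- (idx - 1L) %% (dims[1] * dims[2])
        pos <- c(geom$y_mm[rem %% dims[1] + 1L],
                 geom$x_mm[rem %/% dims[1] + 1L],
                 geom$z_mm[s + 1L])
        dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
        rv <- runif(1, 1.0, 1.5)
        n_bright <- round((1 - config$vessel_suppression) * n_steps)
        bright_start <- if (n_bright >= n_steps) 1L else
          sample.int(n_steps - n_bright + 1L, 1L)
        for (st in seq_len(n_steps)) {
          dir <- dir + 0.25 * rnorm(3); dir <- dir / sqrt(sum(dir^2))
          pos2 <- pos + step_mm * dir
          u <- sqrt(((pos2[1] - geom$center[1]) / geom$semi[1])^2 +
                      ((pos2[2] - geom$center[2]) / geom$semi[2])^2 +
                      ((pos2[3] - geom$center[3]) / geom$semi[3])^2)
          if (u > 0.9) {  # steer back toward the brain center
            dir <- geom$center - pos
            dir <- dir / sqrt(sum(dir^2))
            pos2 <- pos + step_mm * dir
          }
          pos <- pos2
          if (st >= bright_start && st < bright_start + n_bright) {
            vx <- ball_voxels(geom, dims, pos, rv)
            vx <- vx[brain[vx] & !lesion_mask[vx]]
            vessel_mask[vx] <- TRUE
          }
        }
      }
      vol[vessel_mask] <- PHANTOM_VESSEL
    }

    # lesions stamped after vessels so lesion intensity wins; masks disjoint
    gt <- boxes_df()
    for (i in seq_along(placed)) {
      vx <- ball_voxels(geom, dims, placed[[i]]$ctr, placed[[i]]$r)
      vessel_mask[vx] <- FALSE
      lesion_mask[vx] <- TRUE
      vol[vx] <- config$lesion_intensity * PHANTOM_TISSUE
      gt <- rbind(gt, lesion_boxes_from_voxels(vx, dims, scan_id, i))
    }

    if (config$noise_sigma > 0)
      vol <- vol + array(rnorm(prod(dims), 0, config$noise_sigma), dims)

    list(volume = bm_volume(vol, config$pixel_size_mm,
                            config$slice_thickness_mm, scan_id),
         truth = list(lesions = lesions, gt_boxes = gt, brain_mask = brain,
                      lesion_mask = lesion_mask, vessel_mask = vessel_mask))
  })
}

# Tight per-slice bounding boxes of a voxel index set (0-based box coords).
lesion_boxes_from_voxels <- function(vx, dims, scan_id, lesion_id) {
  if (!length(vx)) return(boxes_df())
  s <- (vx - 1L) %/% (dims[1] * dims[2])
  rem <- (vx - 1L) %% (dims[1] * dims[2])
  cc <- rem %/% dims[1]
  rr <- rem %% dims[1]
  out <- lapply(sort(unique(s)), function(si) {
    k <- s == si
    boxes_df(scan_id, si, min(cc[k]), min(rr[k]),
             max(cc[k]) - min(cc[k]) + 1L, max(rr[k]) - min(rr[k]) + 1L,
             NA_real_, lesion_id)
  })
  do.call(rbind, out)
}

#' Generate a phantom cohort
#'
#' Produces `n_scans` lesion-bearing scans plus `n_normals` lesion-free scans
#' (vessels retained), each generated with its own seed derived
#' deterministically from the master seed, so cohort generation is
#' order-independent. With `dir = NULL` volumes and truth stay in memory;
#' otherwise NIfTI volumes, per-scan truth CSVs and a JSON manifest are
#' written under `dir`.
#'
#' @param n_scans number of lesion-bearing scans.
#' @param n_normals number of lesion-free scans.
#' @param config template [phantom_config]; the master seed is `config$seed`.
#' @param dir optional output directory.
#' @param keep_masks keep the per-scan truth masks (brain/lesion/vessel
#'   logical arrays) in the in-memory cohort? Defaults to `TRUE`; set to
#'   `FALSE` for large cohorts where only the truth boxes are needed
#'   downstream (the cross-validation harness uses boxes only).
#' @return A list of class `bm_cohort`: `scans` (named list with `volume` and
#'   `truth`, `NULL` when written to disk), `manifest` (data.frame with
#'   scan_id, role, seed, n_lesions and file paths), `config`.
#' @export
generate_cohort <- function(n_scans, n_normals = 0L, config = phantom_config(),
                            dir = NULL, keep_masks = TRUE) {
  stopifnot(n_scans >= 0, n_normals >= 0)
  ids <- c(sprintf("scan%03d", seq_len(n_scans)),
           sprintf("normal%03d", seq_len(n_normals)))
  roles <- rep(c("lesion", "normal"), c(n_scans, n_normals))
  seeds <- vapply(seq_along(ids), function(i) derive_seed(config$seed, i), 0)
  scans <- vector("list", length(ids)); names(scans) <- ids
  n_les <- integer(length(ids))
  vol_paths <- truth_paths <- rep(NA_character_, length(ids))
  for (i in seq_along(ids)) {
    cfg_i <- config
    cfg_i$seed <- as.integer(seeds[i])
    if (roles[i] == "normal") cfg_i$n_lesions <- 0L
    sc <- generate_scan(cfg_i, scan_id = ids[i])
    n_les[i] <- if (is.null(sc$truth$lesions)) 0L else nrow(sc$truth$lesions)
    if (is.null(dir)) {
      if (!keep_masks)
        sc$truth[c("brain_mask", "lesion_mask", "vessel_mask")] <- NULL
      scans[[i]] <- sc
    } else {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      vol_paths[i] <- file.path(dir, paste0(ids[i], ".nii.gz"))
      truth_paths[i] <- file.path(dir, paste0(ids[i], "_truth.csv"))
      write_volume(sc$volume, vol_paths[i])
      write_boxes(sc$truth$gt_boxes, truth_paths[i])
    }
  }
  manifest <- data.frame(scan_id = ids, role = roles, seed = seeds,
                         n_lesions = n_les, volume_path = vol_paths,
                         truth_path = truth_paths, stringsAsFactors = FALSE)
  if (!is.null(dir))
    jsonlite::write_json(list(master_seed = config$seed, manifest = manifest),
                         file.path(dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  structure(list(scans = scans, manifest = manifest, config = config),
            class = "bm_cohort")
}
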