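# Label 3D connected components (6-connectivity) of a logical array:
# per-slice 2D labeling (EBImage::bwlabel, 4-connectivity in plane) merged
# across adjacent slices wherever labels share a voxel column, via union-find.
label_components_3d <- function(mask) {
  dims <- dim(mask)
  labs <- array(0L, dims)
  offset <- 0L
  n_per_slice <- integer(dims[3])
  for (s in seq_len(dims[3])) {
    l2 <- EBImage::bwlabel(mask[, , s] * 1)
    n <- max(l2)
    l2[l2 > 0] <- l2[l2 > 0] + offset
    labs[, , s] <- l2
    n_per_slice[s] <- n
    offset <- offset + as.integer(n)
  }
  if (offset == 0L) return(labs)
  parent <- seq_len(offset)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (s in seq_len(dims[3] - 1L)) {
    a <- labs[, , s]; b <- labs[, , s + 1L]
    both <- a > 0 & b > 0
    if (!any(both)) next
    pairs <- unique(cbind(a[both], b[both]))
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(offset), find, 0L)
  relab <- match(roots, sort(unique(roots)))
  labs[labs > 0] <- relab[labs[labs > 0]]
  labs
}

#' Brain extraction for phantom volumes
#'
#' A threshold-and-morphology brain extractor: global Otsu threshold, largest
#' 3D connected foreground component (which discards the bright skull rim,
#' separated from brain tissue by the dark CSF gap), then per-slice
#' morphological closing and hole filling. It plays the role that a dedicated
#' brain-extraction tool plays on clinical data, and is adequate for phantoms,
#' where the analytic brain mask is known.
#'
#' @param v a [bm_volume] with a bright skull rim surrounding darker tissue.
#' @param closing_radius radius (pixels) of the disc brush used for per-slice
#'   closing; 2 by default.
#' @return A list: `mask` (logical array congruent with the volume) and
#'   `stripped` (a [bm_volume] equal to the input times the mask).
#' @export
extract_brain <- function(v, closing_radius = 2L) {
  stopifnot(inherits(v, "bm_volume"))
  mx <- max(v$data)
  if (mx <= 0) stop("brain extraction failed: empty foreground")
  scaled <- pmin(pmax(v$data / mx, 0), 1)
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  fg <- scaled > thr
  if (!any(fg)) stop("brain extraction failed: empty foreground")
  labs <- label_components_3d(fg)
  sizes <- tabulate(labs[labs > 0])
  mask <- labs == which.max(sizes)
  brush <- EBImage::makeBrush(2L * closing_radius + 1L, "disc")
  mask <- EBImage::closing(mask * 1, brush)
  mask <- EBImage::fillHull(mask) > 0
  if (!any(mask)) stop("brain extraction failed: empty foreground")
  stripped <- v
  stripped$data <- v$data * mask
  list(mask = mask, stripped = stripped)
}

#' Per-slice 0-1 intensity normalization
#'
#' For each slice independently, intensities over brain voxels are min-max
#' mapped to `[0, 1]`; background stays 0 and slices whose brain intensities
#' are constant map to 0. Computing the range over brain voxels only (rather
#' than the whole slice) keeps the map non-trivial: background zeros would
#' otherwise pin the minimum.
#'
#' @param v a skull-stripped [bm_volume].
#' @param mask logical brain mask congruent with `v`.
#' @return A [bm_volume] with intensities in `[0, 1]`.
#' @export
normalize_slices <- function(v, mask) {
  stopifnot(inherits(v, "bm_volume"), identical(dim(mask), dim(v$data)))
  out <- array(0, dim(v$data))
  for (s in seq_len(dim(v$data)[3])) {
    m <- mask[, , s]
    if (!any(m)) next
    sl <- v$data[, , s]
    vals <- sl[m]
    lo <- min(vals); hi <- max(vals)
    if (hi > lo) {
      sl2 <- (sl - lo) / (hi - lo)
      out[, , s][m] <- sl2[m]
    }
  }
  res <- v
  res$data <- out
  res
}
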