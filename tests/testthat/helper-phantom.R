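# Shared fixtures: small, fast phantom configurations and box constructors.

# Coarse phantom grid for module tests: 24 slices of 128 x 128 at 1.8 mm
# pixels keeps the physical field of view of the default geometry.
small_config <- function(...) {
  args <- modifyList(
    list(grid = c(24L, 128L, 128L), pixel_size_mm = c(1.8, 1.8),
         n_lesions = 2L, lesion_diameter_range_mm = c(6, 14),
         n_vessels = 3L, noise_sigma = 0, seed = 42L),
    list(...))
  do.call(phantom_config, args)
}

# One box per call; b(slice, x, y, w, h)
b <- function(slice, x, y, w, h, score = NA_real_, lesion_id = NA_integer_,
              scan_id = "s") {
  boxes_df(scan_id, slice, x, y, w, h, score, lesion_id)
}

# Random stack of boxes on a few slices (for linking / matching properties)
random_boxes <- function(n, n_slices = 4, extent = 100, scan_id = "s") {
  if (n == 0) return(boxes_df())
  boxes_df(scan_id,
           sample.int(n_slices, n, replace = TRUE) - 1L,
           x = runif(n, 0, extent - 20), y = runif(n, 0, extent - 20),
           w = runif(n, 4, 20), h = runif(n, 4, 20))
}

# Independent connected-component oracle for the linker, via igraph.
link_oracle <- function(boxes, adjacency_iou = 0.3, min_slices = 2L) {
  n <- nrow(boxes)
  edges <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (abs(boxes$slice_index[i] - boxes$slice_index[j]) != 1L) next
    if (box_iou(boxes[i, ], boxes[j, ]) > adjacency_iou)
      edges <- rbind(edges, c(i, j))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  keep <- vapply(seq_len(max(comp)), function(cid)
    length(unique(boxes$slice_index[comp == cid])) >= min_slices, TRUE)
  list(membership = comp, kept_rows = which(keep[comp]))
}

# Partition of kept rows as a canonical set-of-sets signature.
partition_signature <- function(rows, membership) {
  groups <- split(rows, membership[rows])
  sig <- sort(vapply(groups, function(g) paste(sort(g), collapse = ","), ""))
  unname(sig)
}

# Brute-force maximum one-to-one matching TP count given a compatibility
# matrix (gt x pred), by enumeration over all injective assignments.
max_matching_bruteforce <- function(compat) {
  ng <- nrow(compat); np <- ncol(compat)
  if (ng == 0 || np == 0) return(0L)
  best <- 0L
  recurse <- function(gi, used_p, tp) {
    if (tp + (ng - gi + 1L) <= best) return()
    if (gi > ng) { best <<- max(best, tp); return() }
    recurse(gi + 1L, used_p, tp)  # leave gt gi unmatched
    for (pi in seq_len(np)) {
      if (!used_p[pi] && compat[gi, pi]) {
        used_p[pi] <- TRUE
        recurse(gi + 1L, used_p, tp + 1L)
        used_p[pi] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, np), 0L)
  best
}

# Independent compatibility computation for matching tests: a gt/pred lesion
# pair is compatible if any same-slice box pair exceeds the IoU threshold.
compat_matrix <- function(gt, pred, match_iou = 0.5) {
  gids <- sort(unique(gt$lesion_id)); pids <- sort(unique(pred$lesion_id))
  M <- matrix(FALSE, length(gids), length(pids))
  for (gi in seq_along(gids)) for (pi in seq_along(pids)) {
    gb <- gt[gt$lesion_id == gids[gi], ]
    pb <- pred[pred$lesion_id == pids[pi], ]
    for (r in seq_len(nrow(gb))) for (q in seq_len(nrow(pb))) {
      if (gb$slice_index[r] == pb$slice_index[q] &&
          box_iou(gb[r, ], pb[q, ]) > match_iou) M[gi, pi] <- TRUE
    }
  }
  M
}
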