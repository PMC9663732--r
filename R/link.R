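#' Linker configuration
#'
#' @param adjacency_iou IoU threshold (strict `>`) for recognizing boxes on
#'   adjacent slices as the same lesion; default 0.3.
#' @param min_slices minimum number of distinct slices a retained lesion must
#'   span; default 2, so single-slice findings are excluded from training and
#'   evaluation (a >= 5 mm metastasis is observed on two or more 3 mm slices).
#' @return An object of class `linker_config`.
#' @export
linker_config <- function(adjacency_iou = 0.3, min_slices = 2L) {
  if (adjacency_iou < 0 || adjacency_iou > 1) stop("adjacency_iou must be in [0, 1]")
  if (min_slices < 1) stop("min_slices must be >= 1")
  structure(list(adjacency_iou = as.numeric(adjacency_iou),
                 min_slices = as.integer(min_slices)),
            class = "linker_config")
}

#' Link per-slice boxes into numbered 3D lesions
#'
#' The lesion-forming rule: boxes on slices differing by exactly 1 whose 2D
#' IoU exceeds `adjacency_iou` are recognized as the same lesion; lesions are
#' the connected components of this adjacency graph (computed by union-find).
#' A box may link to several boxes on a neighboring slice; all are merged.
#' Components spanning fewer than `min_slices` distinct slices are discarded.
#' Surviving lesions are numbered 1..K in order of each lesion's
#' lexicographically smallest `(slice_index, y, x)`, so the numbering is
#' invariant to the input ordering of the boxes.
#'
#' The same linker is applied to ground-truth labels and to predicted boxes:
#' detections are reported per lesion, not per slice.
#'
#' @param boxes box table from a single scan (mixed `scan_id`s are an error).
#' @param cfg a [linker_config].
#' @return The retained boxes with `lesion_id` filled, ordered by
#'   `(lesion_id, slice_index, y, x)`.
#' @export
link_boxes <- function(boxes, cfg = linker_config()) {
  stopifnot(inherits(cfg, "linker_config"))
  validate_boxes(boxes)
  if (nrow(boxes) == 0) return(boxes)
  if (length(unique(boxes$scan_id)) > 1L)
    stop("link_boxes expects boxes from a single scan; got mixed scan_ids")
  n <- nrow(boxes)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  sl <- boxes$slice_index
  by_slice <- split(seq_len(n), sl)
  for (s in as.integer(names(by_slice))) {
    j <- by_slice[[as.character(s + 1L)]]
    i <- by_slice[[as.character(s)]]
    if (is.null(j)) next
    M <- iou_matrix(boxes[i, , drop = FALSE], boxes[j, , drop = FALSE])
    hits <- which(M > cfg$adjacency_iou, arr.ind = TRUE)
    for (k in seq_len(nrow(hits))) {
      ra <- find(i[hits[k, 1]]); rb <- find(j[hits[k, 2]])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  keep_comp <- vapply(split(sl, comp), function(s) length(unique(s)), 0L)
  keep_comp <- as.integer(names(keep_comp)[keep_comp >= cfg$min_slices])
  if (!length(keep_comp)) {
    out <- boxes[0, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  # canonical numbering by each component's minimal (slice_index, y, x)
  key <- order(boxes$slice_index, boxes$y, boxes$x)
  rank_of <- integer(n); rank_of[key] <- seq_len(n)
  first_rank <- vapply(keep_comp, function(cid) min(rank_of[comp == cid]), 0L)
  ordered_comp <- keep_comp[order(first_rank)]
  out <- boxes[comp %in% keep_comp, , drop = FALSE]
  out$lesion_id <- match(comp[comp %in% keep_comp], ordered_comp)
  out <- out[order(out$lesion_id, out$slice_index, out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize linked lesions
#'
#' @param lesions a linked box table (output of [link_boxes()]).
#' @return A data.frame with one row per lesion, ordered by `lesion_id`:
#'   `lesion_id`, `n_boxes`, `slice_span` (distinct slices), `max_box_area`.
#' @export
lesion_summary <- function(lesions) {
  if (nrow(lesions) == 0)
    return(data.frame(lesion_id = integer(), n_boxes = integer(),
                      slice_span = integer(), max_box_area = numeric()))
  if (anyNA(lesions$lesion_id))
    stop("lesion_summary expects linked boxes (lesion_id filled)")
  ids <- sort(unique(lesions$lesion_id))
  out <- lapply(ids, function(id) {
    b <- lesions[lesions$lesion_id == id, , drop = FALSE]
    data.frame(lesion_id = id, n_boxes = nrow(b),
               slice_span = length(unique(b$slice_index)),
               max_box_area = max(b$w * b$h))
  })
  do.call(rbind, out)
}
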