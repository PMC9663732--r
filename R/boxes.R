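BOX_COLS <- c("scan_id", "slice_index", "x", "y", "w", "h", "score", "lesion_id")

#' Build a table of 2D slice boxes
#'
#' Boxes are axis-aligned rectangles on a single slice, the unit of both the
#' radiologist labels and the detector output. Coordinates are 0-based pixels:
#' `x` is the left column, `y` the top row, and the rectangle is the half-open
#' real region `[x, x + w) x [y, y + h)`, so its area is exactly `w * h`.
#'
#' @param scan_id,slice_index,x,y,w,h,score,lesion_id vectors, recycled to a
#'   common length; `score` (confidence in `[0, 1]`) and `lesion_id` may be `NA`.
#' @return A `data.frame` with columns
#'   `scan_id, slice_index, x, y, w, h, score, lesion_id`.
#' @export
boxes_df <- function(scan_id = character(), slice_index = integer(),
                     x = numeric(), y = numeric(), w = numeric(), h = numeric(),
                     score = NA_real_, lesion_id = NA_integer_) {
  n <- max(length(scan_id), length(slice_index), length(x), length(y),
           length(w), length(h))
  if (length(score) <= 1L) score <- rep(if (length(score)) score else NA_real_, n)
  if (length(lesion_id) <= 1L)
    lesion_id <- rep(if (length(lesion_id)) lesion_id else NA_integer_, n)
  df <- data.frame(scan_id = as.character(scan_id),
                   slice_index = as.integer(slice_index),
                   x = as.numeric(x), y = as.numeric(y),
                   w = as.numeric(w), h = as.numeric(h),
                   score = as.numeric(score),
                   lesion_id = as.integer(lesion_id),
                   stringsAsFactors = FALSE)
  validate_boxes(df)
  df
}

#' Validate a box table
#'
#' Checks the schema and per-row invariants: non-negative `x`, `y`; strictly
#' positive `w`, `h`; scores, when present, in `[0, 1]`. When a volume is
#' supplied, every box must lie within its image bounds.
#'
#' @param boxes a box `data.frame` as produced by [boxes_df()].
#' @param volume optional [bm_volume] to bound-check against.
#' @return `boxes`, invisibly; errors name the first offending row.
#' @export
validate_boxes <- function(boxes, volume = NULL) {
  missing_cols <- setdiff(setdiff(BOX_COLS, c("score", "lesion_id")), names(boxes))
  if (length(missing_cols) > 0)
    stop("box table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(boxes$w) | !is.finite(boxes$h) |
                 boxes$w <= 0 | boxes$h <= 0)
  if (length(bad) > 0)
    stop(sprintf("invalid box at row %d: extents w, h must be > 0", bad[1]))
  bad <- which(boxes$x < 0 | boxes$y < 0 | boxes$slice_index < 0)
  if (length(bad) > 0)
    stop(sprintf("invalid box at row %d: x, y, slice_index must be >= 0", bad[1]))
  sc <- boxes$score
  bad <- which(!is.na(sc) & (sc < 0 | sc > 1))
  if (length(bad) > 0)
    stop(sprintf("invalid box at row %d: score must be in [0, 1]", bad[1]))
  if (!is.null(volume)) {
    d <- dim(volume$data)
    bad <- which(boxes$x + boxes$w > d[2] | boxes$y + boxes$h > d[1] |
                   boxes$slice_index >= d[3])
    if (length(bad) > 0)
      stop(sprintf("box at row %d lies outside the volume bounds", bad[1]))
  }
  invisible(boxes)
}

#' Intersection over union of 2D boxes
#'
#' Pure in-plane geometry on the half-open rectangles; `slice_index` is
#' ignored. The same measure drives both the adjacent-slice lesion linking
#' (threshold 0.3) and the prediction-to-label matching (threshold 0.5).
#'
#' @param a,b box tables (rows are recycled elementwise to a common length).
#' @return Numeric vector of IoU values in `[0, 1]`.
#' @examples
#' a <- boxes_df("s", 0, 0, 0, 10, 10)
#' b <- boxes_df("s", 0, 5, 0, 10, 10)
#' box_iou(a, b)  # 50 / 150
#' @export
box_iou <- function(a, b) {
  if (any(a$w <= 0) || any(a$h <= 0) || any(b$w <= 0) || any(b$h <= 0))
    stop("invalid box: extents w, h must be > 0")
  ix <- pmax(0, pmin(a$x + a$w, b$x + b$w) - pmax(a$x, b$x))
  iy <- pmax(0, pmin(a$y + a$h, b$y + b$h) - pmax(a$y, b$y))
  inter <- ix * iy
  union <- a$w * a$h + b$w * b$h - inter
  inter / union
}

# Cross IoU matrix: rows of A x rows of B (vectorized, no row indexing).
iou_matrix <- function(A, B) {
  if (nrow(A) == 0 || nrow(B) == 0) return(matrix(0, nrow(A), nrow(B)))
  ix <- pmax(outer(A$x + A$w, B$x + B$w, pmin) - outer(A$x, B$x, pmax), 0)
  iy <- pmax(outer(A$y + A$h, B$y + B$h, pmin) - outer(A$y, B$y, pmax), 0)
  inter <- ix * iy
  inter / (outer(A$w * A$h, B$w * B$h, `+`) - inter)
}

#' Read and write box tables
#'
#' CSV with header `scan_id,slice_index,x,y,w,h,score,lesion_id` (`score` and
#' `lesion_id` may be empty); a JSON alternative with identical fields is
#' selected by the `.json` extension. `read_boxes(write_boxes(B))` reproduces
#' `B` field for field.
#'
#' @param path file path; format chosen by extension (`.json` else CSV).
#' @param boxes a box `data.frame`.
#' @return `read_boxes`: a box `data.frame`; `write_boxes`: `path`, invisibly.
#' @export
read_boxes <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path)
    if (length(raw) == 0 || (is.data.frame(raw) && nrow(raw) == 0))
      return(boxes_df())
    df <- as.data.frame(raw, stringsAsFactors = FALSE)
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE,
                   colClasses = c(scan_id = "character"))
  }
  missing_cols <- setdiff(setdiff(BOX_COLS, c("score", "lesion_id")), names(df))
  if (length(missing_cols) > 0)
    stop(sprintf("%s: missing required column(s): %s", basename(path),
                 paste(missing_cols, collapse = ", ")))
  if (is.null(df$score)) df$score <- NA_real_
  if (is.null(df$lesion_id)) df$lesion_id <- NA_integer_
  out <- tryCatch(
    boxes_df(df$scan_id, df$slice_index, df$x, df$y, df$w, df$h,
             df$score, df$lesion_id),
    error = function(e) stop(sprintf("%s: %s", basename(path), conditionMessage(e)),
                             call. = FALSE))
  out
}

#' @rdname read_boxes
#' @export
write_boxes <- function(boxes, path) {
  validate_boxes(boxes)
  boxes <- boxes[, BOX_COLS]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(boxes, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(boxes, path, row.names = FALSE, na = "")
  }
  invisible(path)
}
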