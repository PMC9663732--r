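#' Evaluation configuration
#'
#' @param match_iou IoU threshold (strict `>`) for a predicted box to certify
#'   a ground-truth box on the same slice; default 0.5.
#' @param one_slice_tp logical; when `TRUE` (default) a ground-truth lesion
#'   counts as detected if any single one of its slices is hit — detecting
#'   part of a lesion is enough to direct a radiologist's attention to it.
#' @return An object of class `eval_config`.
#' @export
eval_config <- function(match_iou = 0.5, one_slice_tp = TRUE) {
  if (match_iou < 0 || match_iou > 1) stop("match_iou must be in [0, 1]")
  structure(list(match_iou = as.numeric(match_iou),
                 one_slice_tp = isTRUE(one_slice_tp)),
            class = "eval_config")
}

#' Match predicted lesions to ground-truth lesions on one scan
#'
#' A (ground-truth, predicted) lesion pair is compatible if on some slice a
#' predicted box and a ground-truth box of those lesions have IoU above
#' `match_iou` (the one-slice rule). Matching is greedy one-to-one by
#' descending best-slice IoU, so one predicted lesion cannot certify two
#' ground-truth lesions. TP = matched ground-truth lesions, FN = unmatched
#' ground truth, FP = unmatched predictions; `TP + FN` always equals the
#' number of ground-truth lesions.
#'
#' With `one_slice_tp = FALSE`, every ground-truth slice of the pair must be
#' hit for compatibility (a stricter whole-lesion criterion, off by default).
#'
#' @param gt,pred linked box tables (both must carry `lesion_id`; see
#'   [link_boxes()]), from the same scan.
#' @param cfg an [eval_config].
#' @param scan_id identifier recorded in the output (defaults to the boxes').
#' @return A one-row data.frame: `scan_id`, `TP`, `FN`, `FP`,
#'   `n_gt` (ground-truth lesion count).
#' @export
match_lesions <- function(gt, pred, cfg = eval_config(), scan_id = NULL) {
  stopifnot(inherits(cfg, "eval_config"))
  if (nrow(gt) > 0 && anyNA(gt$lesion_id))
    stop("ground-truth boxes must be linked (lesion_id filled)")
  if (nrow(pred) > 0 && anyNA(pred$lesion_id))
    stop("predicted boxes must be linked (lesion_id filled)")
  if (is.null(scan_id))
    scan_id <- if (nrow(gt) > 0) gt$scan_id[1]
      else if (nrow(pred) > 0) pred$scan_id[1] else "scan"
  gids <- sort(unique(gt$lesion_id))
  pids <- sort(unique(pred$lesion_id))
  # per-slice cross IoUs between gt and pred boxes, aggregated per lesion pair
  acc <- list()
  for (s in intersect(unique(gt$slice_index), unique(pred$slice_index))) {
    g1 <- gt[gt$slice_index == s, , drop = FALSE]
    p1 <- pred[pred$slice_index == s, , drop = FALSE]
    M <- iou_matrix(g1, p1)
    acc[[length(acc) + 1L]] <- data.frame(
      gi = match(g1$lesion_id[row(M)], gids),
      pi = match(p1$lesion_id[col(M)], pids),
      slice = s, iou = as.vector(M))
  }
  pairs <- NULL
  if (length(acc)) {
    hits <- do.call(rbind, acc)
    key <- paste(hits$gi, hits$pi)
    best <- tapply(hits$iou, key, max)
    if (cfg$one_slice_tp) {
      ok <- best > cfg$match_iou
    } else {
      # every gt slice of the lesion must be hit above threshold
      n_slices_gt <- tapply(gt$slice_index, match(gt$lesion_id, gids),
                            function(x) length(unique(x)))
      hit_sl <- hits[hits$iou > cfg$match_iou, , drop = FALSE]
      nhit <- tapply(paste(hit_sl$slice),
                     paste(hit_sl$gi, hit_sl$pi),
                     function(x) length(unique(x)))
      gi_of <- as.integer(vapply(strsplit(names(best), " "), `[`, "", 1))
      ok <- !is.na(nhit[names(best)]) &
        nhit[names(best)] == n_slices_gt[gi_of]
      ok[is.na(ok)] <- FALSE
    }
    if (any(ok)) {
      parts <- strsplit(names(best)[ok], " ")
      pairs <- cbind(gi = as.integer(vapply(parts, `[`, "", 1)),
                     pi = as.integer(vapply(parts, `[`, "", 2)),
                     iou = as.numeric(best[ok]))
    }
  }
  tp <- 0L
  if (!is.null(pairs)) {
    pairs <- pairs[order(-pairs[, "iou"], pairs[, "gi"], pairs[, "pi"]),
                   , drop = FALSE]
    used_g <- used_p <- logical(0)
    used_g <- rep(FALSE, length(gids)); used_p <- rep(FALSE, length(pids))
    for (k in seq_len(nrow(pairs))) {
      gi <- pairs[k, "gi"]; pi <- pairs[k, "pi"]
      if (!used_g[gi] && !used_p[pi]) {
        used_g[gi] <- TRUE; used_p[pi] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  data.frame(scan_id = scan_id, TP = tp, FN = length(gids) - tp,
             FP = length(pids) - tp, n_gt = length(gids),
             stringsAsFactors = FALSE)
}

#' Lesion-level detection metrics
#'
#' The four evaluation statistics, reported as percentages (rates) or false
#' positives per scan:
#' \deqn{Sensitivity = TP / (TP + FN)}
#' \deqn{Precision = TP / (TP + FP)}
#' \deqn{F1 = 2 TP / (2 TP + FN + FP)}
#' \deqn{FP_{avg} = FP_{total} / N}
#' Values are kept at full precision; round only when rendering reports.
#' A zero denominator is an error (`undefined metric`), never silently 0.
#'
#' @param TP,FN,FP non-negative counts.
#' @param FP_total total false positives across `N` scans.
#' @param N number of scans.
#' @return Numeric scalar; percentages in `[0, 100]` for the three rates.
#' @examples
#' sensitivity_pct(540, 74)  # 87.95...
#' @export
sensitivity_pct <- function(TP, FN) {
  if (TP + FN <= 0) stop("undefined sensitivity: TP + FN = 0")
  100 * TP / (TP + FN)
}

#' @rdname sensitivity_pct
#' @export
precision_pct <- function(TP, FP) {
  if (TP + FP <= 0) stop("undefined precision: TP + FP = 0")
  100 * TP / (TP + FP)
}

#' @rdname sensitivity_pct
#' @export
f1_pct <- function(TP, FP, FN) {
  if (2 * TP + FN + FP <= 0) stop("undefined F1: no lesions and no predictions")
  100 * 2 * TP / (2 * TP + FN + FP)
}

#' @rdname sensitivity_pct
#' @export
fp_avg <- function(FP_total, N) {
  if (N <= 0) stop("undefined FP_avg: N = 0")
  FP_total / N
}

# Metrics row from summed counts; NA (and valid = FALSE) where undefined.
metrics_row <- function(TP, FN, FP, N) {
  sens <- if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_
  prec <- if (TP + FP > 0) 100 * TP / (TP + FP) else NA_real_
  f1 <- if (2 * TP + FN + FP > 0) 100 * 2 * TP / (2 * TP + FN + FP) else NA_real_
  data.frame(TP = TP, FN = FN, FP = FP, N = N,
             sensitivity = sens, precision = prec, f1 = f1,
             f1_half = f1 / 2, fp_avg = if (N > 0) FP / N else NA_real_,
             valid = !anyNA(c(sens, prec, f1)))
}

#' Pool per-scan counts across cross-validation folds
#'
#' Per-fold metrics are computed from each fold's summed TP/FN/FP; the
#' overall row pools the counts across all scans of all folds (so the overall
#' sensitivity is `100 * sum(TP) / (sum(TP) + sum(FN))`, not a mean of fold
#' percentages). Pooling is invariant to fold order. Folds where a metric is
#' undefined (e.g. no predictions at all make precision 0/0) carry `NA` and
#' `valid = FALSE`.
#'
#' Alongside the standard F1 the report carries `f1_half`, i.e.
#' `TPR * PPV / (TPR + PPV)` — exactly half the harmonic-mean F1 — because
#' published detection tables sometimes print this variant.
#'
#' @param counts data.frame of per-scan counts (`scan_id`, `TP`, `FN`, `FP`)
#'   as returned by [match_lesions()], one row per scan.
#' @param fold integer/character vector assigning each row to a fold.
#' @return A list of class `bm_report`: `per_fold` (one metrics row per fold)
#'   and `overall` (single pooled row).
#' @export
pool_folds <- function(counts, fold = rep(1L, nrow(counts))) {
  if (nrow(counts) == 0) stop("no scan counts to pool")
  if (length(fold) != nrow(counts)) stop("fold must assign every scan")
  per <- lapply(split(seq_len(nrow(counts)), fold), function(i) {
    m <- metrics_row(sum(counts$TP[i]), sum(counts$FN[i]), sum(counts$FP[i]),
                     length(i))
    m
  })
  per_fold <- do.call(rbind, per)
  per_fold <- cbind(fold = names(per), per_fold)
  rownames(per_fold) <- NULL
  overall <- metrics_row(sum(counts$TP), sum(counts$FN), sum(counts$FP),
                         nrow(counts))
  structure(list(per_fold = per_fold, overall = overall), class = "bm_report")
}

#' @export
print.bm_report <- function(x, digits = 2, ...) {
  fmt <- function(df) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], round, digits)
    df
  }
  cat("Per-fold lesion-level performance:\n")
  print(fmt(x$per_fold), row.names = FALSE)
  cat("Overall (pooled counts):\n")
  print(fmt(x$overall), row.names = FALSE)
  invisible(x)
}

#' False positives per scan on a lesion-free cohort
#'
#' Scans without ground truth admit no sensitivity; every predicted lesion is
#' a false positive and only the false-positive rate per scan is reported.
#'
#' @param fp_per_scan integer vector, predicted-lesion count per normal scan.
#' @return `sum(fp_per_scan) / length(fp_per_scan)` (0 for an empty cohort is
#'   an error).
#' @export
evaluate_normals <- function(fp_per_scan) {
  fp_avg(sum(fp_per_scan), length(fp_per_scan))
}

#' Reading-time reduction summaries
#'
#' `paired_reduction` gives one rater's percent reduction in mean reading
#' time with assistance: `100 * (mean(without) - mean(with)) / mean(without)`.
#' `mean_percent_reduction` averages per-rater percentages arithmetically.
#' `reading_time_ttest` is the standard two-sided paired t-test on the same
#' times — a reporting utility.
#'
#' @param times_without,times_with positive reading times (seconds), paired
#'   by case for the t-test.
#' @param reductions numeric vector of per-rater percent reductions.
#' @return Percent reduction (scalar), or an `htest` for the t-test.
#' @examples
#' mean_percent_reduction(c(15.22, 25.77, 22.88, 19.57))  # 20.86
#' @export
paired_reduction <- function(times_without, times_with) {
  if (length(times_without) == 0 || length(times_with) == 0)
    stop("reading times must be nonempty")
  if (any(times_without <= 0) || any(times_with <= 0))
    stop("reading times must be positive")
  100 * (mean(times_without) - mean(times_with)) / mean(times_without)
}

#' @rdname paired_reduction
#' @export
mean_percent_reduction <- function(reductions) {
  if (length(reductions) == 0) stop("need at least one rater")
  mean(reductions)
}

#' @rdname paired_reduction
#' @export
reading_time_ttest <- function(times_without, times_with) {
  if (any(times_without <= 0) || any(times_with <= 0))
    stop("reading times must be positive")
  t.test(times_without, times_with, paired = TRUE)
}
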