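#' Seeded k-fold split of scans
#'
#' Shuffles the scan ids with the given seed, then assigns them round-robin
#' to `k` folds, so fold sizes differ by at most one (e.g. 113 scans in 5
#' folds give sizes 23/23/23/22/22). Deterministic given the seed.
#'
#' @param scan_ids character vector of scan identifiers.
#' @param k number of folds; 5 by default.
#' @param seed RNG seed for the shuffle.
#' @return A data.frame of class `cv_plan` with columns `scan_id`, `fold`.
#' @export
kfold_split <- function(scan_ids, k = 5L, seed = 1L) {
  n <- length(scan_ids)
  if (k > n) stop(sprintf("cannot split %d scans into %d folds", n, k))
  if (k < 1) stop("k must be >= 1")
  perm <- with_seed(seed, sample.int(n))
  plan <- data.frame(scan_id = scan_ids[perm],
                     fold = rep_len(seq_len(k), n),
                     stringsAsFactors = FALSE)
  plan <- plan[order(match(plan$scan_id, scan_ids)), , drop = FALSE]
  rownames(plan) <- NULL
  structure(plan, class = c("cv_plan", "data.frame"))
}

# Preprocess one scan and link its ground truth; returns the cached pieces
# the detector needs. Volumes are dropped by the caller when done.
prepare_scan <- function(volume, gt_boxes, linker = linker_config()) {
  ex <- extract_brain(volume)
  norm <- normalize_slices(ex$stripped, ex$mask)
  list(norm = norm, mask = ex$mask,
       gt_linked = link_boxes(gt_boxes, linker))
}

#' Run k-fold cross-validation on a phantom cohort
#'
#' The desk-scale counterpart of training and evaluating a detection network
#' under k-fold cross-validation: for every fold, the reference detector is
#' calibrated (grid search maximizing lesion-level F1) on the other folds'
#' lesion scans and applied to the held-out fold; lesion-free scans are
#' evaluated by all `k` calibrated configurations and their false positives
#' per scan averaged. Detections for each (scan, configuration) pair are
#' computed once and reused across folds, which leaves the train/test
#' information flow untouched — calibration only ever aggregates counts from
#' its training scans.
#'
#' @param cohort a `bm_cohort` from [generate_cohort()] (in-memory or
#'   written; written cohorts are reloaded from the manifest paths).
#' @param k number of folds.
#' @param seed seed for the fold assignment.
#' @param grid list of candidate [detector_config]s.
#' @param linker a [linker_config] used for both ground truth and predictions.
#' @param eval_cfg an [eval_config].
#' @return A list of class `bm_cv_result`: `report` (a `bm_report`),
#'   `fp_avg_normal` (mean over folds, `NA` without normals),
#'   `fp_avg_normal_per_fold`, `counts` (per-scan counts with fold),
#'   `plan`, `chosen` (per-fold selected config summary), `log`
#'   (per-stage timings and seeds).
#' @export
run_crossval <- function(cohort, k = 5L, seed = 1L,
                         grid = default_detector_grid(cohort$config$pixel_size_mm),
                         linker = linker_config(),
                         eval_cfg = eval_config()) {
  stopifnot(inherits(cohort, "bm_cohort"))
  t0 <- proc.time()[["elapsed"]]
  man <- cohort$manifest
  lesion_ids <- man$scan_id[man$role == "lesion"]
  normal_ids <- man$scan_id[man$role == "normal"]
  plan <- kfold_split(lesion_ids, k, seed)

  get_scan <- function(id) {
    i <- match(id, man$scan_id)
    if (!is.null(cohort$scans[[id]])) {
      sc <- cohort$scans[[id]]
      list(volume = sc$volume, gt = sc$truth$gt_boxes)
    } else {
      if (is.na(man$volume_path[i]))
        stop(sprintf("missing volume for scan %s", id))
      if (!file.exists(man$truth_path[i]))
        stop(sprintf("missing truth file for scan %s", id))
      list(volume = read_volume(man$volume_path[i], scan_id = id),
           gt = read_boxes(man$truth_path[i]))
    }
  }

  # stage 1: preprocess + detect every scan under every candidate config
  all_ids <- c(lesion_ids, normal_ids)
  counts_cfg <- vector("list", length(grid))       # per config: per-scan counts
  npred_cfg <- matrix(0L, length(normal_ids), length(grid),
                      dimnames = list(normal_ids, NULL))
  for (id in all_ids) {
    raw <- get_scan(id)
    prep <- prepare_scan(raw$volume, raw$gt, linker)
    for (ci in seq_along(grid)) {
      if (id %in% lesion_ids) {
        cnt <- detect_and_count(prep, grid[[ci]], linker, eval_cfg)
        counts_cfg[[ci]] <- rbind(counts_cfg[[ci]], cnt)
      } else {
        det <- detect_slices(prep$norm, prep$mask, grid[[ci]])
        pred <- link_boxes(det, linker)
        npred_cfg[id, ci] <- if (nrow(pred)) length(unique(pred$lesion_id)) else 0L
      }
    }
  }
  t1 <- proc.time()[["elapsed"]]

  # stage 2: per fold, select the config on training scans, score the test fold
  counts <- NULL
  chosen <- NULL
  fp_normal_fold <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    train_ids <- plan$scan_id[plan$fold != f]
    test_ids <- plan$scan_id[plan$fold == f]
    train_counts <- lapply(counts_cfg, function(cc)
      cc[cc$scan_id %in% train_ids, , drop = FALSE])
    sel <- select_detector_config(train_counts, grid)
    fold_counts <- counts_cfg[[sel$index]]
    fold_counts <- fold_counts[fold_counts$scan_id %in% test_ids, , drop = FALSE]
    fold_counts$fold <- f
    counts <- rbind(counts, fold_counts)
    chosen <- rbind(chosen, data.frame(
      fold = f, config_index = sel$index,
      intensity_threshold = sel$config$intensity_threshold,
      min_circularity = sel$config$min_circularity,
      train_f1 = sel$f1, train_fp_avg = sel$fp_avg))
    if (length(normal_ids) > 0)
      fp_normal_fold[f] <- evaluate_normals(npred_cfg[, sel$index])
  }
  report <- pool_folds(counts[, c("scan_id", "TP", "FN", "FP")], counts$fold)
  t2 <- proc.time()[["elapsed"]]

  structure(list(
    report = report,
    fp_avg_normal = if (length(normal_ids) > 0) mean(fp_normal_fold) else NA_real_,
    fp_avg_normal_per_fold = fp_normal_fold,
    counts = counts, plan = plan, chosen = chosen,
    log = list(seed = seed, k = k, n_lesion_scans = length(lesion_ids),
               n_normal_scans = length(normal_ids), n_configs = length(grid),
               detect_seconds = round(t1 - t0, 2),
               evaluate_seconds = round(t2 - t1, 2))),
    class = "bm_cv_result")
}

#' @export
print.bm_cv_result <- function(x, ...) {
  print(x$report)
  if (!is.na(x$fp_avg_normal))
    cat(sprintf("FP_avg on the lesion-free cohort (mean over %d models): %.2f\n",
                x$log$k, x$fp_avg_normal))
  invisible(x)
}

#' Write a cross-validation report as JSON
#'
#' Mirrors the columns of a per-fold detection performance table: TPs, FNs,
#' sensitivity, precision, F1 (and the halved variant), FP_avg, plus the
#' normal-cohort FP_avg, with provenance (seed, problem sizes, timings).
#'
#' @param result a `bm_cv_result` from [run_crossval()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  stopifnot(inherits(result, "bm_cv_result"))
  payload <- list(schema_version = "1.0",
                  per_fold = result$report$per_fold,
                  overall = result$report$overall,
                  fp_avg_normal = result$fp_avg_normal,
                  fp_avg_normal_per_fold = result$fp_avg_normal_per_fold,
                  chosen_configs = result$chosen,
                  log = result$log)
  jsonlite::write_json(payload, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}
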