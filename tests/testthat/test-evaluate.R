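test_that("metric formulas reproduce published-table arithmetic", {
  expect_equal(round(sensitivity_pct(540, 74), 2), 87.95)
  expect_equal(round(sensitivity_pct(76, 2), 2), 97.44)
  expect_equal(round(f1_pct(540, 1636, 74), 2), 38.71)
  expect_equal(fp_avg(sum(c(2, 3, 1)), 3), 2.0)
  expect_error(sensitivity_pct(0, 0), "undefined")
  expect_error(precision_pct(0, 0), "undefined")
  expect_error(fp_avg(5, 0), "undefined")
})

test_that("one hit slice certifies a whole lesion", {
  gt <- rbind(b(2, 10, 10, 10, 10, lesion_id = 1L),
              b(3, 10, 10, 10, 10, lesion_id = 1L),
              b(4, 10, 10, 10, 10, lesion_id = 1L))
  pred <- rbind(b(3, 10, 10, 7, 10, lesion_id = 1L),   # IoU 0.7 on slice 3
                b(4, 40, 40, 7, 10, lesion_id = 1L))
  res <- match_lesions(gt, pred)
  expect_equal(res[c("TP", "FN", "FP")], data.frame(TP = 1L, FN = 0L, FP = 0L),
               ignore_attr = TRUE)
  # under the whole-lesion rule the same prediction no longer counts
  strict <- match_lesions(gt, pred, eval_config(one_slice_tp = FALSE))
  expect_equal(strict$TP, 0L)
})

test_that("missing predictions and unmatched predictions count as FN and FP", {
  gt <- rbind(b(0, 10, 10, 10, 10, lesion_id = 1L),
              b(1, 10, 10, 10, 10, lesion_id = 1L),
              b(0, 50, 50, 8, 8, lesion_id = 2L),
              b(1, 50, 50, 8, 8, lesion_id = 2L))
  none <- match_lesions(gt, boxes_df())
  expect_equal(none[c("TP", "FN", "FP")], data.frame(TP = 0L, FN = 2L, FP = 0L),
               ignore_attr = TRUE)
  pred <- rbind(b(0, 11, 10, 10, 10, lesion_id = 1L),
                b(1, 11, 10, 10, 10, lesion_id = 1L),
                b(0, 50, 51, 8, 8, lesion_id = 2L),
                b(0, 80, 80, 9, 9, lesion_id = 3L),
                b(1, 80, 80, 9, 9, lesion_id = 3L))
  res <- match_lesions(gt, pred)
  expect_equal(res[c("TP", "FN", "FP")], data.frame(TP = 2L, FN = 0L, FP = 1L),
               ignore_attr = TRUE)
  expect_error(match_lesions(gt, b(0, 1, 1, 5, 5)), "linked")
})

test_that("greedy matching equals brute-force optimal matching on small scans", {
  set.seed(13)
  for (i in 1:60) {
    ng <- sample(0:5, 1); np <- sample(0:6, 1)
    gt <- NULL
    for (g in seq_len(ng)) {
      s0 <- sample(0:3, 1)
      gx <- runif(1, 0, 80); gy <- runif(1, 0, 80)
      w <- runif(1, 8, 16); h <- runif(1, 8, 16)
      gt <- rbind(gt, b(s0, gx, gy, w, h, lesion_id = g),
                  b(s0 + 1, gx, gy, w, h, lesion_id = g))
    }
    pred <- NULL
    for (p in seq_len(np)) {
      if (ng > 0 && runif(1) < 0.7) {  # perturbed copy of a random gt lesion
        src <- gt[gt$lesion_id == sample(ng, 1), ][1, ]
        pred <- rbind(pred, b(src$slice_index, src$x + runif(1, 0, 4),
                              src$y + runif(1, 0, 4), src$w, src$h,
                              lesion_id = p))
      } else {
        pred <- rbind(pred, b(sample(0:4, 1), runif(1, 0, 80), runif(1, 0, 80),
                              runif(1, 8, 16), runif(1, 8, 16), lesion_id = p))
      }
    }
    gt <- if (is.null(gt)) boxes_df() else gt
    pred <- if (is.null(pred)) boxes_df() else pred
    res <- match_lesions(gt, pred)
    expect_equal(res$TP + res$FN, ng)  # conservation
    best <- max_matching_bruteforce(compat_matrix(gt, pred))
    expect_equal(res$TP, best)
  }
})

test_that("raising the match threshold never increases TP", {
  set.seed(29)
  for (i in 1:15) {
    gt <- NULL; pred <- NULL
    for (g in 1:3) {
      gx <- runif(1, 0, 60); gy <- runif(1, 0, 60)
      gt <- rbind(gt, b(0, gx, gy, 12, 12, lesion_id = g),
                  b(1, gx, gy, 12, 12, lesion_id = g))
      pred <- rbind(pred, b(0, gx + runif(1, 0, 6), gy + runif(1, 0, 6),
                            12, 12, lesion_id = g))
    }
    tps <- vapply(c(0.3, 0.5, 0.7, 0.9), function(thr)
      match_lesions(gt, pred, eval_config(match_iou = thr))$TP, 0L)
    expect_true(all(diff(tps) <= 0))
  }
})

test_that("fold pooling reproduces published per-fold and overall rates", {
  tps <- c(142L, 147L, 81L, 94L, 76L)
  fns <- c(20L, 23L, 18L, 11L, 2L)
  ns <- c(22L, 23L, 22L, 23L, 23L)
  fpavg <- c(21.14, 21.57, 7.27, 9.61, 12.78)
  fps <- round(fpavg * ns)
  counts <- data.frame(scan_id = sprintf("fold%d", 1:5),
                       TP = tps, FN = fns, FP = fps)
  rep5 <- pool_folds(counts, fold = 1:5)
  expect_equal(round(rep5$per_fold$sensitivity, 2),
               c(87.65, 86.47, 81.82, 89.52, 97.44))
  expect_equal(round(rep5$per_fold$precision, 2),
               c(23.39, 22.86, 33.61, 29.84, 20.54))
  expect_equal(round(rep5$overall$sensitivity, 2), 87.95)
  expect_equal(round(rep5$overall$precision, 2), 24.82)
  expect_equal(round(rep5$overall$f1_half, 2), 19.35)
  # pooled equals single fold when there is one fold; order never matters
  one <- pool_folds(counts, fold = rep(1, 5))
  expect_equal(one$per_fold[, names(one$overall)], one$overall,
               ignore_attr = TRUE)
  rev5 <- pool_folds(counts[5:1, ], fold = 5:1)
  expect_equal(rev5$overall, rep5$overall)
  expect_error(pool_folds(counts[0, ]), "no scan counts")
})

test_that("scans without ground truth contribute only false positives per scan", {
  expect_equal(evaluate_normals(rep(0L, 10)), 0.0)
  expect_equal(evaluate_normals(c(1L, 0L, 3L)), 4 / 3)
  # several calibrated models applied to the same normal set, then averaged
  per_model <- vapply(list(c(1, 0, 3), c(2, 2, 2), c(0, 0, 1), c(1, 1, 1),
                           c(4, 0, 0)), evaluate_normals, 0)
  expect_equal(mean(per_model), mean(c(4 / 3, 2, 1 / 3, 1, 4 / 3)))
})

test_that("reading-time reductions average to the reported summary", {
  expect_equal(round(mean_percent_reduction(c(15.22, 25.77, 22.88, 19.57)), 2),
               20.86)
  expect_equal(paired_reduction(c(100, 120), c(100, 120)), 0.0)
  expect_equal(mean_percent_reduction(17.5), 17.5)
  expect_equal(paired_reduction(c(200, 100), c(90, 60)), 50.0)
  expect_error(paired_reduction(c(10, -5), c(4, 4)), "positive")
  tt <- reading_time_ttest(c(100, 110, 120, 130), c(80, 85, 100, 105))
  expect_s3_class(tt, "htest")
  expect_lt(tt$p.value, 0.05)
})
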