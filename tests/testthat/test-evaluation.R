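test_that("pixel confusion counts are exact", {
  a <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_identical(confusion_counts(a, a)[c("FP", "FN")],
                   list(FP = 0L, FN = 0L))
  b <- 1 - a
  cc <- confusion_counts(b, a)
  expect_identical(cc$TP, 0L)
  expect_identical(cc$TN, 0L)
  # 3x3 hand grid: pred has 4 foreground, truth 3, overlap 2
  pred <- matrix(0, 3, 3); truth <- matrix(0, 3, 3)
  pred[c(1, 2, 4, 5)] <- 1
  truth[c(1, 2, 3)] <- 1
  cc <- confusion_counts(pred, truth)
  expect_identical(unclass(cc), list(TP = 2L, FP = 2L, FN = 1L, TN = 4L))
  expect_error(confusion_counts(pred, matrix(0, 2, 2)), "identical shape")
  expect_error(confusion_counts(pred * 2, truth), "binary")
})

test_that("metric formulas, conventions and identities hold", {
  r <- metrics_from_counts(list(TP = 1, FP = 0, FN = 0, TN = 0))
  expect_true(all(unlist(r[c("iou", "dice", "precision", "recall",
                             "f1")]) == 1))
  r <- metrics_from_counts(list(TP = 50, FP = 10, FN = 10, TN = 0))
  expect_equal(r$iou, 5 / 7)
  expect_equal(r$dice, 5 / 6)
  expect_equal(r$precision, 5 / 6)
  expect_equal(r$recall, 5 / 6)
  expect_equal(r$f1, 5 / 6)
  expect_equal(r$dice, 2 * r$iou / (1 + r$iou))
  # degenerate convention: zero with flags
  r0 <- metrics_from_counts(list(TP = 0, FP = 0, FN = 0, TN = 9))
  expect_true(all(unlist(r0[c("iou", "dice", "precision", "recall",
                              "f1")]) == 0))
  expect_match(r0$degenerate, "precision")
  expect_match(r0$degenerate, "recall")
})

test_that("metrics are invariant under transposition of both grids", {
  set.seed(1)
  pred <- matrix(rbinom(20, 1, 0.4), 4, 5)
  truth <- matrix(rbinom(20, 1, 0.4), 4, 5)
  expect_identical(metrics_from_counts(confusion_counts(pred, truth)),
                   metrics_from_counts(confusion_counts(t(pred), t(truth))))
})

test_that("evaluate aggregates macro per category and micro overall", {
  db <- scene_batch(4, size = 64, seed = 50)
  manifest <- data.frame(image_id = db$image_id,
                         category = c(1L, 1L, 8L, 8L),
                         teeth32 = TRUE, restoration = FALSE,
                         appliance = FALSE, split = "test")
  ds <- c(db, list(manifest = manifest))
  # oracle predictor reproduces the truth exactly
  idx <- 0L
  oracle <- function(x) {
    n <- dim(x)[4]
    out <- db$masks[, , idx + seq_len(n), drop = FALSE]
    idx <<- idx + n
    out
  }
  rep <- evaluate(oracle, ds)
  expect_equal(rep$overall$iou, 1)
  expect_true(all(rep$per_image$iou == 1))
  # constant-background predictor: zero overlap, degenerate precision
  bg <- function(x) array(0L, dim(x)[c(1, 2, 4)])
  rep0 <- evaluate(bg, ds)
  expect_equal(rep0$overall$iou, 0)
  expect_match(rep0$overall$degenerate, "precision")
  # category aggregate is the mean of its per-image rows
  for (cat in c(1L, 8L)) {
    sub <- rep0$per_image[rep0$per_image$category == cat, ]
    expect_equal(rep0$per_category$iou[rep0$per_category$category == cat],
                 mean(sub$iou))
  }
  # pooled overall counts conserve pixels
  n_pix <- as.integer(prod(dim(db$masks)))
  cc <- confusion_counts(array(0L, dim(db$masks)), db$masks)
  expect_identical(cc$TP + cc$FP + cc$FN + cc$TN, n_pix)
  # images without a manifest row are an error
  bad <- ds
  bad$manifest <- manifest[1:2, ]
  expect_error(evaluate(bg, bad), "without a manifest row")
})

test_that("error maps paint false positives blue and false negatives red", {
  pred <- matrix(0, 3, 3); truth <- matrix(0, 3, 3)
  pred[c(1, 2, 4, 5)] <- 1
  truth[c(1, 2, 3)] <- 1
  em <- error_map(pred, truth)
  blue <- em[, , 3] == 1 & em[, , 1] == 0
  red <- em[, , 1] == 1 & em[, , 3] == 0
  expect_identical(sum(blue), 2L)
  expect_identical(sum(red), 1L)
  # exact prediction: no error colors
  em0 <- error_map(truth, truth)
  expect_identical(sum(em0[, , 3] == 1 & em0[, , 1] == 0), 0L)
  # strict superset: blue only
  sup <- truth; sup[c(4, 5)] <- 1
  em1 <- error_map(sup, truth)
  expect_identical(sum(em1[, , 1] == 1 & em1[, , 3] == 0), 0L)
  expect_gt(sum(em1[, , 3] == 1 & em1[, , 1] == 0), 0L)
})
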