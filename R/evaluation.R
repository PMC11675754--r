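# Pixel-level confusion accounting, overlap metrics, per-category reports
# and error maps.

#' Pixel confusion counts
#'
#' @param pred,truth binary masks of identical shape (`(H, W)` or
#'   `(H, W, N)`), values in `{0, 1}`.
#' @return object of class `confusion_counts`: list(TP, FP, FN, TN).
#' @export
confusion_counts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    stop("pred and truth must have identical shape", call. = FALSE)
  stopifnot_binary(pred, "pred"); stopifnot_binary(truth, "truth")
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn),
            class = "confusion_counts")
}

#' Overlap metrics from confusion counts
#'
#' IoU = TP/(TP+FP+FN); Dice = 2TP/(2TP+FP+FN); Precision = TP/(TP+FP);
#' Recall = TP/(TP+FN); F1 = 2PR/(P+R).  Degenerate denominators yield 0
#' with the corresponding flag set.
#'
#' @param counts a [confusion_counts()] (or list with TP/FP/FN/TN).
#' @return one-row data.frame: iou, dice, precision, recall, f1,
#'   degenerate (comma-separated flags, empty if none).
#' @export
metrics_from_counts <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  flags <- character()
  div <- function(num, den, flag) {
    if (den == 0) { flags <<- c(flags, flag); return(0) }
    num / den
  }
  iou <- div(tp, tp + fp + fn, "iou")
  dice <- div(2 * tp, 2 * tp + fp + fn, "dice")
  precision <- div(tp, tp + fp, "precision")
  recall <- div(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) {
    flags <- c(flags, "f1"); 0
  } else 2 * precision * recall / (precision + recall)
  data.frame(iou = iou, dice = dice, precision = precision, recall = recall,
             f1 = f1, degenerate = paste(flags, collapse = ","))
}

#' Evaluate a model over a fixture dataset
#'
#' Produces a metrics row per image, per category (macro average of the
#' per-image rows) and overall (micro: metrics of the pooled pixel counts).
#' Both aggregations are reported because printed category tables in the
#' literature rarely state which is used.
#'
#' @param model a `panseg_model` (or a function `(images) -> masks` for
#'   oracle predictors in tests).
#' @param dataset list with `images`, `masks` and `image_id` (as produced by
#'   [load_dataset()]), or a directory created by [make_dataset()].
#' @param manifest manifest data.frame; defaults to the one stored with the
#'   dataset.
#' @param report_dir optional directory: writes `report.csv` and
#'   `report.json`.
#' @param batch_size evaluation chunk size.
#' @return list with `per_image`, `per_category`, `overall` data.frames,
#'   class `panseg_report`.
#' @export
evaluate <- function(model, dataset, manifest = NULL, report_dir = NULL,
                     batch_size = 8L) {
  if (is.character(dataset)) dataset <- load_dataset(dataset)
  if (is.null(manifest)) manifest <- dataset$manifest
  if (is.null(manifest)) stop("no manifest available", call. = FALSE)
  n <- dim(dataset$images)[4]
  ids <- dataset$image_id %||% sprintf("img%04d", seq_len(n))
  mrow <- match(ids, manifest$image_id)
  if (anyNA(mrow))
    stop("image(s) without a manifest row: ",
         paste(utils::head(ids[is.na(mrow)], 3), collapse = ", "),
         call. = FALSE)
  pred_all <- array(0L, dim(dataset$masks))
  for (b0 in seq(1L, n, by = batch_size)) {
    idx <- b0:min(n, b0 + batch_size - 1L)
    xb <- dataset$images[, , , idx, drop = FALSE]
    pred_all[, , idx] <- if (is.function(model)) model(xb)
                         else predict(model, xb)
  }
  per_image <- NULL
  pooled <- list(TP = 0, FP = 0, FN = 0, TN = 0)
  for (i in seq_len(n)) {
    cc <- confusion_counts(pred_all[, , i], dataset$masks[, , i])
    for (f in names(pooled)) pooled[[f]] <- pooled[[f]] + cc[[f]]
    per_image <- rbind(per_image,
      cbind(data.frame(scope = "image", id = ids[i],
                       category = manifest$category[mrow[i]]),
            metrics_from_counts(cc)))
  }
  per_category <- NULL
  for (cat in sort(unique(per_image$category))) {
    sub <- per_image[per_image$category == cat, ]
    per_category <- rbind(per_category,
      data.frame(scope = "category", id = as.character(cat), category = cat,
                 iou = mean(sub$iou), dice = mean(sub$dice),
                 precision = mean(sub$precision), recall = mean(sub$recall),
                 f1 = mean(sub$f1), degenerate = ""))
  }
  overall <- cbind(data.frame(scope = "overall", id = "all", category = NA),
                   metrics_from_counts(structure(pooled,
                                                 class = "confusion_counts")))
  rep <- structure(list(per_image = per_image, per_category = per_category,
                        overall = overall),
                   class = "panseg_report")
  if (!is.null(report_dir)) {
    dir.create(report_dir, showWarnings = FALSE, recursive = TRUE)
    all <- rbind(per_image, per_category, overall)
    utils::write.csv(all, file.path(report_dir, "report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(rep, file.path(report_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  rep
}

#' @export
print.panseg_report <- function(x, ...) {
  cat("overall (micro):\n")
  print(x$overall[, c("iou", "dice", "precision", "recall", "f1")],
        row.names = FALSE)
  cat("per category (macro):\n")
  print(x$per_category[, c("category", "iou", "dice", "precision",
                           "recall", "f1")], row.names = FALSE)
  invisible(x)
}

#' False-positive / false-negative error map
#'
#' Blue marks false positives, red false negatives; correctly predicted
#' foreground is white, background black.
#'
#' @param pred,truth binary `(H, W)` masks.
#' @return RGB array `(H, W, 3)` in `[0, 1]`.
#' @export
error_map <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth must have identical shape", call. = FALSE)
  stopifnot_binary(pred, "pred"); stopifnot_binary(truth, "truth")
  h <- dim(pred)[1]; w <- dim(pred)[2]
  img <- array(0, c(h, w, 3))
  tp <- pred == 1 & truth == 1
  fp <- pred == 1 & truth == 0
  fn <- pred == 0 & truth == 1
  img[, , 1][tp] <- 1; img[, , 2][tp] <- 1; img[, , 3][tp] <- 1
  img[, , 3][fp] <- 1                       # blue: false positives
  img[, , 1][fn] <- 1                       # red: false negatives
  img
}
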