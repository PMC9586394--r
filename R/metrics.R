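#' Confusion matrix
#'
#' A square count matrix indexed `[true_class, predicted_class]`. For the
#' binary problems in this package the classes are `background`/`breast`
#' (segmentation, pixel counts) or `normal`/`abnormal` (classification,
#' sample counts), with `breast`/`abnormal` as the positive class.
#'
#' @param class_names character vector of class labels.
#' @return zero-initialized `confusion_matrix`.
#' @examples
#' cm <- confusion_matrix(c("background", "breast"))
#' @export
confusion_matrix <- function(class_names) {
  k <- length(class_names)
  if (k < 2L) stop_config("need at least two classes")
  m <- matrix(0, k, k, dimnames = list(truth = class_names,
                                       pred = class_names))
  structure(list(counts = m, class_names = class_names),
            class = "confusion_matrix")
}

#' Accumulate predictions into a confusion matrix
#'
#' Adds per-pixel counts (label maps) or a single count (scalar labels) for
#' each `(truth, pred)` pair.
#'
#' @param pred predicted label map (matrix/vector) or scalar label; values
#'   must be members of `cm$class_names`.
#' @param truth true labels, same shape as `pred`.
#' @param cm a [confusion_matrix()].
#' @return the updated `confusion_matrix`.
#' @export
accumulate_confusion <- function(pred, truth, cm) {
  if (!inherits(cm, "confusion_matrix")) stop_config("cm must be a confusion_matrix")
  pred <- as.character(pred); truth <- as.character(truth)
  if (length(pred) != length(truth))
    stop_config("pred and truth must share shape")
  bad <- setdiff(unique(c(pred, truth)), cm$class_names)
  if (length(bad))
    stop_data("unknown label(s): ", paste(bad, collapse = ", "))
  tab <- table(factor(truth, levels = cm$class_names),
               factor(pred, levels = cm$class_names))
  cm$counts <- cm$counts + unclass(tab)
  cm
}

# binary 0/1 mask -> label map helper
mask_labels <- function(mask, class_names = c("background", "breast")) {
  ifelse(mask > 0, class_names[2], class_names[1])
}

#' Global accuracy
#'
#' Fraction of correctly classified pixels (or samples) regardless of class:
#' `(TP + TN) / (TP + TN + FP + FN)`, i.e. trace over total in the
#' multiclass generalization.
#'
#' @param cm a [confusion_matrix()].
#' @return fraction in `[0, 1]`.
#' @export
global_accuracy <- function(cm) {
  tot <- sum(cm$counts)
  if (tot == 0) stop_data("empty confusion matrix: global accuracy undefined")
  sum(diag(cm$counts)) / tot
}

#' Per-class accuracy
#'
#' Fraction of true pixels of class `c` that were predicted as class `c`:
#' `TP_c / (TP_c + FN_c)`.
#'
#' @param cm a [confusion_matrix()].
#' @param class class name or index.
#' @return fraction in `[0, 1]`.
#' @export
class_accuracy <- function(cm, class) {
  i <- class_index(cm, class)
  n <- sum(cm$counts[i, ])
  if (n == 0) stop_data("class '", cm$class_names[i],
                        "' absent from truth: accuracy undefined")
  cm$counts[i, i] / n
}

#' Mean per-class accuracy
#'
#' Arithmetic mean of [class_accuracy()] over classes with at least one true
#' pixel; absent classes are excluded and reported in the `"excluded"`
#' attribute.
#'
#' @param cm a [confusion_matrix()].
#' @return fraction, with attribute `excluded` naming skipped classes.
#' @export
mean_accuracy <- function(cm) {
  per_class_metric_mean(cm, class_accuracy, rowSums(cm$counts) > 0)
}

#' Intersection over union (Jaccard index)
#'
#' `TP_c / (TP_c + FP_c + FN_c)` for class `c`.
#'
#' @inheritParams class_accuracy
#' @return fraction in `[0, 1]`.
#' @export
iou <- function(cm, class) {
  i <- class_index(cm, class)
  u <- sum(cm$counts[i, ]) + sum(cm$counts[, i]) - cm$counts[i, i]
  if (u == 0) stop_data("class '", cm$class_names[i],
                        "' has empty union: IoU undefined")
  cm$counts[i, i] / u
}

#' Mean intersection over union
#'
#' Arithmetic mean of [iou()] over classes with a non-empty union; classes
#' absent from both prediction and truth are excluded and reported.
#'
#' @param cm a [confusion_matrix()].
#' @return fraction, with attribute `excluded` naming skipped classes.
#' @export
mean_iou <- function(cm) {
  ok <- (rowSums(cm$counts) + colSums(cm$counts)) > 0
  per_class_metric_mean(cm, iou, ok)
}

class_index <- function(cm, class) {
  if (is.character(class)) {
    i <- match(class, cm$class_names)
    if (is.na(i)) stop_data("unknown class: ", class)
    i
  } else as.integer(class)
}

per_class_metric_mean <- function(cm, f, ok) {
  if (!any(ok)) stop_data("metric undefined for every class")
  vals <- vapply(which(ok), function(i) f(cm, i), numeric(1))
  structure(mean(vals), excluded = cm$class_names[!ok])
}

#' Classification scores
#'
#' Accuracy, sensitivity `TP / (TP + FN)` and specificity `TN / (TN + FP)`
#' for a binary confusion matrix with a designated positive class.
#'
#' @param cm a 2-class [confusion_matrix()].
#' @param positive name of the positive (diseased) class.
#' @return list of class `cls_scores` with `accuracy`, `sensitivity`,
#'   `specificity`.
#' @export
cls_scores <- function(cm, positive = "abnormal") {
  if (length(cm$class_names) != 2L)
    stop_config("cls_scores needs a binary confusion matrix")
  p <- class_index(cm, positive)
  n <- setdiff(1:2, p)
  TP <- cm$counts[p, p]; FN <- cm$counts[p, n]
  TN <- cm$counts[n, n]; FP <- cm$counts[n, p]
  if (TP + FN == 0) stop_data("sensitivity undefined: no positive cases")
  if (TN + FP == 0) stop_data("specificity undefined: no negative cases")
  structure(list(accuracy = (TP + TN) / (TP + TN + FP + FN),
                 sensitivity = TP / (TP + FN),
                 specificity = TN / (TN + FP)),
            class = "cls_scores")
}

#' @export
print.cls_scores <- function(x, ...) {
  cat(sprintf("accuracy: %.4f  sensitivity: %.4f  specificity: %.4f\n",
              x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

# ---- boundary-F1 ----

# boundary pixels: mask minus its 4-connectivity erosion; pixels on the image
# border that belong to the mask count as boundary (border is outside).
mask_boundary <- function(mask) {
  m <- mask > 0
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- m
  er <- pad[2:(H + 1L), 2:(W + 1L)] &
    pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
    pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
  m & !er
}

default_bf_tolerance <- function(dims) {
  max(1L, as.integer(round(0.0075 * sqrt(sum(dims^2)))))
}

#' Boundary-F1 (BF) score
#'
#' Measures how closely the predicted boundary of a class matches the true
#' boundary. Boundary pixels are the mask minus its 4-connectivity erosion.
#' A predicted boundary pixel counts as a true positive when it lies within
#' Euclidean distance `tolerance` of some true boundary pixel (and
#' symmetrically for recall); the score is `2*precision*recall /
#' (precision + recall)`, equivalently `2TP / (2TP + FP + FN)`. If both
#' boundaries are empty the score is 1 by convention; if exactly one is
#' empty, 0.
#'
#' @param pred_mask,truth_mask binary matrices of one shape (0/1 or logical).
#' @param tolerance match distance in pixels; default 0.75% of the image
#'   diagonal, rounded, at least 1.
#' @return fraction in `[0, 1]`.
#' @export
bf_score <- function(pred_mask, truth_mask, tolerance = NULL) {
  if (!identical(dim(pred_mask), dim(truth_mask)))
    stop_config("masks must share shape")
  if (is.null(tolerance)) tolerance <- default_bf_tolerance(dim(pred_mask))
  pb <- which(mask_boundary(pred_mask), arr.ind = TRUE)
  tb <- which(mask_boundary(truth_mask), arr.ind = TRUE)
  if (nrow(pb) == 0 && nrow(tb) == 0) return(1)
  if (nrow(pb) == 0 || nrow(tb) == 0) return(0)
  d2 <- outer(pb[, 1], tb[, 1], "-")^2 + outer(pb[, 2], tb[, 2], "-")^2
  tol2 <- tolerance^2
  precision <- mean(apply(d2, 1, min) <= tol2)
  recall <- mean(apply(d2, 2, min) <= tol2)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Segmentation score suite
#'
#' Evaluates predicted binary masks against ground truth with the full metric
#' set: global accuracy, per-class and mean accuracy, per-class and mean IoU,
#' and per-class and mean boundary-F1. Accuracy and IoU aggregate the pixel
#' confusion matrix over the whole set and then average over classes; the BF
#' score is computed per image per class, averaged over images per class, and
#' the mean BF is the average of the per-class values.
#'
#' @param pred_masks,truth_masks lists of binary matrices (or single
#'   matrices).
#' @param tolerance BF match distance in pixels (default as in [bf_score()]).
#' @param class_names labels for the negative and positive class.
#' @return list of class `seg_scores`: `global_accuracy`,
#'   `per_class_accuracy`, `mean_accuracy`, `per_class_iou`, `mean_iou`,
#'   `per_class_bf`, `mean_bf`, `per_image` (data frame), `confusion`.
#' @export
seg_scores <- function(pred_masks, truth_masks, tolerance = NULL,
                       class_names = c("background", "breast")) {
  if (is.matrix(pred_masks)) pred_masks <- list(pred_masks)
  if (is.matrix(truth_masks)) truth_masks <- list(truth_masks)
  if (length(pred_masks) != length(truth_masks))
    stop_config("need one prediction per truth mask")
  cm <- confusion_matrix(class_names)
  n <- length(pred_masks)
  bf <- matrix(NA_real_, n, 2, dimnames = list(NULL, class_names))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- pred_masks[[i]]; t <- truth_masks[[i]]
    cm <- accumulate_confusion(mask_labels(p, class_names),
                               mask_labels(t, class_names), cm)
    bf[i, 1] <- bf_score(1 - (p > 0), 1 - (t > 0), tolerance)
    bf[i, 2] <- bf_score(p > 0, t > 0, tolerance)
    rows[[i]] <- data.frame(image = i, class = class_names,
                            bf = bf[i, ], row.names = NULL)
  }
  acc <- mean_accuracy(cm)
  miou <- mean_iou(cm)
  per_acc <- vapply(seq_along(class_names), function(i) {
    if (sum(cm$counts[i, ]) > 0) class_accuracy(cm, i) else NA_real_
  }, numeric(1))
  per_iou <- vapply(seq_along(class_names), function(i) {
    u <- sum(cm$counts[i, ]) + sum(cm$counts[, i]) - cm$counts[i, i]
    if (u > 0) iou(cm, i) else NA_real_
  }, numeric(1))
  per_bf <- colMeans(bf)
  structure(list(
    global_accuracy = global_accuracy(cm),
    per_class_accuracy = stats::setNames(per_acc, class_names),
    mean_accuracy = as.numeric(acc),
    per_class_iou = stats::setNames(per_iou, class_names),
    mean_iou = as.numeric(miou),
    per_class_bf = per_bf,
    mean_bf = mean(per_bf),
    per_image = do.call(rbind, rows),
    confusion = cm,
    excluded = list(accuracy = attr(acc, "excluded"),
                    iou = attr(miou, "excluded"))
  ), class = "seg_scores")
}

#' @export
print.seg_scores <- function(x, ...) {
  cat(sprintf("Mean Acc. %.4f | Global Acc. %.4f | Mean IoU %.4f | Mean BFScore %.4f\n",
              x$mean_accuracy, x$global_accuracy, x$mean_iou, x$mean_bf))
  invisible(x)
}

#' Write a segmentation evaluation report
#'
#' Writes one CSV row per image per class (BF scores) plus aggregate rows,
#' and a short human-readable summary.
#'
#' @param scores a [seg_scores()] result.
#' @param csv_path,summary_path output file paths (`NULL` to skip one).
#' @return invisibly, the aggregate data frame written.
#' @export
write_seg_report <- function(scores, csv_path, summary_path = NULL) {
  per <- scores$per_image
  agg <- data.frame(
    image = NA_integer_,
    class = c(names(scores$per_class_iou), "mean"),
    bf = c(scores$per_class_bf, scores$mean_bf))
  agg$iou <- c(scores$per_class_iou, scores$mean_iou)
  agg$accuracy <- c(scores$per_class_accuracy, scores$mean_accuracy)
  per$iou <- NA_real_; per$accuracy <- NA_real_
  out <- rbind(per, agg)
  utils::write.csv(out, csv_path, row.names = FALSE)
  if (!is.null(summary_path)) {
    writeLines(c(
      sprintf("Mean Acc.     %.4f", scores$mean_accuracy),
      sprintf("Global Acc.   %.4f", scores$global_accuracy),
      sprintf("Mean IoU      %.4f", scores$mean_iou),
      sprintf("Mean BFScore  %.4f", scores$mean_bf)), summary_path)
  }
  invisible(out)
}
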