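cm_from_counts <- function(TP, TN, FP, FN,
                           classes = c("negative", "positive")) {
  cm <- confusion_matrix(classes)
  cm$counts["positive", "positive"] <- TP
  cm$counts["negative", "negative"] <- TN
  cm$counts["negative", "positive"] <- FP
  cm$counts["positive", "negative"] <- FN
  cm
}

test_that("confusion accumulation counts per-pixel pairs", {
  cm <- confusion_matrix(c("background", "breast"))
  truth <- matrix("breast", 2, 5)
  cm <- accumulate_confusion(truth, truth, cm)
  expect_equal(sum(diag(cm$counts)), 10)
  expect_equal(sum(cm$counts) - sum(diag(cm$counts)), 0)
  cm2 <- accumulate_confusion(matrix("breast", 2, 2),
                              matrix("background", 2, 2),
                              confusion_matrix(c("background", "breast")))
  expect_equal(cm2$counts["background", "breast"], 4)
  # random pair vs per-pixel counting loop
  set.seed(31)
  pred <- matrix(sample(c("background", "breast"), 64, TRUE), 8)
  truth <- matrix(sample(c("background", "breast"), 64, TRUE), 8)
  cm3 <- accumulate_confusion(pred, truth,
                              confusion_matrix(c("background", "breast")))
  ref <- matrix(0, 2, 2, dimnames = dimnames(cm3$counts))
  for (i in seq_along(pred)) ref[truth[i], pred[i]] <- ref[truth[i], pred[i]] + 1
  expect_equal(unname(cm3$counts), unname(ref))
  expect_error(accumulate_confusion(matrix("x", 1, 1), matrix("breast", 1, 1),
                                    cm), class = "vpb_data_error")
})

test_that("accuracy, IoU and classification scores reproduce hand values", {
  cm <- cm_from_counts(TP = 3, TN = 4, FP = 1, FN = 2)
  expect_equal(global_accuracy(cm), 0.7)
  expect_equal(class_accuracy(cm, "positive"), 0.6)
  expect_equal(iou(cm, "positive"), 0.5)
  # two classes at 0.6 and 1.0 -> mean 0.8
  cm2 <- cm_from_counts(TP = 3, TN = 5, FP = 0, FN = 2)
  expect_equal(as.numeric(mean_accuracy(cm2)), mean(c(1.0, 0.6)))
  sc <- cls_scores(cm_from_counts(8, 9, 1, 2), positive = "positive")
  expect_equal(sc$sensitivity, 0.8)
  expect_equal(sc$specificity, 0.9)
  expect_equal(sc$accuracy, 0.85)
  # degenerate all-positive predictor
  deg <- cls_scores(cm_from_counts(10, 0, 10, 0), positive = "positive")
  expect_equal(deg$sensitivity, 1.0)
  expect_equal(deg$specificity, 0.0)
  expect_error(cls_scores(cm_from_counts(0, 5, 0, 0), positive = "positive"),
               class = "vpb_data_error")
})

test_that("perfect and fully wrong predictions bound the metrics", {
  cm <- cm_from_counts(5, 5, 0, 0)
  expect_equal(global_accuracy(cm), 1.0)
  expect_equal(as.numeric(mean_iou(cm)), 1.0)
  cmw <- cm_from_counts(0, 0, 5, 5)
  expect_equal(global_accuracy(cmw), 0.0)
  expect_equal(iou(cmw, "positive"), 0.0)
  expect_error(global_accuracy(confusion_matrix(c("a", "b"))),
               class = "vpb_data_error")
})

test_that("IoU never exceeds class accuracy", {
  set.seed(47)
  for (rep in 1:20) {
    cm <- cm_from_counts(sample(1:50, 1), sample(1:50, 1),
                         sample(0:20, 1), sample(0:20, 1))
    expect_lte(iou(cm, "positive"), class_accuracy(cm, "positive") + 1e-12)
  }
})

test_that("BF score: identical, shifted, and far-apart masks", {
  m <- matrix(0L, 20, 20); m[5:12, 5:12] <- 1L
  expect_equal(bf_score(m, m, tolerance = 1), 1.0)
  expect_equal(bf_score(m, m, tolerance = 5), 1.0)
  shifted <- matrix(0L, 20, 20); shifted[6:13, 5:12] <- 1L
  expect_equal(bf_score(shifted, m, tolerance = 2), 1.0)
  far_pred <- matrix(0L, 30, 30); far_pred[2:5, 2:5] <- 1L
  far_truth <- matrix(0L, 30, 30); far_truth[20:23, 20:23] <- 1L
  expect_equal(bf_score(far_pred, far_truth, tolerance = 2), 0.0)
  # brute-force oracle at tolerance 1 on the one-pixel shift
  pb <- which(shifted - rbind(matrix(0L, 1, 20), shifted[-20, ]) != 0)
  expect_true(bf_score(shifted, m, tolerance = 1) > 0)
})

test_that("BF conventions and symmetry", {
  e <- matrix(0L, 10, 10)
  m <- matrix(0L, 10, 10); m[3:6, 3:6] <- 1L
  expect_equal(bf_score(e, e), 1.0)
  expect_equal(bf_score(e, m), 0.0)
  expect_equal(bf_score(m, e), 0.0)
  set.seed(11)
  a <- matrix(rbinom(100, 1, 0.4), 10)
  b <- matrix(rbinom(100, 1, 0.4), 10)
  expect_equal(bf_score(a, b, 2), bf_score(b, a, 2))
})

test_that("full-mask boundary includes image-border pixels", {
  full <- matrix(1L, 6, 6)
  b <- vpbpool:::mask_boundary(full)
  expect_true(all(b[1, ]) && all(b[6, ]) && all(b[, 1]) && all(b[, 6]))
  expect_false(any(b[2:5, 2:5]))
})

test_that("aggregated mean IoU equals the set-operation oracle", {
  set.seed(19)
  preds <- lapply(1:5, function(i) matrix(rbinom(64, 1, 0.5), 8))
  truths <- lapply(1:5, function(i) matrix(rbinom(64, 1, 0.5), 8))
  sc <- seg_scores(preds, truths, tolerance = 1)
  A <- unlist(lapply(preds, as.vector)); B <- unlist(lapply(truths, as.vector))
  iou_pos <- sum(A == 1 & B == 1) / sum(A == 1 | B == 1)
  iou_neg <- sum(A == 0 & B == 0) / sum(A == 0 | B == 0)
  expect_equal(sc$mean_iou, mean(c(iou_neg, iou_pos)))
  expect_equal(unname(sc$per_class_iou["breast"]), iou_pos)
  expect_true(all(unlist(sc[c("global_accuracy", "mean_accuracy",
                              "mean_iou", "mean_bf")]) >= 0))
  expect_true(all(unlist(sc[c("global_accuracy", "mean_accuracy",
                              "mean_iou", "mean_bf")]) <= 1))
})

test_that("evaluating ground truth against itself scores 1 everywhere", {
  s <- generate_sample(42, "abnormal")
  sc <- seg_scores(s$mask, s$mask)
  expect_equal(sc$global_accuracy, 1.0)
  expect_equal(sc$mean_accuracy, 1.0)
  expect_equal(sc$mean_iou, 1.0)
  expect_equal(sc$mean_bf, 1.0)
  # all-background predictor zeroes the breast IoU
  sc0 <- seg_scores(s$mask * 0L, s$mask)
  expect_equal(unname(sc0$per_class_iou["breast"]), 0.0)
})

test_that("segmentation report writes per-image and aggregate rows", {
  s1 <- generate_sample(1, "normal")
  s2 <- generate_sample(2, "abnormal")
  sc <- seg_scores(list(s1$mask, s2$mask), list(s1$mask, s2$mask))
  csv <- tempfile(fileext = ".csv"); txt <- tempfile(fileext = ".txt")
  write_seg_report(sc, csv, txt)
  out <- read.csv(csv)
  expect_equal(nrow(out), 2 * 2 + 3)
  expect_true(any(grepl("Mean IoU", readLines(txt))))
})
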