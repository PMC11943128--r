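test_that("the confusion matrix equals an exhaustive per-pixel tally", {
  set.seed(88)
  for (rep in 1:10) {
    pred <- random_mask(8, 8)
    truth <- random_mask(8, 8)
    cm <- confusion_matrix(pred, truth)
    expect_equal(unclass(cm), oracle_confusion(pred, truth),
                 ignore_attr = TRUE)
  }

  # perfect agreement is diagonal; total disagreement lands off-diagonal
  m <- random_mask(10, 10)
  cm <- confusion_matrix(m, m)
  expect_equal(cm[1, 2] + cm[2, 1], 0)
  cm2 <- confusion_matrix(matrix(FALSE, 10, 10), matrix(TRUE, 10, 10))
  expect_equal(cm2[["lymph_node", "background"]], 100)

  # pairs are summed
  cm3 <- confusion_matrix(list(m, m), list(m, m))
  expect_equal(sum(cm3), 200)

  expect_error(confusion_matrix(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)),
               "dimension mismatch")
})

test_that("confusion is invariant under simultaneous class relabeling", {
  set.seed(17)
  pred <- random_mask(12, 12)
  truth <- random_mask(12, 12)
  cm <- confusion_matrix(pred, truth)
  flipped <- confusion_matrix(!pred, !truth)
  expect_equal(unclass(cm), unclass(flipped)[2:1, 2:1], ignore_attr = TRUE)
})

test_that("accuracy and IoU identities hold on random confusion matrices", {
  set.seed(99)
  for (rep in 1:50) {
    cm <- confusion_from_counts(
      tp = sample.int(1e6, 1), tn = sample.int(1e6, 1),
      fp = sample.int(1e5, 1), fn = sample.int(1e5, 1)
    )
    # global accuracy is the row-share-weighted mean of per-class recalls
    recalls <- diag(cm) / rowSums(cm)
    shares <- rowSums(cm) / sum(cm)
    expect_equal(global_accuracy(cm), sum(shares * recalls))
    # weighted IoU is bracketed by the class IoUs
    iou <- iou_scores(cm)
    expect_gte(iou$weighted, min(iou$per_class))
    expect_lte(iou$weighted, max(iou$per_class))
    # every reported fraction is in [0, 1]
    rep_ <- metrics_report(cm)
    expect_true(all(rep_[, c("global_accuracy", "mean_accuracy", "mean_iou",
                             "weighted_iou")] >= 0 &
                      rep_[, c("global_accuracy", "mean_accuracy", "mean_iou",
                               "weighted_iou")] <= 1))
  }
  # a diagonal matrix scores perfectly everywhere
  perfect <- confusion_from_counts(tp = 500, tn = 1500, fp = 0, fn = 0)
  expect_equal(global_accuracy(perfect), 1)
  expect_equal(mean_accuracy(perfect), 1)
  expect_equal(iou_scores(perfect)$mean, 1)
})

test_that("column normalisation yields per-class precision and flags empty columns", {
  cm <- confusion_from_counts(tp = 80, tn = 900, fp = 20, fn = 10)
  cn <- column_normalize(cm)
  expect_equal(colSums(cn), c(background = 1, lymph_node = 1))
  expect_equal(cn[2, 2], 80 / (80 + 20))

  none_predicted <- confusion_from_counts(tp = 0, tn = 90, fp = 0, fn = 10)
  cn2 <- column_normalize(none_predicted)
  expect_equal(unname(cn2[, 2]), c(0, 0))
  expect_equal(attr(cn2, "degenerate_columns"), "lymph_node")
})

test_that("BF score matches exhaustive boundary-distance computation", {
  sq <- function(r0, c0, size, h = 40, w = 40) {
    m <- matrix(FALSE, h, w)
    m[r0:(r0 + size - 1), c0:(c0 + size - 1)] <- TRUE
    m
  }
  expect_equal(bf_score(sq(5, 5, 20), sq(5, 5, 20), theta = 2), 1)
  expect_equal(bf_score(matrix(FALSE, 40, 40), sq(5, 5, 20), theta = 2), 0)
  expect_equal(bf_score(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4), theta = 2), 1)

  # 20x20 squares offset by one pixel: every boundary pixel of one is
  # within distance 2 of the other boundary (checked exhaustively)
  a <- sq(5, 5, 20); b <- sq(6, 6, 20)
  ba <- which(boundary_pixels_ref(a), arr.ind = TRUE)
  bb <- which(boundary_pixels_ref(b), arr.ind = TRUE)
  dmat <- sqrt(outer(ba[, 1], bb[, 1], "-")^2 + outer(ba[, 2], bb[, 2], "-")^2)
  expect_true(all(apply(dmat, 1, min) <= 2))
  expect_true(all(apply(dmat, 2, min) <= 2))
  expect_equal(bf_score(a, b, theta = 2), 1)

  # and a randomised cross-check of precision/recall against the same
  # exhaustive distance computation
  set.seed(23)
  for (rep in 1:5) {
    p <- random_mask(15, 15, 0.4)
    t_ <- random_mask(15, 15, 0.4)
    theta <- runif(1, 1, 4)
    bp <- which(boundary_pixels_ref(p), arr.ind = TRUE)
    bt <- which(boundary_pixels_ref(t_), arr.ind = TRUE)
    if (nrow(bp) == 0 || nrow(bt) == 0) next
    d <- sqrt(outer(bp[, 1], bt[, 1], "-")^2 + outer(bp[, 2], bt[, 2], "-")^2)
    prec <- mean(apply(d, 1, min) <= theta)
    rec <- mean(apply(d, 2, min) <= theta)
    want <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    expect_equal(bf_score(p, t_, theta = theta), want)
  }
})

test_that("mean BF score averages per class over images, then over classes", {
  a <- matrix(FALSE, 30, 30); a[10:20, 10:20] <- TRUE
  b <- matrix(FALSE, 30, 30); b[11:21, 11:21] <- TRUE
  per_image_fg <- c(bf_score(a, a, theta = 2), bf_score(a, b, theta = 2))
  per_image_bg <- c(bf_score(!a, !a, theta = 2), bf_score(!a, !b, theta = 2))
  want <- mean(c(mean(per_image_bg), mean(per_image_fg)))
  expect_equal(mean_bf_score(list(a, a), list(a, b), theta = 2), want)
})

test_that("evaluate_segmentation bundles counts and metrics with tidy/glance methods", {
  truth <- matrix(FALSE, 50, 50); truth[10:30, 10:30] <- TRUE
  pred <- matrix(FALSE, 50, 50); pred[12:32, 10:30] <- TRUE
  ev <- evaluate_segmentation(pred, truth)
  expect_s3_class(ev, "seg_eval")
  expect_equal(sum(ev$confusion), 2500)

  g <- glance(ev)
  expect_equal(nrow(g), 1)
  expect_true(all(c("global_accuracy", "mean_iou", "mean_bf_score") %in% names(g)))

  td <- tidy(ev)
  expect_equal(td$class, c("background", "lymph_node"))
  expect_equal(td$recall[2], sum(pred & truth) / sum(truth))

  # truth against itself is perfect on every metric, BF included
  ideal <- evaluate_segmentation(truth, truth)
  gi <- glance(ideal)
  expect_equal(unlist(gi[1, c("global_accuracy", "mean_accuracy", "mean_iou",
                              "weighted_iou", "mean_bf_score")]),
               c(global_accuracy = 1, mean_accuracy = 1, mean_iou = 1,
                 weighted_iou = 1, mean_bf_score = 1))

  p <- ggplot2::autoplot(ev)
  expect_s3_class(p, "ggplot")
})
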