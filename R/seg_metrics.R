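#' Pixel confusion matrix for binary segmentation
#'
#' Sums per-pixel agreement over one or more prediction/truth mask pairs
#' into a K x K count matrix with rows = true class and columns = predicted
#' class, class order `(background, lymph_node)`.
#'
#' @param pred Logical mask or list of logical masks (predicted foreground).
#' @param truth Matching mask or list (true foreground).
#' @return Integer 2 x 2 matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(pred, truth) {
  if (!is.list(pred)) pred <- list(pred)
  if (!is.list(truth)) truth <- list(truth)
  if (length(pred) != length(truth)) {
    stop("pred and truth must hold the same number of masks", call. = FALSE)
  }
  cm <- matrix(0, 2L, 2L,
               dimnames = list(true = c("background", "lymph_node"),
                               predicted = c("background", "lymph_node")))
  for (i in seq_along(pred)) {
    p <- pred[[i]]; t_ <- truth[[i]]
    if (!identical(dim(p), dim(t_))) {
      stop("dimension mismatch in pair ", i, ": pred ",
           paste(dim(p), collapse = "x"), " vs truth ",
           paste(dim(t_), collapse = "x"), call. = FALSE)
    }
    cm[1L, 1L] <- cm[1L, 1L] + sum(!t_ & !p)
    cm[1L, 2L] <- cm[1L, 2L] + sum(!t_ & p)
    cm[2L, 1L] <- cm[2L, 1L] + sum(t_ & !p)
    cm[2L, 2L] <- cm[2L, 2L] + sum(t_ & p)
  }
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Build a confusion matrix from TP/TN/FP/FN pixel counts
#'
#' Convenience constructor for published pixel counts, where "positive" is
#' the lymph-node class: TN and FP fill the background row, FN and TP the
#' lymph-node row.
#'
#' @param tp,tn,fp,fn Non-negative pixel counts.
#' @return A [confusion_matrix()].
#' @export
confusion_from_counts <- function(tp, tn, fp, fn) {
  if (any(c(tp, tn, fp, fn) < 0)) {
    stop("pixel counts must be non-negative", call. = FALSE)
  }
  structure(
    matrix(c(tn, fn, fp, tp), 2L, 2L,
           dimnames = list(true = c("background", "lymph_node"),
                           predicted = c("background", "lymph_node"))),
    class = c("confusion_matrix", "matrix")
  )
}

check_cm <- function(cm) {
  if (sum(cm) <= 0) stop("confusion matrix is empty", call. = FALSE)
  invisible(cm)
}

#' Global pixel accuracy
#'
#' Fraction of all pixels classified correctly: trace / total.
#'
#' @param cm A [confusion_matrix()].
#' @return Fraction in `[0, 1]`.
#' @export
global_accuracy <- function(cm) {
  check_cm(cm)
  sum(diag(cm)) / sum(cm)
}

#' Mean per-class accuracy
#'
#' Unweighted mean over classes of per-class recall (the row-normalised
#' diagonal), so the rare lymph-node class counts as much as background.
#'
#' @param cm A [confusion_matrix()].
#' @return Fraction in `[0, 1]`.
#' @export
mean_accuracy <- function(cm) {
  check_cm(cm)
  mean(diag(cm) / rowSums(cm))
}

#' Per-class, mean and frequency-weighted IoU
#'
#' Per-class IoU (Jaccard index) is `diag_k / (row_k + col_k - diag_k)`;
#' the mean is the unweighted class mean and the weighted IoU weights each
#' class by its true-pixel share `row_k / total`.
#'
#' @param cm A [confusion_matrix()].
#' @return List with `per_class` (named vector), `mean` and `weighted`.
#' @export
iou_scores <- function(cm) {
  check_cm(cm)
  d <- diag(cm)
  union <- rowSums(cm) + colSums(cm) - d
  per_class <- d / union
  names(per_class) <- rownames(cm)
  list(
    per_class = per_class,
    mean = mean(per_class),
    weighted = sum(rowSums(cm) / sum(cm) * per_class)
  )
}

#' Column-normalise a confusion matrix
#'
#' Divides each column by its sum, turning the diagonal into per-class
#' precision (for the lymph-node column, TP / (TP + FP)). A column with no
#' predicted pixels is returned as zeros and flagged in the
#' `degenerate_columns` attribute.
#'
#' @param cm A [confusion_matrix()].
#' @return K x K matrix of fractions; columns sum to 1 (or 0 when flagged).
#' @export
column_normalize <- function(cm) {
  check_cm(cm)
  cs <- colSums(cm)
  degenerate <- cs == 0
  cs[degenerate] <- 1 # avoid 0/0; the column stays all-zero
  out <- sweep(unclass(cm), 2L, cs, "/")
  attr(out, "degenerate_columns") <- colnames(cm)[degenerate]
  out
}

# Foreground pixels 8-adjacent to background; pixels on the image edge count
# as boundary (the outside is treated as background).
boundary_pixels <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  interior <- matrix(TRUE, h, w)
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      interior <- interior & pad[(2:(h + 1L)) + dr, (2:(w + 1L)) + dc]
    }
  }
  mask & !interior
}

# Fraction of `from` boundary pixels within Euclidean distance theta of any
# `to` boundary pixel (via a distance map of the `to` set).
boundary_match_fraction <- function(from, to, theta) {
  if (!any(from)) return(NA_real_)
  dist_to <- t(EBImage::imageData(EBImage::distmap(mask_to_ebi(!to))))
  mean(dist_to[from] <= theta)
}

#' Boundary-F1 (BF) score of one mask pair
#'
#' Boundary pixels are foreground pixels 8-adjacent to background. Precision
#' is the fraction of predicted boundary pixels within Euclidean distance
#' `theta` of any true boundary pixel, recall the symmetric fraction, and
#' the score their harmonic mean (0 when precision + recall is 0). Two masks
#' with empty boundaries agree trivially and score 1; an empty prediction
#' against a non-empty truth scores 0.
#'
#' @param pred,truth Logical masks of equal dimensions.
#' @param theta Distance tolerance in pixels; defaults to 0.75% of the image
#'   diagonal.
#' @return Fraction in `[0, 1]`.
#' @export
bf_score <- function(pred, truth, theta = NULL) {
  if (!identical(dim(pred), dim(truth))) {
    stop("dimension mismatch: pred ", paste(dim(pred), collapse = "x"),
         " vs truth ", paste(dim(truth), collapse = "x"), call. = FALSE)
  }
  theta <- theta %||% default_bf_theta(dim(pred))
  bp <- boundary_pixels(pred)
  bt <- boundary_pixels(truth)
  if (!any(bp) && !any(bt)) return(1)
  if (!any(bp) || !any(bt)) return(0)
  precision <- boundary_match_fraction(bp, bt, theta)
  recall <- boundary_match_fraction(bt, bp, theta)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

default_bf_theta <- function(extent) {
  0.0075 * sqrt(sum(extent[1:2]^2))
}

#' Mean BF score over images and classes
#'
#' Scores each (image, class) pair — the lymph-node class on the masks as
#' given and the background class on their complements — then averages over
#' images within each class and finally over classes. The aggregation order
#' matters and is fixed to this convention.
#'
#' @param pred,truth Lists of logical masks (or single masks).
#' @param theta Distance tolerance; per-image default as in [bf_score()].
#' @return Fraction in `[0, 1]`.
#' @export
mean_bf_score <- function(pred, truth, theta = NULL) {
  if (!is.list(pred)) pred <- list(pred)
  if (!is.list(truth)) truth <- list(truth)
  fg <- mapply(function(p, t_) bf_score(p, t_, theta), pred, truth)
  bg <- mapply(function(p, t_) bf_score(!p, !t_, theta), pred, truth)
  mean(c(mean(bg), mean(fg)))
}

#' Full metric report from a confusion matrix
#'
#' @param cm A [confusion_matrix()].
#' @param mean_bf Optional precomputed mean BF score (it needs the masks,
#'   not just the counts).
#' @return One-row tibble with `global_accuracy`, `mean_accuracy`,
#'   `mean_iou`, `weighted_iou`, `mean_bf_score` and per-class IoU columns.
#' @export
metrics_report <- function(cm, mean_bf = NA_real_) {
  iou <- iou_scores(cm)
  tibble::tibble(
    global_accuracy = global_accuracy(cm),
    mean_accuracy = mean_accuracy(cm),
    mean_iou = iou$mean,
    weighted_iou = iou$weighted,
    mean_bf_score = mean_bf,
    iou_background = iou$per_class[["background"]],
    iou_lymph_node = iou$per_class[["lymph_node"]]
  )
}

#' Evaluate predicted masks against ground truth
#'
#' Computes the pixel confusion matrix and the full metric suite over a set
#' of mask pairs.
#'
#' @param pred,truth Lists of logical masks (or single masks) of pairwise
#'   equal dimensions.
#' @param theta BF-score distance tolerance; default as in [bf_score()].
#' @return A `seg_eval` object: list with `confusion` (the counts),
#'   `metrics` (one-row tibble) and `n_images`. Supports [tidy()],
#'   [glance()] and [ggplot2::autoplot()].
#' @export
evaluate_segmentation <- function(pred, truth, theta = NULL) {
  if (!is.list(pred)) pred <- list(pred)
  if (!is.list(truth)) truth <- list(truth)
  cm <- confusion_matrix(pred, truth)
  structure(
    list(
      confusion = cm,
      metrics = metrics_report(cm, mean_bf = mean_bf_score(pred, truth, theta)),
      n_images = length(pred)
    ),
    class = "seg_eval"
  )
}

#' @export
print.seg_eval <- function(x, ...) {
  cat("<seg_eval> ", x$n_images, " image(s), ",
      format(sum(x$confusion), big.mark = ","), " pixels\n", sep = "")
  print(round(x$metrics, 5))
  invisible(x)
}

#' Tidy a segmentation evaluation into per-class rows
#'
#' @param x A `seg_eval` object.
#' @param ... Unused.
#' @return Tibble with one row per class: recall, precision and IoU.
#' @method tidy seg_eval
#' @export
tidy.seg_eval <- function(x, ...) {
  cm <- x$confusion
  cn <- column_normalize(cm)
  iou <- iou_scores(cm)
  tibble::tibble(
    class = rownames(cm),
    true_pixels = rowSums(cm),
    predicted_pixels = colSums(cm),
    recall = unname(diag(cm) / rowSums(cm)),
    precision = unname(diag(cn)),
    iou = unname(iou$per_class)
  )
}

#' One-row summary of a segmentation evaluation
#'
#' @param x A `seg_eval` object.
#' @param ... Unused.
#' @return The one-row metrics tibble.
#' @method glance seg_eval
#' @export
glance.seg_eval <- function(x, ...) {
  x$metrics
}

#' Plot a segmentation evaluation as a confusion-matrix heatmap
#'
#' Tiles show pixel counts and column-normalised rates (per-class
#' precision on the diagonal).
#'
#' @param object A `seg_eval` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot seg_eval
#' @export
autoplot.seg_eval <- function(object, ...) {
  cm <- object$confusion
  cn <- column_normalize(cm)
  df <- tidyr::expand_grid(
    true = rownames(cm), predicted = colnames(cm)
  )
  df$count <- as.vector(t(unclass(cm)))
  df$rate <- as.vector(t(unclass(cn)))
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true, fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%s\n%.1f%%", format(.data$count, big.mark = ","),
                      100 * .data$rate)
    )) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8",
                                 limits = c(0, 1), name = "column rate") +
    ggplot2::scale_y_discrete(limits = rev(rownames(cm))) +
    ggplot2::labs(x = "predicted class", y = "true class") +
    ggplot2::theme_minimal()
}
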