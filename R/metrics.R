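#' Dice overlap coefficient
#'
#' `2 |X n Y| / (|X| + |Y|)` for two binary masks. When both masks are empty
#' the coefficient is defined as 1 (perfect agreement).
#'
#' @param pred,truth Binary arrays of identical shape.
#' @return Dice fraction in \[0, 1\].
#' @export
dice <- function(pred, truth) {
  assert_that(identical(dim(pred), dim(truth)),
              "prediction/truth shape mismatch")
  assert_that(is_binaryish(pred) && is_binaryish(truth),
              "dice inputs must be binary")
  s <- sum(pred) + sum(truth)
  if (s == 0) return(1)
  2 * sum(pred * truth) / s
}

#' Data-set-level Dice
#'
#' Pools the voxels of all subjects into one prediction set and one truth
#' set before applying the Dice formula (this is not the mean of per-subject
#' scores).
#'
#' @param preds,truths Aligned lists of binary arrays.
#' @return Dice in percent.
#' @export
dice_dataset <- function(preds, truths) {
  assert_that(length(preds) > 0, "empty evaluation set")
  assert_that(length(preds) == length(truths),
              "prediction/truth list length mismatch")
  inter <- 0
  total <- 0
  for (i in seq_along(preds)) {
    assert_that(identical(dim(preds[[i]]), dim(truths[[i]])),
                "prediction/truth shape mismatch")
    assert_that(is_binaryish(preds[[i]]) && is_binaryish(truths[[i]]),
                "dice inputs must be binary")
    inter <- inter + sum(preds[[i]] * truths[[i]])
    total <- total + sum(preds[[i]]) + sum(truths[[i]])
  }
  if (total == 0) return(100)
  100 * 2 * inter / total
}

#' Subject-wise Dice summary
#'
#' @param preds,truths Aligned lists of binary arrays.
#' @return List with `mean`, `std` (population standard deviation) and
#'   `per_subject`, all in percent.
#' @export
dice_subjects <- function(preds, truths) {
  assert_that(length(preds) > 0, "empty evaluation set")
  assert_that(length(preds) == length(truths),
              "prediction/truth list length mismatch")
  per <- vapply(seq_along(preds),
                function(i) 100 * dice(preds[[i]], truths[[i]]), numeric(1))
  n <- length(per)
  list(mean = mean(per), std = sqrt(mean((per - mean(per))^2)),
       per_subject = per)
}

#' Precision-recall curve
#'
#' Sweeps thresholds over the unique scores in descending order (prediction
#' positive when `score >= threshold`).
#'
#' @param scores Numeric vector of anomaly scores.
#' @param labels Binary truth vector (must contain at least one positive).
#' @return Tibble with `threshold`, `precision`, `recall`, ordered by
#'   increasing recall.
#' @export
pr_curve <- function(scores, labels) {
  assert_that(length(scores) == length(labels), "scores/labels mismatch")
  assert_that(all(labels %in% c(0, 1)), "labels must be binary")
  n_pos <- sum(labels)
  assert_that(n_pos > 0, "labels contain no positive")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  tp <- cumsum(l)
  fp <- cumsum(1 - l)
  # keep only the last index of each tied score block
  last <- which(diff(s) != 0)
  last <- c(last, length(s))
  tibble::tibble(threshold = s[last],
                 precision = tp[last] / (tp[last] + fp[last]),
                 recall = tp[last] / n_pos)
}

#' Area under the precision-recall curve
#'
#' Step-wise average precision: `sum((R_k - R_{k-1}) * P_k)` over the curve
#' points (no linear interpolation in precision-recall space).
#'
#' @param curve A tibble from [pr_curve()], or a numeric score vector (then
#'   `labels` must be given).
#' @param labels Binary truth vector when `curve` is a score vector.
#' @return Area in percent.
#' @export
auprc <- function(curve, labels = NULL) {
  if (!is.null(labels)) curve <- pr_curve(curve, labels)
  r <- c(0, curve$recall)
  100 * sum(diff(r) * curve$precision)
}

#' Label axial slices by annotation
#'
#' A slice is abnormal (label 1) iff it contains at least one annotated
#' voxel.
#'
#' @param annotation Binary 3D annotation mask.
#' @param axis Slicing axis (default 3 = axial).
#' @return Integer vector of 0/1 labels, one per slice.
#' @export
label_slices <- function(annotation, axis = 3) {
  annotation <- as_binary_array(annotation, "annotation")
  counts <- apply(annotation, axis, sum)
  as.integer(counts > 0)
}

#' Score axial slices by reconstruction error
#'
#' Per-slice mean absolute input-reconstruction difference over in-mask
#' pixels (0 for slices without mask pixels).
#'
#' @param x Input volume.
#' @param x_hat Reconstruction of identical shape.
#' @param mask Binary brain mask.
#' @param axis Slicing axis (default 3 = axial).
#' @param aggregate `"mean"` (over in-mask pixels; default, independent of
#'   the brain cross-section size) or `"sum"`.
#' @return Numeric vector of slice scores.
#' @export
score_slices <- function(x, x_hat, mask, axis = 3, aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  assert_that(identical(dim(x), dim(x_hat)) && identical(dim(x), dim(mask)),
              "shape mismatch")
  res <- abs(x - x_hat) * mask
  tot <- apply(res, axis, sum)
  if (aggregate == "sum") return(tot)
  npix <- apply(mask, axis, sum)
  ifelse(npix > 0, tot / pmax(npix, 1), 0)
}

#' Relative performance improvement
#'
#' `100 * (improved - baseline) / baseline`, rounded to 2 decimals.
#'
#' @param baseline,improved Scores in percent (baseline must be > 0).
#' @return Relative improvement in percent.
#' @export
relative_improvement <- function(baseline, improved) {
  assert_that(baseline > 0, "baseline must be > 0")
  round(100 * (improved - baseline) / baseline, 2)
}

#' Evaluate segmentations and residuals on a test set
#'
#' Computes the data-set-level Dice, the subject-wise Dice summary, the
#' pooled voxel-level area under the precision-recall curve and (when masks
#' are given) the slice-wise detection area under the curve.
#'
#' @param preds List of binary segmentations.
#' @param truths List of aligned binary annotations.
#' @param residuals Optional list of residual maps (voxel scores for the
#'   precision-recall analysis).
#' @param volumes,reconstructions,masks Optional aligned lists enabling
#'   slice-wise detection scoring.
#' @return A `metrics_report` tibble with one row: `dice_dataset`,
#'   `dice_subject_mean`, `dice_subject_std`, `auprc_voxel`, `auprc_slice`,
#'   `n_subjects` (percent scales).
#' @export
evaluate_segmentation <- function(preds, truths, residuals = NULL,
                                  volumes = NULL, reconstructions = NULL,
                                  masks = NULL) {
  ds <- dice_dataset(preds, truths)
  subj <- dice_subjects(preds, truths)
  auprc_voxel <- NA_real_
  if (!is.null(residuals)) {
    scores <- unlist(lapply(residuals, as.vector))
    labels <- unlist(lapply(truths, as.vector))
    auprc_voxel <- auprc(scores, labels)
  }
  auprc_slice <- NA_real_
  if (!is.null(volumes) && !is.null(reconstructions) && !is.null(masks)) {
    slice_scores <- unlist(lapply(seq_along(volumes), function(i) {
      score_slices(volumes[[i]], reconstructions[[i]], masks[[i]])
    }))
    slice_labels <- unlist(lapply(truths, label_slices))
    auprc_slice <- auprc(slice_scores, slice_labels)
  }
  out <- tibble::tibble(dice_dataset = ds, dice_subject_mean = subj$mean,
                        dice_subject_std = subj$std,
                        auprc_voxel = auprc_voxel,
                        auprc_slice = auprc_slice,
                        n_subjects = length(preds))
  class(out) <- c("metrics_report", class(out))
  attr(out, "per_subject") <- subj$per_subject
  out
}

#' @export
tidy.metrics_report <- function(x, ...) {
  tibble::tibble(subject = seq_along(attr(x, "per_subject")),
                 dice = attr(x, "per_subject"))
}

#' @export
glance.metrics_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Plot a precision-recall curve
#'
#' @param curve Tibble from [pr_curve()].
#' @return A ggplot object.
#' @export
plot_pr_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "recall", y = "precision",
                  title = sprintf("Precision-recall curve (AUPRC %.1f%%)",
                                  auprc(curve))) +
    ggplot2::theme_minimal()
}
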