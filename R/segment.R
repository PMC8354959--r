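#' Voxel-wise residual map
#'
#' Element-wise absolute difference between an input and its reconstruction.
#'
#' @param x Input array.
#' @param x_hat Reconstruction of identical shape.
#' @return Non-negative array of the same shape.
#' @export
residual_map <- function(x, x_hat) {
  assert_that(identical(dim(x), dim(x_hat)),
              "input/reconstruction shape mismatch")
  abs(x - x_hat)
}

#' Post-process a residual map
#'
#' Multiplies the residual by a slightly eroded brain mask (suppressing
#' errors at sharp mask boundaries) and applies a median filter to remove
#' small outliers. Voxels outside the eroded mask are exactly zero.
#'
#' @param res Residual map (non-negative array).
#' @param mask Binary brain mask aligned to `res`.
#' @param erosion_radius Erosion passes of the face-connected structuring
#'   element (default 1).
#' @param median_size Odd median window per axis (default 3; 1 = no filter).
#' @return Post-processed residual map.
#' @export
postprocess_residual <- function(res, mask, erosion_radius = 1,
                                 median_size = 3) {
  mask <- as_binary_array(mask)
  assert_that(identical(dim(res), dim(mask)), "residual/mask shape mismatch")
  assert_that(median_size %% 2 == 1, "median_size must be odd")
  eroded <- erode_mask(mask, erosion_radius)
  if (sum(eroded) == 0) {
    rlang::abort("erosion removed the entire brain mask",
                 class = c("erasevae_degenerate_error", "erasevae_error"))
  }
  out <- res * eroded
  if (median_size > 1) {
    out <- array(nd_median_filter(as.vector(out), as.integer(dim(out)),
                                  as.integer(median_size)),
                 dim = dim(out))
    out <- out * eroded
  }
  out
}

#' Binarize a residual map
#'
#' @param res Residual map.
#' @param threshold Threshold in \[0, 1\]; voxels with residual strictly
#'   greater are positive.
#' @return Binary array.
#' @export
binarize <- function(res, threshold) {
  assert_that(threshold >= 0 && threshold <= 1,
              "threshold must be in [0, 1]")
  (res > threshold) * 1
}

#' Greedy bisection search for the binarization threshold
#'
#' Starting from the interval \[0, 1\], each iteration scores the thresholds
#' at the lower and upper quartile of the current interval by the Dice
#' overlap on the annotated calibration set, then keeps the half of the
#' interval on the side of the better probe (ties keep the lower half).
#' After `iterations` halvings, the probed threshold with the best Dice is
#' returned.
#'
#' @param residuals List of post-processed residual maps.
#' @param annotations List of aligned binary ground-truth masks.
#' @param iterations Number of halvings (default 10).
#' @param score `"pooled"` scores probes by the data-set-level Dice over all
#'   voxels; `"mean"` by the mean subject-wise Dice.
#' @return An object of class `threshold_search`: `best_threshold`,
#'   `best_dice`, `trace` (tibble: iteration, threshold, dice), `interval`.
#' @export
greedy_threshold_search <- function(residuals, annotations, iterations = 10,
                                    score = c("pooled", "mean")) {
  score <- match.arg(score)
  assert_that(length(residuals) > 0, "empty calibration set")
  assert_that(length(residuals) == length(annotations),
              "residuals/annotations length mismatch")
  score_fn <- function(t) {
    preds <- lapply(residuals, binarize, threshold = t)
    if (score == "pooled") {
      dice_dataset(preds, annotations) / 100
    } else {
      dice_subjects(preds, annotations)$mean / 100
    }
  }
  a <- 0
  b <- 1
  trace <- vector("list", iterations)
  for (it in seq_len(iterations)) {
    t_lo <- a + 0.25 * (b - a)
    t_hi <- a + 0.75 * (b - a)
    d_lo <- score_fn(t_lo)
    d_hi <- score_fn(t_hi)
    trace[[it]] <- tibble::tibble(iteration = it,
                                  threshold = c(t_lo, t_hi),
                                  dice = c(d_lo, d_hi))
    if (d_lo >= d_hi) b <- (a + b) / 2 else a <- (a + b) / 2
  }
  trace <- dplyr::bind_rows(trace)
  best <- which.max(trace$dice)
  structure(list(best_threshold = trace$threshold[best],
                 best_dice = trace$dice[best], trace = trace,
                 interval = c(a, b)),
            class = "threshold_search")
}

#' @export
print.threshold_search <- function(x, ...) {
  cat(sprintf(
    "<threshold_search> best threshold %.6f (Dice %.4f), final interval [%.6f, %.6f]\n",
    x$best_threshold, x$best_dice, x$interval[1], x$interval[2]))
  invisible(x)
}

#' @export
tidy.threshold_search <- function(x, ...) x$trace

#' @export
glance.threshold_search <- function(x, ...) {
  tibble::tibble(best_threshold = x$best_threshold, best_dice = x$best_dice,
                 iterations = max(x$trace$iteration),
                 interval_lo = x$interval[1], interval_hi = x$interval[2])
}

#' @export
autoplot.threshold_search <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$threshold, y = .data$dice,
                               colour = factor(.data$iteration))) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "threshold", y = "Dice", colour = "iteration",
                  title = "Greedy threshold search probes") +
    ggplot2::theme_minimal()
}

#' Reconstruct a volume with a 2D or 3D model
#'
#' Rank-3 models reconstruct the volume directly; rank-2 models reconstruct
#' each axial slice and restack. Deterministic (posterior-mean decoding).
#'
#' @param model A `vae_model`.
#' @param vol 3D array of the configured extent.
#' @return Reconstructed 3D array.
#' @export
reconstruct_volume <- function(model, vol) {
  if (model$cfg$rank == 3) return(reconstruct(model, vol))
  slices <- extract_slices(vol, axis = 3)
  stack_slices(lapply(slices, function(s) reconstruct(model, s)), axis = 3)
}

#' Segment a volume with a trained model
#'
#' Full chain: reconstruct (posterior mean), residual map, post-processing,
#' binarization at the calibrated threshold.
#'
#' @param model A `vae_model` (or `vae_train`, whose best model is used).
#' @param vol 3D volume in \[0, 1\].
#' @param mask Binary brain mask.
#' @param threshold Binarization threshold (from
#'   [greedy_threshold_search()]).
#' @param erosion_radius,median_size Post-processing parameters.
#' @return List with `segmentation` (binary array) and `residual`
#'   (post-processed residual map).
#' @export
segment_volume <- function(model, vol, mask, threshold, erosion_radius = 1,
                           median_size = 3) {
  if (inherits(model, "vae_train")) model <- model$model
  x_hat <- reconstruct_volume(model, vol)
  res <- postprocess_residual(residual_map(vol, x_hat), mask,
                              erosion_radius, median_size)
  list(segmentation = binarize(res, threshold), residual = res)
}
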