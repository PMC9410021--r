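#' Per-pixel classification rate
#'
#' Fraction of ground-truth spine pixels (`truth > 0`) whose predicted
#' vertebra id equals the truth; background pixels are ignored entirely.
#'
#' @param pred,truth integer label grids of the same shape.
#' @return Fraction in `[0, 1]`.
#' @export
pixel_classification_rate <- function(pred, truth) {
  assert_that(identical(dim(pred), dim(truth)), "label grid shapes differ")
  spine <- truth > 0
  assert_that(any(spine), "truth contains no spine pixels: rate undefined")
  mean(pred[spine] == truth[spine])
}

#' Identification rate at a distance threshold
#'
#' A ground-truth vertebra counts as correctly identified when the predicted
#' centroid *of the same id* lies no more than `threshold_mm` (default 20 mm,
#' the standard reference distance) from the true centroid. Matching is by id
#' only — a label-swapped prediction is an error even if some centroid is
#' nearby. Missing predictions count as incorrect.
#'
#' @param pred,truth [centroid_set()]s; `truth` must be nonempty.
#' @param threshold_mm inclusive distance threshold in mm.
#' @return List with `rate` and the per-vertebra logical vector `correct`
#'   (named by truth ids).
#' @export
id_rate <- function(pred, truth, threshold_mm = 20) {
  assert_that(nrow(truth) > 0L, "truth centroid set is empty")
  correct <- vapply(seq_len(nrow(truth)), function(r) {
    i <- match(truth$id[r], pred$id)
    if (is.na(i)) return(FALSE)
    d <- sqrt(sum((centroid_position(pred, truth$id[r]) -
                     unlist(truth[r, c("x_mm", "y_mm", "z_mm")]))^2))
    d <= threshold_mm
  }, logical(1))
  names(correct) <- vertebra_names()[truth$id]
  list(rate = mean(correct), correct = correct)
}

#' Centroid distance statistics
#'
#' Mean and population standard deviation (divide by n) of the Euclidean
#' distances between predicted and true centroids, over the vertebra ids
#' present in both sets.
#'
#' @param pred,truth [centroid_set()]s sharing at least one id.
#' @return List with `mean_mm`, `std_mm`, `n`.
#' @export
distance_stats <- function(pred, truth) {
  common <- intersect(pred$id, truth$id)
  assert_that(length(common) > 0L, "no vertebra id present in both centroid sets")
  d <- vapply(common, function(k)
    sqrt(sum((centroid_position(pred, k) - centroid_position(truth, k))^2)),
    numeric(1))
  list(mean_mm = mean(d), std_mm = sqrt(mean((d - mean(d))^2)), n = length(d))
}

#' Segmentation overlap metrics
#'
#' Overall metrics micro-average the two classes (spine and background) over
#' all voxels; the vertebrae-only metrics score the spine class alone, the
#' view in which detection quality actually differs.
#'
#' @param pred,truth [binary_mask()]s (or 0/1 arrays) of the same shape.
#' @return List with elements `overall` (accuracy, recall, iou, dice) and
#'   `vertebrae` (recall, iou, dice).
#' @export
segmentation_metrics <- function(pred, truth) {
  p <- if (inherits(pred, "binary_mask")) pred$data else pred
  t <- if (inherits(truth, "binary_mask")) truth$data else truth
  assert_that(identical(dim(p), dim(t)), "mask shapes differ")
  assert_that(any(t > 0), "truth mask is empty: vertebrae metrics undefined")
  tp <- sum(p == 1 & t == 1); fp <- sum(p == 1 & t == 0)
  fn <- sum(p == 0 & t == 1); tn <- sum(p == 0 & t == 0)
  agree <- tp + tn; n <- length(p)
  list(overall = list(accuracy = agree / n,
                      recall = agree / n,
                      iou = agree / (n + (fp + fn)),
                      dice = 2 * agree / (2 * agree + 2 * (fp + fn))),
       vertebrae = list(recall = tp / (tp + fn),
                        iou = tp / (tp + fp + fn),
                        dice = 2 * tp / (2 * tp + fp + fn)))
}

#' Spine region of a vertebra id
#'
#' @param vertebra_id integer id(s) in 1..26.
#' @return `"cervical"` (1-7), `"thoracic"` (8-19), `"lumbar"` (20-24) or
#'   `"sacral"` (25-26).
#' @export
region_of <- function(vertebra_id) {
  vertebra_id <- as.integer(vertebra_id)
  assert_that(all(!is.na(vertebra_id) & vertebra_id >= 1L & vertebra_id <= 26L),
              "vertebra id must lie in 1..26")
  cut(vertebra_id, breaks = c(0, 7, 19, 24, 26),
      labels = c("cervical", "thoracic", "lumbar", "sacral")) |> as.character()
}

#' Full evaluation report for one scan
#'
#' @param pred_dense,truth_dense integer label grids.
#' @param pred_centroids,truth_centroids [centroid_set()]s.
#' @param threshold_mm identification threshold, default 20 mm.
#' @return A list of class `eval_report`: `pixel_rate`, `id_rate`,
#'   `mean_dist_mm`, `std_dist_mm`, `seg`, `region_breakdown`.
#' @export
eval_report <- function(pred_dense, truth_dense, pred_centroids,
                        truth_centroids, threshold_mm = 20) {
  idr <- id_rate(pred_centroids, truth_centroids, threshold_mm)
  ds <- if (length(intersect(pred_centroids$id, truth_centroids$id)) > 0L)
    distance_stats(pred_centroids, truth_centroids)
  else list(mean_mm = NA_real_, std_mm = NA_real_, n = 0L)
  regions <- region_of(truth_centroids$id)
  breakdown <- lapply(split(idr$correct, regions), mean)
  structure(list(pixel_rate = pixel_classification_rate(pred_dense, truth_dense),
                 id_rate = idr$rate,
                 mean_dist_mm = ds$mean_mm, std_dist_mm = ds$std_mm,
                 seg = segmentation_metrics(array(as.integer(pred_dense > 0), dim(pred_dense)),
                                            array(as.integer(truth_dense > 0), dim(truth_dense))),
                 region_breakdown = breakdown,
                 per_vertebra = idr$correct),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Pixel classification rate (spine only): %.1f%%\n", 100 * x$pixel_rate))
  cat(sprintf("Identification rate (20 mm rule):       %.1f%%\n", 100 * x$id_rate))
  cat(sprintf("Centroid distance: mean %.1f mm, std %.1f mm\n",
              x$mean_dist_mm, x$std_dist_mm))
  cat(sprintf("Spine IoU (vertebrae-only): %.1f%%\n", 100 * x$seg$vertebrae$iou))
  invisible(x)
}
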