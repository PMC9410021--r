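#' Patch specification for the detection stage
#'
#' @param patch_shape 3D patch size in voxels; default `c(80, 80, 96)`.
#' @param patches_per_scan_train random patches drawn per training scan.
#' @param min_spine_patches minimum number of those that must contain spine
#'   voxels (default 8 of 10).
#' @return A list of class `detection_patch_spec`.
#' @export
detection_patch_spec <- function(patch_shape = c(80L, 80L, 96L),
                                 patches_per_scan_train = 10L,
                                 min_spine_patches = 8L) {
  assert_that(all(patch_shape >= 1), "patch shape must be positive")
  assert_that(min_spine_patches <= patches_per_scan_train,
              "min_spine_patches cannot exceed patches_per_scan_train")
  structure(list(patch_shape = as.integer(patch_shape),
                 patches_per_scan_train = as.integer(patches_per_scan_train),
                 min_spine_patches = as.integer(min_spine_patches)),
            class = "detection_patch_spec")
}

#' Training configuration for the detection stage
#'
#' Defaults follow the reference training recipe: Adam at learning rate 1e-3,
#' batch size 16, 70 epochs, binary cross-entropy weighted 1.0 for spine and
#' 0.1 for background voxels (the class weighting that keeps the spine one
#' strongly-predicted component).
#'
#' @param learning_rate,batch_size,epochs Adam optimizer settings.
#' @param loss_weight_spine,loss_weight_background BCE class weights.
#' @param hidden hidden width of the default per-voxel network.
#' @param seed RNG seed for init and patch shuffling.
#' @return A list of class `detection_train_config`.
#' @export
detection_train_config <- function(learning_rate = 1e-3, batch_size = 16L,
                                   epochs = 70L, loss_weight_spine = 1.0,
                                   loss_weight_background = 0.1,
                                   hidden = 8L, seed = 1L) {
  assert_that(learning_rate > 0 && batch_size >= 1 && epochs >= 1,
              "learning rate, batch size and epochs must be positive")
  assert_that(loss_weight_spine > 0 && loss_weight_background > 0,
              "BCE class weights must be > 0")
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), loss_weight_spine = loss_weight_spine,
                 loss_weight_background = loss_weight_background,
                 hidden = as.integer(hidden), seed = as.integer(seed)),
            class = "detection_train_config")
}

# Per-voxel image features for the detection network: raw and box-smoothed
# intensity (kHU) and a soft bone indicator around the 180 HU bone threshold.
detection_features <- function(patch) {
  cbind(as.vector(patch) / 1000,
        as.vector(box_smooth(patch, 1L)) / 1000,
        as.vector(box_smooth(patch, 2L)) / 1000,
        plogis((as.vector(patch) - 180) / 40))
}

# sample one origin such that the patch [origin, origin+patch-1] covers `vox`
origin_covering <- function(vox, patch, shape) {
  lo <- pmax(vox - patch + 1L, 1L)
  hi <- pmin(vox, pmax(shape - patch + 1L, 1L))
  hi <- pmax(hi, lo)
  vapply(1:3, function(ax) lo[ax] + sample.int(hi[ax] - lo[ax] + 1L, 1L) - 1L,
         integer(1))
}

#' Extract detection patches from a scan
#'
#' Training mode draws `patches_per_scan_train` random patches, at least
#' `min_spine_patches` of which contain spine voxels (dense labels are
#' required: the detection stage trains on labeled source data only). Test
#' mode tiles the whole grid with non-overlapping patches regardless of the
#' spine position, zero-padding the last tile.
#'
#' @param vol a [ct_volume()].
#' @param dense integer label array (required in train mode; binarized to
#'   spine/background targets).
#' @param spec a [detection_patch_spec()].
#' @param mode `"train"` or `"test"`.
#' @param seed RNG seed for train-mode sampling.
#' @return List of elements `list(patch, labels, origin)`; `labels` is `NULL`
#'   when `dense` is absent (test mode).
#' @export
extract_detection_patches <- function(vol, dense = NULL,
                                      spec = detection_patch_spec(),
                                      mode = c("train", "test"), seed = 1L) {
  mode <- match.arg(mode)
  shape <- dim(vol$data)
  ps <- spec$patch_shape
  grab <- function(origin) {
    list(patch = extract_patch(vol$data, origin, ps,
                               pad_value = min(vol$data)),
         labels = if (!is.null(dense))
           extract_patch(dense, origin, ps, pad_value = 0L) > 0L,
         origin = origin)
  }
  if (mode == "test") {
    origins <- tile_origins(shape, ps)
    return(lapply(seq_len(nrow(origins)), function(r) grab(origins[r, ])))
  }
  assert_that(!is.null(dense),
              "train mode requires dense labels: the detection stage is trained on labeled (source) scans only")
  spine_vox <- which(dense > 0L, arr.ind = TRUE)
  assert_that(nrow(spine_vox) > 0L, "no spine voxels in the labels")
  max_origin <- pmax(shape - ps + 1L, 1L)
  with_seed(seed, {
    n <- spec$patches_per_scan_train
    out <- vector("list", n)
    for (i in seq_len(n)) {
      origin <- if (i <= spec$min_spine_patches) {
        origin_covering(spine_vox[sample.int(nrow(spine_vox), 1L), ], ps, shape)
      } else {
        vapply(1:3, function(ax) sample.int(max_origin[ax], 1L), integer(1))
      }
      out[[i]] <- grab(origin)
    }
    out
  })
}

#' Class-weighted binary cross-entropy
#'
#' Mean over voxels of `w(target) * (-t*log(p) - (1-t)*log(1-p))` with
#' `w(1) = w_spine`, `w(0) = w_bg`. Predictions are clamped to
#' `[eps, 1-eps]` before taking logs.
#'
#' @param pred probabilities in (0, 1).
#' @param target 0/1 grid of the same shape.
#' @param w_spine,w_bg class weights.
#' @param eps clamping constant.
#' @return Scalar loss.
#' @export
weighted_bce <- function(pred, target, w_spine = 1.0, w_bg = 0.1, eps = 1e-7) {
  assert_that(length(pred) == length(target), "prediction/target shapes differ")
  p <- pmin(pmax(as.numeric(pred), eps), 1 - eps)
  t <- as.numeric(target)
  w <- ifelse(t == 1, w_spine, w_bg)
  mean(w * (-t * log(p) - (1 - t) * log(1 - p)))
}

#' Train the spine detector
#'
#' Fits a per-voxel binary segmenter (by default a small MLP on local
#' intensity features) by minimizing the class-weighted BCE with Adam. The
#' training loop is deterministic given `config$seed`.
#'
#' @param samples patch list from [extract_detection_patches()] (train mode),
#'   possibly concatenated over several scans.
#' @param config a [detection_train_config()].
#' @param model optional model to warm-start from; defaults to a fresh
#'   `pixel_mlp`.
#' @return An object of class `spine_detector` with elements `model`,
#'   `config` and `epoch_loss` (mean training loss per epoch).
#' @export
fit_spine_detector <- function(samples, config = detection_train_config(),
                               model = NULL) {
  assert_that(length(samples) > 0L, "no training samples given")
  assert_that(all(vapply(samples, function(s) !is.null(s$labels), logical(1))),
              "all detection training patches need labels")
  feats <- lapply(samples, function(s) detection_features(s$patch))
  targs <- lapply(samples, function(s) as.numeric(s$labels))
  model <- model %||% pixel_mlp(ncol(feats[[1]]), hidden = config$hidden,
                                output = "sigmoid", seed = config$seed)
  state <- adam_init(model$params)
  epoch_loss <- numeric(config$epochs)
  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(length(samples))
      losses <- numeric(0)
      for (chunk in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        grads <- NULL
        for (i in chunk) {
          fw <- mlp_forward(model, feats[[i]])
          t <- targs[[i]]
          w <- ifelse(t == 1, config$loss_weight_spine, config$loss_weight_background)
          losses <- c(losses, weighted_bce(fw$y, t, config$loss_weight_spine,
                                           config$loss_weight_background))
          d_pre <- w * (fw$y - t) / length(t)      # BCE + sigmoid
          grads <- add_grads(grads, mlp_backward(model, fw$cache, d_pre))
        }
        grads <- scale_grads(grads, 1 / length(chunk))
        upd <- adam_step(model$params, grads, state, config$learning_rate)
        model$params <- upd$params
        state <- upd$state
      }
      epoch_loss[ep] <- mean(losses)
    }
  })
  structure(list(model = model, config = config, epoch_loss = epoch_loss),
            class = "spine_detector")
}

#' @export
print.spine_detector <- function(x, ...) {
  cat(sprintf("Spine detector: per-voxel MLP (%d hidden), %d epochs, final loss %.4g\n",
              x$model$hidden, length(x$epoch_loss), tail(x$epoch_loss, 1)))
  invisible(x)
}

#' Reassemble patch predictions into a full-grid binary mask
#'
#' Tiles must cover the zero-padded grid exactly (the origins produced by the
#' test-mode tiling); padded overhang is cropped. Probabilities of exactly
#' `threshold` are labeled spine (documented tie rule).
#'
#' @param tiles list of numeric patch arrays (probabilities or labels).
#' @param origins matrix of the tiles' 1-based origins.
#' @param full_shape dimensions of the original grid.
#' @param spacing voxel spacing for the returned mask.
#' @param threshold binarization threshold, default 0.5.
#' @return A [binary_mask()] over `full_shape`.
#' @export
assemble_prediction <- function(tiles, origins, full_shape, spacing = c(1, 1, 1),
                                threshold = 0.5) {
  patch <- dim(tiles[[1]])
  expected <- tile_origins(full_shape, patch)
  have <- apply(origins, 1L, paste, collapse = ",")
  for (r in seq_len(nrow(expected))) {
    key <- paste(expected[r, ], collapse = ",")
    assert_that(key %in% have, "missing tile at origin (", key, ")")
  }
  padded <- ceiling(full_shape / patch) * patch
  acc <- array(0, padded)
  for (i in seq_along(tiles)) {
    o <- origins[i, ]
    acc[o[1]:(o[1] + patch[1] - 1), o[2]:(o[2] + patch[2] - 1),
        o[3]:(o[3] + patch[3] - 1)] <- tiles[[i]]
  }
  acc <- acc[seq_len(full_shape[1]), seq_len(full_shape[2]), seq_len(full_shape[3]),
             drop = FALSE]
  binary_mask(array(as.integer(acc >= threshold), full_shape), spacing)
}

#' Predict a spine mask for a whole scan
#'
#' @param object a fitted `spine_detector`.
#' @param vol a [ct_volume()].
#' @param spec a [detection_patch_spec()] (its `patch_shape` drives tiling).
#' @param threshold binarization threshold.
#' @param postprocess keep only the largest connected component (default).
#' @param ... unused.
#' @return A [binary_mask()].
#' @export
predict.spine_detector <- function(object, vol, spec = detection_patch_spec(),
                                   threshold = 0.5, postprocess = TRUE, ...) {
  patches <- extract_detection_patches(vol, dense = NULL, spec = spec, mode = "test")
  tiles <- lapply(patches, function(p) {
    fw <- mlp_forward(object$model, detection_features(p$patch))
    array(fw$y, dim(p$patch))
  })
  origins <- do.call(rbind, lapply(patches, `[[`, "origin"))
  mask <- assemble_prediction(tiles, origins, dim(vol$data), vol$spacing, threshold)
  if (postprocess) mask <- postprocess_largest_component(mask)
  mask
}

#' Keep only the largest connected component of a binary mask
#'
#' Connected-component analysis of the 3D prediction: the spine, consisting
#' of by far the most voxels, is retained as the biggest component while
#' smaller components (bed, cables, speckle) are discarded as artefacts.
#' Ties go to the component whose first voxel has the smaller column-major
#' position. Never adds voxels; an empty mask is returned unchanged with a
#' warning.
#'
#' @param mask a [binary_mask()].
#' @param connectivity `1` for face neighbours (6-connectivity) or `3` for
#'   the full 26-neighbourhood (default: vertebrae touching diagonally stay
#'   one component).
#' @return A [binary_mask()] containing one component (or none).
#' @export
postprocess_largest_component <- function(mask, connectivity = 3L) {
  assert_that(inherits(mask, "binary_mask"), "mask must be a binary_mask")
  lab <- .cc_label(as.logical(mask$data), dim(mask$data), as.integer(connectivity))
  n <- attr(lab, "n_components")
  if (n == 0L) {
    warning("empty detection mask: nothing to post-process")
    return(mask)
  }
  counts <- tabulate(lab, nbins = n)
  keep <- which.max(counts)        # first maximum = smallest origin
  binary_mask(array(as.integer(lab == keep), dim(mask$data)), mask$spacing)
}
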