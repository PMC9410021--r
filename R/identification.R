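#' Patch specification for the identification stage
#'
#' @param patch_shape 3D patch size `(slabs, rows, cols)`; default
#'   `c(8, 80, 320)` — a thin sagittal slab with a wide craniocaudal field of
#'   view so several vertebrae are visible at once.
#' @param patches_per_scan_train random patches per training scan (300 at
#'   full scale).
#' @return A list of class `identification_patch_spec`.
#' @export
identification_patch_spec <- function(patch_shape = c(8L, 80L, 320L),
                                      patches_per_scan_train = 300L) {
  assert_that(all(patch_shape >= 1), "patch shape must be positive")
  structure(list(patch_shape = as.integer(patch_shape),
                 patches_per_scan_train = as.integer(patches_per_scan_train)),
            class = "identification_patch_spec")
}

#' Configuration for the 2-way identification training
#'
#' Defaults follow the reference recipe: Adam at 5e-4, batch size 32, 100
#' epochs, strict alternation between supervised source batches (L1 loss) and
#' unsupervised target batches (surrogate domain sanity loss).
#'
#' @param learning_rate,batch_size,epochs Adam settings.
#' @param n_labeled_target_scans number of labeled target scans mixed into
#'   the supervised stream (the semi-supervised arm); default 0.
#' @param uda_grad_scale step-size multiplier for the unsupervised (sanity
#'   loss) step. The counting-loss weights calibrate the four terms against
#'   each other, not against the supervised L1 subgradient: the order-check
#'   hinge accumulates up to `c1 * n_shift` subgradient per pixel while L1
#'   contributes 1, so the default `NULL` normalizes the target step by
#'   `1 / (c1 * n_shift)`.
#' @param hidden hidden width of the default per-pixel network.
#' @param seed RNG seed.
#' @return A list of class `two_way_train_config`.
#' @export
two_way_train_config <- function(learning_rate = 5e-4, batch_size = 32L,
                                 epochs = 100L, n_labeled_target_scans = 0L,
                                 uda_grad_scale = NULL, hidden = 24L, seed = 1L) {
  assert_that(learning_rate > 0 && batch_size >= 1 && epochs >= 1,
              "learning rate, batch size and epochs must be positive")
  assert_that(n_labeled_target_scans >= 0, "n_labeled_target_scans must be >= 0")
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 n_labeled_target_scans = as.integer(n_labeled_target_scans),
                 uda_grad_scale = uda_grad_scale,
                 hidden = as.integer(hidden), seed = as.integer(seed)),
            class = "two_way_train_config")
}

# Collapse the thin slab axis of a 3D identification patch onto the sagittal
# plane by maximum-intensity projection; labels take the central slab.
ident_project <- function(patch3d) {
  apply(patch3d, c(2, 3), max)
}

ident_project_labels <- function(labels3d) {
  labels3d[ceiling(dim(labels3d)[1] / 2), , ]
}

# Per-pixel features of a projected sagittal patch. Positions are
# scan-absolute mm (patch origin + pixel index), so the network can relate
# image position to vertebra id within a scan.
ident_features <- function(img2d, origin_rc = c(1L, 1L), spacing = c(1, 1)) {
  nr <- nrow(img2d); nc <- ncol(img2d)
  hu <- as.vector(img2d)
  bone <- plogis((hu - 180) / 40)
  row_mm <- rep((origin_rc[1] - 1 + seq_len(nr) - 1) * spacing[1], times = nc)
  col_mm <- rep((origin_rc[2] - 1 + seq_len(nc) - 1) * spacing[2], each = nr)
  cbind(hu / 1000,
        as.vector(box_smooth(img2d, 1L)) / 1000,
        bone,
        row_mm / 100,
        col_mm / 100,
        bone * col_mm / 100)
}

#' Extract identification patches from a scan
#'
#' With labels present, every training patch is guaranteed to contain at
#' least one vertebra pixel; without labels, patches are placed over the
#' detected spine (a detection mask is then required). Test mode tiles the
#' whole scan.
#'
#' @param vol a [ct_volume()].
#' @param dense integer label array, or `NULL` for unlabeled scans.
#' @param det_mask a [binary_mask()] used to locate the spine when no labels
#'   exist.
#' @param spec an [identification_patch_spec()].
#' @param mode `"train"` or `"test"`.
#' @param seed RNG seed for train-mode sampling.
#' @return List of `list(patch, labels, mask, origin)`; `labels`/`mask` are
#'   `NULL` when unavailable.
#' @export
extract_identification_patches <- function(vol, dense = NULL, det_mask = NULL,
                                           spec = identification_patch_spec(),
                                           mode = c("train", "test"), seed = 1L) {
  mode <- match.arg(mode)
  shape <- dim(vol$data)
  ps <- spec$patch_shape
  grab <- function(origin) {
    list(patch = extract_patch(vol$data, origin, ps, pad_value = min(vol$data)),
         labels = if (!is.null(dense)) extract_patch(dense, origin, ps, 0L),
         mask = if (!is.null(det_mask)) extract_patch(det_mask$data, origin, ps, 0L),
         origin = origin)
  }
  if (mode == "test") {
    origins <- tile_origins(shape, ps)
    return(lapply(seq_len(nrow(origins)), function(r) grab(origins[r, ])))
  }
  anchor <- if (!is.null(dense)) {
    which(dense > 0L, arr.ind = TRUE)
  } else {
    assert_that(!is.null(det_mask) && sum(det_mask$data) > 0L,
                "unlabeled scans need a non-empty detection mask; run the detection stage first")
    which(det_mask$data > 0L, arr.ind = TRUE)
  }
  assert_that(nrow(anchor) > 0L, "no spine voxels to anchor patches on")
  with_seed(seed, {
    lapply(seq_len(spec$patches_per_scan_train), function(i) {
      vox <- anchor[sample.int(nrow(anchor), 1L), ]
      grab(origin_covering(vox, ps, shape))
    })
  })
}

#' Supervised L1 loss of the identification stage
#'
#' Mean absolute difference between the continuous per-pixel prediction and
#' the integer dense labels (background target 0). Because predictions are
#' continuous vertebra values, the loss grows with the anatomical distance of
#' an error: predicting C3 for a C1 pixel costs twice as much as C2.
#'
#' @param pred continuous prediction grid.
#' @param dense_labels integer label grid of the same shape.
#' @return Scalar mean absolute error.
#' @export
l1_source_loss <- function(pred, dense_labels) {
  assert_that(length(pred) == length(dense_labels),
              "prediction/label shapes differ")
  mean(abs(as.numeric(pred) - as.numeric(dense_labels)))
}

# Precompute the per-patch tensors the training loop needs.
prep_source_patch <- function(p, spacing) {
  img <- ident_project(p$patch)
  list(X = ident_features(img, p$origin[2:3], spacing[2:3]),
       labels = as.numeric(ident_project_labels(p$labels)))
}

prep_target_patch <- function(p, spacing, weak_args = list()) {
  img <- ident_project(p$patch)
  mask2d <- apply(p$mask, c(2, 3), max)
  build_args <- weak_args[setdiff(names(weak_args), "filter")]
  wm <- do.call(build_weak_mask, c(list(img, mask2d), build_args))
  wm <- merge_enclosed(do.call(filter_components,
                               c(list(wm), weak_args$filter %||% list())))
  list(X = ident_features(img, p$origin[2:3], spacing[2:3]),
       mask = as.numeric(mask2d), dimg = dim(img), wm = wm)
}

#' Train the vertebra identifier with 2-way domain adaptation
#'
#' Alternates strictly between supervised mini-batches from the labeled
#' source stream (L1 loss on dense labels) and unsupervised mini-batches from
#' the target stream (surrogate domain sanity loss on the detection-masked
#' prediction). With an empty target stream the procedure reduces exactly to
#' the supervised baseline. Labeled target scans, when provided, join the
#' supervised stream unchanged.
#'
#' @param source_samples patches from [extract_identification_patches()] on
#'   labeled source scans (concatenated over scans).
#' @param target_samples patches on unlabeled target scans carrying their
#'   detection-mask crop, or `NULL`/empty for the no-adaptation baseline.
#' @param config a [two_way_train_config()].
#' @param dsl_cfg a [dsl_config()]; forced to surrogate mode internally.
#' @param rd reference distances (used by the s3 check when evaluating the
#'   loss; the surrogate gradient flows through s1, s2, s4).
#' @param spacing voxel spacing of the training scans, mm.
#' @param labeled_target_samples optional labeled target patches appended to
#'   the supervised stream (the semi-supervised arm).
#' @param weak_args optional list of arguments for [build_weak_mask()] /
#'   `filter` heuristics used on target patches.
#' @param model optional warm-start model.
#' @return An object of class `vertebra_identifier` with elements `model`,
#'   `config`, `dsl_cfg` and `log` (per-step domain-tagged losses).
#' @export
fit_vertebra_identifier <- function(source_samples, target_samples = NULL,
                                    config = two_way_train_config(),
                                    dsl_cfg = dsl_config(), rd = reference_distances(),
                                    spacing = c(1, 1, 1),
                                    labeled_target_samples = NULL,
                                    weak_args = list(), model = NULL) {
  assert_that(length(source_samples) > 0L, "source stream must not be empty")
  dsl_cfg$mode <- "surrogate"
  uda_scale <- config$uda_grad_scale %||% (1 / (dsl_cfg$c1 * dsl_cfg$n_shift))
  spacing <- check_spacing(spacing, 3L)
  src <- lapply(c(source_samples, labeled_target_samples),
                prep_source_patch, spacing = spacing)
  tgt <- lapply(target_samples %||% list(), prep_target_patch,
                spacing = spacing, weak_args = weak_args)
  model <- model %||% pixel_mlp(ncol(src[[1]]$X), hidden = config$hidden,
                                output = "linear", seed = config$seed)
  state <- adam_init(model$params)
  log <- list()
  source_step <- function(idx) {
    grads <- NULL; loss <- 0
    for (i in idx) {
      fw <- mlp_forward(model, src[[i]]$X)
      loss <- loss + l1_source_loss(fw$y, src[[i]]$labels)
      d_pre <- sign(fw$y - src[[i]]$labels) / length(fw$y)
      grads <- add_grads(grads, mlp_backward(model, fw$cache, d_pre))
    }
    list(grads = scale_grads(grads, 1 / length(idx)), loss = loss / length(idx))
  }
  target_step <- function(idx) {
    grads <- NULL; loss <- 0
    for (i in idx) {
      tp <- tgt[[i]]
      fw <- mlp_forward(model, tp$X)
      yhat <- matrix(fw$y * tp$mask, tp$dimg[1], tp$dimg[2])
      g <- dsl_surrogate_grad(yhat, tp$wm, dsl_cfg)
      loss <- loss + dsl_total(yhat, tp$wm, rd, dsl_cfg,
                               spacing = spacing[2:3])$total
      d_pre <- uda_scale * as.vector(g) * tp$mask
      grads <- add_grads(grads, mlp_backward(model, fw$cache, d_pre))
    }
    list(grads = scale_grads(grads, 1 / length(idx)), loss = loss / length(idx))
  }
  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      s_batches <- split(sample.int(length(src)),
                         ceiling(seq_len(length(src)) / config$batch_size))
      t_batches <- if (length(tgt)) split(sample.int(length(tgt)),
                                          ceiling(seq_len(length(tgt)) / config$batch_size))
                   else list()
      n_steps <- max(length(s_batches), length(t_batches)) * 2L
      si <- 0L; ti <- 0L
      for (step in seq_len(n_steps)) {
        from_source <- step %% 2L == 1L
        if (from_source && si < length(s_batches)) {
          si <- si + 1L
          res <- source_step(s_batches[[si]])
          dom <- "source"
        } else if (!from_source && ti < length(t_batches)) {
          ti <- ti + 1L
          res <- target_step(t_batches[[ti]])
          dom <- "target"
        } else next
        upd <- adam_step(model$params, res$grads, state, config$learning_rate)
        model$params <- upd$params
        state <- upd$state
        log[[length(log) + 1L]] <- data.frame(epoch = ep, domain = dom,
                                              loss = res$loss)
      }
    }
  })
  structure(list(model = model, config = config, dsl_cfg = dsl_cfg,
                 log = do.call(rbind, log)),
            class = "vertebra_identifier")
}

#' @export
print.vertebra_identifier <- function(x, ...) {
  doms <- table(x$log$domain)
  cat(sprintf("Vertebra identifier: per-pixel MLP (%d hidden), %d epochs (%s steps)\n",
              x$model$hidden, x$config$epochs,
              paste(sprintf("%s %d", names(doms), doms), collapse = ", ")))
  invisible(x)
}

#' Predict per-voxel vertebra labels for a whole scan
#'
#' The scan is tiled into identification patches; each tile's continuous
#' sagittal prediction is assembled over the grid, broadcast across its thin
#' slab axis, multiplied by the detection mask, rounded half-up and clipped
#' to 1..26 on spine voxels (a detected spine voxel cannot be background).
#'
#' @param object a fitted `vertebra_identifier`.
#' @param vol a [ct_volume()].
#' @param det_mask a [binary_mask()] from the detection stage.
#' @param spec an [identification_patch_spec()].
#' @param ... unused.
#' @return A list with `dense` (integer 3D label array), `continuous`
#'   (masked continuous 3D array) and `centroids` ([dense_to_sparse()] of the
#'   dense labels).
#' @export
predict.vertebra_identifier <- function(object, vol, det_mask,
                                        spec = identification_patch_spec(), ...) {
  assert_that(inherits(det_mask, "binary_mask"), "a detection mask is required")
  assert_that(identical(dim(det_mask$data), dim(vol$data)),
              "detection mask and volume shapes differ")
  shape <- dim(vol$data)
  ps <- spec$patch_shape
  patches <- extract_identification_patches(vol, spec = spec, mode = "test",
                                            det_mask = det_mask)
  padded <- ceiling(shape / ps) * ps
  cont <- array(0, padded)
  for (p in patches) {
    img <- ident_project(p$patch)
    fw <- mlp_forward(object$model, ident_features(img, p$origin[2:3],
                                                   vol$spacing[2:3]))
    pred2d <- matrix(fw$y, nrow(img), ncol(img))
    o <- p$origin
    cont[o[1]:(o[1] + ps[1] - 1), o[2]:(o[2] + ps[2] - 1), o[3]:(o[3] + ps[3] - 1)] <-
      rep(pred2d, each = ps[1])
  }
  cont <- cont[seq_len(shape[1]), seq_len(shape[2]), seq_len(shape[3]), drop = FALSE]
  cont <- cont * det_mask$data
  dense <- round_half_up(cont)
  dense[dense > 26] <- 26L
  dense[det_mask$data > 0 & dense < 1] <- 1L
  dense[det_mask$data == 0] <- 0L
  storage.mode(dense) <- "integer"
  list(dense = dense, continuous = cont,
       centroids = dense_to_sparse(dense, vol$spacing))
}
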