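#' Default pipeline configuration
#'
#' Nested configuration for the whole phantom -> detection -> weak mask ->
#' identification -> evaluation pipeline, YAML-serializable. The `dsl`,
#' `detection` and `identification` blocks default to the reference training
#' recipe (c1=20, c2=1, c3=1/40, c4=1/100, n_shift=30; detection lr 1e-3,
#' batch 16, 70 epochs; identification lr 5e-4, batch 32, 100 epochs); the
#' `demo` block holds the scaled-down study sizes used by [run_e2e_demo()].
#'
#' @return Nested named list of class `pipeline_config`.
#' @export
default_pipeline_config <- function() {
  structure(list(
    seed = 1L,
    phantom = list(n_vertebrae = 10L, first_vertebra_id = 8L,
                   shape = c(64L, 96L, 352L), spacing = c(1, 1, 1),
                   intensity_spine_hu = 400, intensity_background_hu = 40,
                   intensity_rod_hu = 150, noise_sd_hu = 20,
                   include_bed_artefact = TRUE, target_noise_sd_hu = 60,
                   target_intensity_scale = 0.85, target_max_crop_vox = 10L),
    detection = list(patch_shape = c(80L, 80L, 96L), patches_per_scan_train = 10L,
                     min_spine_patches = 8L, learning_rate = 1e-3,
                     batch_size = 16L, epochs = 70L, loss_weight_spine = 1.0,
                     loss_weight_background = 0.1, hidden = 8L,
                     threshold = 0.5, connectivity = 3L),
    identification = list(patch_shape = c(8L, 80L, 320L),
                          patches_per_scan_train = 300L,
                          learning_rate = 5e-4, batch_size = 32L, epochs = 100L,
                          n_labeled_target_scans = 0L, hidden = 24L),
    dsl = list(c1 = 20, c2 = 1, c3 = 1 / 40, c4 = 1 / 100, n_shift = 30L,
               strict_margin = 0, strict_ge = FALSE,
               spine_only_comparisons = TRUE, normalize_spine = FALSE,
               mode = "surrogate"),
    weakmask = list(hu_threshold = 180, felz_scale = 100, felz_sigma = 0.8,
                    felz_min_size = 40L, min_area = 25L, max_area = 5000L,
                    max_aspect_ratio = 3),
    evaluation = list(threshold_mm = 20),
    demo = list(n_source = 3L, n_target = 3L, n_test = 2L,
                n_vertebrae = 6L, first_vertebra_id = 8L,
                shape = c(24L, 48L, 176L),
                detection_patch = c(24L, 24L, 48L), detection_epochs = 30L,
                detection_batch = 4L, detection_lr = 1e-2,
                identification_patch = c(4L, 40L, 160L),
                patches_per_scan = 40L, identification_epochs = 12L,
                identification_batch = 8L, identification_lr = 3e-3)
  ), class = "pipeline_config")
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    assert_that(key %in% names(defaults), "unknown configuration key: ", full)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      assert_that(is.list(user[[key]]), "configuration block expected at: ", full)
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file, fills every omitted key with its default and rejects
#' unknown keys by name. An empty file yields the full default configuration.
#'
#' @param path YAML file; `NULL` for pure defaults.
#' @return A validated `pipeline_config`.
#' @export
load_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- merge_config(unclass(cfg), user)
  }
  # constraint validation via the block constructors
  dsl_args <- cfg$dsl[setdiff(names(cfg$dsl), character())]
  do.call(dsl_config, dsl_args)
  do.call(detection_train_config,
          cfg$detection[c("learning_rate", "batch_size", "epochs",
                          "loss_weight_spine", "loss_weight_background", "hidden")])
  do.call(two_way_train_config,
          cfg$identification[c("learning_rate", "batch_size", "epochs",
                               "n_labeled_target_scans", "hidden")])
  assert_that(cfg$evaluation$threshold_mm > 0, "threshold_mm must be > 0")
  structure(cfg, class = "pipeline_config")
}

demo_phantom_cfg <- function(cfg, domain, seed) {
  phantom_config(n_vertebrae = cfg$demo$n_vertebrae,
                 first_vertebra_id = cfg$demo$first_vertebra_id,
                 shape = cfg$demo$shape, spacing = cfg$phantom$spacing,
                 intensity_spine_hu = cfg$phantom$intensity_spine_hu,
                 intensity_background_hu = cfg$phantom$intensity_background_hu,
                 intensity_rod_hu = cfg$phantom$intensity_rod_hu,
                 noise_sd_hu = cfg$phantom$noise_sd_hu,
                 include_bed_artefact = cfg$phantom$include_bed_artefact,
                 domain = domain,
                 target_noise_sd_hu = cfg$phantom$target_noise_sd_hu,
                 target_intensity_scale = cfg$phantom$target_intensity_scale,
                 target_max_crop_vox = cfg$phantom$target_max_crop_vox,
                 seed = seed)
}

#' Scaled-down end-to-end domain adaptation study
#'
#' Generates seeded source and target phantoms, trains the detector on the
#' source domain, then trains the identifier twice — supervised-only and with
#' the 2-way sanity-loss adaptation — and optionally a third time with
#' `n_labeled_target` labeled target phantoms added to the supervised stream.
#' All models are evaluated on held-out target phantoms. The study asserts
#' orderings, not the magnitudes of the full-scale experiments, which require
#' real CT data and far longer training.
#'
#' @param cfg a `pipeline_config` (see [load_pipeline_config()]); the `demo`
#'   block controls the problem sizes.
#' @param seed master seed; every random choice in the study derives from it.
#' @param n_labeled_target labeled target phantoms for the semi-supervised
#'   arm; 0 skips that arm.
#' @return A list of class `uda_demo` with per-arm evaluation summaries
#'   (`without_uda`, `with_uda`, optionally `with_labels`), the per-scan
#'   reports, detection metrics with and without post-processing, and a
#'   `manifest` (seed, sizes) sufficient to reproduce the run.
#' @export
run_e2e_demo <- function(cfg = default_pipeline_config(), seed = 1L,
                         n_labeled_target = 0L) {
  d <- cfg$demo
  seed <- as.integer(seed)
  src_ph <- lapply(seq_len(d$n_source), function(i)
    generate_phantom(demo_phantom_cfg(cfg, "source", seed + i)))
  tgt_ph <- lapply(seq_len(d$n_target), function(i)
    generate_phantom(demo_phantom_cfg(cfg, "target", seed + 100L + i)))
  test_ph <- lapply(seq_len(d$n_test), function(i)
    generate_phantom(demo_phantom_cfg(cfg, "target", seed + 200L + i)))

  det_spec <- detection_patch_spec(d$detection_patch,
                                   cfg$detection$patches_per_scan_train,
                                   cfg$detection$min_spine_patches)
  det_cfg <- detection_train_config(d$detection_lr, d$detection_batch,
                                    d$detection_epochs,
                                    cfg$detection$loss_weight_spine,
                                    cfg$detection$loss_weight_background,
                                    cfg$detection$hidden, seed = seed)
  det_samples <- unlist(lapply(seq_along(src_ph), function(i)
    extract_detection_patches(src_ph[[i]]$volume, src_ph[[i]]$dense, det_spec,
                              "train", seed = seed + 10L * i)),
    recursive = FALSE)
  detector <- fit_spine_detector(det_samples, det_cfg)

  masks_raw <- lapply(c(tgt_ph, test_ph), function(ph)
    predict(detector, ph$volume, det_spec, postprocess = FALSE))
  masks <- lapply(masks_raw, postprocess_largest_component,
                  connectivity = cfg$detection$connectivity)
  tgt_masks <- masks[seq_along(tgt_ph)]
  test_masks <- masks[d$n_target + seq_along(test_ph)]

  det_eval <- lapply(seq_along(test_ph), function(i) {
    truth <- test_ph[[i]]$spine_mask
    list(raw = segmentation_metrics(masks_raw[[d$n_target + i]], truth),
         post = segmentation_metrics(test_masks[[i]], truth))
  })

  id_spec <- identification_patch_spec(d$identification_patch, d$patches_per_scan)
  id_cfg <- function(k) two_way_train_config(d$identification_lr,
                                             d$identification_batch,
                                             d$identification_epochs,
                                             n_labeled_target_scans = k,
                                             hidden = cfg$identification$hidden,
                                             seed = seed)
  dslc <- do.call(dsl_config, cfg$dsl)
  rd <- reference_distances()
  wargs <- list(hu_threshold = cfg$weakmask$hu_threshold,
                felz_scale = cfg$weakmask$felz_scale,
                felz_sigma = cfg$weakmask$felz_sigma,
                felz_min_size = cfg$weakmask$felz_min_size,
                filter = list(min_area = cfg$weakmask$min_area,
                              max_area = cfg$weakmask$max_area,
                              max_aspect_ratio = cfg$weakmask$max_aspect_ratio))

  src_patches <- unlist(lapply(seq_along(src_ph), function(i)
    extract_identification_patches(src_ph[[i]]$volume, src_ph[[i]]$dense,
                                   spec = id_spec, mode = "train",
                                   seed = seed + 20L * i)),
    recursive = FALSE)
  tgt_patches <- unlist(lapply(seq_along(tgt_ph), function(i)
    extract_identification_patches(tgt_ph[[i]]$volume, det_mask = tgt_masks[[i]],
                                   spec = id_spec, mode = "train",
                                   seed = seed + 30L * i)),
    recursive = FALSE)
  sp <- cfg$phantom$spacing

  baseline <- fit_vertebra_identifier(src_patches, NULL, id_cfg(0L), dslc, rd,
                                      spacing = sp, weak_args = wargs)
  adapted <- fit_vertebra_identifier(src_patches, tgt_patches, id_cfg(0L), dslc,
                                     rd, spacing = sp, weak_args = wargs)
  arms <- list(without_uda = baseline, with_uda = adapted)

  if (n_labeled_target > 0L) {
    k <- min(n_labeled_target, length(tgt_ph))
    lbl_patches <- unlist(lapply(seq_len(k), function(i)
      extract_identification_patches(tgt_ph[[i]]$volume, tgt_ph[[i]]$dense,
                                     spec = id_spec, mode = "train",
                                     seed = seed + 40L * i)),
      recursive = FALSE)
    arms$with_labels <- fit_vertebra_identifier(src_patches, tgt_patches,
                                                id_cfg(k), dslc, rd, spacing = sp,
                                                labeled_target_samples = lbl_patches,
                                                weak_args = wargs)
  }

  reports <- lapply(arms, function(fit) {
    lapply(seq_along(test_ph), function(i) {
      pr <- predict(fit, test_ph[[i]]$volume, test_masks[[i]], id_spec)
      eval_report(pr$dense, test_ph[[i]]$dense, pr$centroids,
                  test_ph[[i]]$centroids, cfg$evaluation$threshold_mm)
    })
  })
  summarize <- function(reps) list(
    pixel_rate = mean(vapply(reps, `[[`, numeric(1), "pixel_rate")),
    id_rate = mean(vapply(reps, `[[`, numeric(1), "id_rate")),
    mean_dist_mm = mean(vapply(reps, `[[`, numeric(1), "mean_dist_mm")))
  structure(list(summary = lapply(reports, summarize),
                 reports = reports,
                 detection = det_eval,
                 manifest = list(seed = seed, demo = d,
                                 package_version = as.character(utils::packageVersion("spinesanity"))),
                 models = arms),
            class = "uda_demo")
}

#' @export
print.uda_demo <- function(x, ...) {
  cat("Scaled-down domain adaptation study (held-out target phantoms)\n")
  for (arm in names(x$summary)) {
    s <- x$summary[[arm]]
    cat(sprintf("  %-12s pixel rate %.1f%%, id rate %.1f%%, mean dist %.1f mm\n",
                arm, 100 * s$pixel_rate, 100 * s$id_rate, s$mean_dist_mm))
  }
  iou_raw <- mean(vapply(x$detection, function(e) e$raw$vertebrae$iou, numeric(1)))
  iou_post <- mean(vapply(x$detection, function(e) e$post$vertebrae$iou, numeric(1)))
  cat(sprintf("  detection vertebra IoU: %.1f%% raw -> %.1f%% post-processed\n",
              100 * iou_raw, 100 * iou_post))
  invisible(x)
}
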