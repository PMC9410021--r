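test_that("test-mode tiling covers the grid with non-overlapping patches", {
  vol <- ct_volume(array(0, c(160, 160, 192)))
  spec <- detection_patch_spec(c(80, 80, 96))
  tiles <- extract_detection_patches(vol, spec = spec, mode = "test")
  expect_length(tiles, 8L)
  origins <- do.call(rbind, lapply(tiles, `[[`, "origin"))
  expect_equal(nrow(unique(origins)), 8L)
  expect_setequal(origins[, 1], c(1, 81))
  expect_setequal(origins[, 3], c(1, 97))
})

test_that("train-mode patch extraction is seeded and spine-covering", {
  ph <- generate_phantom(tiny_phantom_config(seed = 13))
  spec <- detection_patch_spec(c(16, 24, 48), 10, 8)
  a <- extract_detection_patches(ph$volume, ph$dense, spec, "train", seed = 7)
  b <- extract_detection_patches(ph$volume, ph$dense, spec, "train", seed = 7)
  expect_identical(lapply(a, `[[`, "origin"), lapply(b, `[[`, "origin"))
  n_spine <- sum(vapply(a, function(p) any(p$labels), logical(1)))
  expect_gte(n_spine, 8L)
  expect_error(extract_detection_patches(ph$volume, NULL, spec, "train"),
               "labeled")
})

test_that("weighted BCE reproduces hand-computed values and reductions", {
  expect_equal(weighted_bce(c(0.5, 0.5), c(1, 0)), 1.1 * log(2) / 2)
  # perfect prediction: loss at the clamping floor
  expect_lt(weighted_bce(c(1, 0), c(1, 0)), 1e-5)
  # unit weights reduce to the unweighted loss
  set.seed(3)
  p <- runif(50, 0.01, 0.99); t <- rbinom(50, 1, 0.5)
  expect_equal(weighted_bce(p, t, 1, 1), mean(-t * log(p) - (1 - t) * log(1 - p)))
  # permutation invariance and linearity in each weight
  o <- sample(50)
  expect_equal(weighted_bce(p[o], t[o]), weighted_bce(p, t))
  expect_equal(weighted_bce(p, t, 2, 0.1) - weighted_bce(p, t, 1, 0.1),
               weighted_bce(p, t, 1, 1e-12) - weighted_bce(p, t, 1e-12, 1e-12),
               tolerance = 1e-6)
})

test_that("detector training reduces the loss and is bit-reproducible", {
  ph <- generate_phantom(tiny_phantom_config(seed = 14))
  spec <- detection_patch_spec(c(16, 24, 48), 10, 8)
  samples <- extract_detection_patches(ph$volume, ph$dense, spec, "train", seed = 1)
  cfg <- detection_train_config(5e-3, 4, 5, seed = 2)
  fit1 <- fit_spine_detector(samples, cfg)
  fit2 <- fit_spine_detector(samples, cfg)
  expect_lt(tail(fit1$epoch_loss, 1), fit1$epoch_loss[1])
  expect_identical(fit1$model$params, fit2$model$params)
  expect_error(fit_spine_detector(list(), cfg), "no training samples")
})

test_that("a briefly trained detector recalls most vertebra voxels", {
  spec <- detection_patch_spec(c(16, 24, 48), 10, 8)
  samples <- unlist(lapply(1:2, function(i) {
    ph <- generate_phantom(tiny_phantom_config(seed = 40 + i))
    extract_detection_patches(ph$volume, ph$dense, spec, "train", seed = i)
  }), recursive = FALSE)
  det <- fit_spine_detector(samples, detection_train_config(1e-2, 4, 15, seed = 1))
  held <- generate_phantom(tiny_phantom_config(seed = 50))
  mask <- predict(det, held$volume, spec, postprocess = FALSE)
  body <- held$volume$data > 300        # vertebral bodies proper
  expect_gt(mean(mask$data[body] == 1), 0.8)
})

test_that("assemble_prediction stitches tiles and applies the 0.5 tie rule", {
  ones <- lapply(1:8, function(i) array(1, c(2, 2, 2)))
  origins <- as.matrix(expand.grid(c(1, 3), c(1, 3), c(1, 3)))
  m <- assemble_prediction(ones, origins, c(4, 4, 4))
  expect_equal(sum(m$data), 64L)
  # disjoint tiles concatenate exactly; 0.5 maps to spine
  tiles <- list(array(0.5, c(2, 2, 2)), array(0.4, c(2, 2, 2)))
  m2 <- assemble_prediction(tiles, matrix(c(1, 1, 1, 3, 1, 1), 2, byrow = TRUE),
                            c(4, 2, 2))
  expect_equal(unique(as.vector(m2$data[1:2, , ])), 1L)
  expect_equal(unique(as.vector(m2$data[3:4, , ])), 0L)
  expect_error(assemble_prediction(tiles[1], matrix(c(1, 1, 1), 1), c(4, 2, 2)),
               "missing tile")
})

test_that("largest-component post-processing removes artefacts, keeps the spine", {
  ph <- generate_phantom(tiny_phantom_config(seed = 15, include_bed_artefact = TRUE))
  pred <- ph$spine_mask$data
  bed <- ph$volume$data > 300 & pred == 0
  pred[bed] <- 1L
  cleaned <- postprocess_largest_component(binary_mask(pred, ph$volume$spacing))
  expect_identical(cleaned$data, ph$spine_mask$data)
  # never adds voxels; single component; identity on single components
  expect_true(all(cleaned$data <= pred))
  again <- postprocess_largest_component(cleaned)
  expect_identical(again$data, cleaned$data)
  expect_warning(postprocess_largest_component(
    binary_mask(array(0L, c(4, 4, 4)))), "empty")
})

test_that("equal-size component ties keep the lexicographically first component", {
  m <- array(0L, c(5, 1, 1))
  m[c(1, 2)] <- 1L; m[c(4, 5)] <- 1L
  kept <- postprocess_largest_component(binary_mask(m))
  expect_equal(which(kept$data == 1L), c(1L, 2L))
})
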