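#' Configuration for the synthetic spine phantom
#'
#' The phantom emulates a spine-focused CT scan: a craniocaudal chain of
#' bright cuboid vertebral bodies whose inter-centroid spacing follows the
#' reference-distance table, a dimmer posterior "process" rod that keeps the
#' spine one 3D connected component (as real posterior elements do), a
#' soft-tissue background, optional bed artefact, and Gaussian noise. The
#' `target` domain variant rescales intensities, raises the noise level and
#' randomly crops the volume, mimicking a different scanner/protocol.
#'
#' @param n_vertebrae number of vertebrae rendered (view limited to part of
#'   the spine, as in spine-focused CT).
#' @param first_vertebra_id id of the topmost rendered vertebra;
#'   `first_vertebra_id + n_vertebrae - 1` must be <= 26.
#' @param shape grid dimensions `(sagittal, row, column)` in voxels.
#' @param spacing voxel spacing in mm.
#' @param rd reference distances, see [reference_distances()].
#' @param sizes vertebra extents, see [vertebra_sizes()].
#' @param intensity_spine_hu,intensity_background_hu vertebral body and
#'   soft-tissue intensities; the body intensity must exceed 180 HU and the
#'   background stay below it so the weak-mask threshold separates them.
#' @param intensity_rod_hu posterior rod intensity; kept below 180 HU so the
#'   weak mask still resolves individual vertebrae.
#' @param noise_sd_hu additive Gaussian noise (source domain).
#' @param include_bed_artefact render a thin bright cuboid away from the
#'   spine, like the patient bed.
#' @param domain `"source"` or `"target"`.
#' @param target_noise_sd_hu noise level used instead of `noise_sd_hu` in the
#'   target domain.
#' @param target_intensity_scale multiplicative intensity rescaling applied in
#'   the target domain.
#' @param target_max_crop_vox maximal random crop (voxels) taken off each end
#'   of the column axis in the target domain.
#' @param seed integer RNG seed; generation is deterministic given the seed.
#' @return A validated list of class `phantom_config`.
#' @export
phantom_config <- function(n_vertebrae = 10L,
                           first_vertebra_id = 8L,
                           shape = c(64L, 96L, 352L),
                           spacing = c(1, 1, 1),
                           rd = reference_distances(),
                           sizes = vertebra_sizes(),
                           intensity_spine_hu = 400,
                           intensity_background_hu = 40,
                           intensity_rod_hu = 150,
                           noise_sd_hu = 20,
                           include_bed_artefact = TRUE,
                           domain = c("source", "target"),
                           target_noise_sd_hu = 60,
                           target_intensity_scale = 0.85,
                           target_max_crop_vox = 10L,
                           seed = 1L) {
  domain <- match.arg(domain)
  cfg <- list(n_vertebrae = as.integer(n_vertebrae),
              first_vertebra_id = as.integer(first_vertebra_id),
              shape = as.integer(shape), spacing = check_spacing(spacing, 3L),
              rd = rd, sizes = sizes,
              intensity_spine_hu = intensity_spine_hu,
              intensity_background_hu = intensity_background_hu,
              intensity_rod_hu = intensity_rod_hu,
              noise_sd_hu = noise_sd_hu,
              include_bed_artefact = isTRUE(include_bed_artefact),
              domain = domain,
              target_noise_sd_hu = target_noise_sd_hu,
              target_intensity_scale = target_intensity_scale,
              target_max_crop_vox = as.integer(target_max_crop_vox),
              seed = as.integer(seed))
  assert_that(cfg$n_vertebrae >= 1L && cfg$first_vertebra_id >= 1L &&
                cfg$first_vertebra_id + cfg$n_vertebrae - 1L <= 26L,
              "first_vertebra_id + n_vertebrae - 1 must be <= 26")
  assert_that(cfg$intensity_spine_hu > 180,
              "vertebral body intensity must exceed the 180 HU weak-mask threshold")
  assert_that(cfg$intensity_background_hu < 180,
              "background intensity must stay below 180 HU")
  assert_that(cfg$noise_sd_hu >= 0 && cfg$target_noise_sd_hu >= 0 &&
                cfg$target_intensity_scale > 0,
              "noise levels must be >= 0 and the intensity scale > 0")
  class(cfg) <- "phantom_config"
  cfg
}

#' Generate a synthetic spine phantom
#'
#' @param config a [phantom_config()].
#' @return A list of class `phantom_sample` with elements `volume`
#'   ([ct_volume()]), `centroids` ([centroid_set()]), `dense` (integer label
#'   array), `spine_mask` ([binary_mask()]) and the `config` used.
#' @examples
#' ph <- generate_phantom(phantom_config(n_vertebrae = 4, shape = c(24, 48, 144),
#'                                       include_bed_artefact = FALSE, seed = 7))
#' table(ph$dense[ph$dense > 0])
#' @export
generate_phantom <- function(config = phantom_config()) {
  assert_that(inherits(config, "phantom_config"), "config must be a phantom_config")
  with_seed(config$seed, generate_phantom_impl(config))
}

generate_phantom_impl <- function(cfg) {
  shape <- cfg$shape
  sp <- cfg$spacing
  ids <- cfg$first_vertebra_id + seq_len(cfg$n_vertebrae) - 1L

  # centroid chain along the column axis; spacing from the reference table
  first_half <- cfg$sizes[ids[1], 3] / 2
  col_mm <- cumsum(c(first_half + 12, cfg$rd[head(ids, -1)]))
  max_col <- (shape[3] - 1) * sp[3]
  assert_that(max(col_mm) + cfg$sizes[tail(ids, 1), 3] / 2 <= max_col,
              "grid too short along the column axis for the requested chain")
  sag_mm <- round((shape[1] - 1) / 2) * sp[1]
  row_mm <- round((shape[2] - 1) / 2) * sp[2]
  cs <- centroid_set(ids, cbind(sag_mm, row_mm, col_mm))
  dense <- sparse_to_dense(cs, shape, sp, cfg$sizes)

  # Posterior rod: connects the bodies in 3D (like posterior elements do)
  # but below the weak-mask HU threshold. It occupies sagittal slabs away
  # from the central plane, so the central ground-truth slice contains only
  # the perfectly symmetric body boxes and per-slice centroid medians stay
  # exact; placement is symmetric about the centre so 3D medians stay
  # centred in the sagittal axis too.
  row_half <- cfg$sizes[ids, 2] / 2
  rod_rows <- which((seq_len(shape[2]) - 1) * sp[2] > row_mm + min(row_half) &
                      (seq_len(shape[2]) - 1) * sp[2] <= row_mm + max(row_half) + 6)
  sag_off <- abs((seq_len(shape[1]) - 1) * sp[1] - sag_mm)
  rod_sag <- which(sag_off >= 3 * sp[1] & sag_off <= 5 * sp[1])
  rod_cols <- which((seq_len(shape[3]) - 1) * sp[3] >= col_mm[1] &
                      (seq_len(shape[3]) - 1) * sp[3] <= col_mm[length(col_mm)])
  rod <- array(FALSE, shape)
  rod[rod_sag, rod_rows, rod_cols] <- TRUE
  rod <- rod & dense == 0L
  if (any(rod)) {
    rod_idx <- which(rod, arr.ind = TRUE)
    nearest <- vapply(rod_idx[, 3], function(j) {
      which.min(abs((j - 1) * sp[3] - col_mm))
    }, integer(1))
    dense[rod] <- ids[nearest]
  }

  hu <- array(cfg$intensity_background_hu, shape)
  hu[dense > 0L] <- cfg$intensity_spine_hu
  hu[rod] <- cfg$intensity_rod_hu

  if (cfg$include_bed_artefact) {
    bed_rows <- 2:5
    bed_sag <- max(2L, round(shape[1] * 0.25)):round(shape[1] * 0.75)
    bed_cols <- round(shape[3] * 0.1):round(shape[3] * 0.9)
    hu[bed_sag, bed_rows, bed_cols] <- 350
  }

  noise_sd <- if (cfg$domain == "target") cfg$target_noise_sd_hu else cfg$noise_sd_hu
  if (cfg$domain == "target") hu <- hu * cfg$target_intensity_scale
  hu <- hu + array(rnorm(prod(shape), 0, noise_sd), shape)

  if (cfg$domain == "target" && cfg$target_max_crop_vox > 0L) {
    c0 <- sample.int(cfg$target_max_crop_vox + 1L, 1L) - 1L
    c1 <- sample.int(cfg$target_max_crop_vox + 1L, 1L) - 1L
    keep <- (1L + c0):(shape[3] - c1)
    hu <- hu[, , keep, drop = FALSE]
    dense <- dense[, , keep, drop = FALSE]
    shape <- dim(hu)
    cs$z_mm <- cs$z_mm - c0 * sp[3]
    inside <- cs$z_mm >= 0 & cs$z_mm <= (shape[3] - 1) * sp[3]
    kept_ids <- cs$id[inside]
    cs <- centroid_set(kept_ids, as.matrix(cs[inside, c("x_mm", "y_mm", "z_mm")]))
    dense[!(dense %in% c(0L, kept_ids))] <- 0L
  }

  structure(list(volume = ct_volume(hu, sp),
                 centroids = cs,
                 dense = dense,
                 spine_mask = binary_mask(array(as.integer(dense > 0L), dim(dense)), sp),
                 config = cfg),
            class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("Spine phantom (%s domain): %s voxels, vertebrae %s\n",
              x$config$domain, paste(dim(x$dense), collapse = " x "),
              paste(vertebra_names()[range(x$centroids$id)], collapse = "-")))
  invisible(x)
}

#' Corrupt dense labels for sensitivity studies
#'
#' Produces anatomically implausible label grids that the sanity checks are
#' designed to flag: whole-grid translations along the spine, swapped
#' neighbouring vertebra labels, or per-pixel label jitter.
#'
#' @param dense 2D or 3D integer label grid.
#' @param mode one of `"shift_columns"` (translate every label along the
#'   column axis by `magnitude` voxels), `"swap_adjacent"` (exchange the
#'   labels of a random adjacent pair; `magnitude` ignored), `"jitter_pixels"`
#'   (relabel a `magnitude` fraction of spine pixels to a neighbouring id).
#' @param magnitude shift in voxels, or jitter fraction in `[0, 1]`.
#' @param seed RNG seed for the random modes.
#' @return A corrupted copy of `dense`.
#' @export
corrupt_labels <- function(dense, mode = c("shift_columns", "swap_adjacent", "jitter_pixels"),
                           magnitude = 1, seed = 1L) {
  mode <- match.arg(mode)
  nd <- length(dim(dense))
  assert_that(nd %in% c(2L, 3L), "dense labels must be 2D or 3D")
  with_seed(seed, switch(mode,
    shift_columns = {
      m <- as.integer(magnitude)
      n <- dim(dense)[nd]
      out <- array(0L, dim(dense))
      if (abs(m) < n) {
        src <- if (m >= 0) 1:(n - m) else (1 - m):n
        dst <- if (m >= 0) (1 + m):n else 1:(n + m)
        if (nd == 2L) out[, dst] <- dense[, src] else out[, , dst] <- dense[, , src]
      }
      out
    },
    swap_adjacent = {
      present <- sort(unique(dense[dense > 0L]))
      pairs <- present[(present + 1L) %in% present]
      assert_that(length(pairs) > 0L, "no adjacent vertebra pair present to swap")
      k <- pairs[sample.int(length(pairs), 1L)]
      out <- dense
      out[dense == k] <- k + 1L
      out[dense == k + 1L] <- k
      out
    },
    jitter_pixels = {
      assert_that(magnitude >= 0 && magnitude <= 1, "jitter fraction must be in [0, 1]")
      out <- dense
      spine <- which(dense > 0L)
      n_j <- round(magnitude * length(spine))
      if (n_j > 0L) {
        pick <- sample(spine, n_j)
        delta <- sample(c(-1L, 1L), n_j, replace = TRUE)
        out[pick] <- pmin(26L, pmax(1L, dense[pick] + delta))
      }
      out
    }))
}
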