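#' CT volume container
#'
#' A `ct_volume` holds a 3D grid of Hounsfield-unit intensities together with
#' the per-axis voxel spacing in millimetres. The axis convention throughout
#' the package is `(sagittal slab, row, column)`, with the column axis running
#' craniocaudally along the spine, so that `vol$data[s, , ]` is a sagittal
#' plane. Voxel `(1,1,1)` sits at 0 mm on every axis; the mm position of voxel
#' `(i,j,k)` is `(i-1, j-1, k-1) * spacing`.
#'
#' @param data 3D numeric array of HU intensities.
#' @param spacing numeric length-3 (or scalar) voxel spacing in mm, all > 0.
#' @return An object of class `ct_volume` with elements `data` and `spacing`.
#' @examples
#' v <- ct_volume(array(0, c(4, 4, 4)), spacing = 1)
#' dim(v$data)
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1)) {
  assert_that(is.array(data) && length(dim(data)) == 3L,
              "volume data must be a 3D array")
  assert_that(all(is.finite(data)), "volume intensities must be finite")
  spacing <- check_spacing(spacing, 3L)
  structure(list(data = data, spacing = spacing), class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("CT volume: %d x %d x %d voxels @ (%s) mm, HU range [%.0f, %.0f]\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Read a CT volume from a NIfTI file
#'
#' Intensities are taken as stored (assumed Hounsfield units); the voxel
#' spacing is read from the NIfTI `pixdim` header field.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path) {
  assert_that(file.exists(path), "file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_ss("not a readable NIfTI file: ", path,
                                              " (", conditionMessage(e), ")"))
  data <- as.array(img)
  assert_that(length(dim(data)) == 3L, "expected a 3D NIfTI volume: ", path)
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  assert_that(all(is.finite(spacing)) && all(spacing > 0),
              "NIfTI header field 'pixdim' must carry positive voxel spacing")
  ct_volume(data, spacing)
}

#' Write a CT volume (or any 3D grid) to NIfTI
#'
#' @param vol a [ct_volume()], or a plain 3D array together with `spacing`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing voxel spacing, only used when `vol` is a plain array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, spacing = NULL) {
  if (inherits(vol, "ct_volume")) {
    data <- vol$data
    spacing <- vol$spacing
  } else {
    data <- vol
    spacing <- check_spacing(spacing %||% 1, 3L)
  }
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Binary spine mask
#'
#' @param data 3D array of 0/1 (or logical) values.
#' @param spacing voxel spacing in mm, as for [ct_volume()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1)) {
  assert_that(is.array(data) && length(dim(data)) == 3L,
              "mask data must be a 3D array")
  storage.mode(data) <- "integer"
  assert_that(all(data %in% c(0L, 1L)), "mask values must be 0 or 1")
  spacing <- check_spacing(spacing, 3L)
  structure(list(data = data, spacing = spacing), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("Binary mask: %s voxels, %d foreground\n",
              paste(dim(x$data), collapse = " x "), sum(x$data)))
  invisible(x)
}
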