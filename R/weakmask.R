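#' Weak vertebra segmentation mask
#'
#' An integer grid over the sagittal plane in which 0 means "no component"
#' and `k >= 1` labels the k-th connected component of an unsupervised
#' vertebra segmentation, together with the explicit coordinate set of each
#' component. The mask is deliberately imprecise; the shift sanity check only
#' requires that pixels grouped into one component belong to one vertebra.
#'
#' @param data integer matrix of component ids (0 = background). Components
#'   are taken as the distinct nonzero ids and renumbered contiguously.
#' @return An object of class `weak_mask` with elements `data` (matrix) and
#'   `components` (list of two-column coordinate matrices, row/column).
#' @export
weak_mask <- function(data) {
  assert_that(is.matrix(data), "weak mask data must be a matrix")
  ids <- sort(unique(data[data > 0]))
  comps <- lapply(ids, function(k) which(data == k, arr.ind = TRUE))
  out <- matrix(0L, nrow(data), ncol(data))
  for (i in seq_along(ids)) out[comps[[i]]] <- i
  structure(list(data = out, components = comps), class = "weak_mask")
}

#' @export
print.weak_mask <- function(x, ...) {
  cat(sprintf("Weak mask: %d x %d pixels, %d component(s)\n",
              nrow(x$data), ncol(x$data), length(x$components)))
  invisible(x)
}

#' Number of weak-mask components
#' @param wm a [weak_mask()].
#' @export
n_components <- function(wm) length(wm$components)

#' Build the weak vertebra mask of a sagittal patch
#'
#' Pipeline: (1) multiply the scan by the binary detection prediction to keep
#' only spine intensities; (2) zero every pixel below the HU threshold
#' (default 180, emphasising bone edges); (3) segment the result with the
#' graph-based Felzenszwalb-Huttenlocher algorithm; (4) discard segments
#' dominated by zero-intensity pixels (background). Segments are numbered
#' contiguously in scan order.
#'
#' @param scan_patch numeric matrix of HU intensities (sagittal plane).
#' @param detection_patch 0/1 matrix from the detection stage, same shape.
#' @param hu_threshold intensity threshold in HU; default 180.
#' @param felz_scale,felz_sigma,felz_min_size Felzenszwalb parameters:
#'   region-merging scale, Gaussian pre-smoothing (pixels), minimum segment
#'   size. Defaults tuned on phantoms; the mask is a heuristic, not a
#'   ground-truth segmentation.
#' @return A [weak_mask()]; empty (0 components) when nothing survives the
#'   masking and thresholding.
#' @export
build_weak_mask <- function(scan_patch, detection_patch, hu_threshold = 180,
                            felz_scale = 100, felz_sigma = 0.8,
                            felz_min_size = 40L) {
  assert_that(identical(dim(scan_patch), dim(detection_patch)),
              "scan and detection patch shapes differ")
  x <- scan_patch * (detection_patch != 0)
  x[x < hu_threshold] <- 0
  if (all(x == 0)) return(weak_mask(matrix(0L, nrow(x), ncol(x))))
  seg <- .felz_segment(gaussian_blur(x, felz_sigma), felz_scale,
                       as.integer(felz_min_size))
  keep <- matrix(0L, nrow(x), ncol(x))
  nxt <- 0L
  for (k in seq_len(attr(seg, "n_segments"))) {
    px <- seg == k
    if (mean(x[px] == 0) > 0.5) next      # background segment
    nxt <- nxt + 1L
    keep[px] <- nxt
  }
  weak_mask(keep)
}

#' Filter weak-mask components by shape heuristics
#'
#' Removes components whose area falls outside `[min_area, max_area]` pixels
#' or whose bounding-box aspect ratio exceeds `max_aspect_ratio` — shapes
#' that cannot correspond to a vertebral body. Remaining components are
#' renumbered contiguously.
#'
#' @param wm a [weak_mask()].
#' @param min_area,max_area area bounds in pixels.
#' @param max_aspect_ratio maximal long/short bounding-box side ratio.
#' @return A filtered [weak_mask()].
#' @export
filter_components <- function(wm, min_area = 25L, max_area = 5000L,
                              max_aspect_ratio = 3) {
  out <- matrix(0L, nrow(wm$data), ncol(wm$data))
  nxt <- 0L
  for (coords in wm$components) {
    area <- nrow(coords)
    if (area < min_area || area > max_area) next
    h <- diff(range(coords[, 1])) + 1L
    w <- diff(range(coords[, 2])) + 1L
    if (max(h, w) / min(h, w) > max_aspect_ratio) next
    nxt <- nxt + 1L
    out[coords] <- nxt
  }
  weak_mask(out)
}

#' Merge weak-mask components enclosed in one another
#'
#' If the bounding box of one component lies entirely inside the bounding box
#' of another, the two are merged (the enclosed one absorbed), repeatedly
#' until no enclosure remains. This repairs vertebrae fragmented into an
#' outer rim plus inner blob by the unsupervised segmentation.
#'
#' @param wm a [weak_mask()].
#' @return A [weak_mask()] with enclosed components merged.
#' @export
merge_enclosed <- function(wm) {
  repeat {
    n <- length(wm$components)
    if (n < 2L) return(wm)
    bb <- t(vapply(wm$components, function(co)
      c(min(co[, 1]), max(co[, 1]), min(co[, 2]), max(co[, 2])), numeric(4)))
    merged <- FALSE
    for (a in seq_len(n)) {
      for (b in seq_len(n)) {
        if (a == b) next
        if (bb[a, 1] >= bb[b, 1] && bb[a, 2] <= bb[b, 2] &&
            bb[a, 3] >= bb[b, 3] && bb[a, 4] <= bb[b, 4]) {
          d <- wm$data
          d[d == a] <- b
          wm <- weak_mask(d)
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) return(wm)
  }
}
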