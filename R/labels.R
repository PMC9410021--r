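#' Vertebra naming
#'
#' Vertebrae are numbered 1..26 in craniocaudal order: C1-C7 cervical (1-7),
#' T1-T12 thoracic (8-19), L1-L5 lumbar (20-24), S1-S2 sacral (25-26).
#'
#' @return Character vector of the 26 vertebra names, in id order.
#' @export
vertebra_names <- function() {
  c(paste0("C", 1:7), paste0("T", 1:12), paste0("L", 1:5), paste0("S", 1:2))
}

#' Reference inter-centroid distances
#'
#' Mean centroid-to-centroid distance in mm for each of the 25 adjacent
#' vertebra pairs (C1-C2 ... S1-S2). These literature-derived averages are the
#' "gold standard" that the distance sanity check compares predictions
#' against; they ship as an editable YAML resource rather than constants.
#'
#' @param path optional YAML file keyed `C1-C2: <mm>`, ...; defaults to the
#'   packaged table.
#' @return Named numeric vector of length 25; element `k` is the distance
#'   between vertebrae `k` and `k+1`.
#' @export
reference_distances <- function(path = NULL) {
  path <- path %||% system.file("extdata", "reference_distances.yaml",
                                package = "spinesanity", mustWork = TRUE)
  tab <- yaml::read_yaml(path)
  nm <- vertebra_names()
  expected <- paste0(nm[1:25], "-", nm[2:26])
  assert_that(setequal(names(tab), expected),
              "reference distance table must contain exactly the 25 adjacent pairs")
  d <- as.numeric(unlist(tab[expected]))
  assert_that(all(is.finite(d)) && all(d > 0), "reference distances must be > 0")
  setNames(d, expected)
}

#' Look up the reference distance for an adjacent pair
#'
#' @param rd a table from [reference_distances()].
#' @param k index of the pair (vertebrae `k` and `k+1`), 1..25.
#' @return Distance in mm.
#' @export
adjacent_reference <- function(rd, k) {
  k <- as.integer(k)
  assert_that(length(k) == 1L && !is.na(k) && k >= 1L && k <= 25L,
              "pair index k must lie in 1..25")
  unname(rd[k])
}

#' Average vertebral-body sizes
#'
#' @param path optional YAML file keyed by vertebra name with `[sag, row, col]`
#'   extents in mm; defaults to the packaged table.
#' @return 26 x 3 numeric matrix of extents in mm, rows named C1..S2.
#' @export
vertebra_sizes <- function(path = NULL) {
  path <- path %||% system.file("extdata", "vertebra_sizes.yaml",
                                package = "spinesanity", mustWork = TRUE)
  tab <- yaml::read_yaml(path)
  nm <- vertebra_names()
  assert_that(setequal(names(tab), nm), "size table must contain all 26 vertebrae")
  m <- do.call(rbind, lapply(tab[nm], as.numeric))
  assert_that(ncol(m) == 3L && all(is.finite(m)) && all(m > 0),
              "vertebra sizes must be positive 3D extents")
  dimnames(m) <- list(nm, c("sag_mm", "row_mm", "col_mm"))
  m
}

#' Convert sparse centroids to dense per-voxel labels
#'
#' Each vertebra becomes an axis-aligned box of its id, centred on its
#' centroid with the extent given by the size table. Where boxes overlap, the
#' contested voxel is assigned to the nearer centroid (ties to the lower id).
#' All other voxels are 0.
#'
#' @param cs a [centroid_set()] with positions inside the grid.
#' @param shape integer length-3 grid dimensions.
#' @param spacing voxel spacing in mm.
#' @param sizes extent table from [vertebra_sizes()].
#' @return Integer 3D array with values in 0..26.
#' @export
sparse_to_dense <- function(cs, shape, spacing = c(1, 1, 1), sizes = vertebra_sizes()) {
  shape <- as.integer(shape)
  spacing <- check_spacing(spacing, 3L)
  dense <- array(0L, dim = shape)
  if (nrow(cs) == 0L) return(dense)
  pos <- as.matrix(cs[c("x_mm", "y_mm", "z_mm")])
  max_mm <- (shape - 1L) * spacing
  inside <- pos >= 0 & sweep(pos, 2L, max_mm, `<=`)
  if (!all(inside)) {
    bad <- cs$id[!apply(inside, 1L, all)]
    stop_ss("centroid outside grid for vertebra id(s): ", paste(bad, collapse = ", "))
  }
  best <- array(Inf, dim = shape)
  for (r in seq_len(nrow(cs))) {
    k <- cs$id[r]
    half <- sizes[k, ] / 2
    rng <- lapply(1:3, function(ax) {
      lo <- max(ceiling((pos[r, ax] - half[ax]) / spacing[ax]), 0)
      hi <- min(floor((pos[r, ax] + half[ax]) / spacing[ax]), shape[ax] - 1L)
      if (lo > hi) integer() else (lo:hi) + 1L     # 1-based indices
    })
    if (any(lengths(rng) == 0L)) next
    d2 <- outer(outer(((rng[[1]] - 1) * spacing[1] - pos[r, 1])^2,
                      ((rng[[2]] - 1) * spacing[2] - pos[r, 2])^2, `+`),
                ((rng[[3]] - 1) * spacing[3] - pos[r, 3])^2, `+`)
    cur <- best[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    take <- d2 < cur       # strict: earlier (lower) id wins ties
    blk <- dense[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    blk[take] <- k
    dense[rng[[1]], rng[[2]], rng[[3]]] <- blk
    cur[take] <- d2[take]
    best[rng[[1]], rng[[2]], rng[[3]]] <- cur
  }
  dense
}

# Per-id median voxel position (mm, 0-based convention) of a labelled grid.
# Works for 2D and 3D grids; returns a matrix with one row per id present.
dense_centroids <- function(dense, spacing) {
  nd <- length(dim(dense))
  spacing <- check_spacing(spacing, nd)
  ids <- sort(unique(dense[dense > 0]))
  pos <- matrix(NA_real_, length(ids), nd)
  for (r in seq_along(ids)) {
    idx <- which(dense == ids[r], arr.ind = TRUE)
    if (is.null(dim(idx))) idx <- matrix(idx, ncol = nd)
    pos[r, ] <- apply((idx - 1) * rep(spacing, each = nrow(idx)), 2L, median)
  }
  list(ids = as.integer(ids), pos = pos)
}

#' Recover sparse centroids from dense labels
#'
#' The centroid of each vertebra id present in the grid is the per-axis median
#' of its voxel coordinates, converted to mm. The median makes the recovery
#' robust to outlying mislabelled voxels.
#'
#' @param dense integer 3D array with values in 0..26.
#' @param spacing voxel spacing in mm.
#' @return A [centroid_set()]; ids absent from the grid are absent here.
#' @export
dense_to_sparse <- function(dense, spacing = c(1, 1, 1)) {
  assert_that(length(dim(dense)) == 3L, "dense labels must be a 3D array")
  assert_that(all(dense >= 0 & dense <= 26), "dense labels must lie in 0..26")
  dc <- dense_centroids(dense, spacing)
  centroid_set(dc$ids, dc$pos)
}
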