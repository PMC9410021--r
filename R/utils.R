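# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ss <- function(...) stop(..., call. = FALSE)

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_ss(...)
  invisible(TRUE)
}

# Running-mean (box) smoothing along one axis of a 2D/3D array, window 2h+1,
# edge-clipped (windows shrink at the borders so means stay unbiased).
smooth_axis <- function(a, axis, h) {
  if (h <= 0) return(a)
  d <- dim(a)
  nd <- length(d)
  perm <- c(axis, setdiff(seq_len(nd), axis))
  ap <- aperm(a, perm)
  n <- d[axis]
  m <- matrix(ap, nrow = n)
  cs <- apply(m, 2L, cumsum)
  if (!is.matrix(cs)) cs <- matrix(cs, nrow = n)
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  upper <- cs[hi, , drop = FALSE]
  lower <- rbind(0, cs)[lo, , drop = FALSE]
  out <- (upper - lower) / (hi - lo + 1L)
  dim(out) <- d[perm]
  aperm(out, order(perm))
}

# Separable box smoothing over all axes (cheap stand-in for Gaussian blur).
box_smooth <- function(a, h = 1L) {
  for (ax in seq_along(dim(a))) a <- smooth_axis(a, ax, h)
  a
}

# Separable Gaussian blur of a matrix, kernel truncated at 3 sigma,
# edges handled by replication.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  conv_cols <- function(x) {
    n <- nrow(x)
    xp <- rbind(x[rep(1L, r), , drop = FALSE], x, x[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(x))
    for (t in seq_along(k)) out <- out + k[t] * xp[t:(t + n - 1L), , drop = FALSE]
    out
  }
  t(conv_cols(t(conv_cols(m))))
}

# Non-overlapping tiling of `shape` by `patch`: matrix of 1-based origins.
# The grid is conceptually zero-padded up to the next multiple of `patch`.
tile_origins <- function(shape, patch) {
  n_tiles <- ceiling(shape / patch)
  grids <- lapply(seq_along(shape), function(ax) (seq_len(n_tiles[ax]) - 1L) * patch[ax] + 1L)
  as.matrix(rev(expand.grid(rev(grids))))
}

# Extract a patch at `origin` (1-based), zero-padding past the array edge.
extract_patch <- function(a, origin, patch, pad_value = 0) {
  d <- dim(a)
  out <- array(pad_value, dim = patch)
  src <- vector("list", length(d))
  dst <- vector("list", length(d))
  for (ax in seq_along(d)) {
    s <- origin[ax]:min(origin[ax] + patch[ax] - 1L, d[ax])
    if (s[1] > d[ax]) return(out)
    src[[ax]] <- s
    dst[[ax]] <- seq_along(s)
  }
  out_idx <- do.call(`[<-`, c(list(out), dst, list(value = do.call(`[`, c(list(a), src)))))
  out_idx
}

# Round half up (0.5 -> 1, 1.5 -> 2), unlike base round()'s banker's rounding.
round_half_up <- function(x) floor(x + 0.5)

# Single integer-valued spacing recycling helper.
check_spacing <- function(spacing, nd) {
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, nd)
  assert_that(length(spacing) == nd, "spacing must have one value per axis")
  assert_that(all(is.finite(spacing)) && all(spacing > 0),
              "voxel spacing must be strictly positive and finite")
  spacing
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
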