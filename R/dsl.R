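#' Domain sanity loss configuration
#'
#' The loss combines four anatomical sanity checks on a sagittal-plane
#' prediction: s1 ascending vertebra order along the spine, s2 column-wise
#' label consistency, s3 inter-centroid distances against literature
#' references, s4 label consistency over the weak vertebra mask. The total is
#' `c1*s1 + c2*s2 + c3*s3 + c4*s4`.
#'
#' @param c1,c2,c3,c4 term weights bringing the four parts to a similar
#'   scale; defaults 20, 1, 1/40, 1/100.
#' @param n_shift maximal column shift compared by s1; the order is checked
#'   only locally (up to `n_shift` pixels ahead) for efficiency.
#' @param strict_margin slack below which a difference does not count as a
#'   violation; default 0 (any strictly positive descent / deviation counts).
#' @param strict_ge if `TRUE`, s1 counts equal neighbouring pixels as
#'   violations too (the literal ">= 0" indicator form); default `FALSE`,
#'   since a pixel shifted along the spine may legitimately keep the same
#'   prediction inside one vertebra.
#' @param spine_only_comparisons if `TRUE` (default) only pixel pairs and
#'   columns whose pixels are nonzero (spine) enter the counts; the
#'   invariances apply to spine pixels only.
#' @param normalize_spine if `TRUE`, s1/s2 divide by the number of spine
#'   pixels instead of the total pixel count `n_pix`.
#' @param mode `"exact"` for the indicator counting form, `"surrogate"` for
#'   the gradient-friendly hinge / absolute-deviation form used in training.
#' @return A list of class `dsl_config`.
#' @export
dsl_config <- function(c1 = 20, c2 = 1, c3 = 1 / 40, c4 = 1 / 100,
                       n_shift = 30L, strict_margin = 0, strict_ge = FALSE,
                       spine_only_comparisons = TRUE, normalize_spine = FALSE,
                       mode = c("exact", "surrogate")) {
  mode <- match.arg(mode)
  assert_that(c1 > 0 && c2 > 0 && c3 > 0 && c4 > 0, "term weights must be > 0")
  assert_that(n_shift >= 1L, "n_shift must be >= 1")
  assert_that(strict_margin >= 0, "strict_margin must be >= 0")
  structure(list(c1 = c1, c2 = c2, c3 = c3, c4 = c4,
                 n_shift = as.integer(n_shift), strict_margin = strict_margin,
                 strict_ge = isTRUE(strict_ge),
                 spine_only_comparisons = isTRUE(spine_only_comparisons),
                 normalize_spine = isTRUE(normalize_spine), mode = mode),
            class = "dsl_config")
}

#' Remove background from a raw prediction
#'
#' Multiplies the identification output elementwise with the binary detection
#' mask, forcing every pixel outside the detected spine to exactly 0. The
#' result is the masked prediction all four sanity checks operate on.
#'
#' @param raw_prediction numeric 2D grid of per-pixel vertebra values.
#' @param det_mask 2D grid of 0/1 detection labels, same shape.
#' @return Numeric matrix with background pixels 0.
#' @export
mask_background <- function(raw_prediction, det_mask) {
  assert_that(identical(dim(raw_prediction), dim(det_mask)),
              "prediction and detection mask shapes differ")
  raw_prediction * (det_mask != 0)
}

dsl_normalizer <- function(yhat, cfg) {
  if (cfg$normalize_spine) max(sum(yhat > 0), 1L) else length(yhat)
}

#' Sanity check s1: ascending order along the spine
#'
#' Compares every spine pixel with the same prediction shifted 1..`n_shift`
#' columns to the right; a pixel further along the spine must not receive a
#' smaller vertebra value. Exact mode counts violating pairs (divided by the
#' pixel count); surrogate mode averages the positive part of the descent so
#' gradients exist.
#'
#' @param yhat masked prediction (numeric matrix, rows x columns of the
#'   sagittal plane, background 0).
#' @param cfg a [dsl_config()].
#' @return Nonnegative scalar.
#' @export
dsl_s1 <- function(yhat, cfg = dsl_config()) {
  nc <- ncol(yhat)
  assert_that(nc > cfg$n_shift,
              "grid has ", nc, " columns but n_shift = ", cfg$n_shift,
              "; use a smaller n_shift")
  acc <- 0
  for (s in seq_len(cfg$n_shift)) {
    a <- yhat[, 1:(nc - s), drop = FALSE]
    b <- yhat[, (1 + s):nc, drop = FALSE]
    d <- a - b
    valid <- if (cfg$spine_only_comparisons) a > 0 & b > 0 else TRUE
    if (cfg$mode == "surrogate") {
      acc <- acc + sum(pmax(d, 0)[valid])
    } else {
      viol <- if (cfg$strict_ge) d >= cfg$strict_margin else d > cfg$strict_margin
      acc <- acc + sum(viol & valid)
    }
  }
  acc / dsl_normalizer(yhat, cfg)
}

#' Sanity check s2: column-wise consistency orthogonal to the spine
#'
#' Takes the median spine value of each column as that column's label and
#' counts pixels deviating from it (exact mode), or averages the absolute
#' deviation from the (detached) median (surrogate mode).
#'
#' @inheritParams dsl_s1
#' @return Nonnegative scalar.
#' @export
dsl_s2 <- function(yhat, cfg = dsl_config()) {
  acc <- 0
  for (j in seq_len(ncol(yhat))) {
    v <- yhat[, j]
    if (cfg$spine_only_comparisons) {
      spine <- v > 0
      if (!any(spine)) next
      med <- median(v[spine])
      dev <- abs(v[spine] - med)
    } else {
      med <- median(v)
      dev <- abs(v - med)
    }
    acc <- acc + if (cfg$mode == "surrogate") sum(dev) else sum(dev > cfg$strict_margin)
  }
  acc / dsl_normalizer(yhat, cfg)
}

#' Sanity check s3: inter-centroid distances against literature references
#'
#' Spine pixels are rounded to integer vertebra ids, each id's centroid is the
#' per-axis median of its pixel coordinates in mm, and for every adjacent pair
#' present the absolute difference between the predicted Euclidean centroid
#' distance and the reference distance is accumulated, divided by
#' `n_vert = 25` (the number of adjacent pairs of a full spine).
#'
#' @inheritParams dsl_s1
#' @param rd reference distances from [reference_distances()].
#' @param spacing mm per pixel along (row, column); scalar or length 2.
#' @return Nonnegative scalar (mm / 25); 0 when no adjacent pair is present.
#' @export
dsl_s3 <- function(yhat, rd = reference_distances(), spacing = c(1, 1)) {
  spacing <- check_spacing(spacing, 2L)
  ids_grid <- round_half_up(yhat)
  ids_grid[ids_grid < 1 | ids_grid > 26] <- 0
  dc <- dense_centroids(ids_grid, spacing)
  if (length(dc$ids) < 2L) return(0)
  acc <- 0
  for (k in dc$ids) {
    i2 <- match(k + 1L, dc$ids)
    if (k <= 25L && !is.na(i2)) {
      i1 <- match(k, dc$ids)
      delta <- sqrt(sum((dc$pos[i1, ] - dc$pos[i2, ])^2))
      acc <- acc + abs(delta - adjacent_reference(rd, k))
    }
  }
  acc / 25
}

#' Sanity check s4: consistency over the weak vertebra mask
#'
#' All pixels of one weak-mask connected component should carry the same
#' vertebra value. For each component the number of unique nonzero rounded
#' prediction values minus one is accumulated and divided by the number of
#' components; in surrogate mode the mean absolute deviation from the
#' component's (detached) median replaces the unique count.
#'
#' @param wm a [weak_mask()] on the same grid as `yhat`.
#' @inheritParams dsl_s1
#' @return Nonnegative scalar; 0 for an empty weak mask.
#' @export
dsl_s4 <- function(wm, yhat, cfg = dsl_config()) {
  assert_that(inherits(wm, "weak_mask"), "wm must be a weak_mask")
  n_c <- length(wm$components)
  if (n_c == 0L) return(0)
  acc <- 0
  for (coords in wm$components) {
    assert_that(all(coords[, 1] >= 1 & coords[, 1] <= nrow(yhat) &
                      coords[, 2] >= 1 & coords[, 2] <= ncol(yhat)),
                "weak-mask coordinate outside the prediction grid")
    vals <- yhat[coords]
    if (cfg$mode == "surrogate") {
      acc <- acc + mean(abs(vals - median(vals)))
    } else {
      u <- length(unique(round_half_up(vals[vals > 0])))
      acc <- acc + max(u - 1L, 0L)
    }
  }
  acc / n_c
}

#' Total domain sanity loss
#'
#' @inheritParams dsl_s4
#' @inheritParams dsl_s3
#' @return A list of class `dsl_breakdown` with elements `s1`, `s2`, `s3`,
#'   `s4` and the weighted `total`.
#' @examples
#' yhat <- matrix(rep(c(0, 5, 5, 6, 6), each = 2), nrow = 2)
#' wm <- weak_mask(matrix(rep(c(0, 1, 1, 2, 2), each = 2), nrow = 2))
#' dsl_total(yhat, wm, spacing = c(1, 22))
#' @export
dsl_total <- function(yhat, wm, rd = reference_distances(),
                      cfg = dsl_config(), spacing = c(1, 1)) {
  s <- c(dsl_s1(yhat, cfg), dsl_s2(yhat, cfg),
         dsl_s3(yhat, rd, spacing), dsl_s4(wm, yhat, cfg))
  structure(list(s1 = s[1], s2 = s[2], s3 = s[3], s4 = s[4],
                 weights = c(cfg$c1, cfg$c2, cfg$c3, cfg$c4),
                 total = sum(c(cfg$c1, cfg$c2, cfg$c3, cfg$c4) * s)),
            class = "dsl_breakdown")
}

#' @export
print.dsl_breakdown <- function(x, ...) {
  cat(sprintf("Domain sanity loss: total = %.6g\n", x$total))
  cat(sprintf("  s1 (order)       %.6g  (weight %g)\n", x$s1, x$weights[1]))
  cat(sprintf("  s2 (columns)     %.6g  (weight %g)\n", x$s2, x$weights[2]))
  cat(sprintf("  s3 (distances)   %.6g  (weight %g)\n", x$s3, x$weights[3]))
  cat(sprintf("  s4 (weak mask)   %.6g  (weight %g)\n", x$s4, x$weights[4]))
  invisible(x)
}

# Gradient of the surrogate total with respect to yhat. s3 is evaluated in
# its exact counting form and contributes no gradient (the centroid medians
# are piecewise constant in the pixel values); s1, s2, s4 use the hinge /
# absolute-deviation surrogates with detached medians.
dsl_surrogate_grad <- function(yhat, wm, cfg) {
  g <- matrix(0, nrow(yhat), ncol(yhat))
  nc <- ncol(yhat)
  npix <- dsl_normalizer(yhat, cfg)
  for (s in seq_len(cfg$n_shift)) {
    if (nc - s < 1L) break
    a <- yhat[, 1:(nc - s), drop = FALSE]
    b <- yhat[, (1 + s):nc, drop = FALSE]
    act <- (a - b > 0) & (if (cfg$spine_only_comparisons) a > 0 & b > 0 else TRUE)
    w <- cfg$c1 / npix
    g[, 1:(nc - s)] <- g[, 1:(nc - s)] + w * act
    g[, (1 + s):nc] <- g[, (1 + s):nc] - w * act
  }
  for (j in seq_len(nc)) {
    v <- yhat[, j]
    sel <- if (cfg$spine_only_comparisons) v > 0 else rep(TRUE, length(v))
    if (!any(sel)) next
    med <- median(v[sel])
    g[sel, j] <- g[sel, j] + (cfg$c2 / npix) * sign(v[sel] - med)
  }
  n_c <- length(wm$components)
  if (n_c > 0L) {
    for (coords in wm$components) {
      vals <- yhat[coords]
      med <- median(vals)
      g[coords] <- g[coords] + (cfg$c4 / (n_c * length(vals))) * sign(vals - med)
    }
  }
  g
}
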