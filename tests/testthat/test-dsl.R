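test_that("exact s1, s2 and s4 match the brute-force oracles on random grids", {
  set.seed(101)
  for (rep in 1:40) {
    nr <- sample(2:20, 1); nc <- sample(3:20, 1)
    y <- random_grid(nr, nc)
    ns <- sample.int(nc - 1, 1)
    spine_only <- sample(c(TRUE, FALSE), 1)
    cfg <- dsl_config(n_shift = ns, spine_only_comparisons = spine_only)
    expect_identical(dsl_s1(y, cfg), oracle_s1(y, ns, spine_only))
    expect_identical(dsl_s2(y, cfg), oracle_s2(y, spine_only))
    wm_grid <- matrix(sample(0:4, nr * nc, replace = TRUE), nr, nc)
    expect_identical(dsl_s4(weak_mask(wm_grid), y), oracle_s4(wm_grid, y))
  }
})

test_that("worked values of the four sanity checks are reproduced", {
  cfg2 <- dsl_config(n_shift = 2)
  expect_equal(dsl_s1(matrix(c(3, 2, 1), 1), cfg2), 1.0)
  expect_equal(dsl_s1(matrix(c(1, 1, 2, 2, 3), 1), cfg2), 0.0)
  expect_equal(dsl_s2(matrix(c(2, 2, 3, 2), 4, 1), dsl_config()), 0.25)
  # single adjacent pair deviating 5 mm from its reference: |26-21|/25
  g <- matrix(0, 3, 60)
  g[2, 10] <- 8; g[2, 36] <- 9
  expect_equal(dsl_s3(g, spacing = c(1, 1)), 0.2)
  expect_equal(dsl_s4(weak_mask(matrix(1L, 2, 2)), matrix(c(3, 3, 4, 4), 2)), 1.0)
})

test_that("degenerate inputs give zero loss, not errors", {
  z <- matrix(0, 5, 40)
  cfg <- dsl_config(n_shift = 3)
  expect_equal(dsl_s1(z, cfg), 0)
  expect_equal(dsl_s2(z, cfg), 0)
  expect_equal(dsl_s3(z), 0)
  expect_equal(dsl_s4(weak_mask(matrix(0L, 5, 40)), z), 0)
  # single vertebra: no adjacent pair
  one <- matrix(0, 5, 40); one[3, 10:14] <- 7
  expect_equal(dsl_s3(one), 0)
  # two centroids at exactly the reference distance
  g <- matrix(0, 3, 60); g[2, 10] <- 8; g[2, 31] <- 9
  expect_equal(dsl_s3(g, spacing = c(1, 1)), 0)
})

test_that("n_shift wider than the grid is rejected with advice", {
  expect_error(dsl_s1(matrix(1, 2, 5), dsl_config(n_shift = 5)), "n_shift")
})

test_that("the weighted total combines the terms linearly", {
  # term values (0.1, 0.2, 4, 2) with the standard constants
  cfg <- dsl_config()
  expect_equal(20 * 0.1 + 1 * 0.2 + 4 / 40 + 2 / 100, 2.32)
  y <- matrix(rep(c(0, 5, 5, 6, 6), each = 2), nrow = 2)
  wm <- weak_mask(matrix(rep(c(0, 1, 1, 2, 2), each = 2), nrow = 2))
  bd <- dsl_total(y, wm, cfg = dsl_config(n_shift = 2), spacing = c(1, 22))
  expect_equal(bd$total, 20 * bd$s1 + bd$s2 + bd$s3 / 40 + bd$s4 / 100)
  expect_true(all(c(bd$s1, bd$s2, bd$s3, bd$s4) >= 0))
})

test_that("mask_background zeroes exactly the off-mask pixels", {
  raw <- matrix(runif(12, 1, 5), 3)
  expect_equal(mask_background(raw, matrix(1, 3, 4)), raw)
  expect_equal(mask_background(raw, matrix(0, 3, 4)), matrix(0, 3, 4))
  m <- matrix(c(1, 0), 3, 4)
  out <- mask_background(raw, m)
  expect_true(all(out[m == 0] == 0))
  expect_true(all(out[m == 1] == raw[m == 1]))
  expect_error(mask_background(raw, matrix(1, 2, 2)), "shape")
})

test_that("s1 is invariant to constant shifts of the spine values", {
  set.seed(5)
  y <- random_grid(8, 30)
  cfg <- dsl_config(n_shift = 6)
  y_shift <- y + 3 * (y > 0)
  expect_equal(dsl_s1(y_shift, cfg), dsl_s1(y, cfg))
})

test_that("s3 is invariant under translation of the whole prediction", {
  g <- matrix(0, 10, 80)
  g[4:6, 10:14] <- 9; g[4:6, 32:36] <- 10
  shifted <- corrupt_labels(g, "shift_columns", 7)
  expect_equal(dsl_s3(shifted), dsl_s3(g))
})

test_that("surrogate zero coincides with exact zero", {
  set.seed(6)
  for (rep in 1:25) {
    y <- random_grid(6, 12)
    wm <- weak_mask(matrix(sample(0:3, 72, TRUE), 6, 12))
    ce <- dsl_config(n_shift = 4, mode = "exact")
    cs <- dsl_config(n_shift = 4, mode = "surrogate")
    expect_equal(dsl_s1(y, cs) == 0, dsl_s1(y, ce) == 0)
    expect_equal(dsl_s2(y, cs) == 0, dsl_s2(y, ce) == 0)
    if (dsl_s4(wm, y, cs) == 0) expect_equal(dsl_s4(wm, y, ce), 0)
  }
})

test_that("s2 grows monotonically with the jitter fraction", {
  ph <- generate_phantom(tiny_phantom_config(seed = 12))
  truth <- phantom_slice(ph)$labels
  cfg <- dsl_config()
  mean_s2 <- function(f) mean(vapply(1:20, function(s)
    dsl_s2(corrupt_labels(truth, "jitter_pixels", f, seed = s), cfg), numeric(1)))
  m1 <- mean_s2(0.05); m2 <- mean_s2(0.15); m3 <- mean_s2(0.3)
  expect_lt(m1, m2)
  expect_lt(m2, m3)
})

test_that("the literal >=0 indicator variant counts plateaus as violations", {
  y <- matrix(c(1, 1, 2), 1)
  expect_equal(dsl_s1(y, dsl_config(n_shift = 1)), 0)
  expect_gt(dsl_s1(y, dsl_config(n_shift = 1, strict_ge = TRUE)), 0)
})

test_that("surrogate gradient matches finite differences of the surrogate loss", {
  set.seed(9)
  y <- matrix(runif(60, 0, 4), 6, 10)
  y[sample(60, 15)] <- 0
  wm <- weak_mask(matrix(sample(0:2, 60, TRUE), 6, 10))
  cfg <- dsl_config(n_shift = 3, mode = "surrogate")
  loss <- function(yy) {
    cfg$c1 * dsl_s1(yy, cfg) + cfg$c2 * dsl_s2(yy, cfg) + cfg$c4 * dsl_s4(wm, yy, cfg)
  }
  g <- spinesanity:::dsl_surrogate_grad(y, wm, cfg)
  eps <- 1e-6
  # keep clear of the kinks where the detached-median approximation and the
  # full derivative differ (pixels at or next to a median)
  col_of <- rep(seq_len(ncol(y)), each = nrow(y))
  comp_of <- wm$data
  ok <- vapply(seq_along(y), function(idx) {
    v <- y[, col_of[idx]]
    dmed <- abs(y[idx] - median(v[v > 0]))
    dcomp <- if (comp_of[idx] > 0) {
      abs(y[idx] - median(y[comp_of == comp_of[idx]]))
    } else 1
    y[idx] > 0.1 && dmed > 0.05 && dcomp > 0.05
  }, logical(1))
  for (idx in sample(which(ok), 5)) {
    yp <- y; yp[idx] <- yp[idx] + eps
    ym <- y; ym[idx] <- ym[idx] - eps
    fd <- (loss(yp) - loss(ym)) / (2 * eps)
    expect_equal(g[idx], fd, tolerance = 1e-4)
  }
})
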