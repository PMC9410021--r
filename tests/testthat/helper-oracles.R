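# Independent brute-force implementations of the sanity-check counting
# losses, written as literal loops over the definitions. They are the
# reference the vectorized implementations are checked against and must stay
# independent of the package internals.

oracle_s1 <- function(y, n_shift, spine_only = TRUE, strict_ge = FALSE) {
  nr <- nrow(y); nc <- ncol(y)
  count <- 0L
  for (s in seq_len(n_shift)) {
    for (i in seq_len(nr)) {
      for (j in seq_len(max(nc - s, 0L))) {
        a <- y[i, j]; b <- y[i, j + s]
        if (spine_only && (a <= 0 || b <= 0)) next
        viol <- if (strict_ge) (a - b) >= 0 else (a - b) > 0
        if (viol) count <- count + 1L
      }
    }
  }
  count / length(y)
}

oracle_s2 <- function(y, spine_only = TRUE) {
  count <- 0L
  for (j in seq_len(ncol(y))) {
    v <- y[, j]
    if (spine_only) {
      sel <- v > 0
      if (!any(sel)) next
      med <- median(v[sel])
      count <- count + sum(abs(v[sel] - med) > 0)
    } else {
      med <- median(v)
      count <- count + sum(abs(v - med) > 0)
    }
  }
  count / length(y)
}

oracle_s4 <- function(wm_grid, y) {
  ids <- sort(unique(wm_grid[wm_grid > 0]))
  if (length(ids) == 0L) return(0)
  acc <- 0L
  for (k in ids) {
    vals <- floor(y[wm_grid == k] + 0.5)
    vals <- vals[vals > 0]
    u <- length(unique(vals))
    acc <- acc + max(u - 1L, 0L)
  }
  acc / length(ids)
}

# random masked-prediction-like grid: nonnegative, background zeros
random_grid <- function(nr, nc, p_zero = 0.3, max_id = 6L) {
  vals <- sample(0:max_id, nr * nc, replace = TRUE,
                 prob = c(p_zero, rep((1 - p_zero) / max_id, max_id)))
  matrix(as.numeric(vals), nr, nc)
}
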