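# Brute-force oracles and small fixture builders shared across the suite.

bv <- function(a, vs = 10.5) binary_volume(a, vs)
sv <- function(a, vs = 10.5) scalar_volume(a, vs)

# exhaustive L1 nearest-background search (the independent DT oracle);
# out-of-bounds counts as background
oracle_l1_dt <- function(arr) {
  d <- dim(arr)
  out <- array(0, dim = d)
  fg <- which(arr == 1L)
  if (length(fg) == 0L) return(out)
  bg <- arrayInd(which(arr == 0L), d)
  for (lin in fg) {
    p <- arrayInd(lin, d)
    best <- min(p[1], d[1] - p[1] + 1L, p[2], d[2] - p[2] + 1L,
                p[3], d[3] - p[3] + 1L)   # distance through the boundary
    if (nrow(bg) > 0) {
      best <- min(best, min(abs(bg[, 1] - p[1]) + abs(bg[, 2] - p[2]) +
                              abs(bg[, 3] - p[3])))
    }
    out[lin] <- best
  }
  out
}

# direct truncated-Gaussian separable convolution with reflect padding
oracle_gaussian <- function(arr, sigma, truncate) {
  r <- ceiling(truncate * sigma)
  w <- exp(-(-r:r)^2 / (2 * sigma^2)); w <- w / sum(w)
  d <- dim(arr)
  reflect <- function(i, n) {
    m <- ((i - 1) %% (2 * n) + 2 * n) %% (2 * n)
    ifelse(m < n, m + 1, 2 * n - m)
  }
  out <- array(0, dim = d)
  tmp <- arr
  for (axis in 1:3) {
    res <- array(0, dim = d)
    n <- d[axis]
    for (off in -r:r) {
      idx <- reflect(seq_len(n) + off, n)
      sl <- switch(axis, tmp[idx, , , drop = FALSE],
                   tmp[, idx, , drop = FALSE], tmp[, , idx, drop = FALSE])
      res <- res + w[off + r + 1] * sl
    }
    tmp <- res
  }
  tmp
}

# flat slab pair: baseline slab plus one added layer region on top
slab_pair <- function(d = c(7, 7, 7), slab_z = 2:4, grow_z = 5,
                      extent = 2:6) {
  base <- array(0L, dim = d)
  base[slab_z, extent, extent] <- 1L
  foll <- base
  foll[grow_z, extent, extent] <- 1L
  list(baseline = bv(base), followup = bv(foll),
       mask = bv(array(1L, dim = d)))
}

# a minimal rmv_curve for fitting tests, sampled from a known function
curve_from_fn <- function(fn, ms = seq(6, 594, length.out = 100),
                          counts = rep(10L, length(ms))) {
  mechanostat:::new_rmv_curve(
    tibble::tibble(bin = seq_along(ms), signal = ms, rmv = fn(ms),
                   counts = counts, n_samples = 3L),
    cap = max(ms) + diff(ms[1:2]) / 2, voxel_size = 10.5,
    interval_days = 7)
}

# crafted surface table with given per-bin event counts (n_bins bins on
# a unit cap); used to hand-check probability normalization
table_from_counts <- function(counts_by_event, n_bins) {
  rows <- list()
  for (e in names(counts_by_event)) {
    cnt <- counts_by_event[[e]]
    for (b in seq_len(n_bins)) {
      if (cnt[b] > 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          event = factor(rep(e, cnt[b]),
                         levels = c("formation", "quiescence",
                                    "resorption")),
          signal = rep((b - 0.5) / n_bins, cnt[b]))
      }
    }
  }
  dplyr::bind_rows(rows)
}

default_truth <- function(interval_days = 7, noise = 0) {
  mechanostat_truth(
    "piecewise",
    c(RSL = -2, RVM = 0.04, RT = 150, FT = 300, FVM = 0.02, FSL = 2),
    interval_days = interval_days, voxel_size = 10.5, noise = noise)
}
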