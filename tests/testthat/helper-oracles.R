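# Independent brute-force oracles and small fixture builders used across
# the test files. These deliberately avoid the package's computational
# paths: plain R loops, dense convolutions, polynomial root-finding.

# symmetric reflection with edge repeat, matching the documented boundary rule
reflect_idx <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i else i <- 2 * n + 1 - i
  }
  i
}

# dense separable correlation of a 3D array with a centered window along
# one axis, reflected boundaries, written as explicit loops
slow_conv_axis <- function(arr, w, axis) {
  d <- dim(arr)
  R <- (length(w) - 1) / 2
  out <- array(0, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    acc <- 0
    for (t in -R:R) {
      idx <- c(i, j, k)
      idx[axis] <- reflect_idx(idx[axis] + t, d[axis])
      acc <- acc + w[t + R + 1] * arr[idx[1], idx[2], idx[3]]
    }
    out[i, j, k] <- acc
  }
  out
}

# independent discrete Gaussian smoothing (same kernel definition: sampled,
# sum-normalized, radius ceiling(3 s)), done with stats::filter-free loops
slow_gauss_smooth <- function(arr, s) {
  r <- max(1, ceiling(3 * s))
  tt <- -r:r
  g <- exp(-tt^2 / (2 * s^2))
  g <- g / sum(g)
  for (ax in 1:3) arr <- slow_conv_axis(arr, g, ax)
  arr
}

# central finite differences along an axis (interior only is meaningful)
central_diff <- function(arr, axis, order = 1) {
  d <- dim(arr)
  shift <- function(arr, by) {
    idx <- lapply(seq_along(d), function(a) seq_len(d[a]))
    idx[[axis]] <- pmin(pmax(idx[[axis]] + by, 1), d[axis])
    do.call(`[`, c(list(arr), idx))
  }
  if (order == 1) (shift(arr, 1) - shift(arr, -1)) / 2
  else shift(arr, 1) - 2 * arr + shift(arr, -1)
}

# eigenvalues via the characteristic polynomial and polyroot(), sorted by
# magnitude with signed-ascending tie-break
eig3_polyroot <- function(m) {
  c2 <- m[1, 1] + m[2, 2] + m[3, 3]
  c1 <- m[1, 1] * m[2, 2] + m[1, 1] * m[3, 3] + m[2, 2] * m[3, 3] -
    m[1, 2]^2 - m[1, 3]^2 - m[2, 3]^2
  c0 <- det(m)
  roots <- Re(polyroot(c(-c0, c1, -c2, 1)))
  roots[order(abs(roots), roots)]
}

# brute-force stack-based flood fill over 26-neighbors with an inclusion
# threshold, independent of the BFS in the package
slow_flood_fill <- function(vals, seed, thr) {
  d <- dim(vals)
  mask <- array(FALSE, d)
  mask[seed[1], seed[2], seed[3]] <- TRUE
  stack <- list(seed)
  while (length(stack) > 0) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      p <- cur + c(dz, dy, dx)
      if (any(p < 1) || any(p > d)) next
      if (!mask[p[1], p[2], p[3]] && vals[p[1], p[2], p[3]] >= thr) {
        mask[p[1], p[2], p[3]] <- TRUE
        stack[[length(stack) + 1]] <- p
      }
    }
  }
  mask
}

# smooth random test volume: low-frequency mixture of a few Gaussian bumps
smooth_random_volume <- function(n = 16, n_bumps = 4, seed = 1) {
  withr::with_seed(seed, {
    arr <- array(0, c(n, n, n))
    for (b in seq_len(n_bumps)) {
      ctr <- runif(3, 4, n - 3)
      sig <- runif(1, 2, 4)
      amp <- runif(1, 0.3, 1)
      d2 <- outer(outer((seq_len(n) - ctr[1])^2, (seq_len(n) - ctr[2])^2, "+"),
                  (seq_len(n) - ctr[3])^2, "+")
      arr <- arr + amp * exp(-d2 / (2 * sig^2))
    }
    arr / max(arr)
  })
}

# isolated Gaussian blob volume (sigma in voxels), peak 1 at the center
gaussian_blob_volume <- function(n, sigma, center = rep((n + 1) / 2, 3)) {
  d2 <- outer(outer((seq_len(n) - center[1])^2, (seq_len(n) - center[2])^2, "+"),
              (seq_len(n) - center[3])^2, "+")
  as_volume(exp(-d2 / (2 * sigma^2)))
}

# straight soft-edged tube along x plus optionally an attached sphere, both
# with flat cores and Gaussian edges of unit width (as the phantom module)
tube_volume <- function(n = 48, tube_r = 3, sphere_r = NULL, sphere_offset = NULL) {
  prof <- function(d, r) {
    rc <- pmax(r - sqrt(2 * log(2)), 0.5)
    exp(-pmax(d - rc, 0)^2 / 2)
  }
  zc <- n / 2; yc <- n / 2
  dzy <- sqrt(outer((seq_len(n) - zc)^2, (seq_len(n) - yc)^2, "+"))
  tube2d <- prof(dzy, tube_r)
  arr <- array(rep(tube2d, n), c(n, n, n))
  if (!is.null(sphere_r)) {
    ctr <- c(zc + tube_r + sphere_r, yc, n / 2)
    if (!is.null(sphere_offset)) ctr <- sphere_offset
    d2 <- outer(outer((seq_len(n) - ctr[1])^2, (seq_len(n) - ctr[2])^2, "+"),
                (seq_len(n) - ctr[3])^2, "+")
    arr <- pmax(arr, prof(sqrt(d2), sphere_r))
  }
  as_volume(arr)
}
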