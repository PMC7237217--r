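# Independent brute-force oracles used to verify the fast implementations.
# These deliberately share no code with the package internals.

# Dense 2D convolution (correlation with symmetric/antisymmetric kernels,
# matching the package's convention) with symmetric reflect padding.
brute_conv2 <- function(img, kernel) {
  ny <- nrow(img); nx <- ncol(img)
  ry <- (nrow(kernel) - 1) / 2; rx <- (ncol(kernel) - 1) / 2
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, ny, nx)
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    acc <- 0
    for (j in seq_len(nrow(kernel))) for (k in seq_len(ncol(kernel))) {
      yy <- refl(y + j - 1 - ry, ny)
      xx <- refl(x + k - 1 - rx, nx)
      acc <- acc + kernel[j, k] * img[yy, xx]
    }
    out[y, x] <- acc
  }
  out
}

# Proximity target by direct per-pixel evaluation of every kernel
# (max semantics, unit peak, zero beyond 3 sigma).
brute_target <- function(region, points, sigma) {
  sy <- sigma[1]; sx <- if (length(sigma) > 1) sigma[2] else sigma[1]
  ys <- region[1]:region[3]; xs <- region[2]:region[4]
  out <- matrix(0, length(ys), length(xs))
  for (iy in seq_along(ys)) for (ix in seq_along(xs)) {
    best <- 0
    if (!is.null(points) && nrow(points) > 0) {
      for (p in seq_len(nrow(points))) {
        m <- (ys[iy] - points[p, 1])^2 / (2 * sy^2) +
             (xs[ix] - points[p, 2])^2 / (2 * sx^2)
        v <- if (m > 4.5) 0 else exp(-m)
        if (v > best) best <- v
      }
    }
    out[iy, ix] <- best
  }
  out
}

# Exhaustive-enumeration optimal matching: maximum number of pairs within
# `tol`, ties broken by minimum total distance.  Feasible for <= 8 points.
brute_match <- function(P, G, tol) {
  nP <- nrow(P); nG <- nrow(G)
  if (nP == 0 || nG == 0) return(list(count = 0, total = 0))
  d <- matrix(0, nP, nG)
  for (i in seq_len(nP)) for (j in seq_len(nG))
    d[i, j] <- sqrt(sum((P[i, ] - G[j, ])^2))
  best <- list(count = 0, total = 0)
  recurse <- function(i, used, count, total) {
    if (i > nP) {
      if (count > best$count ||
          (count == best$count && total < best$total - 1e-12))
        best <<- list(count = count, total = total)
      return(invisible())
    }
    recurse(i + 1, used, count, total)  # leave i unmatched
    for (j in seq_len(nG)) {
      if (!used[j] && d[i, j] <= tol + 1e-9) {
        used[j] <- TRUE
        recurse(i + 1, used, count + 1, total + d[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1, rep(FALSE, nG), 0, 0)
  best
}

# Greedy nearest-first matching (for comparison with optimal).
greedy_match <- function(P, G, tol) {
  nP <- nrow(P); nG <- nrow(G)
  if (nP == 0 || nG == 0) return(0)
  d <- matrix(0, nP, nG)
  for (i in seq_len(nP)) for (j in seq_len(nG))
    d[i, j] <- sqrt(sum((P[i, ] - G[j, ])^2))
  d[d > tol] <- Inf
  count <- 0
  while (any(is.finite(d))) {
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    count <- count + 1
    d[ij[1], ] <- Inf
    d[, ij[2]] <- Inf
  }
  count
}

# Dense separable 3D convolution via explicit shifted adds with reflect
# padding (small volumes only).
brute_conv3 <- function(vol, kz, ky, kx) {
  d <- dim(vol)
  refl_idx <- function(n, r) {
    idx <- (1 - r):(n + r)
    vapply(idx, function(i) {
      while (i < 1 || i > n) {
        if (i < 1) i <- 1 - i
        if (i > n) i <- 2 * n + 1 - i
      }
      i
    }, 0)
  }
  rz <- (length(kz) - 1) / 2; ry <- (length(ky) - 1) / 2
  rx <- (length(kx) - 1) / 2
  pz <- refl_idx(d[1], rz); py <- refl_idx(d[2], ry); px <- refl_idx(d[3], rx)
  pad <- vol[pz, py, px, drop = FALSE]
  out <- array(0, d)
  for (a in seq_along(kz)) for (b in seq_along(ky)) for (cc in seq_along(kx)) {
    w <- kz[a] * ky[b] * kx[cc]
    if (w == 0) next
    out <- out + w * pad[(a - 1) + seq_len(d[1]),
                         (b - 1) + seq_len(d[2]),
                         (cc - 1) + seq_len(d[3]), drop = FALSE]
  }
  out
}

# Determinant-of-Hessian response by dense convolution (oracle for
# hessian_enhance + find_maxima on small volumes): returns max(0, -det).
brute_doh <- function(vol, sigma) {
  g <- lapply(sigma, centrofind:::gaussian_kernel_1d, order = 0)
  g1 <- lapply(sigma, centrofind:::gaussian_kernel_1d, order = 1)
  g2 <- lapply(sigma, centrofind:::gaussian_kernel_1d, order = 2)
  dzz <- brute_conv3(vol, g2[[1]], g[[2]], g[[3]])
  dyy <- brute_conv3(vol, g[[1]], g2[[2]], g[[3]])
  dxx <- brute_conv3(vol, g[[1]], g[[2]], g2[[3]])
  dzy <- brute_conv3(vol, g1[[1]], g1[[2]], g[[3]])
  dzx <- brute_conv3(vol, g1[[1]], g[[2]], g1[[3]])
  dyx <- brute_conv3(vol, g[[1]], g1[[2]], g1[[3]])
  det <- dzz * (dyy * dxx - dyx^2) - dzy * (dzy * dxx - dyx * dzx) +
    dzx * (dzy * dyx - dyy * dzx)
  pmax(-det, 0)
}

# Exhaustive local-maximum scan over an ellipsoidal neighbourhood.
brute_local_max <- function(vol, h, threshold) {
  d <- dim(vol)
  hits <- NULL
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    v <- vol[z, y, x]
    if (v <= threshold) next
    ok <- TRUE
    for (dz in -floor(h[1]):floor(h[1])) {
      for (dy in -floor(h[2]):floor(h[2])) {
        for (dx in -floor(h[3]):floor(h[3])) {
          if (dz == 0 && dy == 0 && dx == 0) next
          if ((dz / h[1])^2 + (dy / h[2])^2 + (dx / h[3])^2 > 1) next
          zz <- z + dz; yy <- y + dy; xx <- x + dx
          if (zz < 1 || zz > d[1] || yy < 1 || yy > d[2] ||
              xx < 1 || xx > d[3]) next
          if (vol[zz, yy, xx] > v) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (!ok) break
    }
    if (ok) hits <- rbind(hits, c(z - 1, y - 1, x - 1, v))
  }
  hits
}

# 3D Gaussian blob (intensity profile, not normalized) at a real-valued
# centre, used as a synthetic isolated-object fixture.
gaussian_blob <- function(dims, centre, sigma) {
  zs <- seq_len(dims[1]) - 1; ys <- seq_len(dims[2]) - 1
  xs <- seq_len(dims[3]) - 1
  az <- exp(-(zs - centre[1])^2 / (2 * sigma^2))
  ay <- exp(-(ys - centre[2])^2 / (2 * sigma^2))
  ax <- exp(-(xs - centre[3])^2 / (2 * sigma^2))
  outer(outer(az, ay), ax)
}
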