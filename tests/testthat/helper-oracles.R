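# Independent oracles used to cross-check the package's numerical kernels.
# These deliberately share no code with the implementation: pure-R trilinear
# interpolation, a dense fixed-step ray marcher, a loop-based STAPLE EM, and
# a +y-ray point-in-polygon test.

# Vectorized pure-R trilinear interpolation with zero padding.
# occ: logical array; U: n x 3 continuous 0-based index coordinates.
oracleTrilinear <- function(occ, U) {
  U <- rbind(U)
  n <- dim(occ)
  N <- nrow(U)
  i0 <- floor(U)
  f <- U - i0
  acc <- numeric(N)
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    i <- i0[, 1] + di; j <- i0[, 2] + dj; k <- i0[, 3] + dk
    w <- (if (di) f[, 1] else 1 - f[, 1]) *
         (if (dj) f[, 2] else 1 - f[, 2]) *
         (if (dk) f[, 3] else 1 - f[, 3])
    ok <- i >= 0 & j >= 0 & k >= 0 & i < n[1] & j < n[2] & k < n[3]
    v <- numeric(N)
    if (any(ok)) v[ok] <- occ[cbind(i[ok], j[ok], k[ok]) + 1]
    acc <- acc + w * v
  }
  acc
}

# physical mm point(s) -> 0-based index coordinates, from first principles
oracleToIndex <- function(vol, P) {
  P <- rbind(P)
  rel <- sweep(P, 2L, gridOrigin(vol), `-`) %*% axisDirections(vol)
  sweep(rel, 2L, voxelSpacing(vol), `/`)
}

# Dense fixed-step ray marcher: the brute-force reference for the
# bisection-based caster. Step 0.005 * min(spacing); crossings are taken as
# bracket midpoints (resolution 0.0025 * min(spacing) mm).
oracleCastRay <- function(gtv, ctv, startMm, d, barrier = NULL,
                          graceMm = 0.05, capMm = NULL) {
  sp <- voxelSpacing(gtv)
  step <- 0.005 * min(sp)
  if (is.null(capMm)) capMm <- sqrt(sum((dim(gtv) * sp)^2))
  ts <- seq(0, capMm, by = step)
  P <- outer(ts, d) + matrix(startMm, length(ts), 3, byrow = TRUE)
  U <- oracleToIndex(gtv, P)
  og <- oracleTrilinear(occupancy(gtv), U)
  if (og[1] >= 0.5) {
    iExit <- which(og < 0.5)[1]
    if (is.na(iExit)) return(list(status = "failed"))
    tStart <- (ts[iExit - 1] + ts[iExit]) / 2
  } else {
    tStart <- 0
  }
  oc <- oracleTrilinear(occupancy(ctv), U)
  ocStart <- oracleTrilinear(occupancy(ctv),
                             oracleToIndex(ctv, startMm + tStart * d))
  if (ocStart < 0.5)
    return(list(status = "clamped", tStart = tStart, tEnd = tStart,
                lengthMm = 0))
  after <- ts > tStart
  iC <- which(after & oc < 0.5)[1]
  if (is.na(iC)) return(list(status = "failed"))
  tEnd <- (ts[iC - 1] + ts[iC]) / 2
  between <- ts > tStart + graceMm & ts < tEnd
  if (any(between & og >= 0.5)) return(list(status = "rejected_interior"))
  if (!is.null(barrier)) {
    ob <- oracleTrilinear(occupancy(barrier), U)
    if (any(ts > tStart & ts < tEnd & ob >= 0.5))
      return(list(status = "rejected_barrier"))
  }
  list(status = "accepted", tStart = tStart, tEnd = tEnd,
       lengthMm = tEnd - tStart)
}

# Loop-based STAPLE EM with the same conventions as the implementation
# (union bounding box dilated by one voxel, scalar prior fixed at the mean
# rater foreground fraction, both performance parameters initialized to
# 0.99999, mean-absolute posterior change stopping rule), but coded with
# explicit per-voxel loops and probability products instead of vectorized
# log-space algebra.
oracleStaple <- function(masks, threshold = 0.5, maxIter = 100, tol = 1e-6) {
  K <- length(masks)
  n <- dim(masks[[1]])
  un <- Reduce(`|`, lapply(masks, occupancy))
  idx <- which(un, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - 1, 1)
  hi <- pmin(apply(idx, 2, max) + 1, n)
  D <- sapply(masks, function(m)
    as.numeric(occupancy(m)[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]))
  D <- matrix(D, ncol = K)
  V <- nrow(D)
  prior <- mean(colMeans(D))
  p <- rep(0.99999, K); q <- rep(0.99999, K)
  W <- rep(prior, V)
  for (iter in seq_len(maxIter)) {
    Wnew <- numeric(V)
    for (v in seq_len(V)) {
      a <- prior; b <- 1 - prior
      for (j in seq_len(K)) {
        pj <- min(max(p[j], 1e-12), 1 - 1e-12)
        qj <- min(max(q[j], 1e-12), 1 - 1e-12)
        if (D[v, j] == 1) { a <- a * pj; b <- b * (1 - qj) }
        else { a <- a * (1 - pj); b <- b * qj }
      }
      Wnew[v] <- if (a + b > 0) a / (a + b) else prior
    }
    delta <- mean(abs(Wnew - W))
    W <- Wnew
    for (j in seq_len(K)) {
      p[j] <- sum(W * D[, j]) / sum(W)
      q[j] <- sum((1 - W) * (1 - D[, j])) / sum(1 - W)
    }
    if (delta < tol) break
  }
  prob <- array(0, n)
  prob[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- W
  list(prob = prob, p = p, q = q)
}

# Even-odd containment via a +y ray (the implementation casts in +x).
oraclePointInPolygons <- function(p, polys) {
  crossTotal <- 0
  for (poly in polys) {
    nv <- nrow(poly)
    j <- nv
    for (i in seq_len(nv)) {
      x1 <- poly[j, 1]; y1 <- poly[j, 2]
      x2 <- poly[i, 1]; y2 <- poly[i, 2]
      if (x1 != x2 && ((x1 > p[1]) != (x2 > p[1]))) {
        yi <- y1 + (p[1] - x1) * (y2 - y1) / (x2 - x1)
        if (p[2] < yi) crossTotal <- crossTotal + 1
      }
      j <- i
    }
  }
  crossTotal %% 2 == 1
}

# ---- small fixture builders -------------------------------------------------

# Solid k^3 cube of foreground centered in a padded grid.
cubeVolume <- function(k, pad = 2, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  n <- k + 2 * pad
  occ <- array(FALSE, c(n, n, n))
  occ[pad + seq_len(k), pad + seq_len(k), pad + seq_len(k)] <- TRUE
  BinaryVolume(occ, spacing, origin)
}

# Axis-aligned box mask from voxel-center bounds (mm) on a given grid.
boxVolume <- function(lower, upper, n, spacing = c(1, 1, 1),
                      origin = c(0, 0, 0)) {
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(n[a]) - 1) * spacing[a])
  inside1 <- ax[[1]] >= lower[1] & ax[[1]] <= upper[1]
  inside2 <- ax[[2]] >= lower[2] & ax[[2]] <= upper[2]
  inside3 <- ax[[3]] >= lower[3] & ax[[3]] <= upper[3]
  occ <- array(outer(outer(inside1, inside2, `&`), inside3, `&`), n)
  BinaryVolume(occ, spacing, origin)
}

# closed-form surface voxel count of an a x b x c solid box
boxSurfaceCount <- function(a, b, c) {
  a * b * c - max(a - 2, 0) * max(b - 2, 0) * max(c - 2, 0)
}

# rigid -90-degree rotation about the grid z axis: index (i, j, k) maps to
# (j, n1 + 1 - i, k); the matching direction transform is
# (dx, dy, dz) -> (dy, -dx, dz) and spacing permutes to (s2, s1, s3).
rotateVolumeZ <- function(vol) {
  occ <- occupancy(vol)
  n <- dim(occ)
  occ2 <- aperm(occ, c(2, 1, 3))[, rev(seq_len(n[1])), , drop = FALSE]
  BinaryVolume(occ2, voxelSpacing(vol)[c(2, 1, 3)], gridOrigin(vol))
}

rotateDirectionZ <- function(d) c(d[2], -d[1], d[3])
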