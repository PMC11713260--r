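## Low-level grid numerics shared by all modules: trilinear sampling,
## separable Gaussian smoothing, Euclidean distance transforms, binary
## morphology and connected components.  Everything works on plain 3D
## arrays; geometry (spacing/origin) is handled by the callers.

## World <-> continuous 1-based index coordinates.
.worldToIndex <- function(pts, spacing, origin) {
  sweep(sweep(pts, 2, origin, "-"), 2, spacing, "/") + 1
}

.indexToWorld <- function(idx, spacing, origin) {
  sweep(sweep(idx - 1, 2, spacing, "*"), 2, origin, "+")
}

## Voxel-centre world coordinates of every voxel, as an n x 3 matrix in
## array order (first index fastest).
.voxelCentres <- function(d, spacing, origin) {
  cbind(origin[1] + (rep.int(seq_len(d[1]), d[2] * d[3]) - 1) * spacing[1],
        origin[2] + (rep.int(rep(seq_len(d[2]), each = d[1]), d[3]) - 1) *
          spacing[2],
        origin[3] + (rep(seq_len(d[3]), each = d[1] * d[2]) - 1) * spacing[3])
}

## Trilinear interpolation of a 3D array at continuous 1-based index
## coordinates (n x 3 matrix).  Points outside the grid return `pad`.
.interpTrilinear <- function(a, idx, pad = 0) {
  d <- dim(a)
  n <- nrow(idx)
  out <- rep.int(pad, n)
  eps <- 1e-6  # voxel units: tolerate round-off at the grid boundary
  inside <- idx[, 1] >= 1 - eps & idx[, 1] <= d[1] + eps &
    idx[, 2] >= 1 - eps & idx[, 2] <= d[2] + eps &
    idx[, 3] >= 1 - eps & idx[, 3] <= d[3] + eps
  if (!any(inside)) return(out)
  x <- pmin(pmax(idx[inside, 1], 1), d[1])
  y <- pmin(pmax(idx[inside, 2], 1), d[2])
  z <- pmin(pmax(idx[inside, 3], 1), d[3])
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), max(d[2] - 1L, 1L))
  z0 <- pmin(floor(z), max(d[3] - 1L, 1L))
  x0 <- pmax(x0, 1L); y0 <- pmax(y0, 1L); z0 <- pmax(z0, 1L)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  x1 <- pmin(x0 + 1L, d[1]); y1 <- pmin(y0 + 1L, d[2]); z1 <- pmin(z0 + 1L, d[3])
  v <- a[cbind(x0, y0, z0)] * (1 - fx) * (1 - fy) * (1 - fz) +
    a[cbind(x1, y0, z0)] * fx * (1 - fy) * (1 - fz) +
    a[cbind(x0, y1, z0)] * (1 - fx) * fy * (1 - fz) +
    a[cbind(x1, y1, z0)] * fx * fy * (1 - fz) +
    a[cbind(x0, y0, z1)] * (1 - fx) * (1 - fy) * fz +
    a[cbind(x1, y0, z1)] * fx * (1 - fy) * fz +
    a[cbind(x0, y1, z1)] * (1 - fx) * fy * fz +
    a[cbind(x1, y1, z1)] * fx * fy * fz
  out[inside] <- v
  out
}

## Nearest-neighbour sampling at continuous 1-based index coordinates.
.interpNearest <- function(a, idx, pad = 0) {
  d <- dim(a)
  out <- rep.int(pad, nrow(idx))
  i <- round(idx)
  inside <- i[, 1] >= 1 & i[, 1] <= d[1] & i[, 2] >= 1 & i[, 2] <= d[2] &
    i[, 3] >= 1 & i[, 3] <= d[3]
  out[inside] <- a[i[inside, , drop = FALSE]]
  out
}

## 1D Gaussian convolution matrix with kernel renormalised at the borders
## (truncated at 4 sigma).  sigma in voxel units.
.gaussMatrix <- function(n, sigma) {
  if (sigma <= 0 || n == 1L) return(diag(n))
  r <- min(n - 1L, max(1L, ceiling(4 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - r):min(n, i + r)
    w <- k[j - i + r + 1L]
    K[i, j] <- w / sum(w)
  }
  K
}

## Separable Gaussian smoothing of a 3D array; sigma per axis in voxels.
.smoothGaussian <- function(a, sigma) {
  d <- dim(a)
  sigma <- rep_len(sigma, 3L)
  if (sigma[1] > 0 && d[1] > 1L)
    a <- array(.gaussMatrix(d[1], sigma[1]) %*% matrix(a, d[1]), d)
  if (sigma[2] > 0 && d[2] > 1L) {
    a <- aperm(a, c(2L, 1L, 3L))
    a <- array(.gaussMatrix(d[2], sigma[2]) %*% matrix(a, d[2]),
               d[c(2, 1, 3)])
    a <- aperm(a, c(2L, 1L, 3L))
  }
  if (sigma[3] > 0 && d[3] > 1L) {
    a <- aperm(a, c(3L, 2L, 1L))
    a <- array(.gaussMatrix(d[3], sigma[3]) %*% matrix(a, d[3]),
               d[c(3, 2, 1)])
    a <- aperm(a, c(3L, 2L, 1L))
  }
  a
}

## 1D squared-distance transform (lower envelope of parabolas), positions
## x_i = (i-1) * h.  f: squared distances (may be Inf).
.dt1d <- function(f, h) {
  n <- length(f)
  if (all(is.infinite(f))) return(f)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  h2 <- h * h
  for (q in seq_len(n)[-1L]) {
    if (is.infinite(f[q])) next
    repeat {
      p <- v[k]
      s <- ((f[q] + h2 * (q - 1)^2) - (f[p] + h2 * (p - 1)^2)) /
        (2 * h * (q - p))
      if (k > 1L && s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  d <- numeric(n); k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < (q - 1) * h) k <- k + 1L
    d[q] <- h2 * (q - v[k])^2 + f[v[k]]
  }
  d
}

## Euclidean distance (mm) from every voxel to the nearest TRUE voxel.
.distanceTransform <- function(mask, spacing) {
  d <- dim(mask)
  f <- array(ifelse(mask, 0, Inf), d)
  f <- array(apply(f, c(2, 3), .dt1d, h = spacing[1]), d)
  f <- aperm(array(apply(aperm(f, c(2, 1, 3)), c(2, 3), .dt1d,
                         h = spacing[2]), d[c(2, 1, 3)]), c(2, 1, 3))
  f <- aperm(array(apply(aperm(f, c(3, 2, 1)), c(2, 3), .dt1d,
                         h = spacing[3]), d[c(3, 2, 1)]), c(3, 2, 1))
  sqrt(f)
}

.dilateMask <- function(mask, r_mm, spacing) {
  if (r_mm <= 0 || !any(mask)) return(mask)
  .distanceTransform(mask, spacing) <= r_mm
}

.erodeMask <- function(mask, r_mm, spacing) {
  if (r_mm <= 0) return(mask)
  if (all(mask)) return(mask)
  .distanceTransform(!mask, spacing) > r_mm
}

.closeMask <- function(mask, r_mm, spacing) {
  .erodeMask(.dilateMask(mask, r_mm, spacing), r_mm, spacing)
}

## Largest 6-connected component of a binary mask (igraph under the hood).
.largestComponent <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(mask)
  d <- dim(mask)
  lab <- array(0L, d)
  lab[idx] <- seq_along(idx)
  edges <- vector("list", 3L)
  a <- lab[-d[1], , , drop = FALSE]; b <- lab[-1, , , drop = FALSE]
  s <- a > 0L & b > 0L; edges[[1]] <- cbind(a[s], b[s])
  a <- lab[, -d[2], , drop = FALSE]; b <- lab[, -1, , drop = FALSE]
  s <- a > 0L & b > 0L; edges[[2]] <- cbind(a[s], b[s])
  a <- lab[, , -d[3], drop = FALSE]; b <- lab[, , -1, drop = FALSE]
  s <- a > 0L & b > 0L; edges[[3]] <- cbind(a[s], b[s])
  e <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(e)) g <- igraph::add_edges(g, t(e))
  comp <- igraph::components(g)
  keep <- idx[comp$membership == which.max(comp$csize)]
  out <- array(FALSE, d)
  out[keep] <- TRUE
  out
}

## Central-difference gradient of a 3D array, per-axis spacing in mm.
## Returns a 4D array [d, 3] in units of value/mm (one-sided at borders).
.gradient3 <- function(a, spacing) {
  d <- dim(a)
  g <- array(0, c(d, 3L))
  ix <- function(n) list(lo = c(1L, seq_len(n - 1L)),
                         hi = c(seq_len(n - 1L) + 1L, n),
                         den = c(1L, rep(2L, max(n - 2L, 0L)), 1L))
  if (d[1] > 1L) {
    s <- ix(d[1])
    g[, , , 1] <- (a[s$hi, , , drop = FALSE] - a[s$lo, , , drop = FALSE]) /
      (array(rep(s$den, d[2] * d[3]), d) * spacing[1])
  }
  if (d[2] > 1L) {
    s <- ix(d[2])
    g[, , , 2] <- (a[, s$hi, , drop = FALSE] - a[, s$lo, , drop = FALSE]) /
      (array(rep(rep(s$den, each = d[1]), d[3]), d) * spacing[2])
  }
  if (d[3] > 1L) {
    s <- ix(d[3])
    g[, , , 3] <- (a[, , s$hi, drop = FALSE] - a[, , s$lo, drop = FALSE]) /
      (array(rep(s$den, each = d[1] * d[2]), d) * spacing[3])
  }
  g
}

.sameGeometry <- function(a, b, tol = 1e-6) {
  identical(gridDim(a), gridDim(b)) &&
    max(abs(gridSpacing(a) - gridSpacing(b))) <= tol &&
    max(abs(gridOrigin(a) - gridOrigin(b))) <= tol
}

.stopGeometry <- function(a, b, what = "inputs") {
  if (!.sameGeometry(a, b))
    stop(sprintf("geometry mismatch: %s must share grid dim, spacing and origin",
                 what))
  invisible(TRUE)
}
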