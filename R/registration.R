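## Rigid initialization + multi-resolution demons-style deformable
## registration, and the displacement-field algebra (apply / compose /
## invert / Jacobian) that the whole dose-accumulation workflow runs on.

#' Registration parameters
#'
#' Parameters of the multi-resolution demons-style free-form registration.
#' The similarity drive is the intensity difference after an optional
#' preprocessing step: \code{"meansq_histmatch"} quantile-matches the moving
#' image onto the fixed intensities before a mean-squares demons force
#' (robust to the global contrast/level shifts typical of CBCT), while
#' \code{"lncc"} locally normalises both images (subtract local mean,
#' divide by local standard deviation over a Gaussian window) which makes
#' the force invariant to smooth multiplicative intensity fields.
#'
#' @param levels number of pyramid levels (coarsest is
#'   \code{2^(levels-1)}-fold downsampled).
#' @param iterations iterations per level, coarse to fine; recycled to
#'   \code{levels}.
#' @param sigma_update_mm Gaussian smoothing of each update field, mm
#'   (fluid-like regularisation).
#' @param sigma_field_mm Gaussian smoothing of the total field, mm
#'   (elastic-like regularisation).
#' @param metric "meansq_histmatch" or "lncc".
#' @param lncc_window_mm Gaussian window for the local normalisation, mm.
#' @param max_step_mm maximum update step per iteration, mm.
#' @param tol relative metric improvement below which a level stops
#'   (evaluated over the last \code{patience} iterations).
#' @param patience iterations without sufficient improvement before a level
#'   stops.
#' @param restrict_mask optional 3D logical array on the fixed grid; update
#'   forces outside it are zeroed.
#' @return a list of class \code{"RegistrationParams"}.
#' @export
registrationParams <- function(levels = 4L,
                               iterations = c(150L, 150L, 100L, 80L),
                               sigma_update_mm = 10,
                               sigma_field_mm = 2,
                               metric = c("meansq_histmatch", "lncc"),
                               lncc_window_mm = 12,
                               max_step_mm = 2,
                               tol = 1e-6,
                               patience = 15L,
                               restrict_mask = NULL) {
  metric <- match.arg(metric)
  stopifnot(levels >= 1L, sigma_update_mm >= 0, sigma_field_mm >= 0)
  structure(list(levels = as.integer(levels),
                 iterations = rep_len(as.integer(iterations), levels),
                 sigma_update_mm = sigma_update_mm,
                 sigma_field_mm = sigma_field_mm,
                 metric = metric,
                 lncc_window_mm = lncc_window_mm,
                 max_step_mm = max_step_mm,
                 tol = tol,
                 patience = as.integer(patience),
                 restrict_mask = restrict_mask),
            class = "RegistrationParams")
}

## ---- rigid ---------------------------------------------------------------

.rigidMatrix <- function(rotation_deg) {
  r <- rotation_deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Apply a rigid transform to world points
#'
#' @param transform a \linkS4class{RigidTransform}.
#' @param pts numeric matrix (n x 3) of world points, mm.
#' @return transformed points (n x 3), mm.
#' @export
applyRigidToPoints <- function(transform, pts) {
  R <- .rigidMatrix(transform@rotation)
  sweep(sweep(pts, 2, transform@center, "-") %*% t(R), 2,
        transform@center + transform@translation, "+")
}

#' Invert a rigid transform
#'
#' @param transform a \linkS4class{RigidTransform}.
#' @return the inverse \linkS4class{RigidTransform} (same centre).
#' @export
invertRigid <- function(transform) {
  R <- .rigidMatrix(transform@rotation)
  ## y = R (x - c) + c + t  =>  x = R^T (y - c) + c - R^T t
  Rt <- t(R)
  ## re-extract ZYX Euler angles of R^T so the inverse lives in the same
  ## parameter form (exact away from the gimbal singularity)
  ry <- asin(max(-1, min(1, -Rt[3, 1])))
  rz <- atan2(Rt[2, 1], Rt[1, 1])
  rx <- atan2(Rt[3, 2], Rt[3, 3])
  new("RigidTransform",
      translation = as.numeric(-Rt %*% transform@translation),
      rotation = c(rx, ry, rz) * 180 / pi,
      center = transform@center)
}

#' Resample a volume through a rigid transform (pull-back)
#'
#' The output voxel at world position x samples the moving volume at
#' \code{transform(x)}.  To align a moving image onto a fixed image given
#' the fixed-to-moving mapping, pass that mapping directly.
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @param transform a \linkS4class{RigidTransform} mapping output (fixed)
#'   world points to moving world points.
#' @param pad padding HU for samples outside the moving grid.
#' @return resampled \linkS4class{ImageVolume} on the same grid.
#' @export
resampleRigid <- function(volume, transform, pad = -1000) {
  d <- gridDim(volume)
  pts <- .voxelCentres(d, volume@spacing, volume@origin)
  pts <- applyRigidToPoints(transform, pts)
  idx <- .worldToIndex(pts, volume@spacing, volume@origin)
  imageVolume(array(.interpTrilinear(volume@voxels, idx, pad = pad), d),
              volume@spacing, volume@origin, role = volume@role)
}

#' Rigid registration by normalized cross-correlation
#'
#' Estimates the translation (and optionally small rotations) aligning a
#' moving image onto a fixed image by maximizing normalized
#' cross-correlation, with a coarse deterministic grid search followed by
#' Nelder-Mead refinement on a downsampled pyramid.  The returned transform
#' maps fixed-image world points to moving-image world points (pull-back),
#' i.e. \code{resampleRigid(moving, transform)} aligns the moving image
#' onto the fixed grid.
#'
#' @param fixed,moving \linkS4class{ImageVolume}s with overlapping physical
#'   extents.
#' @param mask optional 3D logical array on the fixed grid restricting the
#'   metric.
#' @param max_translation_mm half-width of the coarse translation search.
#' @param rotations logical; also estimate small rotations (default FALSE,
#'   translation-only).
#' @param bone_threshold_hu when non-NULL, restrict the metric further to
#'   fixed-image voxels above this HU value (bony anatomy, which moves
#'   rigidly), falling back to the full mask if fewer than 500 voxels
#'   qualify.  Soft-tissue deformation otherwise biases the fit.
#' @return a \linkS4class{RigidTransform}.
#' @export
rigidRegister <- function(fixed, moving, mask = NULL,
                          max_translation_mm = 20, rotations = FALSE,
                          bone_threshold_hu = NULL) {
  sd_floor <- 1e-6 * stats::sd(fixed@voxels)
  if (!is.null(bone_threshold_hu)) {
    ## dilate so the metric sees bone *edges*; a bone-only region can be
    ## (numerically) constant in intensity and carries no NCC signal, in
    ## which case fall back to the full mask
    bm <- .dilateMask(fixed@voxels > bone_threshold_hu, 6, fixed@spacing)
    if (!is.null(mask)) bm <- bm & mask
    if (sum(bm) >= 500L && stats::sd(fixed@voxels[bm]) > sd_floor)
      mask <- bm
  }
  .stopGeometry(fixed, moving, "fixed and moving")
  if (stats::sd(fixed@voxels) == 0 || stats::sd(moving@voxels) == 0)
    stop("degenerate (constant) image: rigid registration undefined")
  d <- gridDim(fixed)
  ## evaluate on a subsample of voxels for speed
  keep <- seq(1L, prod(d), by = max(1L, prod(d) %/% 40000L))
  pts <- .voxelCentres(d, fixed@spacing, fixed@origin)[keep, , drop = FALSE]
  fv <- as.numeric(fixed@voxels)[keep]
  if (!is.null(mask)) {
    mk <- as.logical(mask)[keep]
    pts <- pts[mk, , drop = FALSE]
    fv <- fv[mk]
  }
  mv_floor <- min(moving@voxels) + 1e-9
  negNCC <- function(par) {
    tr <- new("RigidTransform",
              translation = par[1:3],
              rotation = if (length(par) > 3) par[4:6] else c(0, 0, 0),
              center = fixed@origin + (d - 1) * fixed@spacing / 2)
    p <- applyRigidToPoints(tr, pts)
    mv <- .interpTrilinear(moving@voxels,
                           .worldToIndex(p, moving@spacing, moving@origin),
                           pad = NA)
    ## out-of-grid samples and padding-valued voxels carry no signal
    ok <- !is.na(mv) & mv > mv_floor
    if (sum(ok) < 50L) return(1)
    if (stats::sd(mv[ok]) <= sd_floor || stats::sd(fv[ok]) <= sd_floor)
      return(1)
    v <- -stats::cor(mv[ok], fv[ok])
    if (is.na(v)) 1 else v
  }
  step <- max(fixed@spacing)
  grid1 <- seq(-max_translation_mm, max_translation_mm, by = step)
  best <- c(0, 0, 0); bestv <- negNCC(best)
  ## coordinate-wise coarse sweep (deterministic), two passes
  for (pass in 1:2) {
    for (ax in 1:3) {
      cand <- vapply(grid1, function(g) {
        p <- best; p[ax] <- p[ax] + g; negNCC(p)
      }, numeric(1))
      j <- which.min(cand)
      if (cand[j] < bestv) {
        best[ax] <- best[ax] + grid1[j]
        bestv <- cand[j]
      }
    }
  }
  ## per-axis line refinement (deterministic; robust where Nelder-Mead
  ## stalls on interpolation ripple)
  for (round in 1:4) {
    width <- step * 2 / round
    for (ax in 1:3) {
      f1 <- function(g) { p <- best; p[ax] <- g; negNCC(p) }
      o <- stats::optimize(f1, c(best[ax] - width, best[ax] + width),
                           tol = 1e-4)
      if (o$objective < bestv) { best[ax] <- o$minimum; bestv <- o$objective }
    }
  }
  rot <- c(0, 0, 0)
  if (rotations) {
    opt <- stats::optim(c(best, 0, 0, 0), negNCC, method = "Nelder-Mead",
                        control = list(maxit = 600, reltol = 1e-10))
    best <- opt$par[1:3]
    rot <- opt$par[4:6]
  }
  new("RigidTransform", translation = best, rotation = rot,
      center = fixed@origin + (d - 1) * fixed@spacing / 2)
}

## ---- demons deformable registration --------------------------------------

## Few-point quantile matching over foreground voxels (above the image
## mean, which excludes air), piecewise-linear between match points.  A
## small number of knots captures global intensity transforms (CBCT
## contrast/level shifts) without absorbing genuine anatomical volume
## changes into the intensity map.
.histMatch <- function(moving, fixed, nq = 7L) {
  ## foreground: above the mean of non-background voxels (background =
  ## the image minimum, i.e. padding/blanked regions, which must not
  ## influence the match)
  nb_m <- moving > min(moving)
  nb_f <- fixed > min(fixed)
  if (!any(nb_m) || !any(nb_f)) return(moving)
  fm <- moving > mean(moving[nb_m])
  ff <- fixed > mean(fixed[nb_f])
  if (!any(fm) || !any(ff)) return(moving)
  qs <- seq(0.01, 0.99, length.out = nq)
  qm <- stats::quantile(moving[fm], qs, names = FALSE)
  qf <- stats::quantile(fixed[ff], qs, names = FALSE)
  ## enforce strictly increasing abscissae for approx
  eps <- diff(range(qm)) * 1e-9 + 1e-12
  qm <- cummax(qm + seq_along(qm) * eps)
  y <- stats::approx(qm, qf, xout = moving, rule = 2)$y
  ## linear extrapolation beyond the knot span (global-span slope);
  ## clamping would flatten the contrast of extreme intensities
  slope <- (qf[nq] - qf[1]) / (qm[nq] - qm[1])
  if (!is.finite(slope) || slope <= 0) slope <- 1
  lo <- moving < qm[1]
  hi <- moving > qm[nq]
  y[lo] <- qf[1] + (moving[lo] - qm[1]) * slope
  y[hi] <- qf[nq] + (moving[hi] - qm[nq]) * slope
  array(y, dim(moving))
}

.localNormalise <- function(a, sigma_vox) {
  mu <- .smoothGaussian(a, sigma_vox)
  v <- .smoothGaussian((a - mu)^2, sigma_vox)
  (a - mu) / sqrt(v + 1e-6 * stats::var(as.numeric(a)) + 1e-12)
}

.downsample2 <- function(a) {
  d <- dim(a)
  nd <- pmax(d %/% 2L, 1L)
  ## average 2x2x2 blocks (truncating odd trailing voxels)
  a <- a[seq_len(nd[1] * 2L), seq_len(nd[2] * 2L), seq_len(nd[3] * 2L),
         drop = FALSE]
  d2 <- dim(a)
  a <- (a[seq(1, d2[1], 2), , , drop = FALSE] +
          a[seq(2, d2[1], 2), , , drop = FALSE]) / 2
  a <- (a[, seq(1, d2[2], 2), , drop = FALSE] +
          a[, seq(2, d2[2], 2), , drop = FALSE]) / 2
  (a[, , seq(1, d2[3], 2), drop = FALSE] +
      a[, , seq(2, d2[3], 2), drop = FALSE]) / 2
}

## resample a 3D array defined on geometry (sp_in, or_in) onto (d_out,
## sp_out, or_out) by trilinear interpolation with edge clamping.
.resampleArray <- function(a, sp_in, or_in, d_out, sp_out, or_out,
                           pad = NULL) {
  pts <- .voxelCentres(d_out, sp_out, or_out)
  idx <- .worldToIndex(pts, sp_in, or_in)
  if (is.null(pad)) {
    d <- dim(a)
    idx[, 1] <- pmin(pmax(idx[, 1], 1), d[1])
    idx[, 2] <- pmin(pmax(idx[, 2], 1), d[2])
    idx[, 3] <- pmin(pmax(idx[, 3], 1), d[3])
    array(.interpTrilinear(a, idx), d_out)
  } else {
    array(.interpTrilinear(a, idx, pad = pad), d_out)
  }
}

#' Deformable registration (multi-resolution demons)
#'
#' Free-form intensity-driven registration returning a dense displacement
#' field on the fixed-image grid (pull-back convention, mm).  The moving
#' image is first resampled through the rigid initialization; the demons
#' force is computed from the intensity difference after the configured
#' preprocessing (histogram matching or local normalisation), smoothed with
#' \code{sigma_update_mm} (fluid), added to the total field, which is then
#' smoothed with \code{sigma_field_mm} (elastic).  A level stops early when
#' the relative metric improvement over \code{patience} iterations falls
#' below \code{tol}.  The returned field composes the rigid initialization,
#' so applying it to the original moving image aligns it onto the fixed
#' grid.
#'
#' @param fixed,moving \linkS4class{ImageVolume}s on compatible grids.
#' @param params a \code{\link{registrationParams}} object.
#' @param init optional \linkS4class{RigidTransform} initialization
#'   (fixed-to-moving); default identity.
#' @param init_field optional \linkS4class{DisplacementField} warm start
#'   (e.g. the result of a previous registration stage).  When given it
#'   must already include any rigid component and \code{init} is ignored;
#'   the returned field refines it.
#' @return a \linkS4class{DisplacementField} on the fixed grid.
#' @export
deformableRegister <- function(fixed, moving, params = registrationParams(),
                               init = NULL, init_field = NULL) {
  .stopGeometry(fixed, moving, "fixed and moving")
  if (!is.null(init_field)) {
    .stopGeometry(fixed, init_field, "fixed and init_field")
    init <- NULL
  }
  if (!is.null(init)) moving <- resampleRigid(moving, init)
  F0 <- fixed@voxels
  M0 <- moving@voxels
  if (!is.null(params$restrict_mask)) {
    ## the registration disregards image data beyond the (dilated)
    ## restriction region: both images are blanked to a common background
    ## there, so field-of-view cuts and far anatomy cannot generate
    ## spurious force or pyramid-level mixing differences
    rmask <- params$restrict_mask > 0.5
    ctx <- .dilateMask(rmask, 3 * max(fixed@spacing), fixed@spacing)
    ## fixed-image voxels at the padding value outside the restriction
    ## carry no data (field-of-view truncation): blank them too, so the
    ## moving image cannot be pulled toward anatomy the fixed never saw
    pad_like <- F0 <= min(F0) + 1 & !rmask
    blank <- !ctx | pad_like
    bg <- min(F0, M0)
    F0[blank] <- bg
    M0[blank] <- bg
  }
  ## normalise intensities to [0, 1] jointly
  rng <- range(c(F0, M0))
  if (diff(rng) == 0) stop("degenerate (constant) images")
  F0 <- (F0 - rng[1]) / diff(rng)
  M0 <- (M0 - rng[1]) / diff(rng)

  ## pyramid (coarse first)
  pyr <- vector("list", params$levels)
  Fl <- F0; Ml <- M0
  sp <- fixed@spacing
  msk <- params$restrict_mask
  for (l in params$levels:1) {
    ## strict mask at every level: a coarse block receives updates only if
    ## all its fine voxels lie inside the restriction (boundary blocks mix
    ## in out-of-region intensities and would drive spurious drift)
    pyr[[l]] <- list(F = Fl, M = Ml, spacing = sp,
                     mask = if (!is.null(msk)) msk > 0.999 else NULL)
    if (l > 1L) {
      Fl <- .downsample2(Fl); Ml <- .downsample2(Ml)
      if (!is.null(msk)) msk <- .downsample2(msk + 0)
      sp <- sp * 2
    }
  }

  u <- NULL  # 4D displacement array at current level, mm
  warned <- FALSE
  for (l in seq_len(params$levels)) {
    lev <- pyr[[l]]
    d <- dim(lev$F)
    if (is.null(u)) {
      u <- if (is.null(init_field)) array(0, c(d, 3L))
      else .upsampleField(init_field@displacement, d)
    } else {
      u <- .upsampleField(u, d)
    }
    Fp <- lev$F; Mp <- lev$M
    if (params$metric == "meansq_histmatch") {
      Mp <- .histMatch(Mp, Fp)
    } else {
      sv <- params$lncc_window_mm / lev$spacing
      Fp <- .localNormalise(Fp, sv)
      Mp <- .localNormalise(Mp, sv)
    }
    gFfix <- .gradient3(Fp, lev$spacing)
    idx0 <- .voxelCentres(d, c(1, 1, 1), c(1, 1, 1))  # 1-based index grid
    su <- params$sigma_update_mm / lev$spacing
    sf <- params$sigma_field_mm / lev$spacing
    alpha2 <- 1 / params$max_step_mm^2
    best <- Inf; bestu <- u; stall <- 0L
    nit <- params$iterations[params$levels - l + 1L]
    for (it in seq_len(nit)) {
      idx <- idx0
      idx[, 1] <- idx[, 1] + as.numeric(u[, , , 1]) / lev$spacing[1]
      idx[, 2] <- idx[, 2] + as.numeric(u[, , , 2]) / lev$spacing[2]
      idx[, 3] <- idx[, 3] + as.numeric(u[, , , 3]) / lev$spacing[3]
      Mw <- array(.interpTrilinear(Mp, idx, pad = 0), d)
      diffI <- Mw - Fp
      metric <- mean(diffI^2)
      if (is.na(metric)) stop("NaN in registration metric")
      if (metric < best * (1 - params$tol)) {
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      if (metric < best) { best <- metric; bestu <- u }
      if (stall >= params$patience) break
      ## symmetric force: mean of fixed and warped-moving gradients
      gM <- .gradient3(Mw, lev$spacing)
      gF <- (gFfix + gM) / 2
      g2 <- gF[, , , 1]^2 + gF[, , , 2]^2 + gF[, , , 3]^2
      denom <- g2 + alpha2 * diffI^2
      denom[denom < 1e-12] <- Inf
      fac <- -diffI / denom
      if (!is.null(lev$mask)) fac[!lev$mask] <- 0
      upd <- array(0, c(d, 3L))
      upd[, , , 1] <- .smoothGaussian(fac * gF[, , , 1], su)
      upd[, , , 2] <- .smoothGaussian(fac * gF[, , , 2], su)
      upd[, , , 3] <- .smoothGaussian(fac * gF[, , , 3], su)
      u <- u + upd
      u[, , , 1] <- .smoothGaussian(u[, , , 1], sf)
      u[, , , 2] <- .smoothGaussian(u[, , , 2], sf)
      u[, , , 3] <- .smoothGaussian(u[, , , 3], sf)
    }
    if (l == params$levels && stall == 0L && nit > params$patience &&
        !warned) {
      warned <- TRUE
      warning("registration stopped at the iteration budget while still ",
              "improving; returning the best field found")
    }
    u <- bestu
  }

  dvf_deform <- u
  if (!is.null(init)) {
    ## compose with the rigid initialization: total(x) = T(x + u(x)) - x
    d <- gridDim(fixed)
    pts <- .voxelCentres(d, fixed@spacing, fixed@origin)
    pw <- pts
    pw[, 1] <- pw[, 1] + as.numeric(dvf_deform[, , , 1])
    pw[, 2] <- pw[, 2] + as.numeric(dvf_deform[, , , 2])
    pw[, 3] <- pw[, 3] + as.numeric(dvf_deform[, , , 3])
    pT <- applyRigidToPoints(init, pw)
    dvf_deform[, , , 1] <- pT[, 1] - pts[, 1]
    dvf_deform[, , , 2] <- pT[, 2] - pts[, 2]
    dvf_deform[, , , 3] <- pT[, 3] - pts[, 3]
  }
  displacementField(dvf_deform, fixed@spacing, fixed@origin)
}

## trilinear upsampling of a 4D displacement field to a target 3D dim
.upsampleField <- function(u, d_out) {
  d_in <- dim(u)[1:3]
  out <- array(0, c(d_out, 3L))
  ## map output index i -> input index 1 + (i-1)*(n_in-1)/(n_out-1)
  sc <- ifelse(d_out > 1L, (d_in - 1) / pmax(d_out - 1, 1L), 0)
  pts <- cbind(1 + (rep.int(seq_len(d_out[1]), d_out[2] * d_out[3]) - 1) * sc[1],
               1 + (rep.int(rep(seq_len(d_out[2]), each = d_out[1]),
                            d_out[3]) - 1) * sc[2],
               1 + (rep(seq_len(d_out[3]), each = d_out[1] * d_out[2]) - 1) *
                 sc[3])
  for (c3 in 1:3)
    out[, , , c3] <- array(.interpTrilinear(u[, , , c3], pts), d_out)
  out
}

## ---- DVF algebra ----------------------------------------------------------

#' Warp a volume, dose grid or mask through a displacement field
#'
#' Pull-back resampling: the output value at world position \code{x} is the
#' input sampled at \code{x + u(x)}.  Out-of-grid samples take the class
#' padding value: -1000 HU for images, 0 Gy for dose, 0 for masks.  Masks
#' use linear interpolation thresholded at 0.5 by default
#' (\code{interpolation = "linear_threshold"}); \code{"nearest"} is
#' available for label-like data.
#'
#' @param x an \linkS4class{ImageVolume}, \linkS4class{DoseGrid} or 3D
#'   logical mask array.
#' @param dvf a \linkS4class{DisplacementField} whose grid matches the
#'   output grid.
#' @param interpolation "trilinear", "nearest" or "linear_threshold".
#' @param pad override of the padding value.
#' @return object of the same kind as \code{x}.
#' @export
applyDVF <- function(x, dvf,
                     interpolation = c("trilinear", "nearest",
                                       "linear_threshold"),
                     pad = NULL) {
  interpolation <- match.arg(interpolation)
  if (is.array(x) && is.logical(x)) {
    if (!identical(dim(x), gridDim(dvf)))
      stop("geometry mismatch: mask grid must match the DVF grid")
    if (interpolation == "trilinear") interpolation <- "linear_threshold"
    v <- .warpArray(x + 0, dvf, interpolation,
                    if (is.null(pad)) 0 else pad)
    return(array(v >= 0.5, dim(x)))
  }
  if (is(x, "ImageVolume")) {
    .stopGeometry(x, dvf, "volume and DVF")
    v <- .warpArray(x@voxels, dvf, interpolation,
                    if (is.null(pad)) -1000 else pad)
    return(imageVolume(v, x@spacing, x@origin, role = x@role))
  }
  if (is(x, "DoseGrid")) {
    .stopGeometry(x, dvf, "dose and DVF")
    v <- .warpArray(x@dose, dvf, interpolation, if (is.null(pad)) 0 else pad)
    v[v < 0] <- 0
    return(doseGrid(v, x@spacing, x@origin, role = x@role))
  }
  stop("applyDVF: unsupported input type")
}

.warpArray <- function(a, dvf, interpolation, pad) {
  d <- dim(a)
  u <- dvf@displacement
  idx <- .voxelCentres(d, c(1, 1, 1), c(1, 1, 1))
  idx[, 1] <- idx[, 1] + as.numeric(u[, , , 1]) / dvf@spacing[1]
  idx[, 2] <- idx[, 2] + as.numeric(u[, , , 2]) / dvf@spacing[2]
  idx[, 3] <- idx[, 3] + as.numeric(u[, , , 3]) / dvf@spacing[3]
  v <- if (interpolation == "nearest") .interpNearest(a, idx, pad = pad)
  else .interpTrilinear(a, idx, pad = pad)
  array(v, d)
}

#' @describeIn applyDVF method for images.
setMethod("warpVolume", "ImageVolume",
          function(x, dvf, ...) applyDVF(x, dvf, ...))

#' @describeIn applyDVF method for dose grids.
setMethod("warpVolume", "DoseGrid",
          function(x, dvf, ...) applyDVF(x, dvf, ...))

#' Compose two displacement fields
#'
#' Returns the field equivalent to warping first by \code{dvf_bc} then by
#' \code{dvf_ab} (pull-back):
#' \code{u(x) = u_ab(x) + u_bc(x + u_ab(x))}.
#'
#' @param dvf_ab,dvf_bc \linkS4class{DisplacementField}s on a common grid.
#' @return the composed \linkS4class{DisplacementField}.
#' @export
composeDVF <- function(dvf_ab, dvf_bc) {
  .stopGeometry(dvf_ab, dvf_bc, "fields")
  d <- gridDim(dvf_ab)
  ua <- dvf_ab@displacement
  ub <- dvf_bc@displacement
  idx <- .voxelCentres(d, c(1, 1, 1), c(1, 1, 1))
  idx[, 1] <- idx[, 1] + as.numeric(ua[, , , 1]) / dvf_ab@spacing[1]
  idx[, 2] <- idx[, 2] + as.numeric(ua[, , , 2]) / dvf_ab@spacing[2]
  idx[, 3] <- idx[, 3] + as.numeric(ua[, , , 3]) / dvf_ab@spacing[3]
  ## clamp sampling of u_bc to the grid (extend border values)
  idc <- idx
  idc[, 1] <- pmin(pmax(idc[, 1], 1), d[1])
  idc[, 2] <- pmin(pmax(idc[, 2], 1), d[2])
  idc[, 3] <- pmin(pmax(idc[, 3], 1), d[3])
  out <- array(0, c(d, 3L))
  for (c3 in 1:3)
    out[, , , c3] <- ua[, , , c3] +
      array(.interpTrilinear(ub[, , , c3], idc), d)
  displacementField(out, dvf_ab@spacing, dvf_ab@origin)
}

#' Invert a displacement field by fixed-point iteration
#'
#' Finds g with \code{f(x + g(x)) + g(x) = 0} (so warping by g undoes
#' warping by f) via the standard fixed-point scheme
#' \code{g_{k+1}(x) = -f(x + g_k(x))}.  Emits a warning with residual
#' statistics if the tolerance is not met on at least 99\% of voxels.
#'
#' @param dvf a diffeomorphic \linkS4class{DisplacementField}.
#' @param tol_mm residual tolerance, mm.
#' @param max_iter maximum fixed-point iterations.
#' @return the inverse \linkS4class{DisplacementField}.
#' @export
invertDVF <- function(dvf, tol_mm = 0.05, max_iter = 50L) {
  d <- gridDim(dvf)
  u <- dvf@displacement
  g <- -u
  idx0 <- .voxelCentres(d, c(1, 1, 1), c(1, 1, 1))
  for (it in seq_len(max_iter)) {
    idx <- idx0
    idx[, 1] <- pmin(pmax(idx[, 1] + as.numeric(g[, , , 1]) / dvf@spacing[1],
                          1), d[1])
    idx[, 2] <- pmin(pmax(idx[, 2] + as.numeric(g[, , , 2]) / dvf@spacing[2],
                          1), d[2])
    idx[, 3] <- pmin(pmax(idx[, 3] + as.numeric(g[, , , 3]) / dvf@spacing[3],
                          1), d[3])
    gn <- array(0, c(d, 3L))
    for (c3 in 1:3)
      gn[, , , c3] <- -array(.interpTrilinear(u[, , , c3], idx), d)
    delta <- max(abs(gn - g))
    g <- gn
    if (delta < tol_mm / 4) break
  }
  ## residual check
  idx <- idx0
  idx[, 1] <- pmin(pmax(idx[, 1] + as.numeric(g[, , , 1]) / dvf@spacing[1], 1),
                   d[1])
  idx[, 2] <- pmin(pmax(idx[, 2] + as.numeric(g[, , , 2]) / dvf@spacing[2], 1),
                   d[2])
  idx[, 3] <- pmin(pmax(idx[, 3] + as.numeric(g[, , , 3]) / dvf@spacing[3], 1),
                   d[3])
  res <- array(0, c(d, 3L))
  for (c3 in 1:3)
    res[, , , c3] <- array(.interpTrilinear(u[, , , c3], idx), d) +
      g[, , , c3]
  rmag <- sqrt(res[, , , 1]^2 + res[, , , 2]^2 + res[, , , 3]^2)
  frac_ok <- mean(rmag <= tol_mm)
  if (frac_ok < 0.99)
    warning(sprintf(paste0("DVF inversion residual > %.3g mm on %.1f%% of ",
                           "voxels (median %.3g, max %.3g mm)"),
                    tol_mm, 100 * (1 - frac_ok), stats::median(rmag),
                    max(rmag)))
  displacementField(g, dvf@spacing, dvf@origin)
}

#' Jacobian determinant of a displacement field
#'
#' Central-difference determinant of \code{I + grad(u)}; values below or at
#' zero indicate folding.
#'
#' @param dvf a \linkS4class{DisplacementField}.
#' @return a list with \code{jacobian} (3D array), \code{min}, \code{max}
#'   and \code{frac_nonpositive}.
#' @export
jacobianDeterminant <- function(dvf) {
  u <- dvf@displacement
  g1 <- .gradient3(u[, , , 1], dvf@spacing)
  g2 <- .gradient3(u[, , , 2], dvf@spacing)
  g3 <- .gradient3(u[, , , 3], dvf@spacing)
  a11 <- 1 + g1[, , , 1]; a12 <- g1[, , , 2]; a13 <- g1[, , , 3]
  a21 <- g2[, , , 1]; a22 <- 1 + g2[, , , 2]; a23 <- g2[, , , 3]
  a31 <- g3[, , , 1]; a32 <- g3[, , , 2]; a33 <- 1 + g3[, , , 3]
  J <- a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
  list(jacobian = J, min = min(J), max = max(J),
       frac_nonpositive = mean(J <= 0))
}
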