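## Extended-FOV merged CBCT: the weekly CBCT stitched into the planning CT
## by a restricted deformable registration within the limiting contour,
## plus the ROI HU measurement / tolerance / linear calibration operations
## used to justify dose calculation on native CBCT HU.

#' Extract the limiting contour of a CBCT
#'
#' The limiting contour is the CBCT body: the largest connected component
#' above the body threshold, morphologically closed, intersected with the
#' valid-FOV region (voxels above the FOV padding).  Registration and
#' stitching disregard image data beyond it.
#'
#' @param cbct an \linkS4class{ImageVolume} (FOV-truncated CBCT).
#' @param body_threshold_hu HU threshold separating tissue from air;
#'   default -300.
#' @param closing_mm radius of the morphological closing, mm.
#' @param fov_pad_hu padding value marking out-of-FOV voxels.
#' @return a 3D logical mask.
#' @export
makeLimitingContour <- function(cbct, body_threshold_hu = -300,
                                closing_mm = 8, fov_pad_hu = -1000) {
  v <- cbct@voxels
  valid_fov <- v > fov_pad_hu + 1e-6
  m <- v > body_threshold_hu & valid_fov
  if (!any(m)) stop("empty limiting contour: no voxels above threshold")
  m <- .largestComponent(m)
  m <- .closeMask(m, closing_mm, cbct@spacing) & valid_fov
  if (!any(m)) stop("empty limiting contour after closing")
  m
}

#' Build the merged CBCT
#'
#' Deformably registers the pCT (moving) onto the CBCT (fixed) with the
#' update restricted to the limiting contour, then stitches: CBCT voxels
#' inside the limiting contour eroded by the blend band, warped pCT
#' outside the contour dilated by the band, and a linear alpha blend in
#' between.  The output lives on the pCT grid extent, so all downstream
#' dose work shares one geometry.  The provenance of every voxel and the
#' pCT-to-CBCT DVF are recorded.
#'
#' @param pct the planning \linkS4class{ImageVolume}.
#' @param cbct the weekly \linkS4class{ImageVolume} (same grid).
#' @param limiting 3D logical mask from \code{\link{makeLimitingContour}}.
#' @param params \code{\link{registrationParams}}; its
#'   \code{restrict_mask} is overridden by \code{limiting}.
#' @param blend_mm half-width of the alpha-blend band, mm (0 disables
#'   blending).
#' @param rigid_init optional precomputed \linkS4class{RigidTransform}
#'   (CBCT-to-pCT pull-back); computed automatically when NULL (bony
#'   anatomy above \code{bone_threshold_hu} drives the fit).
#' @param bone_threshold_hu HU threshold for the automatic rigid
#'   initialization.
#' @param week week index stored in the result.
#' @return a \linkS4class{MergedCBCT}.
#' @export
mergeCBCT <- function(pct, cbct, limiting = NULL,
                      params = registrationParams(), blend_mm = 6,
                      rigid_init = NULL, bone_threshold_hu = 200,
                      week = 1L) {
  .stopGeometry(pct, cbct, "pCT and CBCT")
  if (is.null(limiting)) limiting <- makeLimitingContour(cbct)
  if (!any(limiting)) stop("empty limiting contour")
  params$restrict_mask <- limiting
  if (is.null(rigid_init))
    rigid_init <- rigidRegister(cbct, pct, mask = limiting,
                                max_translation_mm = 12,
                                bone_threshold_hu = bone_threshold_hu)
  dvf <- deformableRegister(cbct, pct, params = params, init = rigid_init)
  warped_pct <- applyDVF(pct, dvf)

  sp <- gridSpacing(pct)
  inner <- .erodeMask(limiting, blend_mm, sp)
  outer <- .dilateMask(limiting, blend_mm, sp)
  prov <- array(2L, gridDim(pct))      # deformed pCT
  prov[outer & !inner] <- 3L           # blend band
  prov[inner] <- 1L                    # CBCT
  if (blend_mm <= 0) {
    prov <- array(ifelse(limiting, 1L, 2L), gridDim(pct))
    alpha <- ifelse(limiting, 1, 0)
  } else {
    ## alpha: 1 on the inner region, 0 outside the outer, linear across
    dist_in <- .distanceTransform(inner, sp)
    alpha <- pmax(0, 1 - dist_in / (2 * blend_mm))
    alpha[inner] <- 1
    alpha[!outer] <- 0
  }
  merged <- alpha * cbct@voxels + (1 - alpha) * warped_pct@voxels
  new("MergedCBCT",
      volume = imageVolume(array(merged, gridDim(pct)), sp,
                           gridOrigin(pct), role = "mCBCT"),
      provenance = prov, source_week = as.integer(week),
      dvf_pct_to_cbct = dvf)
}

#' Measure mean and SD of HU inside an ROI
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @param roi non-empty 3D logical mask on the same grid.
#' @return named numeric c(mean, sd) in HU (sd is the sample SD; 0 for a
#'   single voxel).
#' @export
measureROIHU <- function(volume, roi) {
  if (!identical(dim(roi), gridDim(volume)))
    stop("ROI grid must match the volume grid")
  if (!any(roi)) stop("empty ROI")
  v <- volume@voxels[roi]
  c(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0)
}

#' Check two ROI measurements against an HU tolerance
#'
#' @param a,b measurements from \code{\link{measureROIHU}} (or any numeric
#'   whose first element is the mean).
#' @param tol acceptance tolerance, HU (default 40).
#' @return list with \code{pass} (logical) and \code{difference}
#'   (mean_a - mean_b, HU).
#' @export
checkHUTolerance <- function(a, b, tol = 40) {
  diff <- unname(a[1] - b[1])
  list(pass = abs(diff) <= tol, difference = diff)
}

#' Fit a linear CBCT-to-CT HU calibration
#'
#' Least-squares line CT = slope * CBCT + intercept from paired HU values
#' (monthly-QA phantom inserts or paired ROI means).
#'
#' @param cbct_hu,ct_hu paired HU values; at least two distinct CBCT
#'   abscissae required.
#' @param source provenance label.
#' @return an \linkS4class{HUCalibration}.
#' @export
fitHUCalibration <- function(cbct_hu, ct_hu, source = "paired ROI") {
  if (length(cbct_hu) != length(ct_hu))
    stop("paired HU vectors must have equal length")
  if (length(unique(cbct_hu)) < 2L)
    stop("need at least 2 distinct CBCT HU values")
  fit <- stats::lm(ct_hu ~ cbct_hu)
  co <- stats::coef(fit)
  new("HUCalibration", slope = unname(co[2]), intercept = unname(co[1]),
      source = source,
      residual_sd = if (length(cbct_hu) > 2L)
        stats::sigma(fit) else 0)
}

#' Apply a linear HU calibration to a volume
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @param cal an \linkS4class{HUCalibration}.
#' @return the calibrated \linkS4class{ImageVolume}.
#' @export
applyHUCalibration <- function(volume, cal) {
  imageVolume(cal@slope * volume@voxels + cal@intercept,
              volume@spacing, volume@origin, role = volume@role)
}
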