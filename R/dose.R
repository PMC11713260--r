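## Simplified anatomy-responsive dose engine (the recalculated-dose
## pathway), DVF-based dose deformation (the deformed-dose pathway), and
## spatial accumulation to the reference week.
##
## The engine is a deliberately simple megavoltage-like model: per beam it
## ray-traces water-equivalent depth (WED) from the body entry along one of
## the four cardinal gantry axes, applies an exponential depth kernel with
## a linear build-up ramp, and a sigmoid lateral penumbra from the signed
## distance to the rectangular aperture edge.  It is not a clinical dose
## algorithm; it exists to respond to the anatomy of the day with
## closed-form testability.

#' Convert HU to relative electron density
#'
#' Piecewise-linear lookup through configurable knots, clamped outside the
#' knot range.  Default knots: -1000 HU -> 0.0 (air), 0 HU -> 1.0 (water),
#' 1000 HU -> 1.6 (dense bone).
#'
#' @param hu numeric vector or array of HU values.
#' @param knots_hu,knots_density lookup knots.
#' @return relative density, same shape as \code{hu}.
#' @examples
#' huToRelativeDensity(c(-1000, 0, 500, 1000))
#' @export
huToRelativeDensity <- function(hu, knots_hu = c(-1000, 0, 1000),
                                knots_density = c(0, 1, 1.6)) {
  v <- stats::approx(knots_hu, knots_density, xout = as.numeric(hu),
                     rule = 2)$y
  if (is.array(hu)) array(v, dim(hu)) else v
}

## cumulative WED (mm) along a cardinal beam axis.
## axis: 1 (x) or 2 (y); from_high: beam enters from the high-coordinate side.
.wedAlongAxis <- function(density, spacing, axis, from_high) {
  d <- dim(density)
  perm <- switch(axis, c(1L, 2L, 3L), c(2L, 1L, 3L))
  a <- aperm(density, perm)
  da <- dim(a)
  if (from_high) a <- a[da[1]:1, , , drop = FALSE]
  m <- matrix(a, da[1])
  cs <- apply(m * spacing[axis], 2, cumsum)
  ## WED at the voxel centre: full path above + half of own voxel
  wed <- array(cs - m * spacing[axis] / 2, da)
  if (from_high) wed <- wed[da[1]:1, , , drop = FALSE]
  aperm(wed, perm)
}

## depth-dose kernel: linear build-up ramp over d_max, then exponential
.depthKernel <- function(wed, mu_eff, d_max) {
  pmin(wed / d_max, 1) * exp(-mu_eff * wed)
}

## sigmoid aperture transmission from signed rectangle distance (mm,
## negative inside)
.penumbra <- function(sd_mm, width_mm) {
  1 / (1 + exp(4 * sd_mm / width_mm))
}

## raw (unnormalized) dose of one fraction-equivalent delivery
.rawDose <- function(anatomy, plan) {
  d <- gridDim(anatomy)
  sp <- gridSpacing(anatomy)
  org <- gridOrigin(anatomy)
  density <- huToRelativeDensity(anatomy@voxels)
  X <- .voxelCentres(d, sp, org)
  k <- plan@kernel
  out <- array(0, d)
  for (b in plan@beams) {
    g <- b$gantry_deg %% 360
    if (!g %in% c(0, 90, 180, 270))
      stop("the simplified engine supports the cardinal gantry angles only")
    ## gantry 0: source +y (beam travels -y); 180: source -y;
    ## 90: source +x; 270: source -x.  u = in-plane axis, v = z.
    axis <- if (g %in% c(0, 180)) 2L else 1L
    from_high <- g %in% c(0, 90)
    wed <- .wedAlongAxis(density, sp, axis, from_high)
    u <- if (axis == 2L) X[, 1] else X[, 2]
    ap <- b$aperture
    du <- pmax(ap[["u_min"]] - u, u - ap[["u_max"]])
    dv <- pmax(ap[["v_min"]] - X[, 3], X[, 3] - ap[["v_max"]])
    sd_mm <- pmax(du, dv)
    out <- out + b$weight * .depthKernel(wed, k[["mu_eff"]], k[["d_max"]]) *
      array(.penumbra(sd_mm, k[["penumbra_mm"]]), d)
  }
  out
}

#' Normalize a plan on the planning anatomy
#'
#' Freezes the normalization constant so the summed beam contribution at
#' the isocenter equals the per-fraction prescription on this anatomy.
#' The constant is then reused unchanged for every recalculation on later
#' anatomy, mirroring how a clinical plan's monitor units stay fixed.
#'
#' @param plan a \linkS4class{PlanSpec} from \code{\link{generatePlan}}.
#' @param anatomy the planning \linkS4class{ImageVolume}.
#' @return the plan with its normalization set.
#' @export
planNormalize <- function(plan, anatomy) {
  iso_idx <- round(.worldToIndex(matrix(plan@isocenter, 1),
                                 gridSpacing(anatomy), gridOrigin(anatomy)))
  d <- gridDim(anatomy)
  if (any(iso_idx < 1) || any(iso_idx > d))
    stop("isocenter outside the anatomy grid")
  density <- huToRelativeDensity(anatomy@voxels[iso_idx[1], iso_idx[2],
                                                iso_idx[3]])
  if (density < 0.05) stop("isocenter outside body (air-like density)")
  raw <- .rawDose(anatomy, plan)
  r_iso <- raw[iso_idx[1], iso_idx[2], iso_idx[3]]
  if (r_iso <= 0) stop("zero raw dose at isocenter; check plan geometry")
  plan@normalization <- (plan@prescription_gy / plan@n_fractions) / r_iso
  plan
}

#' Compute one fraction of dose on an anatomy
#'
#' Runs the simplified four-field engine on the given anatomy with the
#' frozen plan normalization, returning the single-fraction dose grid.
#' Deterministic.  Errors if the plan has not been normalized
#' (\code{\link{planNormalize}}) or the isocenter falls outside the body.
#'
#' @param anatomy an \linkS4class{ImageVolume} (pCT or merged CBCT).
#' @param plan a normalized \linkS4class{PlanSpec}.
#' @param role role tag for the output grid.
#' @return a \linkS4class{DoseGrid} (Gy per fraction).
#' @export
computeDose <- function(anatomy, plan, role = "dose") {
  if (is.na(plan@normalization))
    stop("plan is not normalized; call planNormalize() on the planning CT")
  iso_idx <- round(.worldToIndex(matrix(plan@isocenter, 1),
                                 gridSpacing(anatomy), gridOrigin(anatomy)))
  d <- gridDim(anatomy)
  if (any(iso_idx < 1) || any(iso_idx > d))
    stop("isocenter outside the anatomy grid")
  if (huToRelativeDensity(anatomy@voxels[iso_idx[1], iso_idx[2],
                                         iso_idx[3]]) < 0.05)
    stop("isocenter outside body (air-like density)")
  doseGrid(.rawDose(anatomy, plan) * plan@normalization,
           gridSpacing(anatomy), gridOrigin(anatomy), role = role)
}

#' Deform a dose grid through a displacement field
#'
#' Trilinear pull-back resampling of the dose; out-of-grid samples are
#' 0 Gy.  This is the deformed-dose pathway: the dose computed on one
#' anatomy is mapped through the registration DVF instead of being
#' recalculated.
#'
#' @param dose a \linkS4class{DoseGrid}.
#' @param dvf a \linkS4class{DisplacementField} on the output grid.
#' @param role optional role tag for the output (defaults to the input's).
#' @return the warped \linkS4class{DoseGrid}.
#' @export
deformDose <- function(dose, dvf, role = NULL) {
  out <- applyDVF(dose, dvf, interpolation = "trilinear")
  if (!is.null(role)) out@role <- role
  out
}

#' Accumulate weekly doses on the reference grid
#'
#' Computes \code{sum_i w_i * deform(dose_i, dvf_i)}: each weekly dose is
#' deformed to the reference week through its DVF and summed with its
#' fraction weight.  Week 1 is the reference, so its field should be the
#' identity (zero) field.  Default weights are 5 fractions per week, the
#' weekly-CBCT-as-surrogate convention of the workflow.
#'
#' @param weekly_doses list of 5 per-fraction \linkS4class{DoseGrid}s.
#' @param dvfs_to_reference list of 5 \linkS4class{DisplacementField}s
#'   mapping the reference grid into each week (pull-back).
#' @param weights fractions represented by each week.
#' @param role role tag of the cumulative grid ("sum_ecD" or "sum_mdD").
#' @return the cumulative \linkS4class{DoseGrid}.
#' @export
accumulateDose <- function(weekly_doses, dvfs_to_reference,
                           weights = rep(5, length(weekly_doses)),
                           role = "sum") {
  n <- length(weekly_doses)
  if (length(dvfs_to_reference) != n || length(weights) != n)
    stop("weekly doses, fields and weights must have equal length")
  ref <- weekly_doses[[1]]
  acc <- array(0, gridDim(ref))
  for (i in seq_len(n)) {
    wd <- deformDose(weekly_doses[[i]], dvfs_to_reference[[i]])
    .stopGeometry(ref, wd, "weekly doses")
    acc <- acc + weights[i] * wd@dose
  }
  doseGrid(acc, gridSpacing(ref), gridOrigin(ref), role = role)
}
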