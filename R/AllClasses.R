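#' @import methods
NULL

#' Virtual base class for objects living on an axis-aligned 3D grid
#'
#' All volumetric objects in the package (images, dose grids, displacement
#' fields, structure sets) share the same geometry model: an axis-aligned
#' voxel grid with per-axis spacing (mm) and an origin giving the world
#' coordinate (mm) of the centre of voxel (1,1,1).  World coordinates of
#' voxel centres are \code{origin + (index - 1) * spacing}.  No oblique
#' orientations are supported.
#'
#' @slot spacing numeric(3), per-axis voxel size in mm, all > 0.
#' @slot origin numeric(3), world coordinate (mm) of the first voxel centre.
#' @name GridVolume-class
#' @aliases GridVolume
#' @exportClass GridVolume
setClass("GridVolume",
         representation("VIRTUAL", spacing = "numeric", origin = "numeric"),
         prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("GridVolume", function(object) {
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 finite positive values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite values (mm)")
  TRUE
})

#' 3D scalar image volume in Hounsfield units
#'
#' @slot voxels 3D numeric array of HU values.
#' @slot role character tag, e.g. "pCT", "CBCT", "mCBCT".
#' @name ImageVolume-class
#' @aliases ImageVolume
#' @exportClass ImageVolume
setClass("ImageVolume", contains = "GridVolume",
         representation(voxels = "array", role = "character"),
         prototype(role = "image"))

setValidity("ImageVolume", function(object) {
  if (length(dim(object@voxels)) != 3L)
    return("voxels must be a 3D array")
  if (anyNA(object@voxels)) return("voxels must not contain NA")
  TRUE
})

#' 3D absorbed dose grid in Gy
#'
#' @slot dose 3D numeric array of dose values (Gy), all >= 0.
#' @slot role character tag: one of "pD", "ecD", "mdD", "sum_ecD", "sum_mdD"
#'   or a free-form label.
#' @name DoseGrid-class
#' @aliases DoseGrid
#' @exportClass DoseGrid
setClass("DoseGrid", contains = "GridVolume",
         representation(dose = "array", role = "character"),
         prototype(role = "dose"))

setValidity("DoseGrid", function(object) {
  if (length(dim(object@dose)) != 3L) return("dose must be a 3D array")
  if (anyNA(object@dose)) return("dose must not contain NA")
  if (min(object@dose) < 0) return("dose values must be non-negative")
  TRUE
})

#' Dense displacement vector field (DVF)
#'
#' Per-voxel 3-vector displacements in mm on the fixed-image grid, stored as
#' a 4D array \code{[nx, ny, nz, 3]}.  The convention is pull-back: to
#' resample a moving image onto this grid, the voxel at world position
#' \code{x} samples the moving image at \code{x + u(x)}.
#'
#' @slot displacement 4D numeric array, last dimension of extent 3 (mm).
#' @name DisplacementField-class
#' @aliases DisplacementField
#' @exportClass DisplacementField
setClass("DisplacementField", contains = "GridVolume",
         representation(displacement = "array"))

setValidity("DisplacementField", function(object) {
  d <- dim(object@displacement)
  if (length(d) != 4L || d[4] != 3L)
    return("displacement must be a 4D array with last extent 3")
  if (any(!is.finite(object@displacement)))
    return("displacement must be finite everywhere")
  TRUE
})

#' Named binary masks plus landmark points on a common grid
#'
#' @slot dim integer(3), grid extent shared by all masks.
#' @slot masks named list of 3D logical arrays.
#' @slot landmarks numeric matrix (n x 3) of world points in mm, with
#'   rownames as landmark labels; may have zero rows.
#' @slot provenance character: "ground_truth", "dir_generated" or
#'   "transferred".
#' @name StructureSet-class
#' @aliases StructureSet
#' @exportClass StructureSet
setClass("StructureSet", contains = "GridVolume",
         representation(dim = "integer", masks = "list",
                        landmarks = "matrix", provenance = "character"),
         prototype(provenance = "ground_truth",
                   landmarks = matrix(numeric(0), 0, 3)))

setValidity("StructureSet", function(object) {
  if (length(object@dim) != 3L || any(object@dim < 1L))
    return("dim must be 3 positive integers")
  if (length(object@masks)) {
    if (is.null(names(object@masks)) || any(!nzchar(names(object@masks))))
      return("masks must be a named list")
    for (nm in names(object@masks)) {
      m <- object@masks[[nm]]
      if (!is.logical(m) || !identical(dim(m), object@dim))
        return(sprintf("mask '%s' must be a logical array on the stated grid", nm))
    }
  }
  if (ncol(object@landmarks) != 3L)
    return("landmarks must have 3 columns (x, y, z in mm)")
  if (nrow(object@landmarks) &&
      is.null(rownames(object@landmarks)))
    return("landmarks must have rownames")
  if (!object@provenance %in% c("ground_truth", "dir_generated", "transferred"))
    return("provenance must be ground_truth, dir_generated or transferred")
  TRUE
})

#' Rigid transform (translation plus optional small rotations)
#'
#' Maps a world point x to \code{R (x - center) + center + translation},
#' where R is built from small Euler angles (degrees) about x, y, z.
#'
#' @slot translation numeric(3), mm.
#' @slot rotation numeric(3), degrees; defaults to zero (pure translation).
#' @slot center numeric(3), rotation centre in mm.
#' @name RigidTransform-class
#' @aliases RigidTransform
#' @exportClass RigidTransform
setClass("RigidTransform",
         representation(translation = "numeric", rotation = "numeric",
                        center = "numeric"),
         prototype(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                   center = c(0, 0, 0)))

setValidity("RigidTransform", function(object) {
  if (length(object@translation) != 3L || any(!is.finite(object@translation)))
    return("translation must be 3 finite values (mm)")
  if (length(object@rotation) != 3L || any(!is.finite(object@rotation)))
    return("rotation must be 3 finite angles (degrees)")
  if (length(object@center) != 3L) return("center must be length 3")
  TRUE
})

#' Four-field box treatment plan
#'
#' A static four-field box arrangement (gantry 0/90/180/270 degrees) with
#' rectangular apertures fitted to the PTV projection plus margin.  The
#' normalization constant is frozen at planning time so that the summed
#' beam contribution at the isocenter on the planning CT equals the
#' per-fraction prescription; it is never re-derived on later anatomy.
#'
#' @slot isocenter numeric(3), mm (PTV centroid at planning).
#' @slot beams list of beams; each beam is a list with elements
#'   \code{gantry_deg}, \code{aperture} (named numeric: u_min, u_max,
#'   v_min, v_max in beam's-eye-view mm) and \code{weight}.
#' @slot prescription_gy total prescription dose, Gy.
#' @slot n_fractions integer fraction count.
#' @slot normalization Gy per unit raw engine output; NA until the plan is
#'   normalized on an anatomy with \code{planNormalize}.
#' @slot kernel named numeric: \code{mu_eff} (1/mm), \code{d_max} (mm),
#'   \code{penumbra_mm} (sigmoid width, mm).
#' @name PlanSpec-class
#' @aliases PlanSpec
#' @exportClass PlanSpec
setClass("PlanSpec",
         representation(isocenter = "numeric", beams = "list",
                        prescription_gy = "numeric", n_fractions = "integer",
                        normalization = "numeric", kernel = "numeric"),
         prototype(normalization = NA_real_,
                   kernel = c(mu_eff = 0.005, d_max = 15, penumbra_mm = 6)))

setValidity("PlanSpec", function(object) {
  if (object@prescription_gy <= 0) return("prescription must be positive")
  if (object@n_fractions <= 0L) return("fraction count must be positive")
  if (!length(object@beams)) return("plan must contain at least one beam")
  for (b in object@beams) {
    if (is.null(b$weight) || b$weight <= 0) return("beam weights must be > 0")
  }
  TRUE
})

#' Extended field-of-view merged CBCT
#'
#' The weekly CBCT stitched into the (deformably matched) planning CT.
#' Inside the eroded limiting contour the voxels come from the CBCT;
#' outside the dilated contour from the warped pCT; a linear alpha blend
#' fills the band between.
#'
#' @slot volume an \linkS4class{ImageVolume} on the pCT grid.
#' @slot provenance integer 3D array: 1 = CBCT, 2 = deformed pCT, 3 = blend.
#' @slot source_week integer week index (1-5).
#' @slot dvf_pct_to_cbct the \linkS4class{DisplacementField} used to warp
#'   the pCT into the CBCT anatomy (pull-back, on the output grid).
#' @name MergedCBCT-class
#' @aliases MergedCBCT
#' @exportClass MergedCBCT
setClass("MergedCBCT",
         representation(volume = "ImageVolume", provenance = "array",
                        source_week = "integer",
                        dvf_pct_to_cbct = "DisplacementField"))

setValidity("MergedCBCT", function(object) {
  if (!identical(dim(object@provenance), dim(object@volume@voxels)))
    return("provenance grid must match the volume grid")
  if (!all(object@provenance %in% 1:3))
    return("provenance labels must be 1 (CBCT), 2 (deformed pCT) or 3 (blend)")
  TRUE
})

#' Linear CBCT-to-CT HU calibration
#'
#' @slot slope unitless, > 0.
#' @slot intercept HU.
#' @slot source "monthly-QA table" or "paired ROI".
#' @slot residual_sd HU, residual standard deviation of the fit.
#' @name HUCalibration-class
#' @aliases HUCalibration
#' @exportClass HUCalibration
setClass("HUCalibration",
         representation(slope = "numeric", intercept = "numeric",
                        source = "character", residual_sd = "numeric"),
         prototype(source = "paired ROI", residual_sd = NA_real_))

setValidity("HUCalibration", function(object) {
  if (!is.finite(object@slope) || object@slope <= 0)
    return("slope must be finite and > 0")
  if (!is.finite(object@intercept)) return("intercept must be finite")
  TRUE
})
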