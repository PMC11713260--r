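#' Construct an ImageVolume
#'
#' @param voxels 3D numeric array of HU values.
#' @param spacing numeric(3) voxel size, mm.
#' @param origin numeric(3) world position of the first voxel centre, mm.
#' @param role character tag ("pCT", "CBCT", "mCBCT", ...).
#' @return an \linkS4class{ImageVolume}.
#' @examples
#' v <- imageVolume(array(0, c(4, 4, 4)), spacing = c(2, 2, 2))
#' gridDim(v)
#' @export
imageVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        role = "image") {
  new("ImageVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), role = role)
}

#' Construct a DoseGrid
#'
#' @param dose 3D numeric array, Gy.
#' @param spacing,origin grid geometry (mm).
#' @param role dose role tag ("pD", "ecD", "mdD", "sum_ecD", "sum_mdD", ...).
#' @return a \linkS4class{DoseGrid}.
#' @export
doseGrid <- function(dose, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     role = "dose") {
  new("DoseGrid", dose = dose, spacing = as.numeric(spacing),
      origin = as.numeric(origin), role = role)
}

#' Construct a DisplacementField
#'
#' @param displacement 4D numeric array \code{[nx, ny, nz, 3]}, mm,
#'   pull-back convention.
#' @param spacing,origin grid geometry (mm) of the fixed image.
#' @return a \linkS4class{DisplacementField}.
#' @export
displacementField <- function(displacement, spacing = c(1, 1, 1),
                              origin = c(0, 0, 0)) {
  new("DisplacementField", displacement = displacement,
      spacing = as.numeric(spacing), origin = as.numeric(origin))
}

#' Zero displacement field on a reference grid
#'
#' @param reference a \linkS4class{GridVolume} derivative providing the grid.
#' @return a \linkS4class{DisplacementField} with all-zero displacements.
#' @export
zeroField <- function(reference) {
  d <- gridDim(reference)
  displacementField(array(0, c(d, 3L)), gridSpacing(reference),
                    gridOrigin(reference))
}

#' Construct a StructureSet
#'
#' @param masks named list of 3D logical arrays on a common grid.
#' @param spacing,origin grid geometry (mm).
#' @param landmarks optional numeric matrix (n x 3, mm) with rownames.
#' @param provenance "ground_truth", "dir_generated" or "transferred".
#' @param dim integer(3); required only when \code{masks} is empty.
#' @return a \linkS4class{StructureSet}.
#' @export
structureSet <- function(masks, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         landmarks = NULL, provenance = "ground_truth",
                         dim = NULL) {
  if (is.null(dim)) {
    if (!length(masks)) stop("dim must be given when masks is empty")
    dim <- base::dim(masks[[1]])
  }
  if (is.null(landmarks)) landmarks <- matrix(numeric(0), 0, 3)
  new("StructureSet", dim = as.integer(dim), masks = masks,
      spacing = as.numeric(spacing), origin = as.numeric(origin),
      landmarks = landmarks, provenance = provenance)
}

#' Construct a RigidTransform
#'
#' @param translation numeric(3), mm.
#' @param rotation numeric(3) small Euler angles, degrees.
#' @param center numeric(3) rotation centre, mm.
#' @return a \linkS4class{RigidTransform}.
#' @export
rigidTransform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                           center = c(0, 0, 0)) {
  new("RigidTransform", translation = as.numeric(translation),
      rotation = as.numeric(rotation), center = as.numeric(center))
}

## ---- accessor methods -----------------------------------------------------

#' @rdname grid-accessors
setMethod("gridSpacing", "GridVolume", function(x) x@spacing)

#' @rdname grid-accessors
setMethod("gridOrigin", "GridVolume", function(x) x@origin)

#' @rdname grid-accessors
setMethod("gridDim", "ImageVolume", function(x) dim(x@voxels))

#' @rdname grid-accessors
setMethod("gridDim", "DoseGrid", function(x) dim(x@dose))

#' @rdname grid-accessors
setMethod("gridDim", "DisplacementField",
          function(x) dim(x@displacement)[1:3])

#' @rdname grid-accessors
setMethod("gridDim", "StructureSet", function(x) x@dim)

#' @describeIn ImageVolume-class raw HU array.
setMethod("gridValues", "ImageVolume", function(x) x@voxels)

#' @describeIn DoseGrid-class raw Gy array.
setMethod("gridValues", "DoseGrid", function(x) x@dose)

#' @describeIn DisplacementField-class raw 4D displacement array (mm).
setMethod("gridValues", "DisplacementField", function(x) x@displacement)

#' @describeIn ImageVolume-class role tag.
setMethod("gridRole", "ImageVolume", function(x) x@role)

#' @describeIn DoseGrid-class role tag.
setMethod("gridRole", "DoseGrid", function(x) x@role)

#' @describeIn StructureSet-class structure names.
setMethod("structureNames", "StructureSet", function(x) names(x@masks))

#' @describeIn StructureSet-class extract one mask.
setMethod("structureMask", "StructureSet", function(x, name) {
  if (!name %in% names(x@masks))
    stop(sprintf("unknown structure '%s'", name))
  x@masks[[name]]
})

#' @describeIn StructureSet-class landmark matrix.
setMethod("landmarks", "StructureSet", function(x) x@landmarks)

## ---- show methods ---------------------------------------------------------

.showGeometry <- function(x) {
  d <- gridDim(x)
  cat(sprintf("  grid: %d x %d x %d, spacing %s mm, origin %s mm\n",
              d[1], d[2], d[3],
              paste(format(gridSpacing(x), digits = 4), collapse = " x "),
              paste(format(gridOrigin(x), digits = 4), collapse = ", ")))
}

setMethod("show", "ImageVolume", function(object) {
  cat(sprintf("ImageVolume <%s>\n", object@role))
  .showGeometry(object)
  cat(sprintf("  HU range: [%.1f, %.1f]\n",
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "DoseGrid", function(object) {
  cat(sprintf("DoseGrid <%s>\n", object@role))
  .showGeometry(object)
  cat(sprintf("  dose range: [%.3f, %.3f] Gy\n",
              min(object@dose), max(object@dose)))
})

setMethod("show", "DisplacementField", function(object) {
  cat("DisplacementField (pull-back, mm)\n")
  .showGeometry(object)
  mag <- sqrt(rowSums(matrix(object@displacement,
                             ncol = 3L)^2))
  cat(sprintf("  |u|: mean %.3f, max %.3f mm\n", mean(mag), max(mag)))
})

setMethod("show", "StructureSet", function(object) {
  cat(sprintf("StructureSet <%s>\n", object@provenance))
  .showGeometry(object)
  vv <- prod(object@spacing) / 1000
  for (nm in names(object@masks))
    cat(sprintf("  %-10s %8.1f cc\n", nm, sum(object@masks[[nm]]) * vv))
  if (nrow(object@landmarks))
    cat(sprintf("  %d landmarks\n", nrow(object@landmarks)))
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform t = (%s) mm, r = (%s) deg\n",
              paste(format(object@translation, digits = 4), collapse = ", "),
              paste(format(object@rotation, digits = 4), collapse = ", ")))
})

setMethod("show", "PlanSpec", function(object) {
  cat(sprintf("PlanSpec: %g Gy in %d fractions (%.3f Gy/fx), %d beams\n",
              object@prescription_gy, object@n_fractions,
              object@prescription_gy / object@n_fractions,
              length(object@beams)))
  cat(sprintf("  isocenter (%s) mm, %s\n",
              paste(format(object@isocenter, digits = 4), collapse = ", "),
              if (is.na(object@normalization)) "not normalized"
              else sprintf("normalization %.5g Gy/unit", object@normalization)))
})

setMethod("show", "MergedCBCT", function(object) {
  cat(sprintf("MergedCBCT week %d\n", object@source_week))
  .showGeometry(object@volume)
  tab <- tabulate(object@provenance, 3L)
  cat(sprintf("  provenance: CBCT %d, deformed-pCT %d, blend %d voxels\n",
              tab[1], tab[2], tab[3]))
})

setMethod("show", "HUCalibration", function(object) {
  cat(sprintf("HUCalibration (%s): CT = %.4f * CBCT %+.2f HU\n",
              object@source, object@slope, object@intercept))
})
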