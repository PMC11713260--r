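#' Grid geometry accessors
#'
#' \code{gridSpacing}, \code{gridOrigin} and \code{gridDim} return the voxel
#' spacing (mm), the world coordinate of the first voxel centre (mm) and the
#' voxel counts per axis of any gridded object.
#'
#' @param x a \linkS4class{GridVolume} derivative.
#' @return numeric(3) (or integer(3) for \code{gridDim}).
#' @name grid-accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' @rdname grid-accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname grid-accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' Extract the raw value array of a gridded object
#'
#' Returns the underlying numeric array: HU voxels for an
#' \linkS4class{ImageVolume}, Gy values for a \linkS4class{DoseGrid}, the
#' 4D mm displacement array for a \linkS4class{DisplacementField}.
#'
#' @param x the object.
#' @return a numeric array.
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' Role tag of an image or dose object
#'
#' @param x an \linkS4class{ImageVolume} or \linkS4class{DoseGrid}.
#' @return character scalar.
#' @export
setGeneric("gridRole", function(x) standardGeneric("gridRole"))

#' Warp a gridded object through a displacement field
#'
#' Pull-back resampling: the output voxel at world position \code{x} takes
#' the input value at \code{x + u(x)}.  See \code{\link{applyDVF}} for the
#' functional interface; \code{warpVolume} is the generic the per-class
#' methods hang off.
#'
#' @param x object to warp (image, dose grid or structure set).
#' @param dvf a \linkS4class{DisplacementField} on the output grid.
#' @param ... passed to the methods (e.g. \code{interpolation}).
#' @return an object of the same class as \code{x}.
#' @export
setGeneric("warpVolume", function(x, dvf, ...) standardGeneric("warpVolume"))

#' Names of the masks in a structure set
#'
#' @param x a \linkS4class{StructureSet}.
#' @return character vector of structure names.
#' @export
setGeneric("structureNames", function(x) standardGeneric("structureNames"))

#' Extract one binary mask from a structure set
#'
#' @param x a \linkS4class{StructureSet}.
#' @param name structure name.
#' @return 3D logical array.
#' @export
setGeneric("structureMask", function(x, name) standardGeneric("structureMask"))

#' Landmark points of a structure set
#'
#' @param x a \linkS4class{StructureSet}.
#' @return numeric matrix (n x 3) of world points in mm with labelled rows.
#' @export
setGeneric("landmarks", function(x) standardGeneric("landmarks"))
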