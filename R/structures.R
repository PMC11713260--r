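## Contour propagation and geometric scoring: Dice similarity, target
## registration error, weekly volume statistics, and the phantom-based
## commissioning harness for the registration engine.

#' Propagate a structure set through a displacement field
#'
#' Warps every mask by pull-back linear interpolation thresholded at 0.5
#' and every landmark by pushing it through the inverse field mapping.
#' Provenance becomes "dir_generated".  A structure warped entirely out of
#' the grid yields an empty mask with a warning.
#'
#' @param structs a \linkS4class{StructureSet}.
#' @param dvf a \linkS4class{DisplacementField} on the target grid.
#' @return the propagated \linkS4class{StructureSet}.
#' @export
propagateStructures <- function(structs, dvf) {
  if (!identical(gridDim(structs), gridDim(dvf)))
    stop("geometry mismatch: structure grid must match the DVF grid")
  out <- lapply(structureNames(structs), function(nm) {
    m <- applyDVF(structureMask(structs, nm), dvf)
    if (!any(m) && any(structureMask(structs, nm)))
      warning(sprintf("structure '%s' warped entirely out of the grid", nm))
    m
  })
  names(out) <- structureNames(structs)
  structureSet(out, gridSpacing(structs), gridOrigin(structs),
               landmarks = landmarks(structs), provenance = "dir_generated")
}

#' Transfer structures rigidly
#'
#' Maps selected masks (typically the PTV, whose planning margins already
#' absorb deformation) by rigid resampling only; provenance becomes
#' "transferred".
#'
#' @param structs a \linkS4class{StructureSet}.
#' @param rigid a \linkS4class{RigidTransform} (output-to-input pull-back).
#' @param names structures to transfer (default: all).
#' @return a \linkS4class{StructureSet} holding the transferred masks.
#' @export
transferStructures <- function(structs, rigid, names = NULL) {
  if (is.null(names)) names <- structureNames(structs)
  missing <- setdiff(names, structureNames(structs))
  if (length(missing))
    stop("unknown structure: ", paste(missing, collapse = ", "))
  d <- gridDim(structs)
  pts <- applyRigidToPoints(rigid, .voxelCentres(d, gridSpacing(structs),
                                                 gridOrigin(structs)))
  idx <- .worldToIndex(pts, gridSpacing(structs), gridOrigin(structs))
  out <- lapply(names, function(nm) {
    array(.interpTrilinear(structureMask(structs, nm) + 0, idx,
                           pad = 0) >= 0.5, d)
  })
  names(out) <- names
  structureSet(out, gridSpacing(structs), gridOrigin(structs),
               provenance = "transferred")
}

#' Dice similarity coefficient
#'
#' \code{2 |A & B| / (|A| + |B|)}.  Two empty masks are defined to be
#' identical (DSC 1); empty vs non-empty gives 0.
#'
#' @param a,b 3D logical masks on the same grid.
#' @return DSC in [0, 1].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks must share one grid")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0L) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Target registration error
#'
#' Euclidean distances between predicted and true landmark positions,
#' matched by label.
#'
#' @param pred,truth numeric matrices (n x 3, mm) with matching rownames.
#' @return list with \code{per_point} (named mm distances), \code{mean} and
#'   \code{sd}.
#' @export
targetRegistrationError <- function(pred, truth) {
  if (is.null(rownames(pred)) || is.null(rownames(truth)) ||
      !setequal(rownames(pred), rownames(truth)))
    stop("landmark label mismatch")
  truth <- truth[rownames(pred), , drop = FALSE]
  d <- sqrt(rowSums((pred - truth)^2))
  list(per_point = d, mean = mean(d),
       sd = if (length(d) > 1L) stats::sd(d) else 0)
}

#' Categorize a Dice coefficient
#'
#' Total, deterministic banding of DSC values: "high" above 0.9, "low"
#' below 0.6, "medium" otherwise (both boundaries fall in "medium").
#'
#' @param d DSC values in [0, 1].
#' @return character vector of categories.
#' @export
dscCategory <- function(d) {
  if (any(d < 0 | d > 1)) stop("DSC must lie in [0, 1]")
  ifelse(d > 0.9, "high", ifelse(d < 0.6, "low", "medium"))
}

#' Weekly volume statistics for one structure
#'
#' Volumes by voxel counting, signed percent differences from the planning
#' mask, and the median percent difference across weeks (mean-of-middle-two
#' for even counts, i.e. \code{stats::median}).
#'
#' @param weekly_masks list of weekly 3D logical masks.
#' @param pct_mask the planning mask (non-empty).
#' @param spacing voxel spacing, mm.
#' @return list with \code{pct_cc}, \code{weekly_cc}, \code{percent_diff}
#'   and \code{median_percent_diff}.
#' @export
volumeStats <- function(weekly_masks, pct_mask, spacing = c(1, 1, 1)) {
  if (!length(weekly_masks)) stop("need at least one weekly mask")
  if (!any(pct_mask)) stop("empty planning mask")
  vv <- prod(spacing) / 1000
  v0 <- sum(pct_mask) * vv
  vw <- vapply(weekly_masks, function(m) sum(m) * vv, numeric(1))
  pd <- 100 * (vw - v0) / v0
  list(pct_cc = v0, weekly_cc = vw, percent_diff = pd,
       median_percent_diff = stats::median(pd))
}

#' Commissioning run of the registration engine on phantom ground truth
#'
#' Generates the phantom series, registers the planning CT to each weekly
#' volume, scores per-structure DSC between the propagated and ground-truth
#' masks and per-landmark TRE against the analytically displaced
#' landmarks, and returns a per-week, per-structure report plus summary
#' rows (mean +/- sd), in the style of a deformable-QA analysis.
#'
#' @param config a \code{\link{phantomConfig}}.
#' @param params \code{\link{registrationParams}} for the engine under
#'   test.
#' @param structures structure names to score.
#' @param weeks which weeks to include (default all five).
#' @return list with \code{table} (data.frame: week, structure, dsc,
#'   category), \code{tre} (data.frame: week, landmark, tre_mm),
#'   \code{summary} (data.frame with one row per structure plus an overall
#'   row: mean_dsc, sd_dsc, mean_tre_mm, sd_tre_mm) and \code{regularity}
#'   (per-week fraction of positive Jacobian determinant inside the body).
#' @export
commissioningRun <- function(config = phantomConfig(),
                             params = registrationParams(),
                             structures = c("bladder", "rectum", "target"),
                             weeks = 1:5) {
  p <- generatePlanningCT(config)
  series <- generateWeeklySeries(p$image, p$structures, config)
  rows <- list(); trerows <- list(); regrows <- list()
  for (w in weeks) {
    wk <- series$weeks[[w]]
    lim <- makeLimitingContour(wk)
    params$restrict_mask <- lim
    rig <- rigidRegister(wk, p$image, mask = lim, max_translation_mm = 12,
                         bone_threshold_hu = 200)
    dvf <- deformableRegister(wk, p$image, params = params, init = rig)
    prop <- propagateStructures(p$structures, dvf)
    truth <- series$truth$masks[[w]]
    for (nm in structures) {
      d <- dice(structureMask(prop, nm), structureMask(truth, nm))
      rows[[length(rows) + 1L]] <-
        data.frame(week = w, structure = nm, dsc = d,
                   category = dscCategory(d))
    }
    ## landmarks: predicted week position of each pCT landmark is the
    ## point whose registered (pull-back) source matches; evaluate by
    ## mapping pCT landmarks through the inverse of the registration field
    inv <- invertDVF(dvf)
    lm0 <- landmarks(p$structures)
    idx <- .worldToIndex(lm0, gridSpacing(p$image), gridOrigin(p$image))
    pred <- lm0
    for (c3 in 1:3)
      pred[, c3] <- lm0[, c3] +
        .interpTrilinear(inv@displacement[, , , c3], idx)
    tre <- targetRegistrationError(pred, series$truth$landmarks[[w]])
    trerows[[length(trerows) + 1L]] <-
      data.frame(week = w, landmark = names(tre$per_point),
                 tre_mm = unname(tre$per_point))
    ## field regularity QA: fraction of positive Jacobian inside the body
    jd <- jacobianDeterminant(dvf)
    body_w <- structureMask(series$truth$masks[[w]], "body")
    regrows[[length(regrows) + 1L]] <-
      data.frame(week = w, frac_positive_jacobian =
                   mean(jd$jacobian[body_w] > 0))
  }
  tab <- do.call(rbind, rows)
  tre <- do.call(rbind, trerows)
  per_struct <- do.call(rbind, lapply(structures, function(nm) {
    d <- tab$dsc[tab$structure == nm]
    data.frame(structure = nm, mean_dsc = mean(d), sd_dsc = stats::sd(d),
               mean_tre_mm = NA_real_, sd_tre_mm = NA_real_)
  }))
  overall <- data.frame(structure = "ALL", mean_dsc = mean(tab$dsc),
                        sd_dsc = stats::sd(tab$dsc),
                        mean_tre_mm = mean(tre$tre_mm),
                        sd_tre_mm = stats::sd(tre$tre_mm))
  list(table = tab, tre = tre, summary = rbind(per_struct, overall),
       regularity = do.call(rbind, regrows))
}
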