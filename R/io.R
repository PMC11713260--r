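## NIfTI volume I/O, study-table fixtures, and the end-to-end pipeline
## driver.  The on-disk grid convention is axis-aligned with world =
## origin + index * spacing (mm); orientation matrices beyond that are out
## of scope and rejected on read.

#' Write a gridded object to NIfTI
#'
#' Images and dose grids are written as 3D volumes, displacement fields as
#' 4D volumes (last dimension the x/y/z displacement in mm).  Spacing goes
#' to pixdim and the origin to the sform translation.
#'
#' @param x an \linkS4class{ImageVolume}, \linkS4class{DoseGrid} or
#'   \linkS4class{DisplacementField}.
#' @param path output file (.nii or .nii.gz).
#' @param datatype NIfTI storage type; "double" is lossless, "float"
#'   stores 32-bit.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(x, path, datatype = "double") {
  a <- gridValues(x)
  img <- RNifti::asNifti(a)
  sp <- gridSpacing(x)
  org <- gridOrigin(x)
  RNifti::pixdim(img) <- if (length(dim(a)) == 4L) c(sp, 1) else sp
  aff <- diag(c(sp, 1))
  aff[1:3, 4] <- org
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a gridded object from NIfTI
#'
#' @param path NIfTI file.
#' @param kind "image", "dose" or "dvf".
#' @param role role tag for image/dose results.
#' @return the matching object.
#' @export
readVolume <- function(path, kind = c("image", "dose", "dvf"),
                       role = "image") {
  kind <- match.arg(kind)
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim(img))  # strip the niftiImage class
  nd <- length(dim(a))
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  sp <- pd[1:3]
  xf <- RNifti::xform(img)
  org <- xf[1:3, 4]
  if (max(abs(xf[1:3, 1:3] - diag(sp))) > 1e-3 * max(sp))
    stop("header/grid mismatch: only axis-aligned volumes with ",
         "xform scale equal to pixdim are supported")
  if (kind == "dvf") {
    if (nd != 4L || dim(a)[4] != 3L)
      stop("a displacement field must be a 4D volume with last extent 3")
    return(displacementField(a, sp, org))
  }
  if (nd != 3L) stop("expected a 3D volume")
  if (kind == "dose") doseGrid(a, sp, org, role = role)
  else imageVolume(a, sp, org, role = role)
}

#' Write / read landmarks as CSV
#'
#' Plain CSV with columns name, x, y, z (mm).
#'
#' @param lm numeric matrix (n x 3) with rownames.
#' @param path file path.
#' @return \code{writeLandmarks}: the path, invisibly;
#'   \code{readLandmarks}: the landmark matrix.
#' @export
writeLandmarks <- function(lm, path) {
  utils::write.csv(data.frame(name = rownames(lm), x = lm[, 1],
                              y = lm[, 2], z = lm[, 3],
                              row.names = NULL),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeLandmarks
#' @export
readLandmarks <- function(path) {
  df <- utils::read.csv(path)
  m <- as.matrix(df[, c("x", "y", "z")])
  rownames(m) <- df$name
  m
}

#' Load one of the shipped study tables
#'
#' The package ships, as plain CSV, the per-patient summary tables of a
#' published 20-patient cervical-cancer CBCT dose-accumulation study:
#' organ volumes and weekly percent differences (T1), bladder / rectum /
#' PTV DVH-metric percent differences (T3, T4, T5), per-patient gamma pass
#' rates (T6) and ROI HU measurements (T7).  They allow the evaluation
#' layer's summary statistics to be recomputed exactly from printed
#' per-patient values.
#'
#' @param id one of "T1", "T3", "T4", "T5", "T6", "T7".
#' @return a data.frame with patient-labelled rows.
#' @export
loadStudyTable <- function(id = c("T1", "T3", "T4", "T5", "T6", "T7")) {
  id <- match.arg(id)
  file <- switch(id, T1 = "T1_volumes.csv", T3 = "T3_bladder.csv",
                 T4 = "T4_rectum.csv", T5 = "T5_ptv.csv",
                 T6 = "T6_gamma.csv", T7 = "T7_hu.csv")
  path <- system.file("extdata", "study_tables", file,
                      package = "doseAccum", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  nexp <- c(T1 = 20L, T3 = 20L, T4 = 20L, T5 = 20L, T6 = 20L, T7 = 9L)[[id]]
  if (nrow(df) != nexp)
    stop(sprintf("fixture %s is corrupt: %d rows, expected %d", id,
                 nrow(df), nexp))
  df
}

#' Run the full dose-accumulation pipeline on the synthetic phantom
#'
#' Executes the whole workflow: phantom generation, per-week merged-CBCT
#' construction (rigid + deformable registration under the limiting
#' contour), contour propagation and rigid PTV transfer, weekly dose
#' recalculation (ecD pathway) and planning-dose deformation (mdD
#' pathway), registration of each merged CBCT to the week-1 reference,
#' spatial accumulation of both dose sets, and the dosimetric evaluation
#' (DVH metric percent differences with bands, gamma pass rates, weekly
#' volume statistics).  All randomness derives from \code{config$seed}.
#'
#' @param config a \code{\link{phantomConfig}}.
#' @param reg_params \code{\link{registrationParams}} used for all
#'   deformable registrations.
#' @param prescription_gy,n_fractions plan prescription.
#' @param fractions_per_week accumulation weight per weekly CBCT.
#' @param metrics named list: structure -> character vector of DVH metric
#'   ids to evaluate.
#' @param gamma_structures structures scored with gamma (3%/2 mm, 20%
#'   threshold).
#' @param out_dir optional directory; when given, volumes (NIfTI), the
#'   report tables (CSV) and landmarks (CSV) are written there.
#' @return list with the phantom, plan, merged CBCTs, propagated
#'   structures, dose grids (pD, cumulative ecD/mdD), the evaluation
#'   report, volume statistics and gamma results.
#' @export
runPipeline <- function(config = phantomConfig(),
                        reg_params = registrationParams(),
                        prescription_gy = 45, n_fractions = 25L,
                        fractions_per_week = 5,
                        metrics = list(bladder = c("D2cc", "Dmax", "Dmean",
                                                   "D50", "V45"),
                                       rectum = c("D2cc", "Dmax", "Dmean",
                                                  "D50"),
                                       PTV45 = c("D90", "D98", "Dmax",
                                                 "Dmean")),
                        gamma_structures = c("bladder", "rectum"),
                        out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  ## (1) phantom
  phant <- stage("phantom", {
    p <- generatePlanningCT(config)
    list(p = p,
         series = generateWeeklySeries(p$image, p$structures, config))
  })
  pct <- phant$p$image
  structs <- phant$p$structures

  ## (2) plan + planning dose
  plan <- stage("plan", planNormalize(
    generatePlan(structs, prescription_gy, n_fractions), pct))
  pd <- stage("dose_pD", computeDose(pct, plan, role = "pD"))

  ## (3) merged CBCTs + contour propagation
  merged <- vector("list", 5L)
  props <- vector("list", 5L)
  for (w in 1:5) {
    merged[[w]] <- stage(sprintf("merge_week%d", w), {
      cb <- phant$series$weeks[[w]]
      mergeCBCT(pct, cb, makeLimitingContour(cb), params = reg_params,
                week = w)
    })
    props[[w]] <- stage(sprintf("propagate_week%d", w), {
      s <- propagateStructures(structs, merged[[w]]@dvf_pct_to_cbct)
      ## PTV is transferred, not deformed
      s@masks$PTV45 <- structureMask(
        transferStructures(structs, rigidTransform(), "PTV45"), "PTV45")
      s
    })
  }

  ## (4) weekly doses: ecD (recalculate) and mdD (deform pD)
  ec <- lapply(1:5, function(w) stage(sprintf("dose_ecD_week%d", w),
    computeDose(merged[[w]]@volume, plan, role = "ecD")))
  md <- lapply(1:5, function(w) stage(sprintf("dose_mdD_week%d", w), {
    out <- deformDose(pd, merged[[w]]@dvf_pct_to_cbct, role = "mdD")
    out
  }))

  ## (5) register weeks 2-5 to the week-1 reference and accumulate
  dvfs_ref <- vector("list", 5L)
  dvfs_ref[[1]] <- zeroField(pd)
  for (w in 2:5)
    dvfs_ref[[w]] <- stage(sprintf("register_ref_week%d", w),
      deformableRegister(merged[[1]]@volume, merged[[w]]@volume,
                         params = reg_params))
  sum_ec <- stage("accumulate_ecD",
    accumulateDose(ec, dvfs_ref, weights = rep(fractions_per_week, 5),
                   role = "sum_ecD"))
  sum_md <- stage("accumulate_mdD",
    accumulateDose(md, dvfs_ref, weights = rep(fractions_per_week, 5),
                   role = "sum_mdD"))
  pd_total <- doseGrid(pd@dose * n_fractions, pd@spacing, pd@origin,
                       role = "pD")

  ## (6) evaluation on the week-1 structures (reference anatomy)
  ref_structs <- props[[1]]
  rows <- list()
  gamma_rows <- list()
  gammas <- list()
  for (nm in names(metrics)) {
    msk <- structureMask(ref_structs, nm)
    if (!any(msk)) next
    for (met in metrics[[nm]]) {
      vals <- c(pD = dvhMetric(pd_total, msk, met),
                ecD = dvhMetric(sum_ec, msk, met),
                mdD = dvhMetric(sum_md, msk, met))
      cmp <- c(ecd_pd = if (vals[["pD"]] != 0)
                 percentDiff(vals[["ecD"]], vals[["pD"]]) else NA_real_,
               mdd_pd = if (vals[["pD"]] != 0)
                 percentDiff(vals[["mdD"]], vals[["pD"]]) else NA_real_,
               mdd_ecd = if (vals[["ecD"]] != 0)
                 percentDiff(vals[["mdD"]], vals[["ecD"]]) else NA_real_)
      for (cn in names(cmp))
        rows[[length(rows) + 1L]] <-
          data.frame(patient = "phantom", structure = nm, metric = met,
                     comparison = cn, percent_diff = unname(cmp[[cn]]))
    }
  }
  for (nm in gamma_structures) {
    msk <- structureMask(ref_structs, nm)
    if (!any(msk)) next
    for (cmp in c("ecd", "mdd")) {
      g <- stage(sprintf("gamma_%s_%s", nm, cmp),
        gammaAnalysis(pd_total, if (cmp == "ecd") sum_ec else sum_md, msk))
      gammas[[paste(nm, cmp, sep = "_")]] <- g
      gamma_rows[[length(gamma_rows) + 1L]] <-
        data.frame(patient = "phantom", structure = nm,
                   comparison = paste0("pd_", cmp),
                   pass_rate = g$pass_rate)
    }
  }
  metr_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient = character(0), structure = character(0),
               metric = character(0), comparison = character(0),
               percent_diff = numeric(0))
  gam_df <- if (length(gamma_rows)) do.call(rbind, gamma_rows) else NULL
  report <- buildReport(metr_df, gam_df)

  vols <- lapply(c(bladder = "bladder", rectum = "rectum"), function(nm)
    volumeStats(lapply(phant$series$truth$masks, structureMask, name = nm),
                structureMask(structs, nm), gridSpacing(pct)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeVolume(pct, file.path(out_dir, "pct.nii.gz"))
    writeVolume(pd_total, file.path(out_dir, "pd_total.nii.gz"))
    writeVolume(sum_ec, file.path(out_dir, "sum_ecd.nii.gz"))
    writeVolume(sum_md, file.path(out_dir, "sum_mdd.nii.gz"))
    for (w in 1:5)
      writeVolume(merged[[w]]@volume,
                  file.path(out_dir, sprintf("mcbct_w%d.nii.gz", w)))
    utils::write.csv(report$metrics,
                     file.path(out_dir, "metrics.csv"), row.names = FALSE)
    utils::write.csv(report$gamma_summary,
                     file.path(out_dir, "gamma_summary.csv"),
                     row.names = FALSE)
    writeLandmarks(landmarks(structs), file.path(out_dir, "landmarks.csv"))
  }

  list(config = config, pct = pct, structures = structs,
       series = phant$series, plan = plan, merged = merged,
       propagated = props, pd = pd, pd_total = pd_total,
       sum_ecd = sum_ec, sum_mdd = sum_md, report = report,
       volume_stats = vols, gamma = gammas)
}
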