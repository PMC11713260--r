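## Synthetic deformable pelvis phantom: planning CT, weekly CBCT series with
## analytic (diffeomorphic, invertible) ground-truth deformations, organ
## masks, landmarks and a four-field box plan.  Every downstream stage of
## the pipeline is testable against this ground truth without any external
## data.

#' Phantom configuration
#'
#' Defines the synthetic pelvis: grid geometry, organ placement and target
#' volumes, HU assignments, the per-week deformation/degradation schedule
#' and the CBCT field-of-view model.  Defaults emulate the study
#' conditions: a ~89 cc bladder and ~70 cc rectum pelvis (within the
#' reported 27-320 cc bladder and 42-177 cc rectum ranges), five weekly
#' CBCTs with bladder filling changes and small setup shifts, a CBCT
#' field of view of 465 mm transverse diameter and 160 mm longitudinal
#' extent, and HU values measured on a planning CT (bladder 11.4, muscle
#' 46.9, fat -97.9, cortical bone 851.0, trabecular bone 143.1).
#'
#' The weekly deformation is a composition of (a) a radial bladder
#' expansion/contraction about the bladder centre with Gaussian falloff
#' and (b) a global rigid shift; both are analytic, so the exact forward
#' map, its inverse and its Jacobian are available in closed form.
#' Inside the falloff core the anatomy scales uniformly, so a weekly
#' \code{bladder_scale} of k multiplies the bladder volume by exactly k.
#'
#' @param grid_shape integer(3) voxel counts.
#' @param spacing_mm numeric(3) voxel size, mm.  The world origin is chosen
#'   so the grid is centred on (0, 0, 0).
#' @param bladder_center numeric(3) mm.
#' @param bladder_axis_ratio numeric(3); semi-axis proportions, scaled to
#'   meet \code{bladder_volume_cc}.
#' @param bladder_volume_cc target bladder volume, cc (must lie in
#'   27-320 cc).
#' @param rectum_center_xy numeric(2) rectum axis position (x, y), mm.
#' @param rectum_radius_mm,rectum_length_mm rectum tube geometry, mm.
#' @param target_center,target_semi_axes uterus/cervix target ellipsoid, mm.
#' @param ptv_margin_mm isotropic PTV expansion of the target, mm.
#' @param body_semi_axes numeric(2) transverse body ellipse semi-axes, mm.
#' @param hu_map named numeric of HU assignments; must contain bladder,
#'   muscle, fat, cortical, trabecular, gas, air (target and rectum
#'   optional soft-tissue entries).
#' @param weekly_params list of 5 lists with elements \code{bladder_scale}
#'   (volume scale factor), \code{shift_mm} (numeric(3) rigid shift) and
#'   \code{gas} (NULL or list(offset_mm, radius_mm), a rectal gas pocket
#'   relative to the rectum centre).
#' @param falloff_sigma_mm Gaussian falloff length of the radial field
#'   beyond the bladder, mm.
#' @param cbct_fov named numeric: \code{transverse_mm} (FOV diameter) and
#'   \code{longitudinal_mm} (FOV length).  465/160 mm by default; the
#'   narrow +/- 87.5 mm transverse alternative can be configured.
#' @param cbct_noise_sd additive Gaussian noise, HU.
#' @param cbct_contrast_scale multiplicative HU scale of the CBCT.
#' @param cbct_shading_amplitude peak-to-centre radial quadratic shading,
#'   HU.
#' @param seed integer seed driving all phantom randomness.
#' @return a validated list of class \code{"PhantomConfig"}.
#' @export
phantomConfig <- function(grid_shape = c(96L, 96L, 48L),
                          spacing_mm = c(5, 5, 4),
                          bladder_center = c(0, -38, -15),
                          bladder_axis_ratio = c(1, 0.75, 0.85),
                          bladder_volume_cc = 89,
                          rectum_center_xy = c(0, 48),
                          rectum_radius_mm = 13.5,
                          rectum_length_mm = 120,
                          target_center = c(0, 12, 5),
                          target_semi_axes = c(24, 16, 30),
                          ptv_margin_mm = 7,
                          body_semi_axes = c(170, 110),
                          hu_map = c(bladder = 11.4, muscle = 46.9,
                                     fat = -97.9, cortical = 851.0,
                                     trabecular = 143.1, gas = -950,
                                     air = -1000, target = 60,
                                     rectum = 25),
                          weekly_params = NULL,
                          falloff_sigma_mm = 45,
                          cbct_fov = c(transverse_mm = 465,
                                       longitudinal_mm = 160),
                          cbct_noise_sd = 15,
                          cbct_contrast_scale = 0.9,
                          cbct_shading_amplitude = 25,
                          seed = 20240925) {
  if (is.null(weekly_params))
    weekly_params <- list(
      list(bladder_scale = 1.60, shift_mm = c(3, -2, 1), gas = NULL),
      list(bladder_scale = 1.30, shift_mm = c(-2, 3, -2),
           gas = list(offset_mm = c(0, 0, 20), radius_mm = 9)),
      list(bladder_scale = 0.75, shift_mm = c(1, 1, 3), gas = NULL),
      list(bladder_scale = 1.45, shift_mm = c(-3, -1, -2), gas = NULL),
      list(bladder_scale = 0.85, shift_mm = c(2, 2, -2),
           gas = list(offset_mm = c(0, 0, -25), radius_mm = 7)))
  cfg <- list(grid_shape = as.integer(grid_shape),
              spacing_mm = as.numeric(spacing_mm),
              bladder_center = bladder_center,
              bladder_axis_ratio = bladder_axis_ratio,
              bladder_volume_cc = bladder_volume_cc,
              rectum_center_xy = rectum_center_xy,
              rectum_radius_mm = rectum_radius_mm,
              rectum_length_mm = rectum_length_mm,
              target_center = target_center,
              target_semi_axes = target_semi_axes,
              ptv_margin_mm = ptv_margin_mm,
              body_semi_axes = body_semi_axes,
              hu_map = hu_map,
              weekly_params = weekly_params,
              falloff_sigma_mm = falloff_sigma_mm,
              cbct_fov = cbct_fov,
              cbct_noise_sd = cbct_noise_sd,
              cbct_contrast_scale = cbct_contrast_scale,
              cbct_shading_amplitude = cbct_shading_amplitude,
              seed = as.integer(seed))
  .validatePhantomConfig(cfg)
  structure(cfg, class = "PhantomConfig")
}

.validatePhantomConfig <- function(cfg) {
  if (any(cfg$spacing_mm <= 0)) stop("all spacings must be > 0")
  extent <- cfg$grid_shape * cfg$spacing_mm
  if (extent[1] < cfg$cbct_fov[["transverse_mm"]] ||
      extent[2] < cfg$cbct_fov[["transverse_mm"]])
    stop("grid too small for FOV: transverse extent ",
         paste(extent[1:2], collapse = " x "), " mm < FOV diameter ",
         cfg$cbct_fov[["transverse_mm"]], " mm")
  if (extent[3] < cfg$cbct_fov[["longitudinal_mm"]])
    stop("grid too small for FOV: longitudinal extent ", extent[3],
         " mm < FOV length ", cfg$cbct_fov[["longitudinal_mm"]], " mm")
  if (cfg$bladder_volume_cc < 27 || cfg$bladder_volume_cc > 320)
    stop("bladder_volume_cc must lie in the supported 27-320 cc range")
  hu <- cfg$hu_map
  need <- c("bladder", "muscle", "fat", "cortical", "trabecular", "gas",
            "air")
  if (!all(need %in% names(hu)))
    stop("hu_map must contain: ", paste(need, collapse = ", "))
  if (any(!is.finite(hu))) stop("hu_map values must be finite")
  if (!(max(hu[c("gas", "air")]) < hu[["fat"]] &&
        hu[["fat"]] < hu[["bladder"]] &&
        hu[["bladder"]] < hu[["muscle"]] &&
        hu[["muscle"]] < hu[["trabecular"]] &&
        hu[["trabecular"]] < hu[["cortical"]]))
    stop("hu_map ordering violated: need gas/air < fat < bladder < muscle ",
         "< trabecular < cortical")
  if (length(cfg$weekly_params) != 5L)
    stop("weekly_params must describe exactly 5 weeks")
  invisible(TRUE)
}

## grid origin placing the world centre of the volume at (0,0,0)
.phantomOrigin <- function(cfg) {
  -(cfg$grid_shape - 1) * cfg$spacing_mm / 2
}

## bladder semi-axes meeting the volume target: (4/3) pi a b c = V
.bladderSemiAxes <- function(cfg, scale = 1) {
  v_mm3 <- cfg$bladder_volume_cc * 1000 * scale
  r <- cfg$bladder_axis_ratio
  a <- (3 * v_mm3 / (4 * pi * prod(r)))^(1 / 3)
  a * r
}

#' Generate the planning CT and its structure set
#'
#' Paints an elliptical body with a fat rind and muscle interior, a bony
#' pelvic ring (cortical shell, trabecular core), bladder, rectum and a
#' uterus/cervix target, then derives the PTV45 by isotropic expansion.
#' Masks are exactly consistent with the painted HU regions.  Deterministic
#' (no randomness is used for the planning CT).
#'
#' @param config a \code{\link{phantomConfig}}.
#' @return list with elements \code{image} (an \linkS4class{ImageVolume},
#'   role "pCT") and \code{structures} (a \linkS4class{StructureSet} with
#'   masks body, bones, bladder, rectum, target, PTV45 and six landmarks).
#' @export
generatePlanningCT <- function(config) {
  .validatePhantomConfig(config)
  d <- config$grid_shape
  sp <- config$spacing_mm
  org <- .phantomOrigin(config)
  X <- .voxelCentres(d, sp, org)
  hu <- config$hu_map

  bsa <- config$body_semi_axes
  rho2 <- (X[, 1] / bsa[1])^2 + (X[, 2] / bsa[2])^2
  body <- array(rho2 <= 1, d)

  ## bone ring (normalised elliptical annulus, pelvis height band)
  rb <- sqrt((X[, 1] / 150)^2 + (X[, 2] / 100)^2)
  inband <- rb >= 0.84 & rb <= 0.95 & abs(X[, 3]) <= 50
  cortical <- array(inband & (rb >= 0.92 | rb <= 0.87), d)
  trabecular <- array(inband & rb > 0.87 & rb < 0.92, d)
  bones <- cortical | trabecular

  ba <- .bladderSemiAxes(config)
  bc <- config$bladder_center
  bladder <- array(((X[, 1] - bc[1]) / ba[1])^2 +
                     ((X[, 2] - bc[2]) / ba[2])^2 +
                     ((X[, 3] - bc[3]) / ba[3])^2 <= 1, d)

  rc <- config$rectum_center_xy
  rectum <- array((X[, 1] - rc[1])^2 + (X[, 2] - rc[2])^2 <=
                    config$rectum_radius_mm^2 &
                    abs(X[, 3]) <= config$rectum_length_mm / 2, d)

  tc <- config$target_center
  ts <- config$target_semi_axes
  target <- array(((X[, 1] - tc[1]) / ts[1])^2 +
                    ((X[, 2] - tc[2]) / ts[2])^2 +
                    ((X[, 3] - tc[3]) / ts[3])^2 <= 1, d)

  organs <- list(bladder = bladder, rectum = rectum, target = target)
  nm <- names(organs)
  for (i in 1:2) for (j in (i + 1):3)
    if (any(organs[[i]] & organs[[j]]))
      stop(sprintf("organ overlap after placement: %s and %s collide",
                   nm[i], nm[j]))

  ptv <- .dilateMask(target, config$ptv_margin_mm, sp)

  vox <- array(hu[["air"]], d)
  fat <- body & array(rho2 > 0.64, d)
  vox[body] <- hu[["muscle"]]
  vox[fat] <- hu[["fat"]]
  vox[trabecular] <- hu[["trabecular"]]
  vox[cortical] <- hu[["cortical"]]
  vox[target] <- if ("target" %in% names(hu)) hu[["target"]] else
    hu[["muscle"]]
  vox[bladder] <- hu[["bladder"]]
  vox[rectum] <- if ("rectum" %in% names(hu)) hu[["rectum"]] else
    hu[["muscle"]]

  vv <- prod(sp) / 1000
  vol_cc <- sum(bladder) * vv
  if (abs(vol_cc - config$bladder_volume_cc) / config$bladder_volume_cc >
      0.05)
    stop(sprintf("bladder discretisation failed the 5%% volume target: %.1f vs %.1f cc",
                 vol_cc, config$bladder_volume_cc))

  lm <- rbind(bladder_centroid = bc,
              bladder_fid = bc + c(ba[1], 0, 0),
              rectum_centroid = c(rc, 0),
              rectum_fid = c(rc[1], rc[2] + config$rectum_radius_mm, 30),
              target_centroid = tc,
              target_fid = tc + c(0, ts[2], 0))
  colnames(lm) <- c("x", "y", "z")

  list(image = imageVolume(vox, sp, org, role = "pCT"),
       structures = structureSet(list(body = body, bones = bones,
                                      bladder = bladder, rectum = rectum,
                                      target = target, PTV45 = ptv),
                                 sp, org, landmarks = lm,
                                 provenance = "ground_truth"))
}

## ---- analytic deformation model -------------------------------------------

## radial profile: rho(r) = r * (1 + (lambda-1) h(r)),
## h = 1 for r <= R0, exp(-(r-R0)^2 / (2 sigma^2)) beyond.
.radialRho <- function(r, lambda, R0, sigma) {
  h <- ifelse(r <= R0, 1, exp(-(r - R0)^2 / (2 * sigma^2)))
  r * (1 + (lambda - 1) * h)
}

.radialRhoPrime <- function(r, lambda, R0, sigma) {
  h <- ifelse(r <= R0, 1, exp(-(r - R0)^2 / (2 * sigma^2)))
  hp <- ifelse(r <= R0, 0, -(r - R0) / sigma^2 * h)
  1 + (lambda - 1) * (h + r * hp)
}

## forward point map of one week: phi(x) = c + rho(|x-c|) n + shift
.weekForward <- function(pts, center, lambda, R0, sigma, shift) {
  dx <- sweep(pts, 2, center, "-")
  r <- sqrt(rowSums(dx^2))
  f <- ifelse(r > 0, .radialRho(r, lambda, R0, sigma) / r, lambda)
  sweep(dx * f, 2, center + shift, "+")
}

## inverse point map (vectorised bisection on the monotone radial profile)
.weekInverse <- function(pts, center, lambda, R0, sigma, shift) {
  y <- sweep(pts, 2, center + shift, "-")
  R <- sqrt(rowSums(y^2))
  lo <- pmin(R, R / max(lambda, 1e-9))
  hi <- pmax(R, R / max(lambda, 1e-9)) + 1e-9
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    v <- .radialRho(mid, lambda, R0, sigma)
    smaller <- v < R
    lo[smaller] <- mid[smaller]
    hi[!smaller] <- mid[!smaller]
  }
  r <- (lo + hi) / 2
  f <- ifelse(R > 0, r / R, 1 / lambda)
  sweep(y * f, 2, center, "+")
}

## analytic Jacobian determinant of the radial map at source radius r
.radialJacobian <- function(r, lambda, R0, sigma) {
  rho <- .radialRho(r, lambda, R0, sigma)
  drho <- .radialRhoPrime(r, lambda, R0, sigma)
  ratio <- ifelse(r > 0, rho / r, lambda)
  drho * ratio^2
}

#' Evaluate a week's analytic ground-truth deformation at points
#'
#' Exposes the closed-form forward map so tests and oracles can evaluate
#' the exact deformation without touching the gridded field.
#'
#' @param pts numeric matrix (n x 3) of pCT world points, mm.
#' @param config the \code{\link{phantomConfig}}.
#' @param week week index 1-5.
#' @param inverse if TRUE evaluate the inverse map (week-to-pCT).
#' @return transformed points (n x 3), mm.
#' @export
phantomDeformPoints <- function(pts, config, week, inverse = FALSE) {
  wp <- config$weekly_params[[week]]
  lambda <- wp$bladder_scale^(1 / 3)
  R0 <- max(.bladderSemiAxes(config))
  fun <- if (inverse) .weekInverse else .weekForward
  fun(pts, config$bladder_center, lambda, R0, config$falloff_sigma_mm,
      wp$shift_mm)
}

#' Generate the weekly CBCT series with ground truth
#'
#' For each of the five weeks: applies the analytic deformation (radial
#' bladder expansion/contraction composed with a rigid shift) to the
#' planning CT, optionally inserts a rectal gas pocket, then applies the
#' CBCT degradation model (multiplicative contrast scale, radial quadratic
#' shading, additive Gaussian noise, FOV truncation to the configured
#' cylinder and longitudinal extent; voxels outside the FOV carry
#' -1000 HU).  Returns the degraded weekly volumes together with the
#' ground truth: the exact displacement field of each week (pull-back, on
#' the week grid, so warping the pCT by it reproduces the week anatomy),
#' the warped structure masks and the analytically displaced landmarks.
#'
#' Reproducible: the RNG is seeded from \code{config$seed} so identical
#' configs give bit-identical series.
#'
#' @param pct planning \linkS4class{ImageVolume} from
#'   \code{\link{generatePlanningCT}}.
#' @param structs the matching \linkS4class{StructureSet}.
#' @param config the \code{\link{phantomConfig}}.
#' @return list with \code{weeks} (list of 5 CBCT
#'   \linkS4class{ImageVolume}s), \code{truth} (list with \code{dvf},
#'   \code{masks}, \code{landmarks}, one entry per week) and
#'   \code{fov_mask} (the 3D logical valid-FOV region).
#' @export
generateWeeklySeries <- function(pct, structs, config) {
  .validatePhantomConfig(config)
  d <- gridDim(pct)
  sp <- gridSpacing(pct)
  org <- gridOrigin(pct)
  X <- .voxelCentres(d, sp, org)
  hu <- config$hu_map
  R0 <- max(.bladderSemiAxes(config))
  sigma <- config$falloff_sigma_mm
  ctr <- config$bladder_center

  ## FOV mask (shared across weeks): transverse cylinder + longitudinal band
  fov_r <- config$cbct_fov[["transverse_mm"]] / 2
  fov_l <- config$cbct_fov[["longitudinal_mm"]] / 2
  fov <- array(X[, 1]^2 + X[, 2]^2 <= fov_r^2 & abs(X[, 3]) <= fov_l, d)

  set.seed(config$seed)
  weeks <- vector("list", 5L)
  dvfs <- vector("list", 5L)
  masks <- vector("list", 5L)
  lms <- vector("list", 5L)
  for (w in 1:5) {
    wp <- config$weekly_params[[w]]
    lambda <- wp$bladder_scale^(1 / 3)
    ## guard against folding: check the analytic radial Jacobian
    rgrid <- seq(0, max(d * sp), length.out = 512L)
    if (min(.radialJacobian(rgrid, lambda, R0, sigma)) <= 0)
      stop(sprintf("week %d deformation too strong: analytic Jacobian <= 0",
                   w))
    src <- .weekInverse(X, ctr, lambda, R0, sigma, wp$shift_mm)
    u <- array(src - X, c(d, 3L))  # pull-back displacement, mm
    dvf <- displacementField(u, sp, org)

    anat <- .warpArray(pct@voxels, dvf, "trilinear", pad = hu[["air"]])

    wk_masks <- lapply(structureNames(structs), function(nm)
      applyDVF(structureMask(structs, nm), dvf))
    names(wk_masks) <- structureNames(structs)

    if (!is.null(wp$gas)) {
      gc <- c(config$rectum_center_xy, 0) + wp$gas$offset_mm + wp$shift_mm
      gm <- (X[, 1] - gc[1])^2 + (X[, 2] - gc[2])^2 +
        (X[, 3] - gc[3])^2 <= wp$gas$radius_mm^2
      anat[gm] <- hu[["gas"]]
    }

    lm_true <- phantomDeformPoints(landmarks(structs), config, w)
    rownames(lm_true) <- rownames(landmarks(structs))

    ## CBCT degradation
    v <- anat * config$cbct_contrast_scale
    if (config$cbct_shading_amplitude != 0) {
      rho2 <- (X[, 1]^2 + X[, 2]^2) / fov_r^2
      v <- v + config$cbct_shading_amplitude * (rho2 - 0.5) * fov
    }
    if (config$cbct_noise_sd > 0)
      v <- v + array(stats::rnorm(prod(d), 0, config$cbct_noise_sd), d)
    v[!fov] <- -1000

    weeks[[w]] <- imageVolume(array(v, d), sp, org, role = "CBCT")
    dvfs[[w]] <- dvf
    masks[[w]] <- structureSet(wk_masks, sp, org, landmarks = lm_true,
                               provenance = "ground_truth")
    lms[[w]] <- lm_true
  }
  list(weeks = weeks,
       truth = list(dvf = dvfs, masks = masks, landmarks = lms),
       fov_mask = fov)
}

#' Build the four-field box plan
#'
#' Creates beams at gantry 0/90/180/270 degrees with rectangular apertures
#' equal to the PTV beam's-eye-view projection plus a margin, isocenter at
#' the PTV centroid, and stores the prescription.  The plan must be
#' normalized on the planning anatomy with \code{\link{planNormalize}}
#' before doses are computed.
#'
#' @param structs \linkS4class{StructureSet} containing a non-empty PTV
#'   mask.
#' @param prescription_gy total prescription, Gy (> 0).
#' @param n_fractions number of fractions (> 0).
#' @param ptv_name name of the PTV mask (default "PTV45").
#' @param aperture_margin_mm margin added around the PTV projection, mm.
#' @return an unnormalized \linkS4class{PlanSpec}.
#' @export
generatePlan <- function(structs, prescription_gy = 45, n_fractions = 25L,
                         ptv_name = "PTV45", aperture_margin_mm = 7) {
  if (prescription_gy <= 0) stop("prescription must be > 0")
  if (n_fractions <= 0) stop("fraction count must be > 0")
  ptv <- structureMask(structs, ptv_name)
  if (!any(ptv)) stop("PTV mask is empty")
  sp <- gridSpacing(structs)
  org <- gridOrigin(structs)
  idx <- which(ptv, arr.ind = TRUE)
  w <- sweep(sweep(idx - 1, 2, sp, "*"), 2, org, "+")
  iso <- colMeans(w)
  ext <- unname(apply(w, 2, range))
  m <- aperture_margin_mm
  ## BEV axes: u = in-plane axis perpendicular to the beam, v = z
  ap_x <- c(u_min = ext[1, 2] - m, u_max = ext[2, 2] + m,
            v_min = ext[1, 3] - m, v_max = ext[2, 3] + m)  # beams along x: u=y
  ap_y <- c(u_min = ext[1, 1] - m, u_max = ext[2, 1] + m,
            v_min = ext[1, 3] - m, v_max = ext[2, 3] + m)  # beams along y: u=x
  beams <- list(list(gantry_deg = 0, aperture = ap_y, weight = 1),
                list(gantry_deg = 90, aperture = ap_x, weight = 1),
                list(gantry_deg = 180, aperture = ap_y, weight = 1),
                list(gantry_deg = 270, aperture = ap_x, weight = 1))
  new("PlanSpec", isocenter = as.numeric(iso), beams = beams,
      prescription_gy = prescription_gy,
      n_fractions = as.integer(n_fractions))
}
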