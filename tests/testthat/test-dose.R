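# Simplified dose engine, dose deformation and accumulation.

test_that("HU to density lookup anchors and interpolates", {
  expect_equal(huToRelativeDensity(-1000), 0)
  expect_equal(huToRelativeDensity(0), 1)
  expect_equal(huToRelativeDensity(500), 1.3)
  expect_equal(huToRelativeDensity(-2000), 0)     # clamped
  expect_equal(huToRelativeDensity(3000), 1.6)    # clamped
  a <- huToRelativeDensity(array(c(-1000, 0), c(2, 1, 1)))
  expect_true(is.array(a))
})

test_that("single-beam depth dose in water matches the closed-form kernel", {
  d <- c(21L, 40L, 21L)
  sp <- c(5, 5, 5)
  org <- -(d - 1) * sp / 2
  water <- imageVolume(array(0, d), sp, org)   # HU 0 -> density 1
  ap <- c(u_min = -200, u_max = 200, v_min = -200, v_max = 200)
  plan <- methods::new("PlanSpec", isocenter = c(0, 0, 0),
                       beams = list(list(gantry_deg = 0, aperture = ap,
                                         weight = 1)),
                       prescription_gy = 45, n_fractions = 25L,
                       normalization = 1,
                       kernel = c(mu_eff = 0.005, d_max = 15,
                                  penumbra_mm = 6))
  dose <- computeDose(water, plan)
  # beam from +y: water-equivalent depth at voxel j is (ny - j + 0.5) * sp
  j <- c(5, 10, 15, 20, 25, 28, 31, 34, 37, 39)
  w <- (d[2] - j + 0.5) * sp[2]
  expected <- pmin(w / 15, 1) * exp(-0.005 * w)
  got <- gridValues(dose)[11, j, 11]
  expect_equal(got, expected, tolerance = 1e-6)
})

test_that("plan normalization delivers the per-fraction prescription at the isocenter", {
  ph <- tinyPhantom()
  plan <- planNormalize(generatePlan(ph$structs), ph$pct)
  pd <- computeDose(ph$pct, plan, role = "pD")
  iso <- round(doseAccum:::.worldToIndex(matrix(plan@isocenter, 1),
                                         gridSpacing(ph$pct),
                                         gridOrigin(ph$pct)))
  expect_equal(gridValues(pd)[iso[1], iso[2], iso[3]], 1.8,
               tolerance = 1e-9)
  expect_equal(gridRole(pd), "pD")
  expect_error(computeDose(ph$pct, generatePlan(ph$structs)),
               "not normalized")
})

test_that("isocenter in air is rejected", {
  d <- c(16L, 16L, 16L)
  sp <- c(5, 5, 5)
  org <- -(d - 1) * sp / 2
  v <- array(-1000, d)
  v[6:11, 6:11, 6:11] <- 0
  vol <- imageVolume(v, sp, org)
  ap <- c(u_min = -10, u_max = 10, v_min = -10, v_max = 10)
  plan <- methods::new("PlanSpec", isocenter = c(-35, -35, -35),
                       beams = list(list(gantry_deg = 0, aperture = ap,
                                         weight = 1)),
                       prescription_gy = 45, n_fractions = 25L,
                       kernel = c(mu_eff = 0.005, d_max = 15,
                                  penumbra_mm = 6))
  expect_error(planNormalize(plan, vol), "outside body")
})

test_that("a lower-density path increases downstream dose (attenuation monotonicity)", {
  d <- c(21L, 40L, 21L)
  sp <- c(5, 5, 5)
  org <- -(d - 1) * sp / 2
  base <- array(0, d)
  lo <- base; lo[8:14, 25:32, 8:14] <- -700    # low-density insert upstream
  hi <- base; hi[8:14, 25:32, 8:14] <- 700     # high-density insert
  ap <- c(u_min = -200, u_max = 200, v_min = -200, v_max = 200)
  plan <- methods::new("PlanSpec", isocenter = c(0, 0, 0),
                       beams = list(list(gantry_deg = 0, aperture = ap,
                                         weight = 1)),
                       prescription_gy = 45, n_fractions = 25L,
                       normalization = 1,
                       kernel = c(mu_eff = 0.005, d_max = 15,
                                  penumbra_mm = 6))
  d_lo <- gridValues(computeDose(imageVolume(lo, sp, org), plan))[11, 10, 11]
  d_hi <- gridValues(computeDose(imageVolume(hi, sp, org), plan))[11, 10, 11]
  expect_gt(d_lo, d_hi)
})

test_that("dose deformation: identity, translation invariance, co-warping consistency", {
  set.seed(8)
  d <- c(16L, 16L, 16L)
  sp <- c(4, 4, 4)
  dose <- doseGrid(array(runif(prod(d), 0, 2), d), sp)
  expect_identical(gridValues(deformDose(dose, zeroField(dose))),
                   gridValues(dose))
  # uniform block translated by an integer voxel: Dmax and integral preserved
  blk <- array(0, d); blk[5:10, 5:10, 5:10] <- 1.5
  bd <- doseGrid(blk, sp)
  u <- array(0, c(d, 3)); u[, , , 1] <- sp[1]
  tb <- deformDose(bd, displacementField(u, sp))
  expect_equal(max(gridValues(tb)), max(gridValues(bd)))
  expect_lt(abs(sum(gridValues(tb)) - sum(gridValues(bd))) /
              sum(gridValues(bd)), 0.005)
  # co-warping: DVH of warped dose over warped mask ~ original over original
  ph <- tinyPhantom()
  dvf <- ph$series$truth$dvf[[2]]
  plan <- planNormalize(generatePlan(ph$structs), ph$pct)
  pd <- computeDose(ph$pct, plan)
  blad <- structureMask(ph$structs, "bladder")
  wd <- deformDose(pd, dvf)
  wm <- applyDVF(blad, dvf)
  m0 <- dvhMetric(pd, blad, "Dmean")
  m1 <- dvhMetric(wd, wm, "Dmean")
  expect_lt(abs(m1 - m0) / m0, 0.02)
})

test_that("accumulation is linear, weighted, and reproduces the 45 Gy total", {
  ph <- tinyPhantom()
  plan <- planNormalize(generatePlan(ph$structs), ph$pct)
  pd <- computeDose(ph$pct, plan)
  ids <- lapply(1:5, function(i) zeroField(pd))
  doses <- lapply(1:5, function(i) pd)
  acc <- accumulateDose(doses, ids, role = "sum_ecD")
  expect_equal(gridValues(acc), 25 * gridValues(pd), tolerance = 1e-9)
  expect_equal(gridRole(acc), "sum_ecD")
  iso <- round(doseAccum:::.worldToIndex(matrix(plan@isocenter, 1),
                                         gridSpacing(ph$pct),
                                         gridOrigin(ph$pct)))
  expect_equal(gridValues(acc)[iso[1], iso[2], iso[3]], 45, tolerance = 1e-6)
  # one week zeroed -> 4/5 of the identity cumulative everywhere
  doses0 <- doses
  doses0[[3]] <- doseGrid(array(0, gridDim(pd)), gridSpacing(pd),
                          gridOrigin(pd))
  acc0 <- accumulateDose(doses0, ids)
  expect_equal(gridValues(acc0), 0.8 * gridValues(acc), tolerance = 1e-12)
  expect_error(accumulateDose(doses[1:4], ids), "equal length")
})

test_that("accumulation through known analytic fields matches a direct-evaluation oracle", {
  # deform each weekly dose by the exact inverse analytic map instead of
  # gridded fields and compare bladder Dmean of the cumulative dose
  ph <- tinyPhantom()
  plan <- planNormalize(generatePlan(ph$structs), ph$pct)
  pd <- computeDose(ph$pct, plan)
  # weekly dose = dose computed on the (exactly known) deformed anatomy
  weekly <- lapply(1:5, function(w)
    computeDose(applyDVF(ph$pct, ph$series$truth$dvf[[w]]), plan))
  # fields mapping week-1 (reference) anatomy into week w: composition of
  # the analytic maps, evaluated pointwise (the oracle's transform)
  d <- gridDim(ph$pct)
  X <- doseAccum:::.voxelCentres(d, gridSpacing(ph$pct), gridOrigin(ph$pct))
  flds <- lapply(1:5, function(w) {
    if (w == 1) return(zeroField(pd))
    src <- phantomDeformPoints(
      phantomDeformPoints(X, ph$cfg, 1, inverse = TRUE), ph$cfg, w)
    displacementField(array(src - X, c(d, 3)), gridSpacing(ph$pct),
                      gridOrigin(ph$pct))
  })
  acc <- accumulateDose(weekly, flds)
  blad1 <- structureMask(ph$series$truth$masks[[1]], "bladder")
  got <- dvhMetric(acc, blad1, "Dmean")
  # oracle: evaluate each weekly dose at the analytically mapped points of
  # the bladder voxels directly (no gridded warp of the dose)
  vox <- which(blad1)
  pts1 <- X[vox, , drop = FALSE]
  pct_pts <- phantomDeformPoints(pts1, ph$cfg, 1, inverse = TRUE)
  total <- numeric(length(vox))
  for (w in 1:5) {
    pw <- if (w == 1) pts1 else phantomDeformPoints(pct_pts, ph$cfg, w)
    idx <- doseAccum:::.worldToIndex(pw, gridSpacing(ph$pct),
                                     gridOrigin(ph$pct))
    total <- total + 5 * doseAccum:::.interpTrilinear(gridValues(weekly[[w]]),
                                                      idx)
  }
  expect_lt(abs(got - mean(total)) / mean(total), 0.05)
})
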