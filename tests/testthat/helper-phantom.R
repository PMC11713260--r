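# Shared small-scale fixtures, built once per session and cached.

.cache <- new.env(parent = emptyenv())

# coarse phantom: fast to generate, large enough for organ geometry
tinyConfig <- function(...) {
  phantomConfig(grid_shape = c(48L, 48L, 26L), spacing_mm = c(8, 8, 8),
                cbct_fov = c(transverse_mm = 380, longitudinal_mm = 160),
                ...)
}

tinyPhantom <- function() {
  if (is.null(.cache$tiny)) {
    cfg <- tinyConfig()
    p <- generatePlanningCT(cfg)
    ser <- generateWeeklySeries(p$image, p$structures, cfg)
    .cache$tiny <- list(cfg = cfg, pct = p$image, structs = p$structures,
                        series = ser)
  }
  .cache$tiny
}

# identity-week phantom without degradation (CBCT = FOV-cropped pCT)
identityConfig <- function(...) {
  idw <- lapply(1:5, function(i)
    list(bladder_scale = 1, shift_mm = c(0, 0, 0), gas = NULL))
  phantomConfig(weekly_params = idw, cbct_noise_sd = 0,
                cbct_contrast_scale = 1, cbct_shading_amplitude = 0, ...)
}

# light registration parameters for unit tests (accuracy not under test)
liteParams <- function(...) {
  registrationParams(iterations = c(40L, 40L, 25L, 15L), ...)
}

# smooth random blob image for registration tests
blobImage <- function(d = c(32L, 32L, 32L), spacing = c(4, 4, 4), seed = 42,
                      sd_hu = 300) {
  set.seed(seed)
  a <- array(stats::rnorm(prod(d)), d)
  a <- doseAccum:::.smoothGaussian(a, c(2, 2, 2))
  a <- (a - mean(a)) / stats::sd(a) * sd_hu
  imageVolume(a, spacing, -(d - 1) * spacing / 2)
}

# landmark prediction through the inverse of a registration field
predictLandmarks <- function(lm0, dvf) {
  inv <- suppressWarnings(invertDVF(dvf))
  idx <- doseAccum:::.worldToIndex(lm0, gridSpacing(inv), gridOrigin(inv))
  pred <- lm0
  for (c3 in 1:3)
    pred[, c3] <- lm0[, c3] +
      doseAccum:::.interpTrilinear(gridValues(inv)[, , , c3], idx)
  pred
}
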