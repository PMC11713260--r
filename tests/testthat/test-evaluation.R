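# DVH metrics, percent-difference banding, Wilcoxon, gamma, reporting.

test_that("cumulative DVH is a step function with the right plateaus", {
  d <- c(10L, 10L, 1L)
  dose <- doseGrid(array(45, d), spacing = c(10, 10, 10))  # 1 cc voxels
  mask <- array(TRUE, d)
  curve <- computeDVH(dose, mask, bin_width_gy = 0.5)
  expect_equal(curve$volume_fraction[curve$dose_gy <= 45],
               rep(1, sum(curve$dose_gy <= 45)))
  expect_equal(curve$volume_fraction[curve$dose_gy > 45],
               rep(0, sum(curve$dose_gy > 45)))
  expect_equal(curve$total_cc, 100)
  # two voxels at 40 and 50 Gy: V(45) is half the volume
  d2 <- c(2L, 1L, 1L)
  dg <- doseGrid(array(c(40, 50), d2), spacing = c(10, 10, 10))
  cv <- computeDVH(dg, array(TRUE, d2), bin_width_gy = 1)
  expect_equal(cv$volume_fraction[cv$dose_gy == 45], 0.5)
  # monotone non-increasing for random dose
  set.seed(2)
  rg <- doseGrid(array(runif(64, 0, 60), c(4, 4, 4)))
  rc <- computeDVH(rg, array(TRUE, c(4, 4, 4)), 0.25)
  expect_true(all(diff(rc$volume_cc) <= 1e-12))
  expect_error(computeDVH(rg, array(FALSE, c(4, 4, 4))), "empty mask")
})

test_that("DVH metrics follow the voxel-boundary convention", {
  # ten 1 cc voxels with doses 1..10 Gy
  d <- c(10L, 1L, 1L)
  dose <- doseGrid(array(1:10, d), spacing = c(10, 10, 10))
  mask <- array(TRUE, d)
  expect_equal(dvhMetric(dose, mask, "D2cc"), 9)
  expect_equal(dvhMetric(dose, mask, "Dmax"), 10)
  expect_equal(dvhMetric(dose, mask, "Dmean"), 5.5)
  expect_equal(dvhMetric(dose, mask, "D50"), 6)
  # uniform 45 Gy, 100 cc
  u <- doseGrid(array(45, c(10L, 10L, 1L)), spacing = c(10, 10, 10))
  um <- array(TRUE, c(10L, 10L, 1L))
  expect_equal(dvhMetric(u, um, "V45"), 100)
  expect_equal(dvhMetric(u, um, "D90"), 45)
  # D2cc requires more than 2 cc
  small <- doseGrid(array(5, c(3L, 1L, 1L)), spacing = c(5, 10, 10))  # 1.5 cc
  expect_error(dvhMetric(small, array(TRUE, c(3L, 1L, 1L)), "D2cc"),
               "2 cc")
  expect_error(dvhMetric(u, um, "Q13"), "unknown")
})

test_that("DVH metrics equal a sort-based brute-force oracle on random masks", {
  set.seed(17)
  for (rep in 1:5) {
    d <- c(10L, 10L, 10L)
    sp <- runif(3, 3, 8)
    dose <- doseGrid(array(rexp(prod(d), 1 / 20), d), sp)
    mask <- array(runif(prod(d)) < 0.4, d)
    if (sum(mask) < 60) next
    v <- dose@dose[mask]
    vox_cc <- prod(sp) / 1000
    oracle_dx <- function(frac) {
      s <- sort(v, decreasing = TRUE)
      cum <- seq_along(s) * vox_cc
      s[which(cum >= frac * length(v) * vox_cc - 1e-12)[1]]
    }
    expect_equal(dvhMetric(dose, mask, "Dmax"), max(v), tolerance = 1e-9)
    expect_equal(dvhMetric(dose, mask, "Dmean"), mean(v), tolerance = 1e-9)
    expect_equal(dvhMetric(dose, mask, "D50"), oracle_dx(0.5),
                 tolerance = 1e-9)
    expect_equal(dvhMetric(dose, mask, "D90"), oracle_dx(0.9),
                 tolerance = 1e-9)
    s <- sort(v, decreasing = TRUE)
    expect_equal(dvhMetric(dose, mask, "D2cc"),
                 s[which(seq_along(s) * vox_cc >= 2 - 1e-12)[1]],
                 tolerance = 1e-9)
    expect_equal(dvhMetric(dose, mask, "V45"), sum(v >= 45) * vox_cc,
                 tolerance = 1e-9)
  }
})

test_that("percent differences are signed and reject a zero reference", {
  expect_equal(percentDiff(51.5, 50), 3)
  expect_equal(percentDiff(50, 50), 0)
  expect_equal(percentDiff(45, 50), -10)
  expect_error(percentDiff(1, 0), "zero reference")
})

test_that("banding uses boundaries inclusive downward", {
  expect_equal(as.character(diffBand(c(1.9, -4.6, 15.3, 2, 5, -2, -5, 5.01))),
               c("<=2", "2-5", ">5", "<=2", "2-5", "<=2", "2-5", ">5"))
})

test_that("within-threshold counts reproduce the published summaries", {
  t3 <- loadStudyTable("T3")
  t4 <- loadStudyTable("T4")
  t5 <- loadStudyTable("T5")
  both <- c("ecd_pd", "mdd_pd")
  expect_equal(countWithin(t3, paste0("D2cc_", both), 5), 19)
  expect_equal(countWithin(t3, paste0("Dmax_", both), 5), 17)
  expect_equal(countWithin(t3, paste0("Dmean_", both), 5), 16)
  expect_equal(countWithin(t3, paste0("D2cc_", both), 2), 11)
  expect_equal(countWithin(t4, paste0("D2cc_", both), 5), 18)
  expect_equal(countWithin(t4, paste0("Dmax_", both), 5), 13)
  expect_equal(countWithin(t5, paste0("D90_", both), 2), 19)
  expect_equal(countWithin(t5, paste0("D98_", both), 5), 18)
  # any threshold large enough admits everyone
  expect_equal(countWithin(t3, paste0("V45_", both), 1000), 20)
  expect_error(countWithin(t3, "nope", 5), "missing comparison")
})

test_that("exact Wilcoxon signed-rank matches full sign-pattern enumeration", {
  enumerate_p <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    V <- sum(r[d > 0])
    vs <- vapply(0:(2^n - 1), function(code) {
      sgn <- as.integer(intToBits(code))[1:n]
      sum(r[sgn == 1])
    }, numeric(1))
    min(1, 2 * min(mean(vs <= V), mean(vs >= V)))
  }
  set.seed(33)
  for (rep in 1:8) {
    n <- sample(5:12, 1)
    a <- round(rnorm(n), 1)
    b <- round(rnorm(n), 1)   # rounding forces occasional ties/zeros
    got <- wilcoxonSignedRank(a, b)
    expect_equal(got$p, enumerate_p(a - b), tolerance = 1e-12)
  }
  # canonical example: six all-positive differences
  got <- wilcoxonSignedRank(c(1, 2, 3, 4, 5, 6) + 10, rep(10, 6))
  expect_equal(got$p, 2 / 64)
  expect_equal(got$statistic, 21)
  # identical vectors
  expect_equal(wilcoxonSignedRank(1:6, 1:6)$p, 1)
})

test_that("exact Wilcoxon agrees with stats::wilcox.test on tie-free data", {
  set.seed(41)
  a <- rnorm(10)
  b <- rnorm(10)
  got <- wilcoxonSignedRank(a, b)
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
  expect_equal(got$p, unname(ref$p.value), tolerance = 1e-12)
  expect_equal(got$statistic, unname(ref$statistic))
})

test_that("Wilcoxon detects a one-sd shift in most seeded replicates", {
  hits <- 0L
  for (i in 1:200) {
    set.seed(1000 + i)
    a <- rnorm(20)
    b <- a + 1 + rnorm(20, sd = 0.2)
    if (wilcoxonSignedRank(a, b)$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})

test_that("gamma analysis: identity, uniform offset boundary, scale invariance", {
  set.seed(12)
  d <- c(16L, 16L, 16L)
  sp <- c(4, 4, 4)
  base <- doseAccum:::.smoothGaussian(array(runif(prod(d), 20, 60), d),
                                      c(1.5, 1.5, 1.5))
  ref <- doseGrid(base, sp)
  mask <- array(TRUE, d)
  g0 <- gammaAnalysis(ref, ref, mask)
  expect_equal(g0$pass_rate, 100)
  expect_equal(max(g0$gamma, na.rm = TRUE), 0)
  # uniform 50 Gy vs 51.5 Gy: gamma exactly 1 everywhere, boundary pass
  u <- doseGrid(array(50, d), sp)
  v <- doseGrid(array(51.5, d), sp)
  g1 <- gammaAnalysis(u, v, mask)
  expect_equal(g1$pass_rate, 100)
  expect_equal(unique(round(g1$gamma[!is.na(g1$gamma)], 9)), 1)
  # global normalization: scaling both grids leaves gamma unchanged
  g2 <- gammaAnalysis(doseGrid(2 * base, sp),
                      doseGrid(2 * base + 1e-9, sp), mask)
  expect_equal(g2$pass_rate, 100)
  expect_error(gammaAnalysis(ref, ref, array(FALSE, d)), "empty mask")
})

test_that("gamma pass rate does not increase when criteria tighten", {
  ph <- tinyPhantom()
  plan <- planNormalize(generatePlan(ph$structs), ph$pct)
  pd <- computeDose(ph$pct, plan)
  wd <- deformDose(pd, ph$series$truth$dvf[[3]])
  mask <- structureMask(ph$structs, "bladder")
  p32 <- gammaAnalysis(pd, wd, mask, dose_crit = 3, dist_crit = 2)$pass_rate
  p22 <- gammaAnalysis(pd, wd, mask, dose_crit = 2, dist_crit = 2)$pass_rate
  p31 <- gammaAnalysis(pd, wd, mask, dose_crit = 3, dist_crit = 1)$pass_rate
  expect_lte(p22, p32 + 1e-9)
  expect_lte(p31, p32 + 1e-9)
})

test_that("gamma matches an exhaustive dense-search oracle on a small grid", {
  # reference with a smooth gradient; evaluated = reference translated by
  # 2.2 mm along x
  d <- c(32L, 32L, 8L)
  sp <- c(2, 2, 2)
  X <- doseAccum:::.voxelCentres(d, sp, c(0, 0, 0))
  ref_a <- array(40 + 0.6 * X[, 1] + 0.2 * X[, 2], d)
  idx <- doseAccum:::.worldToIndex(cbind(X[, 1] + 2.2, X[, 2], X[, 3]),
                                   sp, c(0, 0, 0))
  ev_a <- array(doseAccum:::.interpTrilinear(ref_a, idx, pad = 0), d)
  ref <- doseGrid(ref_a, sp)
  ev <- doseGrid(ev_a, sp)
  mask <- array(FALSE, d)
  mask[8:25, 8:25, 4:5] <- TRUE
  res <- gammaAnalysis(ref, ev, mask)
  # oracle: full dense search without shells or early termination, on a
  # subsample of evaluated voxels
  dn <- max(ref_a)
  dd_gy <- 0.03 * dn
  off1 <- seq(-30, 30) * 0.2
  offs <- as.matrix(expand.grid(off1, off1, off1))
  offs <- offs[sqrt(rowSums(offs^2)) <= 6 + 1e-9, ]
  sel <- which(!is.na(res$gamma) & mask)
  set.seed(5)
  sel <- sample(sel, 25)
  ii <- arrayInd(sel, d)
  for (k in seq_along(sel)) {
    pts <- cbind(ii[k, 1] + offs[, 1] / sp[1],
                 ii[k, 2] + offs[, 2] / sp[2],
                 ii[k, 3] + offs[, 3] / sp[3])
    evd <- doseAccum:::.interpTrilinear(ev_a, pts, pad = NA)
    g2 <- (evd - ref_a[sel[k]])^2 / dd_gy^2 + rowSums(offs^2) / 4
    oracle <- sqrt(min(g2, na.rm = TRUE))
    expect_lt(abs(res$gamma[sel[k]] - oracle), 0.02)
  }
})

test_that("report assembly summarises gamma means and band counts", {
  t6 <- loadStudyTable("T6")
  gr <- do.call(rbind, lapply(c("bladder_pd_ecd", "rectum_pd_ecd",
                                "bladder_pd_mdd", "rectum_pd_mdd"),
                              function(cn) {
    parts <- strsplit(cn, "_")[[1]]
    data.frame(patient = t6$patient, structure = parts[1],
               comparison = paste(parts[2], parts[3], sep = "_"),
               pass_rate = t6[[cn]])
  }))
  metrics <- data.frame(patient = "P1", structure = "bladder",
                        metric = "D2cc", comparison = "ecd_pd",
                        percent_diff = 4.5)
  rep <- buildReport(metrics, gr)
  gs <- rep$gamma_summary
  expect_equal(round(gs$mean_pass_rate[gs$structure == "bladder" &
                                         gs$comparison == "pd_ecd"]), 94)
  expect_equal(as.character(rep$metrics$band), "2-5")
  # empty inputs survive
  empty <- buildReport(metrics[0, ], NULL)
  expect_equal(nrow(empty$band_counts), 0)
  # single patient: means equal that patient's values
  one <- buildReport(metrics, gr[gr$patient == "P1", ])
  expect_equal(one$gamma_summary$mean_pass_rate,
               gr$pass_rate[gr$patient == "P1"][
                 order(gr$structure[gr$patient == "P1"],
                       gr$comparison[gr$patient == "P1"])])
})
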