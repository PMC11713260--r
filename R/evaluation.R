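## Dosimetric evaluation: DVH construction and metrics, percent-difference
## banding and within-threshold counting, exact Wilcoxon signed-rank
## testing, and 3D gamma analysis.

#' Cumulative dose-volume histogram
#'
#' Voxel-counting cumulative DVH: for each bin edge d, the volume (absolute
#' cc and fraction) receiving at least d Gy.
#'
#' @param dose a \linkS4class{DoseGrid}.
#' @param mask non-empty 3D logical mask on the dose grid.
#' @param bin_width_gy histogram bin width, Gy.
#' @return list of class "DVHCurve": \code{dose_gy} (bin edges),
#'   \code{volume_cc}, \code{volume_fraction}, \code{total_cc}.
#' @export
computeDVH <- function(dose, mask, bin_width_gy = 0.01) {
  if (!identical(dim(mask), gridDim(dose)))
    stop("mask grid must match the dose grid")
  if (!any(mask)) stop("empty mask")
  v <- dose@dose[mask]
  vv <- prod(dose@spacing) / 1000
  edges <- seq(0, max(v) + bin_width_gy, by = bin_width_gy)
  ## cumulative count of voxels with dose >= edge
  cnt <- length(v) - findInterval(edges - 1e-12, sort(v))
  structure(list(dose_gy = edges, volume_cc = cnt * vv,
                 volume_fraction = cnt / length(v),
                 total_cc = length(v) * vv),
            class = "DVHCurve")
}

#' DVH metrics
#'
#' Computes one of: \code{Dmax} (hottest voxel), \code{Dmean},
#' \code{D2cc} (minimum dose of the hottest 2 cc), \code{Dx} for x in
#' percent (minimum dose of the hottest x\% of the structure, e.g.
#' \code{"D50"}, \code{"D90"}, \code{"D98"}), and \code{Vd} for d in Gy
#' (absolute volume in cc receiving at least d Gy, e.g. \code{"V45"}).
#' Dose-at-volume metrics use the voxel-boundary convention: voxel doses
#' are sorted descending and the value at the first voxel whose cumulative
#' volume reaches the requested volume is returned.
#'
#' @param dose a \linkS4class{DoseGrid}.
#' @param mask non-empty 3D logical mask on the dose grid.
#' @param which metric id: "Dmax", "Dmean", "D2cc", "D<x>", "V<d>".
#' @return metric value (Gy for D-metrics, cc for V-metrics).
#' @export
dvhMetric <- function(dose, mask, which) {
  if (!identical(dim(mask), gridDim(dose)))
    stop("mask grid must match the dose grid")
  if (!any(mask)) stop("empty mask")
  v <- dose@dose[mask]
  vv <- prod(dose@spacing) / 1000
  total_cc <- length(v) * vv
  if (which == "Dmax") return(max(v))
  if (which == "Dmean") return(mean(v))
  if (which == "D2cc") {
    if (total_cc <= 2)
      stop("D2cc undefined: structure volume <= 2 cc")
    return(.doseAtVolume(v, vv, 2))
  }
  if (grepl("^D[0-9.]+$", which)) {
    x <- as.numeric(sub("^D", "", which))
    if (x <= 0 || x > 100) stop("Dx requires x in (0, 100]")
    return(.doseAtVolume(v, vv, total_cc * x / 100))
  }
  if (grepl("^V[0-9.]+$", which)) {
    d <- as.numeric(sub("^V", "", which))
    return(sum(v >= d) * vv)
  }
  stop(sprintf("unknown DVH metric '%s'", which))
}

## minimum dose of the hottest `vol_cc` of the voxel list (voxel-boundary
## convention)
.doseAtVolume <- function(v, voxel_cc, vol_cc) {
  s <- sort(v, decreasing = TRUE)
  k <- which(seq_along(s) * voxel_cc >= vol_cc - 1e-12)[1]
  if (is.na(k)) k <- length(s)
  s[k]
}

#' Signed percent difference
#'
#' \code{100 (value - reference) / reference}; the planning dose is the
#' reference throughout the workflow.
#'
#' @param value,reference numeric (Gy or cc); reference must be non-zero.
#' @return signed percent difference.
#' @export
percentDiff <- function(value, reference) {
  if (any(reference == 0)) stop("zero reference in percent difference")
  100 * (value - reference) / reference
}

#' Band a percent difference
#'
#' Three-way banding of |percent difference| with boundaries inclusive
#' downward: \code{<=2}, \code{2-5} (2 < |pd| <= 5) and \code{>5}.
#'
#' @param pd signed percent differences.
#' @return factor with levels "<=2", "2-5", ">5".
#' @export
diffBand <- function(pd) {
  a <- abs(pd)
  factor(ifelse(a <= 2, "<=2", ifelse(a <= 5, "2-5", ">5")),
         levels = c("<=2", "2-5", ">5"))
}

#' Count patients within a percent-difference threshold
#'
#' Counts the rows of a percent-difference table whose absolute value is
#' within the threshold for every requested comparison column
#' simultaneously ("regardless of the method of dose calculation").
#'
#' @param table data.frame of signed percent differences, one row per
#'   patient, comparisons as columns.
#' @param comparisons column names to require.
#' @param threshold percent threshold (inclusive).
#' @return integer count.
#' @export
countWithin <- function(table, comparisons, threshold) {
  missing <- setdiff(comparisons, colnames(table))
  if (length(missing))
    stop("missing comparison column: ", paste(missing, collapse = ", "))
  sub <- abs(as.matrix(table[, comparisons, drop = FALSE]))
  if (anyNA(sub)) stop("missing cells in percent-difference table")
  sum(apply(sub <= threshold, 1, all))
}

#' Exact Wilcoxon signed-rank test
#'
#' Two-sided paired test with the classical conventions: zero differences
#' dropped, ties mid-ranked.  The null distribution of the positive-rank
#' sum is computed exactly by enumerating the generating polynomial over
#' the realized (mid-)ranks for n <= \code{exact_max} (equivalent to full
#' sign-pattern enumeration); larger samples use the normal approximation
#' with tie correction and continuity correction.
#'
#' @param a,b paired numeric vectors (length >= 5).
#' @param exact_max largest post-zero-drop n for the exact branch.
#' @return list with \code{statistic} (V, positive-rank sum), \code{p},
#'   \code{n} (pairs used) and \code{method}.
#' @export
wilcoxonSignedRank <- function(a, b, exact_max = 25L) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 5L) stop("need at least 5 pairs")
  d <- a - b
  d <- d[d != 0]
  if (!length(d))
    return(list(statistic = 0, p = 1, n = 0L, method = "degenerate"))
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exact_max) {
    ## ranks on a half-unit lattice; enumerate P(V = v) by polynomial
    ## multiplication over 2r (integer lattice)
    r2 <- round(2 * r)
    maxs <- sum(r2)
    poly <- numeric(maxs + 1L)  # index i-1 = rank-sum value
    poly[1L] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), poly[seq_len(maxs + 1L - ri)])
      poly <- poly + shifted
    }
    poly <- poly / 2^n
    v2 <- round(2 * V)
    p_le <- sum(poly[seq_len(v2 + 1L)])
    p_ge <- sum(poly[(v2 + 1L):(maxs + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = V, p = p, n = n, method = method)
}

#' 3D gamma analysis
#'
#' Global-normalization gamma: for every reference voxel inside the mask
#' with dose at or above \code{low_threshold} percent of the reference
#' maximum, the gamma index is the minimum over a spherical search
#' neighbourhood (radius \code{3 * dist_crit}, trilinear interpolation of
#' the evaluated dose on a lattice of step \code{dist_crit / 10}) of
#' \code{sqrt((dd / (dose_crit% Dmax))^2 + (|dr| / dist_crit)^2)}.  The
#' search proceeds over shells of increasing radius with early termination
#' once the spatial term alone exceeds the running minimum, which is exact
#' for the lattice.  Pass rate is the percentage of evaluated voxels with
#' gamma <= 1.
#'
#' @param reference,evaluated \linkS4class{DoseGrid}s on a common grid.
#' @param mask non-empty 3D logical mask (evaluation region).
#' @param dose_crit dose criterion, percent of the global normalization.
#' @param dist_crit distance-to-agreement criterion, mm.
#' @param low_threshold low-dose cutoff, percent of the normalization.
#' @param pass_rate_threshold pass/fail flag level, percent.
#' @param step_mm search lattice step (default \code{dist_crit / 10}).
#' @return list of class "GammaResult": \code{gamma} (3D array, NA outside
#'   the evaluated region), \code{pass_rate} (percent), \code{pass}
#'   (logical flag), \code{n_evaluated} and \code{criteria}.
#' @export
gammaAnalysis <- function(reference, evaluated, mask,
                          dose_crit = 3, dist_crit = 2, low_threshold = 20,
                          pass_rate_threshold = 90, step_mm = NULL) {
  .stopGeometry(reference, evaluated, "reference and evaluated dose")
  if (!identical(dim(mask), gridDim(reference)))
    stop("mask grid must match the dose grid")
  if (!any(mask)) stop("empty mask")
  d <- gridDim(reference)
  sp <- gridSpacing(reference)
  dnorm_gy <- max(reference@dose)
  if (dnorm_gy <= 0) stop("reference dose is identically zero")
  dd_gy <- dose_crit / 100 * dnorm_gy
  eval_sel <- mask & reference@dose >= low_threshold / 100 * dnorm_gy
  if (!any(eval_sel))
    stop("empty evaluated region after the low-dose threshold")
  if (is.null(step_mm)) step_mm <- dist_crit / 10
  r_max <- 3 * dist_crit

  vox <- which(eval_sel)
  refv <- reference@dose[vox]
  idx0 <- which(eval_sel, arr.ind = TRUE)  # integer voxel indices
  n <- nrow(idx0)

  ## shift lattice grouped into shells of increasing |shift|
  steps <- floor(r_max / step_mm)
  off1 <- seq(-steps, steps) * step_mm
  offs <- as.matrix(expand.grid(dx = off1, dy = off1, dz = off1))
  rr <- sqrt(rowSums(offs^2))
  keep <- rr <= r_max + 1e-9
  offs <- offs[keep, , drop = FALSE]
  rr <- rr[keep]
  shell <- findInterval(rr, seq(0, r_max + step_mm, by = step_mm),
                        left.open = TRUE) # 1 + floor index; rr=0 -> 0
  ord <- order(shell, rr)
  offs <- offs[ord, , drop = FALSE]
  rr <- rr[ord]
  shell <- shell[ord]

  g2 <- rep(Inf, n)   # running min gamma^2
  active <- rep(TRUE, n)
  ev <- evaluated@dose
  for (sh in sort(unique(shell))) {
    ## smallest spatial term reachable in this or any later shell
    spat2 <- (max(sh - 1, 0) * step_mm / dist_crit)^2
    active <- active & g2 > spat2
    if (!any(active)) break
    sel <- which(shell == sh)
    ai <- which(active)
    ## chunk to bound memory: n_active x n_shell interpolations
    chunk <- max(1L, floor(4e6 / length(sel)))
    for (start in seq(1L, length(ai), by = chunk)) {
      ii <- ai[start:min(start + chunk - 1L, length(ai))]
      base <- idx0[ii, , drop = FALSE]
      m <- length(ii); s <- length(sel)
      pts <- cbind(rep(base[, 1], each = s) + rep(offs[sel, 1] / sp[1], m),
                   rep(base[, 2], each = s) + rep(offs[sel, 2] / sp[2], m),
                   rep(base[, 3], each = s) + rep(offs[sel, 3] / sp[3], m))
      evd <- .interpTrilinear(ev, pts, pad = NA)
      dd2 <- (matrix(evd, nrow = s) -
                matrix(refv[ii], nrow = s, ncol = m, byrow = TRUE))^2 /
        dd_gy^2
      dr2 <- matrix((rr[sel] / dist_crit)^2, nrow = s, ncol = m)
      tot <- dd2 + dr2
      tot[is.na(tot)] <- Inf  # out-of-grid samples cannot contribute
      g2[ii] <- pmin(g2[ii], apply(tot, 2, min))
    }
  }
  gam <- sqrt(g2)
  out <- array(NA_real_, d)
  out[vox] <- gam
  pr <- 100 * mean(gam <= 1 + 1e-9)
  structure(list(gamma = out, pass_rate = pr,
                 pass = pr >= pass_rate_threshold,
                 n_evaluated = n,
                 criteria = c(dose_pct = dose_crit, dist_mm = dist_crit,
                              low_threshold_pct = low_threshold,
                              normalization_gy = dnorm_gy)),
            class = "GammaResult")
}

#' Assemble the evaluation report tables
#'
#' Collects per-patient, per-structure DVH metric percent differences,
#' their bands, gamma pass rates and summary lines (band counts, mean
#' gamma per structure and comparison) into plain data.frames ready for
#' CSV export.
#'
#' @param metrics data.frame with columns patient, structure, metric,
#'   comparison, percent_diff (may have zero rows).
#' @param gamma_rates data.frame with columns patient, structure,
#'   comparison, pass_rate (may have zero rows or be NULL).
#' @return list with \code{metrics} (input plus band column),
#'   \code{band_counts} (per structure/metric/comparison/band),
#'   \code{gamma_summary} (mean pass rate per structure/comparison) and
#'   \code{text} (one-line summaries).
#' @export
buildReport <- function(metrics, gamma_rates = NULL) {
  stopifnot(is.data.frame(metrics))
  if (nrow(metrics)) {
    metrics$band <- diffBand(metrics$percent_diff)
    bc <- stats::aggregate(patient ~ structure + metric + comparison + band,
                           data = metrics, FUN = length)
    names(bc)[names(bc) == "patient"] <- "count"
  } else {
    metrics$band <- factor(character(0), levels = c("<=2", "2-5", ">5"))
    bc <- data.frame(structure = character(0), metric = character(0),
                     comparison = character(0),
                     band = character(0), count = integer(0))
  }
  gs <- NULL
  txt <- character(0)
  if (!is.null(gamma_rates) && nrow(gamma_rates)) {
    gs <- stats::aggregate(pass_rate ~ structure + comparison,
                           data = gamma_rates, FUN = mean)
    names(gs)[names(gs) == "pass_rate"] <- "mean_pass_rate"
    txt <- c(txt, sprintf("mean gamma pass rate %s %s: %.1f%% (rounds to %d%%)",
                          gs$structure, gs$comparison, gs$mean_pass_rate,
                          round(gs$mean_pass_rate)))
  } else {
    gs <- data.frame(structure = character(0), comparison = character(0),
                     mean_pass_rate = numeric(0))
  }
  list(metrics = metrics, band_counts = bc, gamma_summary = gs, text = txt)
}
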