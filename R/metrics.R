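# Quantification of polarization: cluster statistics on spherical membrane
# fields, exponential growth-rate fits, and the microscopy-style line-scan
# cap-width estimator (Gaussian blur + Gaussian fit + FWHM).

#' Cluster statistics of a membrane density field
#'
#' Locates the density maximum, estimates the background as the
#' area-weighted spatial median, measures the cluster height (maximum over
#' background) and the full width at half maximum as arc length along the
#' great circle through the cap center, and counts distinct clusters
#' (local maxima exceeding background + 25% of the global height, after
#' smoothing by spherical-harmonic truncation).
#'
#' @param object A [SystemState-class] (the total membrane Cdc42 density
#'   mT + mD is analyzed) or a numeric matrix (ntheta x nphi) membrane
#'   field.
#' @param params Optional [ModelParameters-class]; when given with a
#'   SystemState, per-protein membrane fractions are included (and
#'   conservation is checked).
#' @param ... Passed on to methods.
#' @return A [ClusterStats-class] object.
#' @export
setGeneric("clusterStats", function(object, params = NULL, ...)
  standardGeneric("clusterStats"))

#' @rdname clusterStats
#' @param grid Grid (from [sphereGrid()]) for the matrix method.
#' @param compute_fwhm Set FALSE to skip the great-circle FWHM scan.
#' @param smooth_l Truncation degree for cluster-count smoothing
#'   (default 16).
#' @param count_threshold Fraction of the global height a local maximum
#'   must exceed (above background) to count as a cluster (default 0.25).
#' @param merge_angle Candidate maxima closer than this geodesic angle
#'   (radians) are merged into one cluster (default 0.6).
#' @param background One of `"median"` (spatial median, default) or
#'   `"lower-half-mean"` (mean of the lower half of the field).
#' @export
setMethod("clusterStats", "matrix",
          function(object, params = NULL, grid, compute_fwhm = TRUE,
                   smooth_l = 16L, count_threshold = 0.25,
                   merge_angle = 0.6, background = c("median",
                                                     "lower-half-mean"),
                   ...) {
  background <- match.arg(background)
  g <- grid
  f <- object
  if (any(f < -1e-9 * max(abs(f), 1e-300)))
    stop("membrane field must be nonnegative")
  wfull <- rep(g$wtheta, times = g$nphi)
  if (background == "median") {
    bg <- .weightedMedian(as.vector(f), wfull)
  } else {
    v <- as.vector(f); o <- order(v)
    cw <- cumsum(wfull[o]) / sum(wfull)
    keep <- o[cw <= 0.5]
    bg <- sum(v[keep] * wfull[keep]) / sum(wfull[keep])
  }
  imax <- which(f == max(f), arr.ind = TRUE)[1, ]
  height <- max(f) - bg
  # flat field: no measurable cluster
  if (height <= 1e-10 * max(abs(f), 1e-300) || height <= 0) {
    return(new("ClusterStats", nClusters = 0L, height = 0,
               fwhm = NA_real_, center = c(0, 0, 1), background = bg,
               membraneFractions = c(cdc42 = NA_real_, bem1 = NA_real_,
                                     cdc24 = NA_real_)))
  }
  th <- g$theta[imax[1]]; ph <- g$phi[imax[2]]
  center <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  C <- .shtAnalyze(g, f)
  # refine peak position and value spectrally (the quadrature grid is not
  # rotation invariant; the band-limited field is)
  pk <- .refinePeak(g, C, center, max(f))
  center <- pk$center
  height <- pk$value - bg
  fwhm <- NA_real_
  if (compute_fwhm)
    fwhm <- .greatCircleFWHM(g, C, center, bg)
  n <- .countClusters(g, C, bg, height, smooth_l, count_threshold,
                      merge_angle)
  new("ClusterStats", nClusters = n, height = height, fwhm = fwhm,
      center = center, background = bg,
      membraneFractions = c(cdc42 = NA_real_, bem1 = NA_real_,
                            cdc24 = NA_real_))
})

#' @rdname clusterStats
#' @export
setMethod("clusterStats", "SystemState",
          function(object, params = NULL, ...) {
  f <- membraneField(object, "cdc42")
  cs <- clusterStats(f, grid = object@grid, ...)
  if (!is.null(params))
    cs@membraneFractions <- membraneFractions(object, params)
  cs
})

setMethod("show", "ClusterStats", function(object) {
  cat("ClusterStats\n")
  cat(sprintf("  clusters: %d; height: %.4g um^-2 over background %.4g\n",
              object@nClusters, object@height, object@background))
  cat(sprintf("  FWHM: %s um; center: (%.3f, %.3f, %.3f)\n",
              format(object@fwhm, digits = 4), object@center[1],
              object@center[2], object@center[3]))
  fr <- object@membraneFractions
  if (!all(is.na(fr)))
    cat(sprintf("  membrane fractions: Cdc42 %.1f%%, Bem1 %.1f%%, Cdc24 %.1f%%\n",
                100 * fr[["cdc42"]], 100 * fr[["bem1"]], 100 * fr[["cdc24"]]))
})

# refine the location/value of a band-limited field's maximum by repeated
# local search on shrinking geodesic stencils around the grid argmax
.refinePeak <- function(g, C, center, value, rounds = 3L) {
  rho <- pi / g$L          # initial search radius ~ one grid spacing
  psis <- seq(0, 2 * pi, length.out = 9)[-9]
  for (r in seq_len(rounds)) {
    ref <- if (abs(center[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- ref - sum(ref * center) * center
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(center[2] * e1[3] - center[3] * e1[2],
            center[3] * e1[1] - center[1] * e1[3],
            center[1] * e1[2] - center[2] * e1[1])
    pts <- rbind(center,
                 t(vapply(psis, function(ps)
                   cos(rho) * center +
                     sin(rho) * (cos(ps) * e1 + sin(ps) * e2),
                   numeric(3))),
                 t(vapply(psis, function(ps)
                   cos(rho / 2) * center +
                     sin(rho / 2) * (cos(ps) * e1 + sin(ps) * e2),
                   numeric(3))))
    vals <- .shtEvaluate(g, C, pmax(pmin(pts[, 3], 1), -1),
                         atan2(pts[, 2], pts[, 1]))
    i <- which.max(vals)
    center <- pts[i, ] / sqrt(sum(pts[i, ]^2))
    value <- vals[i]
    rho <- rho / 2
  }
  list(center = center, value = value)
}

# FWHM along the great circle through `center`; field given spectrally
.greatCircleFWHM <- function(g, C, center, bg, npts = 1441L) {
  e1 <- center / sqrt(sum(center^2))
  ref <- if (abs(e1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e2 <- ref - sum(ref * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  s <- seq(-pi, pi, length.out = npts)      # angle along the circle
  xyz <- outer(cos(s), e1) + outer(sin(s), e2)
  mu <- pmin(1, pmax(-1, xyz[, 3]))
  phi <- atan2(xyz[, 2], xyz[, 1])
  prof <- .shtEvaluate(g, C, mu, phi)
  ipk <- which.max(prof)
  half <- bg + (prof[ipk] - bg) / 2
  # walk outward from the peak to the first half-height crossings
  right <- NA_real_
  for (i in seq(ipk, npts - 1L)) {
    if (prof[i + 1] < half && prof[i] >= half) {
      right <- s[i] + (half - prof[i]) * (s[i + 1] - s[i]) /
        (prof[i + 1] - prof[i])
      break
    }
  }
  left <- NA_real_
  for (i in seq(ipk, 2L)) {
    if (prof[i - 1] < half && prof[i] >= half) {
      left <- s[i] + (half - prof[i]) * (s[i - 1] - s[i]) /
        (prof[i - 1] - prof[i])
      break
    }
  }
  if (is.na(right)) right <- pi
  if (is.na(left)) left <- -pi
  g$R * (right - left)
}

# count distinct local maxima after spectral smoothing
.countClusters <- function(g, C, bg, height, smooth_l, count_threshold,
                           merge_angle) {
  Ls <- min(smooth_l, g$L)
  Cs <- C
  if (Ls < g$L) Cs[(Ls + 2):(g$L + 1), ] <- 0
  fs <- .shtSynthesize(g, Cs)
  thr <- bg + count_threshold * height
  nth <- g$ntheta; nph <- g$nphi
  jm1 <- c(nph, seq_len(nph - 1)); jp1 <- c(seq_len(nph - 1) + 1, 1)
  ismax <- matrix(TRUE, nth, nph)
  ismax <- ismax & fs >= fs[, jm1] & fs >= fs[, jp1]
  ismax[-1, ] <- ismax[-1, ] & fs[-1, ] >= fs[-nth, ] &
    fs[-1, ] >= fs[-nth, jm1] & fs[-1, ] >= fs[-nth, jp1]
  ismax[-nth, ] <- ismax[-nth, ] & fs[-nth, ] >= fs[-1, ] &
    fs[-nth, ] >= fs[-1, jm1] & fs[-nth, ] >= fs[-1, jp1]
  cand <- which(ismax & fs > thr, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(0L)
  th <- g$theta[cand[, 1]]; ph <- g$phi[cand[, 2]]
  xyz <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  # greedy merge of candidates within merge_angle geodesic distance
  n <- nrow(xyz)
  lab <- seq_len(n)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    ang <- acos(pmin(1, pmax(-1, sum(xyz[i, ] * xyz[j, ]))))
    if (ang < merge_angle) lab[lab == lab[j]] <- lab[i]
  }
  length(unique(lab))
}

#' Fit an exponential growth rate to a cluster-height time series
#'
#' Least-squares slope of log(height) versus time over the given window,
#' matching how the early-phase cluster growth rate is compared with the
#' linear stability prediction.
#'
#' @param times Numeric vector of times (s).
#' @param heights Numeric vector of cluster heights (same length).
#' @param window Length-2 time window; default the full range.
#' @return Growth rate (1/s).
#' @examples
#' t <- seq(0, 1000, by = 50)
#' fitExponentialGrowth(t, 2 * exp(0.00417 * t))
#' @export
fitExponentialGrowth <- function(times, heights, window = range(times)) {
  stopifnot(length(times) == length(heights))
  sel <- times >= window[1] & times <= window[2] & is.finite(heights)
  if (sum(sel) < 5L)
    stop("need at least 5 points with finite heights in the window")
  if (any(heights[sel] <= 0))
    stop("nonpositive heights in the fit window")
  unname(stats::coef(stats::lm(log(heights[sel]) ~ times[sel]))[2])
}

#' Gaussian-fit cap width from a membrane line scan
#'
#' Reproduces the experimental cap-width measurement: a Gaussian
#' `base + A exp(-(s - s0)^2 / (2 sigma^2))` is fitted to the line-scan
#' intensities by nonlinear least squares and the cap width is reported as
#' the full width at half maximum, `2 sqrt(2 ln 2) sigma`.
#'
#' @param profile A [LineScanProfile-class] object (or anything coercible
#'   via [lineScanProfile()]).
#' @return FWHM in um, or `NA` (with attribute `reason = "no cap"`) when
#'   the fit fails or finds no positive-amplitude peak. The fitted
#'   parameters are attached as attribute `fit` on success.
#' @examples
#' s <- seq(0, 24.8, length.out = 100)
#' y <- 10 + 40 * exp(-(s - 12)^2 / (2 * 0.8^2))
#' capwidthFromLinescan(lineScanProfile(s, y))
#' @export
capwidthFromLinescan <- function(profile) {
  if (!is(profile, "LineScanProfile"))
    stop("profile must be a LineScanProfile (see lineScanProfile())")
  s <- profile@arclength; y <- profile@intensity
  if (length(s) < 8L) stop("need at least 8 samples spanning the cap")
  nocap <- function() structure(NA_real_, reason = "no cap")
  base0 <- stats::quantile(y, 0.25, names = FALSE)
  A0 <- max(y) - base0
  if (A0 <= 0) return(nocap())
  s00 <- s[which.max(y)]
  sig0 <- max(diff(range(s)) / 10, mean(diff(s)))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ base + A * exp(-(s - s0)^2 / (2 * sig^2)),
                      start = list(base = base0, A = A0, s0 = s00,
                                   sig = sig0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(nocap())
  cf <- stats::coef(fit)
  if (!is.finite(cf[["A"]]) || cf[["A"]] <= 0 || !is.finite(cf[["sig"]]))
    return(nocap())
  structure(2 * sqrt(2 * log(2)) * abs(cf[["sig"]]), fit = cf)
}

#' Construct a line-scan profile
#'
#' @param arclength Positions along the membrane contour (um), strictly
#'   increasing.
#' @param intensity Intensities (arbitrary units).
#' @return A [LineScanProfile-class] object.
#' @export
lineScanProfile <- function(arclength, intensity) {
  new("LineScanProfile", arclength = as.numeric(arclength),
      intensity = as.numeric(intensity))
}

#' Read/write line scans as two-column CSV
#'
#' Files have columns `arclength_um`, `intensity`.
#'
#' @param path CSV path.
#' @return [readLineScan()]: a [LineScanProfile-class];
#'   [writeLineScan()]: `path` invisibly.
#' @export
readLineScan <- function(path) {
  d <- utils::read.csv(path)
  lineScanProfile(d$arclength_um, d$intensity)
}

#' @rdname readLineScan
#' @param profile A [LineScanProfile-class] object.
#' @export
writeLineScan <- function(profile, path) {
  utils::write.csv(data.frame(arclength_um = profile@arclength,
                              intensity = profile@intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' 3x3 Gaussian blur of an intensity image
#'
#' Convolution with a normalized 3x3 Gaussian kernel (sigma = 0.85 px,
#' kernel renormalized to sum 1) using reflective borders; mimics the
#' pre-averaging applied to raw micrographs before line-scan extraction.
#'
#' @param image Numeric matrix of intensities.
#' @param sigma Kernel width in pixels (default 0.85).
#' @return Blurred matrix of the same dimensions.
#' @examples
#' blur3x3(matrix(c(rep(0, 12), 1, rep(0, 12)), 5, 5))
#' @export
blur3x3 <- function(image, sigma = 0.85) {
  if (any(!is.finite(image))) stop("image must be finite")
  gker <- exp(-(-1:1)^2 / (2 * sigma^2))
  K <- outer(gker, gker)
  K <- K / sum(K)
  nr <- nrow(image); nc <- ncol(image)
  # reflective padding by one pixel
  pr <- rbind(image[1, , drop = FALSE], image, image[nr, , drop = FALSE])
  pp <- cbind(pr[, 1, drop = FALSE], pr, pr[, nc, drop = FALSE])
  out <- matrix(0, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    out <- out + K[di + 2, dj + 2] *
      pp[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
  }
  out
}

#' Average protein density inside a polarity cluster
#'
#' Converts a cluster occupancy into an average areal density:
#' `(fraction * N) / (area_fraction * 4 pi R^2)`.
#'
#' @param fraction Fraction of the protein pool inside the cluster, in
#'   (0, 1].
#' @param N Total copies per cell.
#' @param area_fraction Fraction of the membrane area occupied by the
#'   cluster, in (0, 1].
#' @param R Cell radius (um).
#' @return Density in molecules/um^2.
#' @examples
#' clusterDensity(0.10, 1000, 0.10, 3.95)  # ~5 Cdc24 per um^2
#' @export
clusterDensity <- function(fraction, N, area_fraction, R) {
  stopifnot(N > 0, R > 0)
  if (fraction <= 0 || fraction > 1 || area_fraction > 1)
    stop("fractions must lie in (0, 1]")
  if (area_fraction <= 0) stop("cluster area must be positive")
  (fraction * N) / (area_fraction * 4 * pi * R^2)
}

#' Extract an equatorial line scan from a simulated state
#'
#' Samples the total membrane Cdc42 density along the great circle through
#' the cap center (the simulated analogue of a microscopy membrane line
#' scan including the cap).
#'
#' @param state A [SystemState-class] object.
#' @param n_points Number of samples along the full circle (default 200).
#' @return A [LineScanProfile-class]; arclength spans `2 pi R`, centred on
#'   the cap.
#' @export
lineScanFromState <- function(state, n_points = 200L) {
  g <- state@grid
  f <- membraneField(state, "cdc42")
  cs <- clusterStats(f, grid = g, compute_fwhm = FALSE)
  C <- .shtAnalyze(g, f)
  e1 <- cs@center
  ref <- if (abs(e1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e2 <- ref - sum(ref * e1) * e1; e2 <- e2 / sqrt(sum(e2^2))
  s <- seq(-pi, pi, length.out = n_points)
  xyz <- outer(cos(s), e1) + outer(sin(s), e2)
  prof <- .shtEvaluate(g, C, pmin(1, pmax(-1, xyz[, 3])),
                       atan2(xyz[, 2], xyz[, 1]))
  lineScanProfile(g$R * s, prof)
}
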