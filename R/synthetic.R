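# Synthetic-data generators: the initial perturbations used to seed the
# nonlinear simulations, parametric membrane cap fields for estimator
# tests, and noisy microscopy-style line scans. All generators are pure
# functions of their arguments and seed.

# run expr with a locally-seeded RNG, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Random-lattice initial perturbation
#'
#' Draws one i.i.d. uniform[-1, 1] number per site of a cubic lattice
#' (spacing `lattice_spacing`, default 1 um) covering the cell, builds a
#' continuous perturbation function f(x, y, z) by trilinear interpolation
#' (so |f| <= 1), and multiplies every membrane species of the homogeneous
#' base state by `1 + amplitude * f` at each surface point. Cytosolic
#' fields are left untouched. Deterministic for a given seed.
#'
#' @param params A [ModelParameters-class] object.
#' @param base The homogeneous base state ([HomogeneousState-class]).
#' @param amplitude Relative perturbation amplitude (default 0.01).
#' @param lattice_spacing Lattice spacing (um, default 1).
#' @param seed Integer RNG seed (required).
#' @param grid Grid from [sphereGrid()]; default resolution if omitted.
#' @return A perturbed [SystemState-class].
#' @examples
#' p <- controlParameters()
#' hs <- homogeneousSteadyState(p)
#' st <- randomLatticePerturbation(p, hs, seed = 1,
#'                                 grid = sphereGrid(R = p[["R"]], L = 8))
#' @export
randomLatticePerturbation <- function(params, base, amplitude = 0.01,
                                      lattice_spacing = 1, seed,
                                      grid = NULL) {
  stopifnot(amplitude >= 0, lattice_spacing > 0)
  if (amplitude >= 1)
    stop("amplitude >= 1 would break positivity of the initial state")
  if (missing(seed)) stop("a seed is required for reproducibility")
  st <- uniformState(base, grid)
  if (amplitude == 0) return(st)
  g <- st@grid
  R <- g$R
  # lattice covering the sphere with one cell of margin
  ax <- seq(floor(-R / lattice_spacing) - 1,
            ceiling(R / lattice_spacing) + 1) * lattice_spacing
  nax <- length(ax)
  vals <- .withSeed(seed, array(stats::runif(nax^3, -1, 1),
                                dim = c(nax, nax, nax)))
  # surface points
  sinth <- sin(g$theta)
  x <- R * outer(sinth, cos(g$phi))
  y <- R * outer(sinth, sin(g$phi))
  z <- R * matrix(g$mu, g$ntheta, g$nphi)
  f <- .trilinear(ax, vals, as.vector(x), as.vector(y), as.vector(z))
  fmat <- matrix(f, g$ntheta, g$nphi)
  for (j in 1:4) st@membrane[, , j] <- st@membrane[, , j] *
      (1 + amplitude * fmat)
  st
}

# trilinear interpolation of values on a cubic lattice with axis `ax`
.trilinear <- function(ax, vals, x, y, z) {
  h <- ax[2] - ax[1]
  ix <- pmin(pmax(floor((x - ax[1]) / h) + 1, 1), length(ax) - 1)
  iy <- pmin(pmax(floor((y - ax[1]) / h) + 1, 1), length(ax) - 1)
  iz <- pmin(pmax(floor((z - ax[1]) / h) + 1, 1), length(ax) - 1)
  tx <- (x - ax[ix]) / h; ty <- (y - ax[iy]) / h; tz <- (z - ax[iz]) / h
  n <- length(ax)
  idx <- function(i, j, k) i + n * (j - 1) + n^2 * (k - 1)
  v <- vals
  (1 - tx) * (1 - ty) * (1 - tz) * v[idx(ix, iy, iz)] +
    tx * (1 - ty) * (1 - tz) * v[idx(ix + 1, iy, iz)] +
    (1 - tx) * ty * (1 - tz) * v[idx(ix, iy + 1, iz)] +
    (1 - tx) * (1 - ty) * tz * v[idx(ix, iy, iz + 1)] +
    tx * ty * (1 - tz) * v[idx(ix + 1, iy + 1, iz)] +
    tx * (1 - ty) * tz * v[idx(ix + 1, iy, iz + 1)] +
    (1 - tx) * ty * tz * v[idx(ix, iy + 1, iz + 1)] +
    tx * ty * tz * v[idx(ix + 1, iy + 1, iz + 1)]
}

#' Broad-cap initial perturbation
#'
#' Adds a perturbation linear in one spatial direction to every membrane
#' species: each field is set to `base * (1 + amplitude * (x . d) / R)`,
#' where d is the cap direction; the perturbation changes sign at the
#' center plane, so total copy numbers are unchanged exactly.
#'
#' @inheritParams randomLatticePerturbation
#' @param cap_direction Unit 3-vector for the cap center (default +z).
#' @return A perturbed [SystemState-class].
#' @export
broadCapPerturbation <- function(params, base, amplitude = 0.01,
                                 cap_direction = c(0, 0, 1), grid = NULL) {
  stopifnot(amplitude >= 0)
  if (amplitude >= 1) stop("amplitude >= 1 would break positivity")
  d <- cap_direction / sqrt(sum(cap_direction^2))
  st <- uniformState(base, grid)
  if (amplitude == 0) return(st)
  g <- st@grid
  sinth <- sin(g$theta)
  proj <- outer(sinth, cos(g$phi)) * d[1] + outer(sinth, sin(g$phi)) * d[2] +
    matrix(g$mu, g$ntheta, g$nphi) * d[3]       # (x . d) / R on the surface
  for (j in 1:4) st@membrane[, , j] <- st@membrane[, , j] *
      (1 + amplitude * proj)
  st
}

#' Parametric Gaussian membrane cap field
#'
#' Builds `background + height * exp(-theta_c^2 / (2 angular_sigma^2))`
#' on the grid, where theta_c is the angle to `center`. A closed-form
#' fixture for the cluster-statistics estimators: its FWHM along a great
#' circle is `R * 2 sqrt(2 ln 2) * angular_sigma`.
#'
#' @param grid Grid from [sphereGrid()].
#' @param background Background density (molecules/um^2).
#' @param height Peak height over background.
#' @param angular_sigma Angular width (radians), in (0, pi/2).
#' @param center Unit 3-vector of the cap center.
#' @return Numeric matrix (ntheta x nphi).
#' @examples
#' g <- sphereGrid(R = 3.95, L = 16)
#' f <- syntheticMembraneCap(g, 2, 50, 0.3)
#' clusterStats(f, grid = g)
#' @export
syntheticMembraneCap <- function(grid, background, height, angular_sigma,
                                 center = c(0, 0, 1)) {
  stopifnot(angular_sigma > 0, angular_sigma < pi / 2)
  g <- grid
  d <- center / sqrt(sum(center^2))
  sinth <- sin(g$theta)
  cosang <- outer(sinth, cos(g$phi)) * d[1] +
    outer(sinth, sin(g$phi)) * d[2] + matrix(g$mu, g$ntheta, g$nphi) * d[3]
  ang <- acos(pmax(pmin(cosang, 1), -1))   # cosang first: keeps dim
  background + height * exp(-ang^2 / (2 * angular_sigma^2))
}

#' Synthetic noisy membrane line scan
#'
#' Samples `background + amplitude * exp(-(s - s0)^2 / (2 sigma^2))` with
#' `sigma = true_fwhm / (2 sqrt(2 ln 2))` on an equatorial contour of
#' length `2 pi R`, adding i.i.d. Gaussian noise, emulating the intensity
#' profiles extracted from microscopy images for cap-width estimation.
#'
#' @param true_fwhm True cap FWHM (um).
#' @param background Background intensity.
#' @param amplitude Peak amplitude over background.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param n_points Number of samples (>= 16).
#' @param seed Integer RNG seed (required if `noise_sd > 0`).
#' @param R Cell radius (um, default the control-cell 3.95).
#' @return A [LineScanProfile-class] object.
#' @examples
#' pr <- syntheticLinescan(2, 10, 50, noise_sd = 0, n_points = 64)
#' capwidthFromLinescan(pr)
#' @export
syntheticLinescan <- function(true_fwhm, background, amplitude,
                              noise_sd = 0, n_points = 100L, seed = NULL,
                              R = 3.95) {
  stopifnot(n_points >= 16L, noise_sd >= 0, true_fwhm > 0)
  if (noise_sd > 0 && is.null(seed))
    stop("a seed is required when noise_sd > 0")
  s <- seq(0, 2 * pi * R, length.out = n_points)
  s0 <- pi * R
  sig <- true_fwhm / (2 * sqrt(2 * log(2)))
  y <- background + amplitude * exp(-(s - s0)^2 / (2 * sig^2))
  if (noise_sd > 0)
    y <- y + .withSeed(seed, stats::rnorm(n_points, 0, noise_sd))
  lineScanProfile(s, y)
}
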