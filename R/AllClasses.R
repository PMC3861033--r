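#' @import methods
NULL

.SPECIES_MEM <- c("mT", "mD", "mB", "mBG")
.SPECIES_CYT <- c("cD", "cB", "cG")
.PARAM_NAMES <- c("D2", "D3", "R", "N42", "NB", "N24",
                  "alpha1", "alpha2", "alpha3", "beta1", "beta2", "beta3",
                  "gamma1", "gamma2", "delta1", "delta2")

#' Model parameters for the GDI-mediated polarization model
#'
#' Holds the 16 constants of the bulk-surface reaction-diffusion model:
#' membrane and cytosolic diffusion constants (\code{D2}, \code{D3}, in
#' um^2/s), cell radius \code{R} (um), total copy numbers of Cdc42, Bem1 and
#' Cdc24 (\code{N42}, \code{NB}, \code{N24}, molecules), and ten kinetic
#' rates. All rates are stored in internal units (um, s, molecules):
#' \describe{
#'   \item{alpha1}{GEF-catalyzed nucleotide-exchange coefficient (um^2/s);
#'     the exchange rate of membrane Cdc42-GDP is \code{alpha2 + alpha1 *
#'     mBG}.}
#'   \item{alpha2}{intrinsic nucleotide-exchange rate (1/s).}
#'   \item{alpha3}{GAP-mediated hydrolysis rate of Cdc42-GTP (1/s).}
#'   \item{beta1}{GEF-mediated Cdc42 attachment coefficient (um^3/s);
#'     deposits cytosolic Cdc42-GDP directly in GTP form.}
#'   \item{beta2}{background Cdc42-GDP attachment coefficient (um/s).}
#'   \item{beta3}{GDI extraction rate of membrane Cdc42-GDP (1/s); the
#'     GTP-bound form is not extracted.}
#'   \item{gamma1}{Cdc42-GTP-dependent Bem1 attachment coefficient (um^3/s).}
#'   \item{gamma2}{Bem1 detachment rate (1/s).}
#'   \item{delta1}{Cdc24 binding coefficient to membrane Bem1 (um^3/s).}
#'   \item{delta2}{Cdc24 release rate from the membrane Bem1-Cdc24 complex
#'     (1/s).}
#' }
#'
#' @slot values Named numeric vector of the 16 parameters.
#'
#' @seealso [controlParameters()] for the calibrated control-cell preset,
#'   [readParameters()] / [writeParameters()] for config-file I/O.
#' @export
setClass("ModelParameters", representation(values = "numeric"))

setValidity("ModelParameters", function(object) {
  v <- object@values
  if (!identical(names(v), .PARAM_NAMES))
    return(sprintf("values must be named exactly: %s",
                   paste(.PARAM_NAMES, collapse = ", ")))
  if (any(!is.finite(v))) return("all parameters must be finite")
  if (any(v <= 0)) {
    bad <- names(v)[v <= 0]
    return(sprintf("all parameters must be strictly positive; offending: %s",
                   paste(bad, collapse = ", ")))
  }
  TRUE
})

#' Spatially uniform (unpolarized) steady state
#'
#' The seven uniform species values solving the well-mixed steady state of
#' the model under the three copy-number conservation constraints. Membrane
#' concentrations (\code{mT}, \code{mD}, \code{mB}, \code{mBG}) are in
#' molecules/um^2, cytosolic concentrations (\code{cD}, \code{cB},
#' \code{cG}) in molecules/um^3.
#'
#' @slot values Named numeric vector (mT, mD, mB, mBG, cD, cB, cG).
#' @slot residual Maximum absolute time-derivative residual at the root.
#' @slot params The [ModelParameters-class] the state was computed for.
#' @export
setClass("HomogeneousState",
         representation(values = "numeric", residual = "numeric",
                        params = "ModelParameters"))

#' Full spatial state of the bulk-surface system
#'
#' Four membrane concentration fields on the sphere r = R (molecules/um^2)
#' and three cytosolic concentration fields in the ball r <= R
#' (molecules/um^3), on the solver's pseudospectral grid: Gauss-Legendre
#' colatitudes x equispaced azimuths for the angular directions, a
#' conservative finite-volume grid in radius.
#'
#' @slot membrane Numeric array (ntheta, nphi, 4); species order mT, mD,
#'   mB, mBG.
#' @slot cytosol Numeric array (nr, ntheta, nphi, 3); species order cD, cB,
#'   cG.
#' @slot grid The spatial grid (as built by [sphereGrid()]).
#' @slot time Simulation time (s) the state corresponds to.
#' @export
setClass("SystemState",
         representation(membrane = "array", cytosol = "array",
                        grid = "list", time = "numeric"))

setValidity("SystemState", function(object) {
  g <- object@grid
  dm <- dim(object@membrane); dc <- dim(object@cytosol)
  if (length(dm) != 3L || dm[3] != 4L)
    return("membrane must be an (ntheta, nphi, 4) array")
  if (length(dc) != 4L || dc[4] != 3L)
    return("cytosol must be an (nr, ntheta, nphi, 3) array")
  if (dm[1] != g$ntheta || dm[2] != g$nphi)
    return("membrane dimensions do not match grid")
  if (dc[1] != g$nr || dc[2] != g$ntheta || dc[3] != g$nphi)
    return("cytosol dimensions do not match grid")
  if (length(object@time) != 1L || !is.finite(object@time))
    return("time must be a single finite number")
  TRUE
})

#' Mode-resolved linear growth rates on the sphere
#'
#' Leading growth rate per spherical-harmonic degree l, from the dispersion
#' relation of the model linearized about the homogeneous state. By
#' rotational symmetry the rate is independent of the azimuthal order m
#' (each degree is (2l+1)-fold degenerate), so one rate per degree is
#' reported.
#'
#' @slot l Integer vector of degrees (0..l_max).
#' @slot sigma Complex vector of leading growth rates (1/s) per degree.
#' @slot dominantL Degree with the largest real part among l >= 1.
#' @slot params The parameters the spectrum was computed for.
#' @export
setClass("GrowthSpectrum",
         representation(l = "integer", sigma = "complex",
                        dominantL = "integer", params = "ModelParameters"))

#' Time-course of a bulk-surface simulation
#'
#' Ordered snapshots of the system state at requested output times together
#' with a per-output-time metrics table (cluster height, FWHM, cluster
#' count, membrane fractions, conservation diagnostics) and solver metadata.
#'
#' @slot times Numeric vector of output times (s), strictly increasing.
#' @slot metrics data.frame with one row per output time.
#' @slot snapshots List of [SystemState-class] objects (possibly a subset of
#'   output times, controlled by the solver options).
#' @slot solverInfo List of solver settings and diagnostics (resolution,
#'   time step, iteration counts, positivity clamps, conservation drift).
#' @export
setClass("Trajectory",
         representation(times = "numeric", metrics = "data.frame",
                        snapshots = "list", solverInfo = "list"))

#' Cluster statistics of a membrane density field
#'
#' Quantification of polarization: number of clusters, cluster height
#' (maximum density over background), full width at half maximum measured
#' as arc length along the great circle through the cap center, the cap
#' center direction, and per-protein membrane fractions when computed from
#' a full system state.
#'
#' @slot nClusters Number of distinct clusters (0 for a flat field).
#' @slot height Maximum density minus background (molecules/um^2).
#' @slot fwhm Full width at half maximum (um), NA for a flat field.
#' @slot center Unit 3-vector of the density maximum direction.
#' @slot background Background level (spatial median by default).
#' @slot membraneFractions Named fractions of each protein pool on the
#'   membrane (NA when computed from a bare field).
#' @export
setClass("ClusterStats",
         representation(nClusters = "integer", height = "numeric",
                        fwhm = "numeric", center = "numeric",
                        background = "numeric",
                        membraneFractions = "numeric"))

#' Membrane line-scan intensity profile
#'
#' Arclength/intensity pairs emulating a microscopy line scan drawn along
#' the cell membrane through the polarity cap, as used for the
#' Gaussian-fit cap width estimate.
#'
#' @slot arclength Positions along the membrane contour (um), strictly
#'   increasing.
#' @slot intensity Intensities (arbitrary units), finite.
#' @export
setClass("LineScanProfile",
         representation(arclength = "numeric", intensity = "numeric"))

setValidity("LineScanProfile", function(object) {
  s <- object@arclength; y <- object@intensity
  if (length(s) != length(y)) return("arclength and intensity lengths differ")
  if (any(!is.finite(s)) || any(!is.finite(y)))
    return("arclength and intensity must be finite")
  if (any(diff(s) <= 0)) return("arclength must be strictly increasing")
  TRUE
})
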