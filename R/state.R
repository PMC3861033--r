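#' Build a spatially uniform SystemState from a homogeneous state
#'
#' @param hom A [HomogeneousState-class] object.
#' @param grid A grid from [sphereGrid()]; defaults to the package default
#'   resolution for the radius stored in the parameters.
#' @param time Initial time (s).
#' @return A [SystemState-class] object.
#' @examples
#' hs <- homogeneousSteadyState(controlParameters())
#' st <- uniformState(hs, sphereGrid(R = 3.95, L = 8))
#' @export
uniformState <- function(hom, grid = NULL, time = 0) {
  v <- hom@params@values
  if (is.null(grid)) grid <- sphereGrid(R = v[["R"]])
  if (abs(grid$R - v[["R"]]) > 1e-12 * v[["R"]])
    stop("grid radius does not match parameter R")
  y <- hom@values
  mem <- array(rep(y[.SPECIES_MEM], each = grid$ntheta * grid$nphi),
               dim = c(grid$ntheta, grid$nphi, 4))
  cyt <- array(rep(y[.SPECIES_CYT],
                   each = grid$nr * grid$ntheta * grid$nphi),
               dim = c(grid$nr, grid$ntheta, grid$nphi, 3))
  new("SystemState", membrane = mem, cytosol = cyt, grid = grid,
      time = as.numeric(time))
}

#' Extract a membrane field from a SystemState
#'
#' @param state A [SystemState-class] object.
#' @param species One of `"mT"`, `"mD"`, `"mB"`, `"mBG"`, or `"cdc42"` for
#'   the total membrane Cdc42 density (mT + mD).
#' @return Numeric matrix (ntheta x nphi), molecules/um^2.
#' @export
membraneField <- function(state, species = "cdc42") {
  if (species == "cdc42")
    return(state@membrane[, , 1] + state@membrane[, , 2])
  i <- match(species, .SPECIES_MEM)
  if (is.na(i)) stop("unknown membrane species: ", species)
  state@membrane[, , i]
}

#' Extract a cytosolic field from a SystemState
#'
#' @param state A [SystemState-class] object.
#' @param species One of `"cD"`, `"cB"`, `"cG"`.
#' @return Numeric array (nr x ntheta x nphi), molecules/um^3.
#' @export
cytosolField <- function(state, species = "cD") {
  i <- match(species, .SPECIES_CYT)
  if (is.na(i)) stop("unknown cytosolic species: ", species)
  state@cytosol[, , , i]
}

#' Total copies of each protein pool in a SystemState
#'
#' Integrates the membrane fields over the sphere and the cytosolic fields
#' over the ball with the grid's quadrature.
#'
#' @param state A [SystemState-class] object.
#' @return List with `membrane`, `cytosol` and `total` (each a length-3
#'   vector: Cdc42, Bem1, Cdc24 copies).
#' @export
proteinTotals <- function(state) {
  g <- state@grid
  mem <- c(.surfaceIntegral(g, state@membrane[, , 1]) +
             .surfaceIntegral(g, state@membrane[, , 2]),
           .surfaceIntegral(g, state@membrane[, , 3]) +
             .surfaceIntegral(g, state@membrane[, , 4]),
           .surfaceIntegral(g, state@membrane[, , 4]))
  cyt <- c(.volumeIntegral(g, state@cytosol[, , , 1]),
           .volumeIntegral(g, state@cytosol[, , , 2]),
           .volumeIntegral(g, state@cytosol[, , , 3]))
  list(membrane = mem, cytosol = cyt, total = mem + cyt)
}

setMethod("show", "SystemState", function(object) {
  g <- object@grid
  tots <- proteinTotals(object)
  cat(sprintf("SystemState at t = %.6g s\n", object@time))
  cat(sprintf("  grid: L = %d, ntheta = %d, nphi = %d, nr = %d, R = %.4g um\n",
              g$L, g$ntheta, g$nphi, g$nr, g$R))
  cat(sprintf("  totals (membrane + cytosol): Cdc42 %.4g, Bem1 %.4g, Cdc24 %.4g\n",
              tots$total[1], tots$total[2], tots$total[3]))
  c42 <- membraneField(object, "cdc42")
  cat(sprintf("  membrane Cdc42 density: min %.4g, max %.4g um^-2\n",
              min(c42), max(c42)))
})
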