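# Parameter-scan engines: phase diagrams from the linear stability
# analysis (fast) and final-cluster-width curves from full simulations.

#' Polarization-capability phase diagram
#'
#' Evaluates, on a 2-D multiplicative grid around `params`, whether the
#' homogeneous state supports a growing non-uniform mode
#' ([isPolarizable()]), the membrane Cdc42-GTP fraction of the unpolarized
#' state, and optionally whether a failure to polarize could be rescued by
#' changing the diffusion constants.
#'
#' @param axis1,axis2 Parameter names (e.g. `"N24"`, `"alpha3"`).
#' @param factors1,factors2 Multiplicative factors applied to the control
#'   values; defaults are 21 log-spaced values spanning 1e-2 to 1e1.
#' @param params Base [ModelParameters-class] (default control).
#' @param rescue Also evaluate [diffusionRescue()] per cell (slower,
#'   default FALSE).
#' @param l_max Passed to [isPolarizable()].
#' @return data.frame with one row per grid cell: the two factors and
#'   absolute values, `polarizable`, `gtp_fraction` (membrane Cdc42-GTP /
#'   N42 in the unpolarized state), `rescued` (NA unless `rescue`), and
#'   `error` for cells whose homogeneous state failed.
#' @examples
#' \donttest{
#' sw <- capabilitySweep("N24", "alpha3",
#'                       factors1 = c(0.1, 1), factors2 = c(1, 3))
#' }
#' @export
capabilitySweep <- function(axis1, axis2,
                            factors1 = 10^seq(-2, 1, length.out = 21),
                            factors2 = 10^seq(-2, 1, length.out = 21),
                            params = controlParameters(),
                            rescue = FALSE, l_max = 10L) {
  stopifnot(axis1 %in% .PARAM_NAMES, axis2 %in% .PARAM_NAMES)
  cells <- expand.grid(f1 = factors1, f2 = factors2)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    f1 <- cells$f1[i]; f2 <- cells$f2[i]
    pp <- scaleParameters(params, structure(c(f1, f2),
                                            names = c(axis1, axis2)))
    row <- data.frame(f1 = f1, f2 = f2,
                      v1 = pp@values[[axis1]], v2 = pp@values[[axis2]],
                      polarizable = NA, gtp_fraction = NA_real_,
                      rescued = NA, error = NA_character_)
    tryCatch({
      hs <- homogeneousSteadyState(pp)
      v <- pp@values
      row$gtp_fraction <- .sphereArea(v[["R"]]) * hs@values[["mT"]] /
        v[["N42"]]
      row$polarizable <- isPolarizable(pp, l_max, base = hs)
      if (rescue && !row$polarizable)
        row$rescued <- diffusionRescue(pp, l_max = l_max)
      else if (rescue) row$rescued <- TRUE
    }, error = function(e) row$error <<- conditionMessage(e))
    row
  })
  res <- do.call(rbind, out)
  names(res)[1:4] <- c(paste0(axis1, "_factor"), paste0(axis2, "_factor"),
                       axis1, axis2)
  attr(res, "axes") <- c(axis1, axis2)
  res
}

#' Unpolarized membrane Cdc42-GTP fraction along one parameter axis
#'
#' Computes the homogeneous state for each scaled parameter value and
#' reports the membrane Cdc42-GTP pool as a fraction of total cellular
#' Cdc42; near the capability boundary the fraction drops switch-like.
#'
#' @param parameter Parameter name.
#' @param factors Multiplicative factors on the control value.
#' @param params Base [ModelParameters-class].
#' @param l_max Passed to [isPolarizable()].
#' @return data.frame with `factor`, `value`, `gtp_fraction`,
#'   `polarizable`.
#' @examples
#' cdc42gtpVsParameter("alpha3", factors = c(0.5, 1, 2, 4))
#' @export
cdc42gtpVsParameter <- function(parameter,
                                factors = 10^seq(-2, 1, length.out = 21),
                                params = controlParameters(), l_max = 10L) {
  stopifnot(parameter %in% .PARAM_NAMES)
  out <- lapply(factors, function(f) {
    pp <- scaleParameters(params, structure(f, names = parameter))
    row <- data.frame(factor = f, value = pp@values[[parameter]],
                      gtp_fraction = NA_real_, polarizable = NA)
    tryCatch({
      hs <- homogeneousSteadyState(pp)
      row$gtp_fraction <- .sphereArea(pp@values[["R"]]) *
        hs@values[["mT"]] / pp@values[["N42"]]
      row$polarizable <- isPolarizable(pp, l_max, base = hs)
    }, error = function(e) NULL)
    row
  })
  do.call(rbind, out)
}

#' Final cluster width along one parameter axis
#'
#' For each scaled parameter value, runs the nonlinear dynamics to steady
#' state and records the final Cdc42 cluster FWHM, height and cluster
#' count. Along the axis the previous cell's final state is reused as the
#' initial condition (continuation) to cut the time to steady state;
#' set `cold_start_every` to re-seed from the perturbed homogeneous state
#' periodically as a hysteresis guard.
#'
#' @param parameter Parameter name.
#' @param factors Multiplicative factors on the control value (a modest
#'   range, e.g. 1/3 .. 3, is recommended: simulations are costly).
#' @param params Base [ModelParameters-class].
#' @param grid Grid for the simulations (defaults to a reduced L = 16
#'   resolution for sweep economy).
#' @param t_max,tol Passed to [runToSteadyState()].
#' @param solver_options Passed to [simulate()].
#' @param cold_start_every Re-seed from scratch every this many cells
#'   (default 0 = always continue from the previous state).
#' @param perturbation_seed Seed for the initial random perturbation.
#' @return data.frame with `factor`, `value`, `polarizable` (linear
#'   prediction), `polarized` (simulation outcome), `fwhm`, `height`,
#'   `n_clusters`, `converged`.
#' @export
fwhmSweep <- function(parameter, factors, params = controlParameters(),
                      grid = NULL, t_max = 3e4, tol = 1e-5,
                      solver_options = list(), cold_start_every = 0L,
                      perturbation_seed = 1L) {
  stopifnot(parameter %in% .PARAM_NAMES)
  if (is.null(grid)) grid <- sphereGrid(R = params@values[["R"]], L = 16)
  prev_state <- NULL
  out <- lapply(seq_along(factors), function(i) {
    f <- factors[i]
    pp <- scaleParameters(params, structure(f, names = parameter))
    row <- data.frame(factor = f, value = pp@values[[parameter]],
                      polarizable = NA, polarized = NA, fwhm = NA_real_,
                      height = NA_real_, n_clusters = NA_integer_,
                      converged = NA, error = NA_character_)
    res <- tryCatch({
      hs <- homogeneousSteadyState(pp)
      row$polarizable <- isPolarizable(pp, base = hs)
      cold <- is.null(prev_state) ||
        (cold_start_every > 0L && (i - 1L) %% cold_start_every == 0L)
      init <- if (cold) {
        randomLatticePerturbation(pp, hs, seed = perturbation_seed,
                                  grid = grid)
      } else {
        # continuation: rescale the previous final state to the new totals
        .rescaleTotals(prev_state, pp)
      }
      runToSteadyState(pp, init, tol = tol, t_max = t_max,
                       solver_options = solver_options)
    }, error = function(e) {
      row$error <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) {
      prev_state <<- res$state
      row$polarized <- res$polarized
      row$converged <- res$converged
      row$fwhm <- res$stats@fwhm
      row$height <- res$stats@height
      row$n_clusters <- res$stats@nClusters
    }
    row
  })
  do.call(rbind, out)
}

# scale a state's fields so pool totals match the copy numbers in params
.rescaleTotals <- function(state, params) {
  tots <- proteinTotals(state)$total
  v <- params@values
  want <- c(v[["N42"]], v[["NB"]], v[["N24"]])
  # Cdc42 pool: mT, mD, cD ; Bem1 pool: mB, mBG(B part), cB ; Cdc24: mBG, cG
  # mBG carries one Bem1 and one Cdc24; rescale it by the Cdc24 ratio and
  # put the Bem1 imbalance into mB/cB via the Bem1 ratio afterwards.
  r42 <- want[1] / tots[1]; rB <- want[2] / tots[2]; r24 <- want[3] / tots[3]
  st <- state
  st@membrane[, , 1] <- st@membrane[, , 1] * r42
  st@membrane[, , 2] <- st@membrane[, , 2] * r42
  st@cytosol[, , , 1] <- st@cytosol[, , , 1] * r42
  st@membrane[, , 4] <- st@membrane[, , 4] * r24
  st@cytosol[, , , 3] <- st@cytosol[, , , 3] * r24
  # Bem1: free forms absorb the remainder
  tB_complex <- .surfaceIntegral(st@grid, st@membrane[, , 4])
  tB_free <- tots[2] - .surfaceIntegral(state@grid, state@membrane[, , 4])
  fB <- (want[2] - tB_complex) / tB_free
  if (!is.finite(fB) || fB <= 0) fB <- rB
  st@membrane[, , 3] <- st@membrane[, , 3] * fB
  st@cytosol[, , , 2] <- st@cytosol[, , , 2] * fB
  st
}
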