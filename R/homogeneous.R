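#' Homogeneous (unpolarized) steady state
#'
#' Solves for the spatially uniform steady state of the model: uniform
#' membrane concentrations on the sphere and uniform cytosolic
#' concentrations in the ball, with zero net reaction and boundary flux per
#' species, under the three copy-number conservation constraints. When the
#' model has multiple uniform roots the stable unpolarized branch is
#' selected operationally: the state reached by relaxing the well-mixed
#' two-compartment ODE system from the all-cytosolic initial condition,
#' then polished by Newton iteration to the requested tolerance.
#'
#' @param params A [ModelParameters-class] object.
#' @param tol Relative residual tolerance for the root (default 1e-10).
#' @param t_relax Relaxation horizon for the ODE stage (s).
#' @return A [HomogeneousState-class] object.
#' @examples
#' hs <- homogeneousSteadyState(controlParameters())
#' hs
#' @export
homogeneousSteadyState <- function(params, tol = 1e-10, t_relax = 1e6) {
  v <- params@values
  A <- .sphereArea(v[["R"]]); V <- .ballVolume(v[["R"]])
  rhs <- function(t, y, parms) {
    r <- .reactionKernel(v, y[1], y[2], y[3], y[4], y[5], y[6], y[7])
    list(c(r$dmT, r$dmD, r$dmB, r$dmBG,
           -A / V * r$FD, -A / V * r$FB, -A / V * r$FG))
  }
  y0 <- c(0, 0, 0, 0, v[["N42"]] / V, v[["NB"]] / V, v[["N24"]] / V)
  sol <- deSolve::ode(y0, c(0, t_relax), rhs, NULL, method = "lsoda",
                      rtol = 1e-12, atol = 1e-12)
  y <- as.numeric(sol[nrow(sol), -1])

  # Newton polish on the reduced system: unknowns y (7), equations: the 4
  # membrane sources and 3 conservation laws (boundary-flux balance is
  # implied by the membrane equations at a uniform state).
  Ffun <- function(y) {
    r <- .reactionKernel(v, y[1], y[2], y[3], y[4], y[5], y[6], y[7])
    c(r$dmT, r$dmD, r$dmB, r$dmBG,
      A * (y[1] + y[2]) + V * y[5] - v[["N42"]],
      A * (y[3] + y[4]) + V * y[6] - v[["NB"]],
      A * y[4] + V * y[7] - v[["N24"]])
  }
  scale <- pmax(abs(y), 1e-8)
  bestnorm <- max(abs(Ffun(y)))
  for (it in seq_len(50)) {
    if (bestnorm == 0) break
    J <- pracma::jacobian(Ffun, y)
    step <- tryCatch(solve(J, Ffun(y)), error = function(e) NULL)
    if (is.null(step)) break
    cand <- y - step
    candnorm <- max(abs(Ffun(cand)))
    # accept only improving steps: keeps the polish inert on degenerate,
    # badly scaled systems where relaxation already nailed the root
    if (!is.finite(candnorm) || candnorm >= bestnorm) break
    y <- cand; bestnorm <- candnorm
    if (max(abs(step) / scale) < 1e-14) break
  }
  r <- .reactionKernel(v, y[1], y[2], y[3], y[4], y[5], y[6], y[7])
  resid <- max(abs(c(r$dmT, r$dmD, r$dmB, r$dmBG, r$FD, r$FB, r$FG)))
  relresid <- resid / max(abs(c(r$FD + v[["beta3"]] * y[2], 1e-12)))
  if (!all(is.finite(y)) || any(y < -1e-7 * max(abs(y))) ||
      relresid > tol && resid > tol * max(v[["beta3"]], 1)) {
    stop(sprintf(paste0("homogeneous steady state did not converge: ",
                        "max residual %.3e (relative %.3e), tolerance %g"),
                 resid, relresid, tol))
  }
  y[y < 0] <- 0
  names(y) <- c(.SPECIES_MEM, .SPECIES_CYT)
  new("HomogeneousState", values = y, residual = resid, params = params)
}

setMethod("show", "HomogeneousState", function(object) {
  y <- object@values
  cat("HomogeneousState (unpolarized uniform steady state)\n")
  cat(sprintf("  membrane [um^-2]: mT = %.4g, mD = %.4g, mB = %.4g, mBG = %.4g\n",
              y["mT"], y["mD"], y["mB"], y["mBG"]))
  cat(sprintf("  cytosol [um^-3]:  cD = %.4g, cB = %.4g, cG = %.4g\n",
              y["cD"], y["cB"], y["cG"]))
  fr <- membraneFractions(object)
  cat(sprintf("  membrane fractions: Cdc42 %.1f%%, Bem1 %.1f%%, Cdc24 %.1f%%\n",
              100 * fr["cdc42"], 100 * fr["bem1"], 100 * fr["cdc24"]))
  cat(sprintf("  residual: %.3e\n", object@residual))
})

#' Membrane fractions of the three protein pools
#'
#' Fraction of each total protein pool residing on the membrane:
#' Cdc42 as (integral of mT + mD) / N42, Bem1 as (integral of mB + mBG) /
#' NB, Cdc24 as (integral of mBG) / N24.
#'
#' @param object A [HomogeneousState-class] or [SystemState-class] object.
#' @param ... Further arguments; for `SystemState`, `params` (a
#'   [ModelParameters-class]) is required and conservation is checked
#'   against it (`tol`, default 1e-3 relative).
#' @return Named numeric vector `c(cdc42 =, bem1 =, cdc24 =)`, each in
#'   [0, 1].
#' @export
setGeneric("membraneFractions",
           function(object, ...) standardGeneric("membraneFractions"))

#' @rdname membraneFractions
#' @export
setMethod("membraneFractions", "HomogeneousState", function(object, ...) {
  v <- object@params@values
  A <- .sphereArea(v[["R"]])
  y <- object@values
  c(cdc42 = A * (y[["mT"]] + y[["mD"]]) / v[["N42"]],
    bem1  = A * (y[["mB"]] + y[["mBG"]]) / v[["NB"]],
    cdc24 = A * y[["mBG"]] / v[["N24"]])
})

#' @rdname membraneFractions
#' @param params ModelParameters for conservation checking (SystemState
#'   method).
#' @param tol Relative conservation tolerance (SystemState method; default
#'   1e-3, loose enough for the ~0.01 %% mass imbalance a 1 %% random
#'   initial perturbation legitimately carries).
#' @export
setMethod("membraneFractions", "SystemState",
          function(object, params, tol = 1e-3, ...) {
  tots <- proteinTotals(object)
  v <- params@values
  ref <- c(v[["N42"]], v[["NB"]], v[["N24"]])
  drift <- abs(tots$total - ref) / ref
  if (any(drift > tol))
    stop(sprintf(paste0("conservation violated beyond tolerance: relative ",
                        "deviations %.2e / %.2e / %.2e (tol %g)"),
                 drift[1], drift[2], drift[3], tol))
  c(cdc42 = tots$membrane[1] / ref[1],
    bem1  = tots$membrane[2] / ref[2],
    cdc24 = tots$membrane[3] / ref[3])
})
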