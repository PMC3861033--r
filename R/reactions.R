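#' Membrane reaction terms and boundary uptake fluxes
#'
#' Evaluates, pointwise on the membrane, the net reaction source for each
#' membrane species and the matching boundary uptake flux for each
#' cytosolic species. Inputs are local species values (vectors of equal
#' length are accepted, so whole grids can be evaluated at once):
#'
#' \deqn{\partial_t m_D |_{reac} = \beta_2 c_D + \alpha_3 m_T -
#'   (\alpha_2 + \alpha_1 m_{BG}) m_D - \beta_3 m_D}
#' \deqn{\partial_t m_T |_{reac} = \beta_1 m_{BG} c_D +
#'   (\alpha_2 + \alpha_1 m_{BG}) m_D - \alpha_3 m_T}
#' \deqn{\partial_t m_B |_{reac} = \gamma_1 m_T c_B - \gamma_2 m_B -
#'   \delta_1 m_B c_G + \delta_2 m_{BG}}
#' \deqn{\partial_t m_{BG} |_{reac} = \delta_1 m_B c_G - \delta_2 m_{BG}}
#'
#' with cytosolic concentrations evaluated at the membrane (r = R). The
#' boundary fluxes (positive from cytosol to membrane, molecules/um^2/s)
#' are \eqn{F_D = (\beta_2 + \beta_1 m_{BG}) c_D - \beta_3 m_D},
#' \eqn{F_B = \gamma_1 m_T c_B - \gamma_2 m_B} and
#' \eqn{F_G = \delta_1 m_B c_G - \delta_2 m_{BG}}. The cytosol itself is
#' purely diffusive; these fluxes enter it only through the boundary
#' condition \eqn{D_3 \partial_r c |_R = -F}. Each protein pool is
#' conserved pointwise by construction: the Cdc42 membrane sources sum to
#' \eqn{F_D}, the Bem1 sources to \eqn{F_B}, and the Cdc24-containing
#' complex source equals \eqn{F_G}.
#'
#' @param state Named list or data.frame with components `mT`, `mD`, `mB`,
#'   `mBG` (molecules/um^2) and `cD`, `cB`, `cG` (molecules/um^3), each a
#'   nonnegative numeric vector (recycled to a common length).
#' @param params A [ModelParameters-class] object.
#' @return List with `membrane` (named list of the four source terms,
#'   molecules/um^2/s) and `flux` (named list `FD`, `FB`, `FG`).
#' @examples
#' p <- controlParameters()
#' reactionTerms(list(mT = 1, mD = 3, mB = 12, mBG = 5,
#'                    cD = 8, cB = 15, cG = 3.5), p)
#' @export
reactionTerms <- function(state, params) {
  need <- c(.SPECIES_MEM, .SPECIES_CYT)
  missing <- setdiff(need, names(state))
  if (length(missing))
    stop("state is missing component(s): ", paste(missing, collapse = ", "))
  for (nm in need) {
    x <- state[[nm]]
    if (any(!is.finite(x)) || any(x < 0))
      stop("negative or non-finite concentration in '", nm,
           "': reaction terms require nonnegative inputs")
  }
  v <- params@values
  mT <- state$mT; mD <- state$mD; mB <- state$mB; mBG <- state$mBG
  cD <- state$cD; cB <- state$cB; cG <- state$cG
  exch <- v[["alpha2"]] + v[["alpha1"]] * mBG
  FD <- (v[["beta2"]] + v[["beta1"]] * mBG) * cD - v[["beta3"]] * mD
  FB <- v[["gamma1"]] * mT * cB - v[["gamma2"]] * mB
  FG <- v[["delta1"]] * mB * cG - v[["delta2"]] * mBG
  list(
    membrane = list(
      mT  = v[["beta1"]] * mBG * cD + exch * mD - v[["alpha3"]] * mT,
      mD  = v[["beta2"]] * cD + v[["alpha3"]] * mT - exch * mD -
            v[["beta3"]] * mD,
      mB  = FB - v[["delta1"]] * mB * cG + v[["delta2"]] * mBG,
      mBG = FG),
    flux = list(FD = FD, FB = FB, FG = FG))
}

# raw vectorized kernel used by the integrator (no input checking)
.reactionKernel <- function(v, mT, mD, mB, mBG, cD, cB, cG) {
  exch <- v[["alpha2"]] + v[["alpha1"]] * mBG
  FD <- (v[["beta2"]] + v[["beta1"]] * mBG) * cD - v[["beta3"]] * mD
  FB <- v[["gamma1"]] * mT * cB - v[["gamma2"]] * mB
  FG <- v[["delta1"]] * mB * cG - v[["delta2"]] * mBG
  list(dmT = v[["beta1"]] * mBG * cD + exch * mD - v[["alpha3"]] * mT,
       dmD = v[["beta2"]] * cD + v[["alpha3"]] * mT - exch * mD -
             v[["beta3"]] * mD,
       dmB = FB - v[["delta1"]] * mB * cG + v[["delta2"]] * mBG,
       dmBG = FG,
       FD = FD, FB = FB, FG = FG)
}
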