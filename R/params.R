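#' Construct a ModelParameters object
#'
#' All values are given in internal units (um, s, molecules). Note that the
#' intrinsic nucleotide-exchange rate `alpha2` is in 1/s here; the
#' literature value of 0.12 per minute corresponds to `alpha2 = 0.002`.
#'
#' @param D2,D3 Membrane and cytosolic diffusion constants (um^2/s).
#' @param R Cell radius (um).
#' @param N42,NB,N24 Total copy numbers of Cdc42, Bem1 and Cdc24.
#' @param alpha1,alpha2,alpha3,beta1,beta2,beta3,gamma1,gamma2,delta1,delta2
#'   Kinetic rates, see [ModelParameters-class] for meanings and units.
#' @return A validated [ModelParameters-class] object.
#' @examples
#' p <- modelParameters()  # control preset
#' p[["alpha1"]] * 5       # effective GEF-catalyzed exchange rate in a cluster
#' @export
modelParameters <- function(D2 = 0.03, D3 = 11, R = 3.95,
                            N42 = 3000, NB = 6500, N24 = 1000,
                            alpha1 = 0.2, alpha2 = 0.12 / 60, alpha3 = 1,
                            beta1 = 0.266, beta2 = 0.28, beta3 = 1,
                            gamma1 = 0.2667, gamma2 = 0.35,
                            delta1 = 0.00297, delta2 = 0.35) {
  v <- c(D2 = D2, D3 = D3, R = R, N42 = N42, NB = NB, N24 = N24,
         alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
         beta1 = beta1, beta2 = beta2, beta3 = beta3,
         gamma1 = gamma1, gamma2 = gamma2, delta1 = delta1, delta2 = delta2)
  new("ModelParameters", values = v)
}

#' Control-cell parameter preset
#'
#' The calibrated control-cell constants: D2 = 0.03 um^2/s, D3 = 11 um^2/s,
#' R = 3.95 um, N42 = 3000, NB = 6500, N24 = 1000, alpha1 = 0.2 um^2/s,
#' alpha2 = 0.12/min (stored as 0.002/s), alpha3 = 1/s, beta1 = 0.266
#' um^3/s, beta2 = 0.28 um/s, beta3 = 1/s, gamma1 = 0.2667 um^3/s,
#' gamma2 = 0.35/s, delta1 = 0.00297 um^3/s, delta2 = 0.35/s.
#'
#' @return A [ModelParameters-class] object.
#' @examples
#' controlParameters()
#' @export
controlParameters <- function() modelParameters()

#' Scale selected parameters by multiplicative factors
#'
#' Convenience for parameter sweeps: returns a copy of `params` with the
#' named entries multiplied by `factor`.
#'
#' @param params A [ModelParameters-class] object.
#' @param ... Named factors, e.g. `alpha3 = 2, N24 = 0.5`.
#' @return A new [ModelParameters-class] object.
#' @examples
#' scaleParameters(controlParameters(), alpha3 = 3)
#' @export
scaleParameters <- function(params, ...) {
  f <- c(...)
  bad <- setdiff(names(f), .PARAM_NAMES)
  if (length(bad))
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
  v <- params@values
  v[names(f)] <- v[names(f)] * f
  new("ModelParameters", values = v)
}

#' @describeIn modelParameters Extract a single parameter by name.
#' @param x A ModelParameters object.
#' @param i Parameter name.
#' @export
setMethod("[[", "ModelParameters", function(x, i) {
  if (!i %in% .PARAM_NAMES) stop("unknown parameter: ", i)
  unname(x@values[[i]])
})

#' Parameter vector accessor
#'
#' @param object A [ModelParameters-class] object.
#' @return Named numeric vector of all 16 parameters.
#' @export
setGeneric("paramValues", function(object) standardGeneric("paramValues"))

#' @rdname paramValues
#' @export
setMethod("paramValues", "ModelParameters", function(object) object@values)

setMethod("show", "ModelParameters", function(object) {
  v <- object@values
  cat("ModelParameters (units: um, s, molecules)\n")
  cat(sprintf("  geometry: R = %.4g um; diffusion: D2 = %.4g, D3 = %.4g um^2/s\n",
              v["R"], v["D2"], v["D3"]))
  cat(sprintf("  copy numbers: N42 = %g, NB = %g, N24 = %g\n",
              v["N42"], v["NB"], v["N24"]))
  cat(sprintf("  Cdc42 cycle: alpha1 = %.4g, alpha2 = %.4g, alpha3 = %.4g\n",
              v["alpha1"], v["alpha2"], v["alpha3"]))
  cat(sprintf("  attachment/extraction: beta1 = %.4g, beta2 = %.4g, beta3 = %.4g\n",
              v["beta1"], v["beta2"], v["beta3"]))
  cat(sprintf("  Bem1/Cdc24: gamma1 = %.4g, gamma2 = %.4g, delta1 = %.4g, delta2 = %.4g\n",
              v["gamma1"], v["gamma2"], v["delta1"], v["delta2"]))
})

#' Read model parameters from a YAML config file
#'
#' The file is a flat key-value mapping with keys named exactly as the
#' parameter slots (`D2`, `D3`, `R`, `N42`, `NB`, `N24`, `alpha1` ...
#' `delta2`), values in internal units (um, s, molecules). The special
#' value `preset: control` loads the control preset, with any further keys
#' overriding individual entries.
#'
#' @param path Path to the YAML file.
#' @return A [ModelParameters-class] object.
#' @seealso [writeParameters()]
#' @export
readParameters <- function(path) {
  x <- yaml::read_yaml(path)
  base <- if (identical(x$preset, "control")) controlParameters()@values else NULL
  x$preset <- NULL
  bad <- setdiff(names(x), .PARAM_NAMES)
  if (length(bad))
    stop("unknown parameter key(s) in ", path, ": ", paste(bad, collapse = ", "))
  if (is.null(base)) {
    missing <- setdiff(.PARAM_NAMES, names(x))
    if (length(missing))
      stop("missing parameter key(s) in ", path, ": ",
           paste(missing, collapse = ", "))
    base <- controlParameters()@values  # template for ordering
  }
  for (k in names(x)) base[[k]] <- as.numeric(x[[k]])
  new("ModelParameters", values = base[.PARAM_NAMES])
}

#' Write model parameters to a YAML config file
#'
#' @param params A [ModelParameters-class] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeParameters <- function(params, path) {
  v <- params@values
  hdr <- c("# model parameters; units um, s, molecules",
           "# D2, D3: um^2/s | R: um | N42, NB, N24: molecules",
           "# alpha1: um^2/s | alpha2, alpha3, beta3, gamma2, delta2: 1/s",
           "# beta1, gamma1, delta1: um^3/s | beta2: um/s")
  body <- vapply(names(v), function(k) sprintf("%s: %.17g", k, v[[k]]), "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

# geometry helpers used throughout
.sphereArea <- function(R) 4 * pi * R^2
.ballVolume <- function(R) 4 / 3 * pi * R^3
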