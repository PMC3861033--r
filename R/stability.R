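# Linear stability analysis on the sphere. Perturbations about the
# homogeneous state are expanded as Y_lm e^{sigma t}; each cytosolic species
# solves the radial diffusion eigenproblem in the ball (regular at the
# origin), giving a modified spherical Bessel profile i_l(sqrt(sigma/D3) r)
# for Re sigma > 0, the oscillatory j_l(sqrt(-sigma/D3) r) for sigma < 0, and
# r^l at sigma = 0. The three cytosolic amplitudes and four membrane
# amplitudes then satisfy the linearized membrane equations (with lateral
# diffusion -D2 l(l+1)/R^2) and the three linearized boundary-flux
# conditions; sigma_l is the root of the resulting 7x7 determinant with the
# largest real part.

# logarithmic radial derivative f'(R)/f(R) of the regular radial profile
.radialLogDeriv <- function(sigma, l, D3, R) {
  if (abs(sigma) < 1e-13) return(l / R)
  if (Re(sigma) > 0 && Im(sigma) == 0) {
    q <- sqrt(sigma / D3); x <- q * R
    # i_l(x) = sqrt(pi/(2x)) I_{l+1/2}(x); scaled form cancels in the ratio
    il  <- besselI(x, l + 0.5, expon.scaled = TRUE)
    il1 <- besselI(x, l + 1.5, expon.scaled = TRUE)
    if (il == 0) return(q)   # x large: i_l'/i_l -> 1
    q * (il1 / il + l / x)
  } else if (Im(sigma) == 0) {
    k <- sqrt(-sigma / D3); x <- k * R
    jl  <- besselJ(x, l + 0.5)
    jl1 <- besselJ(x, l + 1.5)
    k * (l / x - jl1 / jl)
  } else {
    # complex sigma: power series / continued fraction via recurrence on the
    # ratio r_l = i_{l+1}/i_l of modified spherical Bessel functions with
    # complex argument x = sqrt(sigma/D3) R (principal branch).
    x <- sqrt(as.complex(sigma) / D3) * R
    lmax <- l + 30 + ceiling(Mod(x))
    r <- x / (2 * lmax + 3)          # asymptotic seed for i_{lmax+1}/i_lmax
    for (ll in lmax:l) r <- x / ((2 * ll + 1) + x * r)
    (x / R) * (r + l / x)
  }
}

# determinant of the linearized system at growth rate sigma for degree l
.dispersionDet <- function(sigma, l, v, y) {
  lap <- l * (l + 1) / v[["R"]]^2
  gp <- .radialLogDeriv(sigma, l, v[["D3"]], v[["R"]])
  mT <- y[["mT"]]; mD <- y[["mD"]]; mB <- y[["mB"]]; mBG <- y[["mBG"]]
  cD <- y[["cD"]]; cB <- y[["cB"]]; cG <- y[["cG"]]
  ex <- v[["alpha2"]] + v[["alpha1"]] * mBG
  dd <- v[["D2"]] * lap + sigma
  D3gp <- v[["D3"]] * gp
  z <- if (is.complex(sigma) || is.complex(gp)) 0i else 0
  # unknown order: dmT, dmD, dmB, dmBG, CD, CB, CG (cytosol values at R)
  M <- matrix(z, 7, 7)
  M[1, ] <- c(-v[["alpha3"]] - dd, ex, z, v[["beta1"]] * cD +
                v[["alpha1"]] * mD, v[["beta1"]] * mBG, z, z)
  M[2, ] <- c(v[["alpha3"]], -ex - v[["beta3"]] - dd, z,
              -v[["alpha1"]] * mD, v[["beta2"]], z, z)
  M[3, ] <- c(v[["gamma1"]] * cB, z,
              -v[["gamma2"]] - v[["delta1"]] * cG - dd, v[["delta2"]],
              z, v[["gamma1"]] * mT, -v[["delta1"]] * mB)
  M[4, ] <- c(z, z, v[["delta1"]] * cG, -v[["delta2"]] - dd,
              z, z, v[["delta1"]] * mB)
  # boundary conditions: D3 gp C + dF = 0 per cytosolic species
  M[5, ] <- c(z, -v[["beta3"]], z, v[["beta1"]] * cD,
              v[["beta2"]] + v[["beta1"]] * mBG + D3gp, z, z)
  M[6, ] <- c(v[["gamma1"]] * cB, z, -v[["gamma2"]], z,
              z, v[["gamma1"]] * mT + D3gp, z)
  M[7, ] <- c(z, z, v[["delta1"]] * cG, -v[["delta2"]],
              z, z, v[["delta1"]] * mB + D3gp)
  det(M)
}

#' Leading linear growth rate for one spherical-harmonic degree
#'
#' Finds the root of the dispersion determinant with the largest real part
#' for degree `l`, by a sign-change scan along the real axis (dense near
#' zero, log-spaced out to +/-10 per second) with bisection refinement.
#' For `l = 0` the conservation laws force a root at sigma = 0 (total-mass
#' mode); it is removed by deflation and reported alongside the leading
#' nonzero root if that is larger.
#'
#' @param params A [ModelParameters-class] object.
#' @param base The homogeneous base state (computed if omitted).
#' @param l Spherical-harmonic degree (integer >= 0).
#' @return Complex scalar: the leading growth rate sigma_l (1/s). Purely
#'   real roots carry a zero imaginary part.
#' @examples
#' dispersionGrowthRate(controlParameters(), l = 1)
#' @export
dispersionGrowthRate <- function(params, base = NULL, l) {
  stopifnot(length(l) == 1L, l >= 0, l == round(l))
  if (is.null(base)) base <- homogeneousSteadyState(params)
  v <- params@values; y <- base@values
  deflate <- (l == 0L)
  f <- function(s) {
    d <- Re(.dispersionDet(s, l, v, y))
    if (deflate) d / s^3 else d
  }
  # scan grid: symmetric log-spacing plus a dense linear band around zero
  pos <- 10^seq(log10(1e-7), log10(10), length.out = 160)
  grid <- sort(unique(c(-rev(pos), seq(-0.05, 0.05, length.out = 201), pos)))
  if (deflate) grid <- grid[abs(grid) > 1e-9]
  fv <- vapply(grid, f, 0)
  ok <- is.finite(fv)
  grid <- grid[ok]; fv <- fv[ok]
  idx <- which(diff(sign(fv)) != 0)
  roots <- vapply(idx, function(i) {
    stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-14)$root
  }, 0)
  if (l == 0L) roots <- c(roots, 0)  # conserved total-mass mode
  # self-consistent bulk-closure root: catches even-multiplicity roots the
  # sign-change scan cannot see (e.g. the reaction-free fourfold root)
  fp <- .fixedPointRoot(l, v, y)
  if (!is.null(fp) && is.finite(Mod(fp))) roots <- c(roots, fp)
  if (!length(roots)) {
    cn <- .complexNewtonRoot(f = function(s) .dispersionDet(s, l, v, y),
                             seeds = c(-0.5 + 0.3i, 0.05 + 0.2i, -2 + 1i))
    if (is.null(cn))
      stop("spectrum undetermined: no dispersion root found for l = ", l)
    return(cn)
  }
  roots[which.max(Re(roots))] + 0i
}

# 4x4 membrane matrix with the cytosolic amplitudes eliminated at trial
# growth rate sigma (bulk closure): its eigenvalues lambda solve the full
# dispersion condition when self-consistent, sigma = lambda(sigma). This
# handles the reaction-free limit, where the 7x7 determinant has a
# fourfold root invisible to sign-change scans.
.bulkClosure4x4 <- function(sigma, l, v, y) {
  lap <- l * (l + 1) / v[["R"]]^2
  gp <- .radialLogDeriv(sigma, l, v[["D3"]], v[["R"]])
  D3gp <- v[["D3"]] * gp
  mT <- y[["mT"]]; mD <- y[["mD"]]; mB <- y[["mB"]]; mBG <- y[["mBG"]]
  cD <- y[["cD"]]; cB <- y[["cB"]]; cG <- y[["cG"]]
  ex <- v[["alpha2"]] + v[["alpha1"]] * mBG
  denD <- v[["beta2"]] + v[["beta1"]] * mBG + D3gp
  denB <- v[["gamma1"]] * mT + D3gp
  denG <- v[["delta1"]] * mB + D3gp
  # C_D = (b3 dmD - b1 cD dmBG)/denD etc., substituted into rows 1-4
  G <- matrix(if (is.complex(D3gp)) 0i else 0, 4, 4)
  G[1, ] <- c(-v[["alpha3"]] - v[["D2"]] * lap,
              ex + v[["beta1"]] * mBG * v[["beta3"]] / denD,
              0,
              v[["beta1"]] * cD + v[["alpha1"]] * mD -
                v[["beta1"]] * mBG * v[["beta1"]] * cD / denD)
  G[2, ] <- c(v[["alpha3"]],
              -ex - v[["beta3"]] - v[["D2"]] * lap +
                v[["beta2"]] * v[["beta3"]] / denD,
              0,
              -v[["alpha1"]] * mD - v[["beta2"]] * v[["beta1"]] * cD / denD)
  G[3, ] <- c(v[["gamma1"]] * cB -
                v[["gamma1"]] * mT * v[["gamma1"]] * cB / denB,
              0,
              -v[["gamma2"]] - v[["delta1"]] * cG - v[["D2"]] * lap +
                v[["gamma1"]] * mT * v[["gamma2"]] / denB +
                v[["delta1"]] * mB * v[["delta1"]] * cG / denG,
              v[["delta2"]] - v[["delta1"]] * mB * v[["delta2"]] / denG)
  G[4, ] <- c(0, 0,
              v[["delta1"]] * cG -
                v[["delta1"]] * mB * v[["delta1"]] * cG / denG,
              -v[["delta2"]] - v[["D2"]] * lap +
                v[["delta1"]] * mB * v[["delta2"]] / denG)
  G
}

# self-consistent leading rate via fixed point on the bulk closure
.fixedPointRoot <- function(l, v, y, sigma0 = 0, maxit = 100L) {
  sigma <- sigma0
  for (it in seq_len(maxit)) {
    G <- .bulkClosure4x4(sigma, l, v, y)
    lam <- eigen(G, only.values = TRUE)$values
    lead <- lam[which.max(Re(lam))]
    if (abs(Im(lead)) < 1e-12) lead <- Re(lead)
    step <- lead - sigma
    if (Mod(step) < 1e-13 * (1 + Mod(sigma))) {
      return(if (is.complex(lead)) lead else as.complex(lead))
    }
    sigma <- sigma + 0.7 * step   # mild damping against cycling
  }
  NULL
}

# damped complex Newton with numerical derivative, for oscillatory branches
.complexNewtonRoot <- function(f, seeds, tol = 1e-12, maxit = 80) {
  for (s0 in seeds) {
    s <- s0
    for (i in seq_len(maxit)) {
      h <- 1e-7 * (abs(s) + 1)
      df <- (f(s + h) - f(s - h)) / (2 * h)
      if (!is.finite(Mod(df)) || Mod(df) == 0) break
      step <- f(s) / df
      s <- s - step
      if (Mod(step) < tol * (1 + Mod(s))) {
        if (Mod(f(s)) < 1e-6) return(s)
        break
      }
    }
  }
  NULL
}

#' Mode-resolved growth spectrum
#'
#' Computes the leading growth rate for each degree l = 0..l_max. If the
#' spectrum is still rising at `l_max` the truncation is extended
#' automatically until the real parts have decreased for three consecutive
#' degrees.
#'
#' @param params A [ModelParameters-class] object.
#' @param l_max Highest degree (default 10).
#' @param base Optional precomputed homogeneous state.
#' @param auto_extend Extend `l_max` until the spectrum is decisively
#'   decaying (default TRUE).
#' @return A [GrowthSpectrum-class] object.
#' @examples
#' gs <- growthSpectrum(controlParameters(), l_max = 4)
#' gs
#' @export
growthSpectrum <- function(params, l_max = 10L, base = NULL,
                           auto_extend = TRUE) {
  stopifnot(l_max >= 1L)
  if (is.null(base)) base <- homogeneousSteadyState(params)
  ls <- 0:l_max
  sig <- vapply(ls, function(l)
    dispersionGrowthRate(params, base, l), complex(1))
  if (auto_extend) {
    while (length(sig) < 65L) {
      n <- length(sig)
      tail3 <- Re(sig[max(1, n - 3):n])
      if (all(diff(tail3) < 0)) break
      lnew <- n  # next degree (degrees are 0-based)
      sig <- c(sig, dispersionGrowthRate(params, base, lnew))
      ls <- c(ls, lnew)
    }
  }
  grow <- which(Re(sig[-1]) == max(Re(sig[-1])))[1]
  new("GrowthSpectrum", l = as.integer(ls), sigma = sig,
      dominantL = as.integer(ls[-1][grow]), params = params)
}

setMethod("show", "GrowthSpectrum", function(object) {
  cat("GrowthSpectrum\n")
  df <- data.frame(l = object@l, Re_sigma = Re(object@sigma),
                   Im_sigma = Im(object@sigma))
  print(df, row.names = FALSE, digits = 5)
  cat(sprintf("dominant l (largest Re sigma among l >= 1): %d\n",
              object@dominantL))
})

#' Convert a growth spectrum to a data.frame
#'
#' @param x A [GrowthSpectrum-class] object.
#' @param ... Ignored.
#' @return data.frame with columns `l`, `re_sigma`, `im_sigma`.
#' @export
setMethod("as.data.frame", "GrowthSpectrum", function(x, ...) {
  data.frame(l = x@l, re_sigma = Re(x@sigma), im_sigma = Im(x@sigma))
})

#' Polarization capability predicate
#'
#' A parameter set can polarize if the homogeneous state is linearly
#' unstable to at least one non-uniform mode: Re sigma_l > 0 for some
#' 1 <= l <= l_max.
#'
#' @inheritParams growthSpectrum
#' @return TRUE/FALSE.
#' @examples
#' isPolarizable(controlParameters())
#' @export
isPolarizable <- function(params, l_max = 10L, base = NULL) {
  if (is.null(base)) base <- homogeneousSteadyState(params)
  for (l in seq_len(l_max)) {
    s <- dispersionGrowthRate(params, base, l)
    if (Re(s) > 0) return(TRUE)
  }
  FALSE
}

#' Can polarization be rescued by changing the diffusion constants?
#'
#' Tests whether any combination of membrane and cytosolic diffusion
#' constants over log-sampled ranges restores a growing mode. Used to
#' distinguish parameter regimes where the reaction network itself fails
#' (no rescue possible) from regimes merely limited by protein
#' redistribution.
#'
#' @param params A [ModelParameters-class] object.
#' @param D2_range,D3_range Length-2 positive ranges for D2 and D3;
#'   defaults span 1e-2 to 1e2 times the values in `params`.
#' @param n Grid points per axis (log-spaced, default 5).
#' @param l_max Passed to [isPolarizable()].
#' @return TRUE if some sampled (D2, D3) yields a growing mode.
#' @export
diffusionRescue <- function(params, D2_range = NULL, D3_range = NULL,
                            n = 5L, l_max = 10L) {
  v <- params@values
  if (is.null(D2_range)) D2_range <- v[["D2"]] * c(1e-2, 1e2)
  if (is.null(D3_range)) D3_range <- v[["D3"]] * c(1e-2, 1e2)
  stopifnot(all(D2_range > 0), all(D3_range > 0))
  if (isPolarizable(params, l_max)) return(TRUE)
  for (d2 in exp(seq(log(D2_range[1]), log(D2_range[2]), length.out = n)))
    for (d3 in exp(seq(log(D3_range[1]), log(D3_range[2]), length.out = n))) {
      pv <- v; pv[["D2"]] <- d2; pv[["D3"]] <- d3
      pp <- new("ModelParameters", values = pv)
      ok <- tryCatch(isPolarizable(pp, l_max), error = function(e) FALSE)
      if (ok) return(TRUE)
    }
  FALSE
}
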