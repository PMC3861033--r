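# Pseudospectral grid on the ball: Gauss-Legendre x Fourier angular grid with
# real spherical-harmonic transforms, and a conservative finite-volume radial
# grid for the cytosol. Spectral coefficients are stored as complex matrices
# C[l+1, m+1] (m = 0..l); negative orders follow from conjugate symmetry of
# real fields.

#' Build the spatial grid for the bulk-surface solver
#'
#' Angular directions use a Gauss-Legendre grid in colatitude (exact
#' quadrature for the spherical-harmonic band limit plus quadratic
#' nonlinearity padding) and an equispaced azimuthal grid handled by FFT.
#' The cytosol uses `nr` conservative finite-volume shells; total protein
#' content is then conserved to machine precision by the integrator.
#'
#' @param R Cell radius (um).
#' @param L Spherical-harmonic truncation degree (default 32).
#' @param nr Number of radial shells (default 24).
#' @param ntheta,nphi Angular grid sizes; defaults apply 3/2-rule padding
#'   (`ntheta = ceil(1.5 (L+1))`, `nphi` the next multiple of 4 at or above
#'   `3 L`).
#' @return A list with nodes, quadrature weights, associated Legendre
#'   tables and radial finite-volume geometry; used as the `grid` slot of
#'   [SystemState-class] objects.
#' @examples
#' g <- sphereGrid(R = 3.95, L = 16)
#' g$ntheta; g$nphi
#' @export
sphereGrid <- function(R, L = 32L, nr = 24L, ntheta = NULL, nphi = NULL) {
  L <- as.integer(L); nr <- as.integer(nr)
  stopifnot(L >= 2L, nr >= 4L, R > 0)
  if (is.null(ntheta)) ntheta <- as.integer(ceiling(1.5 * (L + 1)))
  if (is.null(nphi)) nphi <- as.integer(4 * ceiling(max(3 * L, 8) / 4))
  if (ntheta < L + 1L) stop("ntheta must be at least L + 1")
  if (nphi < 2L * L + 1L) stop("nphi must be at least 2 L + 1")
  gl <- pracma::gaussLegendre(ntheta, -1, 1)
  mu <- gl$x; wtheta <- gl$w
  phi <- 2 * pi * (0:(nphi - 1)) / nphi
  Pleg <- .legendreTables(L, mu)
  rf <- seq(0, R, length.out = nr + 1)
  rc <- 0.5 * (rf[-1] + rf[-(nr + 1)])
  Vshell <- (rf[-1]^3 - rf[-(nr + 1)]^3) / 3    # volume per steradian
  sfac <- rf[nr + 1]^2 / Vshell[nr]             # membrane flux -> outer shell
  # radial-only diffusion FV operator scaffold (per-l angular part added later)
  list(R = R, L = L, nr = nr, ntheta = ntheta, nphi = nphi,
       mu = mu, wtheta = wtheta, phi = phi, Pleg = Pleg,
       rf = rf, rc = rc, Vshell = Vshell, sfac = sfac,
       theta = acos(mu))
}

# Orthonormal (spherical-harmonic normalized) associated Legendre functions
# S_lm(mu) with Y_lm = S_lm exp(i m phi), int |Y|^2 dOmega = 1. Returned as a
# list over m = 0..L of (npts x (L+1-m)) matrices, columns l = m..L.
.legendreTables <- function(L, mu) {
  npts <- length(mu)
  sint <- sqrt(pmax(0, 1 - mu^2))
  out <- vector("list", L + 1)
  Smm <- rep(sqrt(1 / (4 * pi)), npts)
  for (m in 0:L) {
    if (m > 0) Smm <- -sqrt((2 * m + 1) / (2 * m)) * sint * Smm
    cols <- matrix(0, npts, L + 1 - m)
    cols[, 1] <- Smm
    if (L > m) {
      Sl1 <- sqrt(2 * m + 3) * mu * Smm
      cols[, 2] <- Sl1
      Sl0 <- Smm
      if (L > m + 1) for (l in (m + 2):L) {
        a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
        b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
        Sl <- a * (mu * Sl1 - b * Sl0)
        cols[, l - m + 1] <- Sl
        Sl0 <- Sl1; Sl1 <- Sl
      }
    }
    out[[m + 1]] <- cols
  }
  out
}

# forward spherical-harmonic transform of a real (ntheta x nphi) field
.shtAnalyze <- function(g, f) {
  Fm <- t(stats::mvfft(t(f))) / g$nphi            # ntheta x nphi, cols m=0..
  C <- matrix(0 + 0i, g$L + 1, g$L + 1)
  wF <- Fm * g$wtheta                             # row-scale by GL weights
  for (m in 0:g$L) {
    C[(m + 1):(g$L + 1), m + 1] <-
      2 * pi * crossprod(g$Pleg[[m + 1]], wF[, m + 1])
  }
  C
}

# inverse transform: coefficients -> real field on the grid
.shtSynthesize <- function(g, C) {
  G <- matrix(0 + 0i, g$ntheta, g$nphi)
  for (m in 0:g$L) {
    gm <- g$Pleg[[m + 1]] %*% C[(m + 1):(g$L + 1), m + 1]
    G[, m + 1] <- gm
    if (m > 0) G[, g$nphi + 1 - m] <- Conj(gm)
  }
  Re(t(stats::mvfft(t(G), inverse = TRUE)))
}

# batched forward transform of K real fields, input (ntheta, nphi, K),
# output complex array (L+1, L+1, K) with C[l+1, m+1, k]
.shtAnalyzeMulti <- function(g, f) {
  K <- dim(f)[3]
  X <- aperm(f, c(2, 1, 3))
  dim(X) <- c(g$nphi, g$ntheta * K)
  Fm <- stats::mvfft(X) / g$nphi
  C <- array(0 + 0i, c(g$L + 1, g$L + 1, K))
  for (m in 0:g$L) {
    Wm <- matrix(Fm[m + 1, ], g$ntheta, K) * g$wtheta
    C[(m + 1):(g$L + 1), m + 1, ] <- 2 * pi * crossprod(g$Pleg[[m + 1]], Wm)
  }
  C
}

# batched inverse transform: complex (L+1, L+1, K) -> real (ntheta, nphi, K)
.shtSynthesizeMulti <- function(g, C) {
  K <- dim(C)[3]
  G <- matrix(0 + 0i, g$nphi, g$ntheta * K)
  for (m in 0:g$L) {
    gm <- g$Pleg[[m + 1]] %*% matrix(C[(m + 1):(g$L + 1), m + 1, ],
                                     g$L + 1 - m, K)
    G[m + 1, ] <- gm
    if (m > 0) G[g$nphi + 1 - m, ] <- Conj(gm)
  }
  out <- Re(stats::mvfft(G, inverse = TRUE))
  dim(out) <- c(g$nphi, g$ntheta, K)
  aperm(out, c(2, 1, 3))
}

# evaluate a coefficient set at arbitrary directions (mu, phi vectors)
.shtEvaluate <- function(g, C, mu, phi) {
  P <- .legendreTables(g$L, mu)
  val <- numeric(length(mu))
  for (m in 0:g$L) {
    cl <- C[(m + 1):(g$L + 1), m + 1]
    radial <- P[[m + 1]] %*% cl
    if (m == 0) val <- val + Re(radial)
    else val <- val + 2 * Re(radial * exp(1i * m * phi))
  }
  val
}

# surface integral of a grid field over the sphere (area R^2 dmu dphi)
.surfaceIntegral <- function(g, f) {
  g$R^2 * (2 * pi / g$nphi) * sum(g$wtheta * rowSums(f))
}

# volume integral of an (nr x ntheta x nphi) cytosol field
.volumeIntegral <- function(g, c3) {
  (2 * pi / g$nphi) * sum(g$Vshell * colSums(aperm(c3, c(2, 3, 1)) *
                                             g$wtheta, dims = 2))
}

# area-weighted spatial median of a membrane grid field
.weightedMedian <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= 0.5)[1]]
}
.surfaceMedian <- function(g, f) {
  wfull <- rep(g$wtheta, times = g$nphi)
  .weightedMedian(as.vector(f), wfull)
}
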