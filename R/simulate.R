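# Full nonlinear time integration of the bulk-surface system.
#
# Scheme: Strang composition of
#   (a) membrane lateral diffusion, applied exactly in spectral space
#       (half-steps), and
#   (b) a linearized backward-Euler step of the coupled remainder: full
#       per-(l,m) cytosolic diffusion (conservative finite-volume in radius,
#       spectral in angle), membrane reactions, and the membrane-cytosol
#       exchange fluxes.
# In (b) all couplings are implicit; bilinear reaction terms are linearized
# about the state at the step start (Rosenbrock-Euler). The cytosolic
# response to the boundary flux is resolved exactly through the per-degree
# response kernel g_l of the implicit solve; its angular dependence is
# handled by a per-point implicit diagonal part plus a fixed-point iteration
# on the (small) nonlocal remainder. The same linearized flux expression
# updates membrane and cytosol, so each protein pool is conserved to
# machine precision regardless of iteration depth.

.solverSetup <- function(g, params, dt) {
  v <- params@values
  nr <- g$nr; L <- g$L
  # radial FV diffusion operator (no angular part)
  Tr <- matrix(0, nr, nr)
  for (i in seq_len(nr)) {
    if (i < nr) {
      k <- v[["D3"]] * g$rf[i + 1]^2 / ((g$rc[i + 1] - g$rc[i]) * g$Vshell[i])
      Tr[i, i] <- Tr[i, i] - k; Tr[i, i + 1] <- k
    }
    if (i > 1) {
      k <- v[["D3"]] * g$rf[i]^2 / ((g$rc[i] - g$rc[i - 1]) * g$Vshell[i])
      Tr[i, i] <- Tr[i, i] - k; Tr[i, i - 1] <- k
    }
  }
  Sinv <- vector("list", L + 1)
  Se <- matrix(0, nr, L + 1)
  glk <- numeric(L + 1)
  for (l in 0:L) {
    Al <- Tr
    diag(Al) <- diag(Al) - v[["D3"]] * l * (l + 1) / g$rc^2
    Si <- solve(diag(nr) - dt * Al)
    Sinv[[l + 1]] <- Si
    Se[, l + 1] <- Si[, nr]
    glk[l + 1] <- dt * g$sfac * Si[nr, nr]
  }
  gbar <- (max(glk) + min(glk)) / 2
  ll <- 0:L
  memfacHalf <- exp(-v[["D2"]] * ll * (ll + 1) / g$R^2 * dt / 2)
  # row-scaling matrix for spectral coefficients C[l+1, m+1]
  memfacMat <- matrix(memfacHalf, L + 1, L + 1)
  list(Sinv = Sinv, Se = Se, gl = glk, gbar = gbar,
       memfacMat = memfacMat, dt = dt, v = v)
}

# linearized backward-Euler local solve, vectorized over grid points.
# Unknowns per point: mT, mD, mB, mBG, cRD, cRB, cRG. Bilinear terms uv are
# replaced by u0 v + u v0 - u0 v0 (reference: step start). The three
# boundary-value unknowns are eliminated analytically (each cR row has a
# single diagonal entry), leaving a structured 4x4 membrane system solved
# in closed form; everything is plain vector arithmetic. Returns new
# membrane values, boundary cytosol values, and the linearized fluxes.
.localSolve <- function(v, h, gbar, m0, cR0, ctR, nl) {
  mT0 <- m0[, 1]; mD0 <- m0[, 2]; mB0 <- m0[, 3]; mBG0 <- m0[, 4]
  cD0 <- cR0[, 1]; cB0 <- cR0[, 2]; cG0 <- cR0[, 3]
  a1 <- v[["alpha1"]]; a2 <- v[["alpha2"]]; a3 <- v[["alpha3"]]
  b1 <- v[["beta1"]]; b2 <- v[["beta2"]]; b3 <- v[["beta3"]]
  g1 <- v[["gamma1"]]; g2 <- v[["gamma2"]]
  d1 <- v[["delta1"]]; d2 <- v[["delta2"]]
  ex0 <- a2 + a1 * mBG0
  # eliminate boundary values: cRX = pX + qX * m + rX * m' (coefficients
  # from  cRX (1 + gbar kX) = rhs + gbar (off-rate terms) )
  denD <- 1 + gbar * (b2 + b1 * mBG0)
  pD <- (ctR[, 1] - nl[, 1] + gbar * b1 * mBG0 * cD0) / denD
  qD <- gbar * b3 / denD                 # cRD = pD + qD mD + rD mBG
  rD <- -gbar * b1 * cD0 / denD
  denB <- 1 + gbar * g1 * mT0
  pB <- (ctR[, 2] - nl[, 2] + gbar * g1 * mT0 * cB0) / denB
  qB <- gbar * g2 / denB                 # cRB = pB + qB mB + rB mT
  rB <- -gbar * g1 * cB0 / denB
  denG <- 1 + gbar * d1 * mB0
  pG <- (ctR[, 3] - nl[, 3] + gbar * d1 * mB0 * cG0) / denG
  qG <- gbar * d2 / denG                 # cRG = pG + qG mBG + rG mB
  rG <- -gbar * d1 * cG0 / denG
  # membrane system, unknown order (mT, mD, mB, mBG); mB decouples from
  # rows 1-2 and mT/mD from rows 3-4 except through mBG
  a11 <- 1 + h * a3
  a12 <- -h * ex0 - h * b1 * mBG0 * qD
  a14 <- -h * (b1 * cD0 + a1 * mD0) - h * b1 * mBG0 * rD
  r1 <- mT0 - h * (b1 * mBG0 * cD0 + a1 * mBG0 * mD0) + h * b1 * mBG0 * pD
  a21 <- -h * a3
  a22 <- 1 + h * (ex0 + b3) - h * b2 * qD
  a24 <- h * a1 * mD0 - h * b2 * rD
  r2 <- mD0 + h * a1 * mBG0 * mD0 + h * b2 * pD
  a31 <- -h * g1 * cB0 - h * g1 * mT0 * rB
  a33 <- 1 + h * (g2 + d1 * cG0) - h * g1 * mT0 * qB + h * d1 * mB0 * rG
  a34 <- -h * d2 + h * d1 * mB0 * qG
  r3 <- mB0 - h * g1 * mT0 * cB0 + h * d1 * mB0 * cG0 +
        h * g1 * mT0 * pB - h * d1 * mB0 * pG
  a43 <- -h * d1 * cG0 - h * d1 * mB0 * rG
  a44 <- 1 + h * d2 - h * d1 * mB0 * qG
  r4 <- mBG0 - h * d1 * mB0 * cG0 + h * d1 * mB0 * pG
  # row 4: mBG = (r4 - a43 mB)/a44 ; row 3 with that: mB = (r3p - a31 mT)/a33p
  a33p <- a33 - a34 * a43 / a44
  r3p <- r3 - a34 * r4 / a44
  # mBG = u0 + u1 mT after substituting mB
  u0 <- (r4 - a43 * r3p / a33p) / a44
  u1 <- (a43 * a31 / a33p) / a44
  # rows 1-2 reduce to 2x2 in (mT, mD)
  A11 <- a11 + a14 * u1; R1 <- r1 - a14 * u0
  A21 <- a21 + a24 * u1; R2 <- r2 - a24 * u0
  det2 <- A11 * a22 - a12 * A21
  mT <- (R1 * a22 - a12 * R2) / det2
  mD <- (A11 * R2 - A21 * R1) / det2
  mBG <- u0 + u1 * mT
  mB <- (r3p - a31 * mT) / a33p
  cRD <- pD + qD * mD + rD * mBG
  cRB <- pB + qB * mB + rB * mT
  cRG <- pG + qG * mBG + rG * mB
  FD <- (b2 + b1 * mBG0) * cRD + b1 * cD0 * mBG - b1 * mBG0 * cD0 - b3 * mD
  FB <- g1 * (mT0 * cRB + cB0 * mT - mT0 * cB0) - g2 * mB
  FG <- d1 * (mB0 * cRG + cG0 * mB - mB0 * cG0) - d2 * mBG
  list(m = cbind(mT, mD, mB, mBG), cR = cbind(cRD, cRB, cRG),
       Fl = cbind(FD, FB, FG))
}

# Solver engine. The cytosol is held as a list over degree l of complex
# (nr x (3 (l+1))) matrices (columns: orders m = 0..l for cD, then cB, cG),
# so the per-degree implicit solves are single matrix products. Membrane
# lateral diffusion half-steps of adjacent steps are fused into full steps
# away from output times.
.makeEngine <- function(g, params, dt, iter_tol = 1e-9, max_iter = 40L) {
  su <- .solverSetup(g, params, dt)
  L <- g$L; nr <- g$nr
  npts <- g$ntheta * g$nphi
  memfacHalf <- su$memfacMat[, 1]
  memfacFull <- memfacHalf^2
  env <- new.env(parent = emptyenv())
  env$niter_total <- 0
  # membrane lateral diffusion (exact); fac = per-degree decay factors
  memDiffuse <- function(mem, fac) {
    C <- .shtAnalyzeMulti(g, mem)
    for (k in 1:4) C[, , k] <- C[, , k] * fac
    .shtSynthesizeMulti(g, C)
  }
  # boundary values of the cytosol from the per-l storage
  boundaryGrid <- function(bl) {
    Cb <- array(0 + 0i, c(L + 1, L + 1, 3))
    for (l in 0:L) {
      row <- matrix(bl[[l + 1]][nr, ], l + 1, 3)
      for (sp in 1:3) Cb[l + 1, seq_len(l + 1), sp] <- row[, sp]
    }
    out <- .shtSynthesizeMulti(g, Cb)
    dim(out) <- c(npts, 3)
    out
  }
  # coupled implicit step of cytosol diffusion + exchange + reactions
  physics <- function(mem, bl, Fl) {
    cR0 <- boundaryGrid(bl)
    for (l in 0:L) bl[[l + 1]] <- su$Sinv[[l + 1]] %*% bl[[l + 1]]
    ctR <- boundaryGrid(bl)
    m0 <- matrix(mem, npts, 4)
    niter <- 0L
    gdiff <- su$gl - su$gbar
    repeat {
      niter <- niter + 1L
      Fgrid <- array(Fl, c(g$ntheta, g$nphi, 3))
      Fh <- .shtAnalyzeMulti(g, Fgrid)
      nlC <- Fh
      for (sp in 1:3) nlC[, , sp] <- nlC[, , sp] * gdiff
      nl <- .shtSynthesizeMulti(g, nlC)
      dim(nl) <- c(npts, 3)
      ls <- .localSolve(su$v, dt, su$gbar, m0, cR0, ctR, nl)
      dF <- max(abs(ls$Fl - Fl)) / (max(abs(ls$Fl)) + 1e-300)
      conv <- dF < iter_tol || niter >= max_iter
      Fl <- ls$Fl
      if (conv) {
        # transform of the converged flux, reused for the deposit
        Fh <- .shtAnalyzeMulti(g, array(Fl, c(g$ntheta, g$nphi, 3)))
        break
      }
    }
    hs <- dt * g$sfac
    for (l in 0:L) {
      frow <- matrix(Fh[l + 1, seq_len(l + 1), ], l + 1, 3)
      bl[[l + 1]] <- bl[[l + 1]] - outer(su$Se[, l + 1],
                                         hs * as.vector(frow))
    }
    env$niter_total <- env$niter_total + niter
    list(mem = array(ls$m, dim = c(g$ntheta, g$nphi, 4)), bl = bl, Fl = Fl)
  }
  list(memDiffuse = memDiffuse, physics = physics,
       memfacHalf = memfacHalf, memfacFull = memfacFull, env = env)
}

# grid-space cytosol (nr, ntheta, nphi, 3) <-> per-l spectral storage
.cytosolToSpectralList <- function(g, cyt) {
  nr <- g$nr
  bl <- vector("list", g$L + 1)
  Ck <- array(0 + 0i, c(g$L + 1, g$L + 1, 3 * nr))
  f <- aperm(cyt, c(2, 3, 1, 4))
  dim(f) <- c(g$ntheta, g$nphi, nr * 3)
  C <- .shtAnalyzeMulti(g, f)   # (L+1, L+1, nr*3)
  for (l in 0:g$L) {
    blk <- matrix(0 + 0i, nr, 3 * (l + 1))
    for (sp in 1:3) for (mm in 0:l) {
      blk[, (sp - 1) * (l + 1) + mm + 1] <-
        C[l + 1, mm + 1, (sp - 1) * nr + seq_len(nr)]
    }
    bl[[l + 1]] <- blk
  }
  bl
}

.cytosolListToGrid <- function(g, bl) {
  nr <- g$nr
  C <- array(0 + 0i, c(g$L + 1, g$L + 1, nr * 3))
  for (l in 0:g$L) {
    blk <- bl[[l + 1]]
    for (sp in 1:3) for (mm in 0:l) {
      C[l + 1, mm + 1, (sp - 1) * nr + seq_len(nr)] <-
        blk[, (sp - 1) * (l + 1) + mm + 1]
    }
  }
  f <- .shtSynthesizeMulti(g, C)
  dim(f) <- c(g$ntheta, g$nphi, nr, 3)
  aperm(f, c(3, 1, 2, 4))
}

#' Integrate the bulk-surface polarization dynamics
#'
#' Runs the full nonlinear model from an initial [SystemState-class] to
#' `t_end`, recording cluster metrics at the requested output times.
#' The scheme is deterministic: a given initial state and option set always
#' produces the same trajectory.
#'
#' @param params A [ModelParameters-class] object.
#' @param init Initial [SystemState-class] (see [uniformState()],
#'   [randomLatticePerturbation()], [broadCapPerturbation()]).
#' @param t_end End time (s), counted from `init@time`.
#' @param output_times Times (s) at which metrics (and optionally
#'   snapshots) are recorded; default every 100 s. Rounded to whole steps.
#' @param solver_options List; recognized entries `dt` (default 0.5 s),
#'   `iter_tol` (flux iteration tolerance, default 1e-9), `max_iter`,
#'   `keep_snapshots` (`"last"`, `"all"` or `"none"`), `compute_fwhm`
#'   (logical, default TRUE), `positivity_tol` (relative clamp threshold,
#'   default 1e-12).
#' @return A [Trajectory-class] object. Its `metrics` slot has one row per
#'   output time with cluster height, FWHM, cluster count, membrane
#'   fractions and total copies per pool; `solverInfo` records resolution,
#'   step size, mean iteration count, positivity clamps and conservation
#'   drift.
#' @examples
#' \donttest{
#' p <- controlParameters()
#' hs <- homogeneousSteadyState(p)
#' g <- sphereGrid(R = p[["R"]], L = 12, nr = 12)
#' init <- broadCapPerturbation(p, hs, grid = g)
#' tr <- simulate(p, init, t_end = 200, output_times = c(100, 200))
#' tr@metrics
#' }
#' @export
simulate <- function(params, init, t_end, output_times = NULL,
                     solver_options = list()) {
  stopifnot(is(init, "SystemState"), t_end > 0)
  so <- modifyList(list(dt = 0.5, iter_tol = 1e-9, max_iter = 40L,
                        keep_snapshots = "last", compute_fwhm = TRUE,
                        positivity_tol = 1e-12), solver_options)
  g <- init@grid
  dt <- so$dt
  t0 <- init@time
  nstep <- ceiling((t_end - 1e-9) / dt)
  if (is.null(output_times))
    output_times <- seq(min(100, t_end), t_end, by = min(100, t_end))
  out_steps <- sort(unique(pmax(1L, pmin(nstep, round(output_times / dt)))))
  eng <- .makeEngine(g, params, dt, so$iter_tol, so$max_iter)
  mem <- init@membrane
  bl <- .cytosolToSpectralList(g, init@cytosol)
  tot0 <- proteinTotals(init)$total
  npts <- g$ntheta * g$nphi
  Fl <- matrix(0, npts, 3)
  clamped_mass <- 0; clamp_events <- 0L
  metrics <- vector("list", length(out_steps))
  snapshots <- list()
  oi <- 1L
  means0 <- apply(init@membrane, 3, mean)
  # Strang with fused membrane half-steps: open with a half step, apply a
  # full step between physics stages, close with a half step at output
  # times (and reopen when continuing).
  mem <- eng$memDiffuse(mem, eng$memfacHalf)
  for (istep in seq_len(nstep)) {
    st <- eng$physics(mem, bl, Fl)
    mem <- st$mem; bl <- st$bl; Fl <- st$Fl
    at_output <- oi <= length(out_steps) && istep == out_steps[oi]
    if (at_output || istep == nstep) {
      mem <- eng$memDiffuse(mem, eng$memfacHalf)
    } else {
      mem <- eng$memDiffuse(mem, eng$memfacFull)
    }
    if (any(mem < 0)) {
      # clamp undershoots (spectral ringing) to zero and rescale the
      # positive part of each affected field so its surface integral is
      # unchanged: positivity enforcement never creates or destroys mass.
      drop <- 0
      for (j in 1:4) {
        fj <- mem[, , j]
        if (any(fj < 0)) {
          tot_before <- .surfaceIntegral(g, fj)
          drop <- drop - sum(fj[fj < 0])
          fj[fj < 0] <- 0
          tot_after <- .surfaceIntegral(g, fj)
          if (tot_after > 0 && tot_before > 0)
            fj <- fj * (tot_before / tot_after)
          mem[, , j] <- fj
        }
      }
      clamped_mass <- clamped_mass + drop
      clamp_events <- clamp_events + 1L
    }
    if (at_output) {
      tnow <- t0 + istep * dt
      state <- new("SystemState", membrane = mem,
                   cytosol = .cytosolListToGrid(g, bl), grid = g,
                   time = tnow)
      cs <- clusterStats(state, compute_fwhm = so$compute_fwhm)
      tt <- proteinTotals(state)
      v <- params@values
      ref <- c(v[["N42"]], v[["NB"]], v[["N24"]])
      metrics[[oi]] <- data.frame(
        time = tnow, height = cs@height, fwhm = cs@fwhm,
        n_clusters = cs@nClusters,
        frac_cdc42 = tt$membrane[1] / ref[1],
        frac_bem1 = tt$membrane[2] / ref[2],
        frac_cdc24 = tt$membrane[3] / ref[3],
        total_cdc42 = tt$total[1], total_bem1 = tt$total[2],
        total_cdc24 = tt$total[3])
      if (so$keep_snapshots == "all" ||
          (so$keep_snapshots == "last" && oi == length(out_steps)))
        snapshots[[as.character(tnow)]] <- state
      oi <- oi + 1L
      if (istep < nstep) mem <- eng$memDiffuse(mem, eng$memfacHalf)
    }
  }
  metrics <- do.call(rbind, metrics)
  # positivity clamping is mass-restoring, but substantial cumulative
  # clamping signals an under-resolved run: say so once
  if (clamped_mass > 1e-4 * sum(tot0))
    warning(sprintf(paste0("positivity clamping touched %.3g molecules ",
                           "over %d steps (%.2g of total mass); consider ",
                           "a higher spherical-harmonic truncation"),
                    clamped_mass, clamp_events,
                    clamped_mass / sum(tot0)))
  drift <- max(abs(metrics[nrow(metrics),
                           c("total_cdc42", "total_bem1", "total_cdc24")] -
                     tot0) / tot0)
  new("Trajectory", times = metrics$time, metrics = metrics,
      snapshots = snapshots,
      solverInfo = list(L = g$L, ntheta = g$ntheta, nphi = g$nphi,
                        nr = g$nr, dt = dt,
                        mean_flux_iterations = eng$env$niter_total / nstep,
                        clamp_events = clamp_events,
                        clamped_mass = clamped_mass,
                        conservation_drift = drift,
                        t0 = t0, t_end = t0 + nstep * dt))
}

setMethod("show", "Trajectory", function(object) {
  si <- object@solverInfo
  cat(sprintf("Trajectory: %d output times over t = %.5g .. %.5g s\n",
              length(object@times), si$t0, si$t_end))
  cat(sprintf("  grid L = %d (%d x %d angular, %d radial), dt = %g s\n",
              si$L, si$ntheta, si$nphi, si$nr, si$dt))
  cat(sprintf("  conservation drift %.2e, %d positivity clamps\n",
              si$conservation_drift, si$clamp_events))
  n <- nrow(object@metrics)
  print(utils::tail(object@metrics[, c("time", "height", "fwhm",
                                       "n_clusters")], 3),
        row.names = FALSE)
})

#' Run the dynamics to a steady state
#'
#' Integrates in chunks until the maximum relative change of any membrane
#' field over a 100 s window falls below `tol`, or `t_max` is reached.
#' The final state is classified polarized/unpolarized by [clusterStats()]:
#' polarized if the cluster height exceeds `polar_threshold` times the mean
#' membrane Cdc42 density.
#'
#' @param params A [ModelParameters-class] object.
#' @param init Initial [SystemState-class].
#' @param tol Convergence tolerance: max relative membrane field change per
#'   100 s (default 1e-6).
#' @param t_max Time horizon (s, default 1e5). If reached without
#'   convergence the last state is returned flagged `converged = FALSE`.
#' @param check_every Window length for the convergence test (s).
#' @param polar_threshold Polarization flag threshold (default 0.05).
#' @param solver_options Passed to [simulate()].
#' @return List with `state` (final [SystemState-class]), `converged`,
#'   `polarized`, `stats` (final [ClusterStats-class]) and `time`.
#' @examples
#' \donttest{
#' p <- controlParameters()
#' hs <- homogeneousSteadyState(p)
#' g <- sphereGrid(R = p[["R"]], L = 12, nr = 12)
#' res <- runToSteadyState(p, broadCapPerturbation(p, hs, grid = g),
#'                         t_max = 2000)
#' }
#' @export
runToSteadyState <- function(params, init, tol = 1e-6, t_max = 1e5,
                             check_every = 100, polar_threshold = 0.05,
                             solver_options = list()) {
  so <- modifyList(list(keep_snapshots = "last", compute_fwhm = FALSE),
                   solver_options)
  state <- init
  t_acc <- 0
  converged <- FALSE
  while (t_acc < t_max) {
    chunk <- min(check_every, t_max - t_acc)
    prev <- state@membrane
    tr <- simulate(params, state, chunk, output_times = chunk,
                   solver_options = so)
    state <- tr@snapshots[[length(tr@snapshots)]]
    t_acc <- t_acc + chunk
    scalem <- pmax(apply(prev, 3, function(x) mean(abs(x))), 1e-12)
    delta <- max(abs(state@membrane - prev) /
                   rep(scalem, each = dim(prev)[1] * dim(prev)[2]))
    if (delta * (100 / chunk) < tol) { converged <- TRUE; break }
  }
  cs <- clusterStats(state, compute_fwhm = TRUE)
  meanc42 <- mean(membraneField(state, "cdc42"))
  polarized <- is.finite(cs@height) && cs@height > polar_threshold * meanc42
  if (!converged)
    warning("runToSteadyState: not converged by t_max; returning last state")
  list(state = state, converged = converged, polarized = polarized,
       stats = cs, time = state@time)
}
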