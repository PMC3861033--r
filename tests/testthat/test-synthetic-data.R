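test_that("zero-amplitude perturbations return the base state exactly", {
  p <- ctrlParams()
  g <- sphereGrid(R = p[["R"]], L = 8, nr = 8)
  base <- uniformState(ctrlHom(), g)
  st1 <- randomLatticePerturbation(p, ctrlHom(), amplitude = 0, seed = 1,
                                   grid = g)
  st2 <- broadCapPerturbation(p, ctrlHom(), amplitude = 0, grid = g)
  expect_identical(st1@membrane, base@membrane)
  expect_identical(st2@membrane, base@membrane)
})

test_that("random-lattice perturbation is bounded, membrane-only and seeded", {
  p <- ctrlParams()
  g <- sphereGrid(R = p[["R"]], L = 10, nr = 8)
  base <- uniformState(ctrlHom(), g)
  st <- randomLatticePerturbation(p, ctrlHom(), seed = 42, grid = g)
  # trilinear interpolation of [-1,1] noise keeps |f| <= 1: relative
  # deviation of each membrane field is at most the amplitude
  for (j in 1:4) {
    rel <- st@membrane[, , j] / base@membrane[, , j] - 1
    expect_lte(max(abs(rel)), 0.01 + 1e-12)
    expect_gt(max(abs(rel)), 0.001)   # perturbation is actually there
  }
  # cytosol untouched, exactly
  expect_identical(st@cytosol, base@cytosol)
  # determinism / seed dependence
  st_same <- randomLatticePerturbation(p, ctrlHom(), seed = 42, grid = g)
  st_diff <- randomLatticePerturbation(p, ctrlHom(), seed = 43, grid = g)
  expect_identical(st@membrane, st_same@membrane)
  expect_false(identical(st@membrane, st_diff@membrane))
  # amplitude >= 1 refused
  expect_error(randomLatticePerturbation(p, ctrlHom(), amplitude = 1,
                                         seed = 1, grid = g), "positivity")
})

test_that("the perturbation function has ~1 um correlation length", {
  # same-lattice-cell points correlate; points several cells apart do not
  p <- ctrlParams()
  g <- sphereGrid(R = p[["R"]], L = 24, nr = 8)
  st <- randomLatticePerturbation(p, ctrlHom(), seed = 7, grid = g)
  f <- st@membrane[, , 1] / uniformState(ctrlHom(), g)@membrane[, , 1] - 1
  # autocorrelation along the equatorial row at ~R dphi spacing
  eq <- f[which.min(abs(g$mu)), ]
  dphi_um <- 2 * pi * g$R / g$nphi       # ~0.35 um at this resolution
  ac1 <- cor(eq, c(eq[-1], eq[1]))       # neighbours well inside 1 um
  lag10 <- round(5 / dphi_um)            # ~5 um apart
  ac10 <- cor(eq, eq[(seq_along(eq) + lag10 - 1) %% length(eq) + 1])
  expect_gt(ac1, 0.5)
  expect_lt(abs(ac10), 0.4)
})

test_that("different seeds give different cluster positions", {
  p <- ctrlParams()
  g <- smallGrid()
  centers <- lapply(c(21, 22), function(sd) {
    init <- randomLatticePerturbation(p, ctrlHom(), seed = sd, grid = g)
    tr <- simulate(p, init, t_end = 2600, output_times = 2600,
                   solver_options = list(compute_fwhm = FALSE))
    clusterStats(tr@snapshots[[1]])@center
  })
  expect_lt(sum(centers[[1]] * centers[[2]]), 0.999)
})

test_that("broad-cap perturbation conserves mass exactly and seeds a cap", {
  p <- ctrlParams()
  g <- sphereGrid(R = p[["R"]], L = 10, nr = 8)
  base <- uniformState(ctrlHom(), g)
  d <- c(0.6, 0, 0.8)
  st <- broadCapPerturbation(p, ctrlHom(), amplitude = 0.01, grid = g,
                             cap_direction = d)
  t0 <- proteinTotals(base)$total
  t1 <- proteinTotals(st)$total
  # the added term is odd about the center plane: totals unchanged exactly
  expect_equal(t1, t0, tolerance = 1e-13)
  # maximum of the perturbed field lies along the cap direction
  f <- membraneField(st)
  i <- which(f == max(f), arr.ind = TRUE)[1, ]
  xyz <- c(sin(g$theta[i[1]]) * cos(g$phi[i[2]]),
           sin(g$theta[i[1]]) * sin(g$phi[i[2]]), g$mu[i[1]])
  expect_gt(sum(xyz * d), 0.97)
})

test_that("synthetic line scans are deterministic per seed", {
  a <- syntheticLinescan(2, 10, 50, noise_sd = 5, n_points = 64, seed = 9)
  b <- syntheticLinescan(2, 10, 50, noise_sd = 5, n_points = 64, seed = 9)
  d <- syntheticLinescan(2, 10, 50, noise_sd = 5, n_points = 64, seed = 10)
  expect_identical(a@intensity, b@intensity)
  expect_false(identical(a@intensity, d@intensity))
  expect_error(syntheticLinescan(2, 10, 50, noise_sd = 5, n_points = 64),
               "seed")
  # generators do not disturb the caller's RNG stream
  set.seed(1); r1 <- runif(1)
  set.seed(1)
  invisible(syntheticLinescan(2, 10, 50, noise_sd = 5, n_points = 64,
                              seed = 77))
  expect_identical(runif(1), r1)
})
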