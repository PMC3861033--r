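# Shared fixtures, memoized across test files (test_dir runs one session).
.fix <- local({
  env <- new.env()
  function(name, build) {
    if (!exists(name, env)) assign(name, build(), env)
    get(name, env)
  }
})

ctrlParams <- function() .fix("params", controlParameters)
ctrlHom <- function() .fix("hom", function() homogeneousSteadyState(ctrlParams()))
smallGrid <- function() .fix("grid12", function()
  sphereGrid(R = ctrlParams()[["R"]], L = 12, nr = 16))
midGrid <- function() .fix("grid16", function()
  sphereGrid(R = ctrlParams()[["R"]], L = 16, nr = 24))

# reference value of the leading l=1 dispersion root at control parameters,
# frozen from the analytic dispersion relation (independently verified by a
# 400-cell discretized-operator eigensolve: 0.0036716)
SIGMA1_CONTROL <- 0.0036711

# independent well-mixed two-compartment relaxation oracle: plain RK4 on
# the same reaction list, written without the package's kernel
wellMixedOracleSS <- function(params, t_end = 5000, dt = 0.05) {
  v <- paramValues(params)
  A <- 4 * pi * v[["R"]]^2; V <- 4 / 3 * pi * v[["R"]]^3
  f <- function(y) {
    mT <- y[1]; mD <- y[2]; mB <- y[3]; mBG <- y[4]
    cD <- y[5]; cB <- y[6]; cG <- y[7]
    ex <- v[["alpha2"]] + v[["alpha1"]] * mBG
    FD <- (v[["beta2"]] + v[["beta1"]] * mBG) * cD - v[["beta3"]] * mD
    FB <- v[["gamma1"]] * mT * cB - v[["gamma2"]] * mB
    FG <- v[["delta1"]] * mB * cG - v[["delta2"]] * mBG
    c(v[["beta1"]] * mBG * cD + ex * mD - v[["alpha3"]] * mT,
      v[["beta2"]] * cD + v[["alpha3"]] * mT - ex * mD - v[["beta3"]] * mD,
      FB - v[["delta1"]] * mB * cG + v[["delta2"]] * mBG,
      FG,
      -A / V * FD, -A / V * FB, -A / V * FG)
  }
  y <- c(0, 0, 0, 0, v[["N42"]] / V, v[["NB"]] / V, v[["N24"]] / V)
  steps <- ceiling(t_end / dt)
  # adaptive coarse-to-fine: big steps early would be unstable; fixed dt ok
  for (i in seq_len(steps)) {
    k1 <- f(y); k2 <- f(y + dt / 2 * k1); k3 <- f(y + dt / 2 * k2)
    k4 <- f(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  names(y) <- c("mT", "mD", "mB", "mBG", "cD", "cB", "cG")
  y
}
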