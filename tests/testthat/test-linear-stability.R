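test_that("reaction-free limit reproduces pure lateral diffusion decay", {
  # with all rates driven to zero the leading membrane mode of degree l
  # decays at -D2 l(l+1)/R^2
  p <- modelParameters(alpha1 = 1e-12, alpha2 = 1e-12, alpha3 = 1e-12,
                       beta1 = 1e-12, beta2 = 1e-12, beta3 = 1e-12,
                       gamma1 = 1e-12, gamma2 = 1e-12, delta1 = 1e-12,
                       delta2 = 1e-12)
  hs <- homogeneousSteadyState(p)
  v <- paramValues(p)
  sig <- vapply(1:6, function(l)
    Re(dispersionGrowthRate(p, hs, l)), 0)
  expect_equal(sig, -v[["D2"]] * (1:6) * (2:7) / v[["R"]]^2,
               tolerance = 1e-6)
  # strictly decreasing in l
  expect_true(all(diff(sig) < 0))
})

test_that("control parameters: l = 1 grows, higher modes decay", {
  p <- ctrlParams(); hs <- ctrlHom()
  s1 <- dispersionGrowthRate(p, hs, 1)
  expect_lt(abs(Re(s1) / SIGMA1_CONTROL - 1), 1e-4)
  expect_identical(Im(s1), 0)
  for (l in 2:10)
    expect_lt(Re(dispersionGrowthRate(p, hs, l)), 0)
})

test_that("growth spectrum reports the single-cluster mode as dominant", {
  gs <- growthSpectrum(ctrlParams(), l_max = 10)
  expect_identical(gs@dominantL, 1L)
  expect_identical(gs@l[1], 0L)
  df <- as.data.frame(gs)
  expect_named(df, c("l", "re_sigma", "im_sigma"))
  # l = 0 sector: the conserved total-mass mode sits at zero and nothing
  # grows
  expect_equal(df$re_sigma[df$l == 0], 0, tolerance = 1e-12)
  # and the leading non-zero l = 0 root (deflated) is negative
  v <- paramValues(ctrlParams()); y <- ctrlHom()@values
  f0 <- function(s) Re(cdc42polar:::.dispersionDet(s, 0, v, y)) / s^3
  root0 <- uniroot(f0, c(-0.5, -1e-4), tol = 1e-12)$root
  expect_lt(root0, 0)
})

test_that("dominant structure stays single-cluster over wide parameter ranges", {
  # each parameter varied over two orders of magnitude around control, on a
  # sampled grid: whenever some mode grows, the dominant one is l = 1
  for (par in c("N24", "NB", "alpha3", "beta3", "gamma2")) {
    for (fac in c(0.1, 10)) {
      p <- scaleParameters(ctrlParams(), structure(fac, names = par))
      hs <- tryCatch(homogeneousSteadyState(p), error = function(e) NULL)
      if (is.null(hs)) next
      sig <- vapply(1:8, function(l)
        Re(dispersionGrowthRate(p, hs, l)), 0)
      if (any(sig > 0)) expect_identical(which.max(sig), 1L)
    }
  }
})

test_that("sigma_1 is continuous under small parameter perturbations", {
  p <- ctrlParams()
  s0 <- Re(dispersionGrowthRate(p, ctrlHom(), 1))
  for (par in c("alpha3", "beta3", "N24")) {
    pp <- scaleParameters(p, structure(1.01, names = par))
    s1 <- Re(dispersionGrowthRate(pp, homogeneousSteadyState(pp), 1))
    expect_lt(abs(s1 - s0), 0.2 * abs(s0) + 1e-4)  # no root jumping
  }
})

test_that("polarization capability and its loss across a boundary", {
  expect_true(isPolarizable(ctrlParams()))
  # no Cdc42 membrane supply: beta2 ~ 0 and beta1 ~ 0 cannot pattern
  p_off <- modelParameters(beta1 = 1e-12, beta2 = 1e-12)
  expect_false(isPolarizable(p_off))
  # reducing GEF copy number below a threshold loses capability
  expect_false(isPolarizable(scaleParameters(ctrlParams(), N24 = 0.05)))
  # and the boundary is crossed monotonically along the N24 axis
  caps <- vapply(c(0.05, 0.2, 1, 2), function(f)
    isPolarizable(scaleParameters(ctrlParams(), N24 = f)), NA)
  expect_identical(caps, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("diffusion rescue distinguishes network failure from transport", {
  expect_true(diffusionRescue(ctrlParams(), n = 2))   # already polarizable
  # deep in the failure regime (strong hydrolysis, scarce GEF) no choice
  # of diffusion constants rescues polarization, and Cdc42-GTP is gone
  p_deep <- scaleParameters(ctrlParams(), alpha3 = 10, N24 = 0.05)
  expect_false(diffusionRescue(p_deep, n = 3, l_max = 6))
  hs <- homogeneousSteadyState(p_deep)
  gtp_frac <- 4 * pi * p_deep[["R"]]^2 * hs@values[["mT"]] / 3000
  expect_lt(gtp_frac, 0.01)
})
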