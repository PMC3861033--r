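test_that("FWHM of an analytic Gaussian cap matches the closed form", {
  g <- midGrid()
  for (sig in c(0.2, 0.3, 0.45)) {
    f <- syntheticMembraneCap(g, background = 2, height = 40,
                              angular_sigma = sig,
                              center = c(0.48, 0.6, 0.64))
    cs <- clusterStats(f, grid = g)
    expect_equal(cs@fwhm, g$R * 2 * sqrt(2 * log(2)) * sig,
                 tolerance = 0.02)
    expect_identical(cs@nClusters, 1L)
    # height is max - background; background here is dominated by the tails
    expect_gt(cs@height, 35)
  }
  # a cap covering much of the sphere biases the median background upward,
  # shaving the measured width; still close
  f <- syntheticMembraneCap(g, 2, 40, 0.6)
  expect_equal(clusterStats(f, grid = g)@fwhm,
               g$R * 2 * sqrt(2 * log(2)) * 0.6, tolerance = 0.05)
})

test_that("FWHM estimation is rotation invariant on synthetic caps", {
  g <- midGrid()
  set.seed(99)
  vals <- replicate(20, {
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    f <- syntheticMembraneCap(g, 2, 40, 0.35, center = d)
    clusterStats(f, grid = g)@fwhm
  })
  expect_lt((max(vals) - min(vals)) / mean(vals), 0.01)
})

test_that("cluster counting distinguishes one, two, and no caps", {
  g <- midGrid()
  one <- syntheticMembraneCap(g, 2, 40, 0.3)
  two <- syntheticMembraneCap(g, 2, 40, 0.3, center = c(0, 0, 1)) +
    syntheticMembraneCap(g, 0, 40, 0.3, center = c(0, 0, -1))
  expect_identical(clusterStats(one, grid = g)@nClusters, 1L)
  expect_identical(clusterStats(two, grid = g)@nClusters, 2L)
  flat <- matrix(5, g$ntheta, g$nphi)
  cs <- clusterStats(flat, grid = g)
  expect_identical(cs@nClusters, 0L)
  expect_true(is.na(cs@fwhm))
  # sensitivity to the counting threshold: a faint secondary bump below
  # 25% of the main height is not counted, one above is
  faint <- syntheticMembraneCap(g, 2, 40, 0.3, center = c(0, 0, 1)) +
    syntheticMembraneCap(g, 0, 4, 0.3, center = c(0, 0, -1))
  expect_identical(clusterStats(faint, grid = g)@nClusters, 1L)
  expect_identical(clusterStats(faint, grid = g,
                                count_threshold = 0.05)@nClusters, 2L)
})

test_that("exponential growth-rate fitting is exact and noise-robust", {
  t <- seq(0, 2450, by = 50)
  h <- 3 * exp(0.00417 * t)
  expect_equal(fitExponentialGrowth(t, h), 0.00417, tolerance = 1e-10)
  # 5% multiplicative noise, 100 replicates: recovery within 10% (median)
  set.seed(123)
  errs <- replicate(100, {
    hn <- h * exp(rnorm(length(h), 0, 0.05))
    abs(fitExponentialGrowth(t, hn) / 0.00417 - 1)
  })
  expect_lt(median(errs), 0.10)
  expect_error(fitExponentialGrowth(t[1:3], h[1:3]), "5 points")
  expect_error(fitExponentialGrowth(t, h - 10), "nonpositive")
})

test_that("line-scan Gaussian fit recovers the true width", {
  pr <- syntheticLinescan(true_fwhm = 2 * sqrt(2 * log(2)) * 0.8,
                          background = 10, amplitude = 50, noise_sd = 0,
                          n_points = 120)
  est <- capwidthFromLinescan(pr)
  expect_equal(as.numeric(est), 2 * sqrt(2 * log(2)) * 0.8,
               tolerance = 1e-6)
  # flat profile: no cap
  flat <- syntheticLinescan(2, 10, amplitude = 0.0, noise_sd = 1,
                            n_points = 64, seed = 4)
  expect_true(is.na(capwidthFromLinescan(flat)))
})

test_that("line-scan CSV roundtrip preserves the profile", {
  path <- withr::local_tempfile(fileext = ".csv")
  pr <- syntheticLinescan(2, 10, 50, noise_sd = 5, n_points = 64, seed = 2)
  writeLineScan(pr, path)
  pr2 <- readLineScan(path)
  expect_equal(pr2@arclength, pr@arclength)
  expect_equal(pr2@intensity, pr@intensity)
})

test_that("3x3 Gaussian blur: normalization, impulse response, borders", {
  # constant image unchanged
  const <- matrix(3.7, 8, 8)
  expect_equal(blur3x3(const), const)
  # impulse spreads into the 3x3 kernel pattern with unit sum
  imp <- matrix(0, 7, 7); imp[4, 4] <- 1
  out <- blur3x3(imp)
  expect_equal(sum(out), 1, tolerance = 1e-12)
  expect_equal(out[4, 4], max(out))
  expect_true(all(out[c(1:2, 6:7), ] == 0))
  gk <- exp(-(-1:1)^2 / (2 * 0.85^2)); K <- outer(gk, gk) / sum(outer(gk, gk))
  expect_equal(out[3:5, 3:5], K, tolerance = 1e-12)
  # interior mean preserved under reflective borders for random image
  set.seed(5)
  img <- matrix(runif(100), 10, 10)
  expect_equal(mean(blur3x3(img)[2:9, 2:9] - img[2:9, 2:9]) + 1, 1,
               tolerance = 0.02)
  expect_error(blur3x3(matrix(c(1, NA), 2, 2)), "finite")
})

test_that("cluster density worked example and scaling laws", {
  expect_equal(clusterDensity(0.10, 1000, 0.10, 3.95), 5.1, tolerance = 0.01)
  expect_equal(clusterDensity(1, 1000, 1, 3.95),
               1000 / (4 * pi * 3.95^2), tolerance = 1e-12)
  expect_equal(clusterDensity(0.2, 2000, 0.1, 3.95),
               2 * clusterDensity(0.2, 1000, 0.1, 3.95), tolerance = 1e-12)
  expect_error(clusterDensity(0.1, 1000, 0, 3.95), "positive")
  expect_error(clusterDensity(1.2, 1000, 0.1, 3.95), "fraction")
})
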