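# Thin orchestration layer: run configurations, run directories, and the
# three headline experiments (polarization dynamics, growth spectrum,
# parameter sweeps) bound together with config/log/CSV output. A matching
# command-line wrapper ships in inst/scripts/cdc42polar-cli.R.

#' Assemble a run configuration
#'
#' A fully serializable description of one computational experiment;
#' re-executing a saved configuration reproduces the outputs (stochastic
#' steps are fixed by the seed).
#'
#' @param experiment One of `"dynamics"`, `"spectrum"`, `"sweep"`,
#'   `"capwidth"`, `"fixtures"`.
#' @param params A [ModelParameters-class] object (default control).
#' @param perturbation `"random"` or `"broad_cap"` (dynamics only).
#' @param amplitude Perturbation amplitude (default 0.01).
#' @param seed Integer seed.
#' @param t_end Simulation horizon (s; dynamics only).
#' @param L,nr Grid resolution.
#' @param dt Time step (s).
#' @param sweep_axes Character vector of 1 or 2 parameter names (sweep
#'   only).
#' @param sweep_factors List of factor vectors matching `sweep_axes`.
#' @param extra Named list merged into the config.
#' @return A list of class `runConfig`.
#' @export
runConfig <- function(experiment = c("dynamics", "spectrum", "sweep",
                                     "capwidth", "fixtures"),
                      params = controlParameters(),
                      perturbation = "random", amplitude = 0.01,
                      seed = 1L, t_end = 7200, L = 32L, nr = 24L,
                      dt = 0.5, sweep_axes = c("N24", "alpha3"),
                      sweep_factors = NULL, extra = list()) {
  experiment <- match.arg(experiment)
  cfg <- list(experiment = experiment,
              params = as.list(params@values),
              perturbation = perturbation, amplitude = amplitude,
              seed = as.integer(seed), t_end = t_end, L = as.integer(L),
              nr = as.integer(nr), dt = dt, sweep_axes = sweep_axes,
              sweep_factors = sweep_factors)
  cfg <- utils::modifyList(cfg, extra)
  class(cfg) <- "runConfig"
  cfg
}

#' Write / read run configurations (YAML)
#'
#' @param config A `runConfig` list.
#' @param path File path.
#' @return `readRunConfig` returns the config; `writeRunConfig` the path,
#'   invisibly.
#' @export
writeRunConfig <- function(config, path) {
  x <- unclass(config)
  if (is(x$params, "ModelParameters")) x$params <- as.list(x$params@values)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  bad <- setdiff(names(cfg), c(known, "params", "extra"))
  if (length(bad))
    stop("invalid config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(cfg$params)) {
    pv <- unlist(cfg$params)
    bad <- setdiff(names(pv), .PARAM_NAMES)
    if (length(bad))
      stop("invalid parameter key(s) in config: ",
           paste(bad, collapse = ", "))
    cfg$params <- new("ModelParameters",
                      values = pv[.PARAM_NAMES])
  }
  class(cfg) <- "runConfig"
  cfg
}

#' Execute a configured experiment into a run directory
#'
#' Creates `out_dir` (must not exist yet: runs are append-only), stores the
#' configuration, executes the experiment, and writes CSV outputs plus a
#' log of parameters, resolution and wall time. Experiments:
#' \describe{
#'   \item{dynamics}{perturb the homogeneous state, integrate to `t_end`;
#'     writes `metrics.csv` (time, height, FWHM, cluster count, fractions)
#'     and `final_field.csv` (membrane Cdc42 density, long format).}
#'   \item{spectrum}{dispersion relation; writes `spectrum.csv`
#'     (l, Re sigma, Im sigma) and a one-line capability verdict.}
#'   \item{sweep}{capability phase diagram over `sweep_axes`; writes
#'     `sweep.csv`.}
#'   \item{capwidth}{synthetic line scans + estimator round trip; writes
#'     `capwidth.csv`.}
#'   \item{fixtures}{writes perturbation fields and line-scan CSVs used by
#'     the test suite.}
#' }
#'
#' @param config A `runConfig` (see [runConfig()]).
#' @param out_dir Output directory path.
#' @return `out_dir`, invisibly; side effect: files in the run directory
#'   and a line in the registry file `runs.csv` next to it.
#' @export
runExperiment <- function(config, out_dir) {
  stopifnot(inherits(config, "runConfig"))
  if (dir.exists(out_dir))
    stop("run directory already exists (runs are append-only): ", out_dir)
  dir.create(out_dir, recursive = TRUE)
  t0 <- Sys.time()
  writeRunConfig(config, file.path(out_dir, "config.yaml"))
  params <- if (is(config$params, "ModelParameters")) config$params
            else new("ModelParameters",
                     values = unlist(config$params)[.PARAM_NAMES])
  logline <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = file.path(out_dir, "run.log"),
                               append = TRUE)
  logline("experiment: %s | seed: %d | L = %d, nr = %d, dt = %g",
          config$experiment, config$seed, config$L, config$nr, config$dt)
  switch(config$experiment,
    dynamics = {
      hs <- homogeneousSteadyState(params)
      g <- sphereGrid(R = params@values[["R"]], L = config$L,
                      nr = config$nr)
      init <- if (config$perturbation == "random") {
        randomLatticePerturbation(params, hs,
                                  amplitude = config$amplitude,
                                  seed = config$seed, grid = g)
      } else {
        broadCapPerturbation(params, hs, amplitude = config$amplitude,
                             grid = g)
      }
      tr <- simulate(params, init, t_end = config$t_end,
                     solver_options = list(dt = config$dt))
      .writeCsvWithUnits(tr@metrics, file.path(out_dir, "metrics.csv"),
        "# time [s], height [um^-2], fwhm [um], fractions dimensionless")
      st <- tr@snapshots[[length(tr@snapshots)]]
      f <- membraneField(st, "cdc42")
      long <- data.frame(theta = rep(st@grid$theta, times = st@grid$nphi),
                         phi = rep(st@grid$phi, each = st@grid$ntheta),
                         cdc42_density = as.vector(f))
      .writeCsvWithUnits(long, file.path(out_dir, "final_field.csv"),
        "# theta, phi [rad]; cdc42_density [um^-2]")
      logline("conservation drift: %.3e",
              tr@solverInfo$conservation_drift)
    },
    spectrum = {
      gs <- growthSpectrum(params)
      .writeCsvWithUnits(as.data.frame(gs),
                         file.path(out_dir, "spectrum.csv"),
                         "# l dimensionless; re_sigma, im_sigma [1/s]")
      verdict <- if (any(Re(gs@sigma[gs@l >= 1]) > 0))
        "polarizable" else "not polarizable"
      writeLines(verdict, file.path(out_dir, "verdict.txt"))
      logline("dominant l: %d; verdict: %s", gs@dominantL, verdict)
    },
    sweep = {
      fac <- config$sweep_factors
      if (is.null(fac)) fac <- list(10^seq(-2, 1, length.out = 21),
                                    10^seq(-2, 1, length.out = 21))
      sw <- capabilitySweep(config$sweep_axes[1], config$sweep_axes[2],
                            factors1 = fac[[1]], factors2 = fac[[2]],
                            params = params)
      .writeCsvWithUnits(sw, file.path(out_dir, "sweep.csv"),
        "# factors dimensionless; gtp_fraction of total Cdc42")
    },
    capwidth = {
      widths <- c(1, 2, 3)
      rows <- lapply(seq_along(widths), function(i) {
        pr <- syntheticLinescan(widths[i], background = 10, amplitude = 50,
                                noise_sd = 10, n_points = 200,
                                seed = config$seed + i,
                                R = params@values[["R"]])
        est <- capwidthFromLinescan(pr)
        data.frame(true_fwhm = widths[i], estimated_fwhm = as.numeric(est))
      })
      .writeCsvWithUnits(do.call(rbind, rows),
                         file.path(out_dir, "capwidth.csv"),
                         "# true_fwhm, estimated_fwhm [um]")
    },
    fixtures = {
      hs <- homogeneousSteadyState(params)
      g <- sphereGrid(R = params@values[["R"]], L = 16, nr = 12)
      st <- randomLatticePerturbation(params, hs, seed = config$seed,
                                      grid = g)
      f <- membraneField(st, "cdc42")
      .writeCsvWithUnits(
        data.frame(theta = rep(g$theta, times = g$nphi),
                   phi = rep(g$phi, each = g$ntheta),
                   cdc42_density = as.vector(f)),
        file.path(out_dir, "perturbed_field.csv"),
        "# theta, phi [rad]; cdc42_density [um^-2]")
      pr <- syntheticLinescan(2, 10, 50, noise_sd = 10, n_points = 200,
                              seed = config$seed,
                              R = params@values[["R"]])
      writeLineScan(pr, file.path(out_dir, "linescan.csv"))
    })
  wall <- as.numeric(Sys.time() - t0, units = "secs")
  logline("wall time: %.1f s", wall)
  registry <- file.path(dirname(out_dir), "runs.csv")
  reg_row <- sprintf("%s,%s,%d,%.1f", basename(out_dir),
                     config$experiment, config$seed, wall)
  if (!file.exists(registry))
    cat("run,experiment,seed,wall_s\n", file = registry)
  cat(reg_row, "\n", sep = "", file = registry, append = TRUE)
  invisible(out_dir)
}

.writeCsvWithUnits <- function(df, path, header_comment) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_comment, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
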