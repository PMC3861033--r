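Package: cdc42polar
Title: Bulk-Surface Reaction-Diffusion Modelling of GDI-Mediated Cdc42
    Polarization in Budding Yeast
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Mechanistic modelling of actin-independent, GDI-mediated Cdc42
    polarization in Saccharomyces cerevisiae. The cell is represented as a
    spherical cytosolic volume coupled to its plasma membrane: Cdc42 (GTP- and
    GDP-bound), the scaffold Bem1 and the GEF Cdc24 react on the membrane,
    diffuse laterally, and exchange with a diffusing cytosolic pool through
    boundary fluxes. The package computes homogeneous steady states, performs
    linear stability analysis on the sphere (a mode-resolved dispersion
    relation built from modified spherical Bessel radial profiles), integrates
    the full nonlinear bulk-surface dynamics with a pseudospectral
    spherical-harmonic scheme, quantifies polarity clusters (height, FWHM,
    cluster counts, microscopy-style Gaussian cap-width fits on line scans),
    and runs parameter sweeps that map polarization capability, Cdc42-GTP
    levels and final cluster widths across parameter space. Synthetic-data
    generators emulate the initial perturbations and membrane line-scan
    intensity profiles needed to exercise the full pipeline without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    pracma,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
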