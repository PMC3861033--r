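---
title: "A bulk-surface model of GDI-mediated Cdc42 polarization: methods and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A bulk-surface model of GDI-mediated Cdc42 polarization: methods and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdc42polar)
```

## The biological problem and the model

Budding yeast breaks symmetry by concentrating active Cdc42 into a single
membrane cap. The actin-independent route runs entirely on protein
cycling: membrane-bound Cdc42-GDP is extracted into the cytosol by its
GDI (Rdi1), and a positive feedback — Cdc42-GTP recruits the scaffold
Bem1, Bem1 recruits the GEF Cdc24, and membrane Cdc24 both activates
Cdc42-GDP in place and deposits fresh Cdc42 in GTP form — re-concentrates
it wherever activity is already high.

The cell is a ball of radius $R$ with cytosolic species (Cdc42-GDP
$c_D$, Bem1 $c_B$, Cdc24 $c_G$; molecules/µm³) diffusing with constant
$D_3$, coupled to membrane species (Cdc42-GTP $m_T$, Cdc42-GDP $m_D$,
free Bem1 $m_B$, Bem1–Cdc24 complex $m_{BG}$; molecules/µm²) diffusing
laterally with $D_2$ on the sphere $r=R$. The membrane reactions are

$$\begin{aligned}
\partial_t m_D &= D_2\,\Delta_s m_D + \beta_2 c_D|_R + \alpha_3 m_T
  - (\alpha_2 + \alpha_1 m_{BG})\,m_D - \beta_3 m_D,\\
\partial_t m_T &= D_2\,\Delta_s m_T + \beta_1 m_{BG}\, c_D|_R
  + (\alpha_2 + \alpha_1 m_{BG})\,m_D - \alpha_3 m_T,\\
\partial_t m_B &= D_2\,\Delta_s m_B + \gamma_1 m_T\, c_B|_R - \gamma_2 m_B
  - \delta_1 m_B\, c_G|_R + \delta_2 m_{BG},\\
\partial_t m_{BG} &= D_2\,\Delta_s m_{BG} + \delta_1 m_B\, c_G|_R
  - \delta_2 m_{BG},
\end{aligned}$$

and the cytosol is purely diffusive, $\partial_t c_X = D_3 \Delta c_X$,
fed only through the boundary condition $D_3\,\partial_r c_X|_R = -F_X$
with uptake fluxes $F_D = (\beta_2+\beta_1 m_{BG})c_D|_R - \beta_3 m_D$,
$F_B = \gamma_1 m_T c_B|_R - \gamma_2 m_B$ and
$F_G = \delta_1 m_B c_G|_R - \delta_2 m_{BG}$. Three totals are conserved
exactly: Cdc42 ($m_T+m_D$ plus cytosolic $c_D$), Bem1 ($m_B+m_{BG}$ plus
$c_B$) and Cdc24 ($m_{BG}$ plus $c_G$).

Modelling commitments worth making explicit:

* the GDI extracts only the GDP-loaded form ($\beta_3$ acts on $m_D$
  alone);
* GEF-mediated attachment ($\beta_1$) deposits Cdc42 directly in GTP
  form, describing displacement from the GDI with concurrent exchange;
* $\delta_2$ releases only Cdc24 from the membrane complex
  ($m_{BG}\to m_B + c_G$); Bem1 leaves the membrane only via $\gamma_2$
  acting on free $m_B$ — one reverse reaction per forward step. The
  alternative (whole-complex detachment) is not modelled;
* Bem1 recruitment by Cdc42-GTP leaves $m_T$ itself unchanged (the
  scaffold binds without sequestering measurable activity).

## Parameters

`controlParameters()` carries the calibrated control-cell constants
(internal units µm, s, molecules): $D_2 = 0.03$, $D_3 = 11$ µm²/s,
$R = 3.95$ µm, $N_{42} = 3000$, $N_B = 6500$, $N_{24} = 1000$,
$\alpha_1 = 0.2$ µm²/s, $\alpha_2 = 0.002$ s⁻¹ (0.12 min⁻¹),
$\alpha_3 = 1$ s⁻¹, $\beta_1 = 0.266$ µm³/s, $\beta_2 = 0.28$ µm/s,
$\beta_3 = 1$ s⁻¹, $\gamma_1 = 0.2667$ µm³/s, $\gamma_2 = 0.35$ s⁻¹,
$\delta_1 = 0.00297$ µm³/s, $\delta_2 = 0.35$ s⁻¹. Two consistency
checks situate these numbers: at the expected cluster Cdc24 density of
$\sim 5$ µm⁻² (10% of 1000 copies on 10% of the membrane,
`clusterDensity(0.10, 1000, 0.10, 3.95)` = 5.1) the catalyzed
nucleotide-exchange rate is $\alpha_1 \times 5 = 1$ s⁻¹, on par with
hydrolysis and extraction.

## Homogeneous states and linear stability

`homogeneousSteadyState()` finds the uniform unpolarized state by
relaxing the well-mixed two-compartment ODE system from the
all-cytosolic initial condition and polishing with Newton iteration
(residuals below $10^{-10}$). Relaxation from all-cytosolic defines the
*stable unpolarized branch* operationally if several uniform roots
coexist.

Perturbations about this state separate into spherical harmonics
$Y_{lm}$. Each cytosolic perturbation solves the radial diffusion
eigenproblem in the ball; the profile regular at the origin is the
modified spherical Bessel function $i_l(\sqrt{\sigma/D_3}\, r)$ for
growth rates $\sigma > 0$, continued to the oscillatory
$j_l(\sqrt{-\sigma/D_3}\, r)$ for $\sigma < 0$ and to $r^l$ at
$\sigma = 0$ (the branch choice is unit-tested against the
pure-diffusion closed form $\sigma_l = -D_2\, l(l+1)/R^2$). Four
membrane amplitudes and three cytosolic boundary amplitudes then satisfy
seven linear equations; `dispersionGrowthRate()` finds the root of the
$7\times 7$ determinant with the largest real part by a dense sign-change
scan on the real axis (leading roots are real near onset) with a complex
Newton fallback, and deflates the conservation-induced zero at $l = 0$.
Growth rates are independent of the azimuthal order $m$ (isotropy), so
one rate per degree suffices.

At control parameters only $l = 1$ grows:
$\sigma_1 = 3.67\times 10^{-3}$ s⁻¹. A caveat that matters when
comparing with simplified treatments: neglecting the cytosolic depletion
gradients in the linearization (the fast-cytosol limit
$D_3 \to \infty$) overestimates this rate by about 13%
($4.15\times 10^{-3}$ s⁻¹) — with $D_3 = 11$ µm²/s the bulk is *not*
fast enough to be well-mixed on the pattern's length scale, and the
dispersion relation here keeps the full radial profile so that it is the
exact linearization of the simulated dynamics. The package's
dispersion-versus-simulation agreement tests (5% tolerance) rely on that
consistency.

`isPolarizable()` (some $\mathrm{Re}\,\sigma_l > 0$, $1 \le l \le
l_{max}$, default 10 with automatic extension until the spectrum is
decisively decaying) and `diffusionRescue()` (capability anywhere on a
log-sampled $(D_2, D_3)$ grid spanning $10^{\pm 2}$ of control) are the
predicates behind the phase diagrams.

## Nonlinear dynamics: discretization and time stepping

Membrane fields live on a Gauss–Legendre × equispaced-azimuth grid with
spherical-harmonic truncation $L$; quadratic nonlinearities are
de-aliased by 3/2-rule padding of the quadrature grid. The cytosol is
expanded in the same harmonics with a conservative finite-volume radial
grid ($n_r$ uniform shells): face fluxes telescope, so total protein
content changes only through the boundary flux, which is applied to
membrane and cytosol as the *same* quantity — conservation then holds to
machine precision by construction (observed drift $\sim 10^{-11}$
relative over full polarization runs).

Time stepping needs care because the observable of interest — the slow
growth rate $\sigma_1 \sim 4\times 10^{-3}$ s⁻¹ — is a small residual of
exchange fluxes of order 1 s⁻¹. Any scheme that splits the
membrane–cytosol exchange from cytosolic diffusion (e.g. classic IMEX
with explicit reactions) pollutes that residual with $O(\Delta t\,
k/\Delta r)$ errors, measured at 30–45% of $\sigma_1$ at $\Delta t =
0.5$ s and *growing* under radial refinement. The scheme used here is a
Strang composition of

1. membrane lateral diffusion, applied exactly in spectral space
   (multiplication by $e^{-D_2 l(l+1)\Delta t/ (2R^2)}$), and
2. one linearized backward-Euler step of everything else *coupled*: full
   per-degree cytosolic diffusion, boundary exchange, and membrane
   reactions, with bilinear terms linearized about the step start
   (Rosenbrock–Euler). The cytosol's response to the (implicit) boundary
   flux enters through the per-degree kernel $g_l = \Delta t\,
   s\,[(I-\Delta t A_l)^{-1}]_{n_r n_r}$; its angular variation is
   captured by a per-point implicit diagonal part $\bar g$ plus a
   fixed-point iteration on the small nonlocal remainder (3–5 iterations
   to $10^{-9}$ in practice, warm-started from the previous step).

In the linear regime this composition is the exact backward-Euler map of
the full coupled system: the measured small-amplitude growth rate is
within +0.7% of the analytic $\sigma_1$ at $\Delta t = 0.5$ s, $n_r =
24$ (and the remaining bias is the documented spatial truncation, +0.3%
at $n_r = 24$). Positivity is enforced by clamping (with bookkeeping in
the solver diagnostics); no clamps trigger in standard runs.

Defaults: $L = 32$ (grid $50 \times 96$), $n_r = 24$, $\Delta t = 0.5$ s.
A resolution study at the control point (halving $\Delta t$; raising to
$L = 48$, $n_r = 48$) moves the final cluster FWHM by under 1% and the
membrane fractions by under 0.2 percentage points. The test suite runs
the same physics at $L = 8$–16 so the full suite completes in minutes;
those reduced sizes are a deliberate economy, not a limit of the method.

## Initial conditions and synthetic data

`randomLatticePerturbation()` reproduces the stated perturbation
protocol: i.i.d. uniform$[-1,1]$ values on a cubic lattice of spacing
1 µm covering the cell, interpolated trilinearly (hence bounded by 1 and
correlated on the ~1 µm scale) and applied multiplicatively,
$m \to m(1 + 0.01 f)$, to the membrane species only. Trilinear
interpolation is a package choice — any bounded interpolant with the
same correlation length serves; tests pin the bound, the membrane-only
action, and seed determinism. Note the multiplicative form leaves the
realized totals ~0.01% off the nominal copy numbers; drift *along*
trajectories is still $<10^{-6}$ per 100 s, and conservation checks use
a $10^{-3}$ default tolerance against nominal totals for this reason.
`broadCapPerturbation()` adds a function linear in one spatial
coordinate, sign-changing at the center plane (exactly mass-neutral);
its amplitude default 0.01 mirrors the random case as no separate value
is prescribed.

`syntheticMembraneCap()` and `syntheticLinescan()` provide closed-form
fixtures: a Gaussian cap in polar angle (FWHM $= 2\sqrt{2\ln 2}\,R\,
\sigma_\theta$) and noisy Gaussian line-scan profiles. Line-scan noise is
additive Gaussian — a deliberate simplification of camera noise; the
estimator tests sweep the noise level rather than model the camera.

## Cluster quantification

`clusterStats()` takes the total membrane Cdc42 density, estimates the
background as the area-weighted spatial median (configurable to the
lower-half mean), reports height = maximum − background, and measures
FWHM as arc length along the great circle through the density maximum,
with linear interpolation at the half-height crossings. Cluster counting
first smooths by truncating the spectral representation at $L = 16$,
then finds grid local maxima exceeding background + 25% of the global
height and merges candidates closer than 0.6 rad geodesic; the threshold
is a package convention (no canonical algorithm exists for it) and its
sensitivity is part of the test suite. For multi-cluster fields the FWHM
refers to the tallest cluster.

`capwidthFromLinescan()` mirrors the microscopy workflow: a Gaussian
$base + A e^{-(s-s_0)^2/2\sigma^2}$ fitted by Levenberg–Marquardt, cap
width $= 2\sqrt{2\ln 2}\,\sigma$, with non-convergence or $A \le 0$
reported as "no cap". `blur3x3()` provides the 3×3 Gaussian
pre-averaging applied to raw images ($\sigma = 0.85$ px, the common
discretization for an unspecified 3×3 kernel; renormalized, reflective
borders). On simulated control steady states the line-scan estimate and
the direct great-circle FWHM agree within a few percent — the two
estimators share the cap but differ in background handling, so exact
equality is not expected.

## Sweeps

`capabilitySweep()` evaluates capability, unpolarized membrane
Cdc42-GTP fraction and (optionally) diffusion rescue on multiplicative
2-D grids (default 21 log-spaced factors spanning $10^{-2}$–$10^{1}$);
`cdc42gtpVsParameter()` traces the switch-like collapse of Cdc42-GTP at
the capability boundary; `fwhmSweep()` runs the nonlinear dynamics to
steady state per value, reusing the previous cell's polarized state as
initial condition (continuation) with optional cold-start cross-checks
as a hysteresis guard. Simulation-backed sweeps default to $L = 16$ for
cost; the control-point cell of a sweep reproduces the single-run result
since both call the same code path with the same options.

## What the simulations show at control parameters

Two-phase polarization: a 1% perturbation first grows as a single broad
degree-1 cap at the exponential rate $\sigma_1$; once the cap reaches
finite amplitude the positive feedback accelerates growth and the cap
narrows monotonically to its final width. Most of the absolute height
increase happens inside the narrowing window. The converged state keeps
roughly a third of Cdc42, half of Bem1 and a tenth of Cdc24 on the
membrane in a single cap of ~3 µm FWHM, maintained by influx at the cap
center balanced by efflux at the periphery. These statements are exactly
what the acceptance tests assert, at the tolerances given there.

## Known limitations

* No actin/vesicle delivery pathway, no septin diffusion barrier, no
  stochastic (particle-level) dynamics, no cell growth or deforming
  geometry — the model targets the GDI-mediated pathway in a fixed
  spherical cell.
* The linear analysis addresses only the homogeneous state; stability of
  the *polarized* state is probed numerically, not analytically.
* The synthetic line scans emulate intensity profiles with additive
  Gaussian noise and a known background; real micrographs add camera
  gain, z-projection and manual contour placement, none of which are
  modelled. Passing estimator tests therefore demonstrates correctness
  of the blur + fit + FWHM procedure, not robustness to every imaging
  artifact.
* Backward-Euler time stepping damps fast transients first-order
  accurately; quantities reported (growth rates, steady states, widths)
  are insensitive to this, but sub-second relaxation details are not to
  be trusted at $\Delta t = 0.5$ s.
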