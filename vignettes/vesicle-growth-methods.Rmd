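---
title: "Methods: nonequilibrium Monte Carlo of growing vesicles"
author: "vesiclegrowth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nonequilibrium Monte Carlo of growing vesicles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

A vesicle is represented as a closed, dynamically triangulated surface of
sphere topology: `N` vertices (surface particles) with positions `r`, and a
triangulation that defines the adjacency. The configurational energy is

    Etot = Ebend + Etether + Earea

* **Ebend** is the discrete Helfrich energy `(kappa/2) * integral (2H)^2 dA`,
  evaluated with the cotangent Laplace–Beltrami operator and mixed Voronoi
  vertex areas (circumcentric for non-obtuse triangles, area/2 or area/4
  for obtuse ones). This discretisation converges to the continuum value
  (`8*pi*kappa` for a sphere) under refinement, which matters because the
  downstream analysis fits continuum shell theory to the fluctuation
  spectra. A dihedral-angle discretisation was considered and rejected for
  that reason: its rigidity mapping is lattice-dependent. The mixed area
  was preferred over the simpler barycentric area after a controlled
  comparison on thermally rough meshes: the effective spectral rigidity of
  a pure-bending membrane at ~600 vertices is measurably closer to the
  input with the mixed area. Even so, a discrete thermal mesh at this
  resolution carries an effective spectral rigidity 10–20% below the
  input; the deficit shrinks with mesh refinement and is the main
  finite-size systematic of the rigidity-recovery experiment.
* **Etether** is a hard square well on every edge length, zero inside
  `(tether_min, tether_max)` and infinite outside. It enforces mesh
  regularity and is the only steric constraint; defaults `(0.55, 1.60)`
  keep the mean edge length at the unit of length `l0`.
* **Earea** is a per-face spring `(k_a/2) * sum_f (A_f - a0)^2` with target
  `a0 = sqrt(3)/4` (the unit equilateral triangle), so the vertex density
  `rho0 = N/A` stays approximately constant and area growth tracks particle
  uptake, `A(t) ~ N(t)/rho0`. The default `k_a = 20 kBT/l0^4` was chosen
  once, as a compromise: stiff enough that the total-area fluctuations are
  sub-percent for a few hundred vertices, soft enough that vertex
  insertions (which transiently halve local face areas) remain feasible at
  accessible chemical potentials.

The vesicle exchanges surface particles, volume and heat with reservoirs at
chemical potential `mu`, osmotic pressure difference `dp` and temperature
`kBT = 1`. Metropolis acceptance is governed by the grand-potential-like
function

    Phi = Etot - mu*N - dp*V.

Spontaneous curvature is zero throughout (no such term appears in the
energy), and no Gaussian-curvature term is needed because the topology is
fixed.

# Move set and exact reversibility

One sweep attempts, on average, `N` vertex translations, `E*pflip` edge
flips, and `E*pexchange` insertions and removals *each*. Rather than
pre-drawing per-kind counts, each attempt slot picks its kind with
probability proportional to the *current* rates
(`N : E*pflip : E*pexchange : E*pexchange`); the slot count per sweep is
fixed at the sweep start. This matters because `N` and `E` change
mid-sweep: with state-dependent kind weights the generation rate of every
proposal, and of its exact reverse, is known in closed form, and the
Metropolis rule

    P_acc = min(1, [Pgen(rev)/Pgen(fwd)] * exp(-dPhi/kBT))

satisfies detailed balance exactly at `mu = mu_eq`.

Insertion splits a uniformly chosen edge; the new vertex is drawn uniformly
from a cube of half-width `insert_halfwidth` (default `0.35 l0`) centred on
the edge midpoint. Removal collapses a degree-4 vertex (the exact inverse
class) onto one of the two re-triangulating diagonals, chosen at random,
and is valid only if the vertex lies inside the insertion cube of that
diagonal. The pair is exactly reversible: the placement-cube volume cancels
in the round trip, and the generation-rate ratio is

    insertion: [W * v_c * E'] / [2 * W' * n'_rem],

with `W = N + E*(pflip + 2*pexchange)` the slot weight, primes the
post-move mesh, and `n_rem` the number of degree-4 vertices. Exact midpoint
placement would be irreversible in the continuous configuration space
(after any translation the vertex no longer sits on a midpoint, so the
reverse generation probability would vanish) and is additionally infeasible
under the tether (half edges of a unit edge are shorter than
`tether_min`); the cube placement solves both problems.

Invalid proposals (existing opposite edge, degree screens, tether
violations, cube-support violations, size caps) count as attempted null
moves, so the sweep schedule's attempt counts are preserved. The minimum
size is the icosahedron (`N = 12`).

**Audit.** The engine's bookkeeping is verified by an exact two-level
experiment (`tests/testthat/`, helper `audit_two_level`): with translations
frozen, flips off, and `N` capped to {12, 13}, the stationary occupancy of
the upper level must equal a configurational integral over the insertion
cube, which is computed by direct quadrature, independently of the engine.
The occupancy matches within statistical error after ~10^5 accepted
exchanges; the same test detects a missing attempt-rate factor (an error of
order `E'/E ~ 10%` on this mesh) at many standard deviations.

# The equilibrium chemical potential is a marginal point

At `mu_eq` the grand-potential cost of a vertex is nearly intensive:
`Phi ~ (f0 - mu) N + O(curvature)`. Consequently `N` performs an almost
free random walk at `mu_eq`, and the mean flux responds only weakly to
`mu`. Short flux probes therefore cannot resolve `mu_eq` (their standard
error exceeds the systematic flux for any affordable probe length), and a
bisection on probe fluxes is biased by slow shape relaxation.

`calibrate_mu_eq()` instead logs, for every exchange attempt, the
mu-independent part of its acceptance factor. The instantaneous net
exchange rate at *any* chemical potential is then

    j(mu)  proportional to  <min(1, a_ins e^{+mu/kBT})> - <min(1, a_rem e^{-mu/kBT})>,

evaluated analytically over tens of thousands of logged attempts, and the
root is found per round. Runs continue at the updated estimate, and the
procedure iterates to self-consistency while the configuration relaxes.
On a 642-vertex vesicle this pins `mu_eq` to about +-0.01 kBT in a few
minutes; the residual uncertainty at desk scale is dominated by the slow
volume relaxation (volume changes only through shape diffusion), which
leaves a small residual drift in `N` over ~10^4 sweeps.

# Shape spectroscopy

`decompose_configuration()` maps vertices to spherical coordinates about
the vertex centroid and estimates real spherical-harmonic amplitudes
`u_lm` of `r/R - 1` by weighted least squares with solid-angle weights
(barycentric vertex area / r^2); the monopole gives `R`, degree 1 is
fitted and discarded (centroid motion), and `lmax` defaults to
`floor(sqrt(N)/2)` so the system stays strongly overdetermined.
Least-squares inversion is used instead of quadrature because mesh
vertices are irregular. Configurations that are not star-shaped about the
centroid (any surface element facing radially inward) are flagged and
excluded from ensemble averages — the quasispherical parameterisation does
not hold for them.

The ensemble spectrum `<|u_l|^2>`, with `|u_l|^2 = (2l+1)^{-1} sum_m
u_lm^2`, is fit to the pressurized elastic-shell form

    <|u_l|^2> = kBT / (2 A_l),
    A_l = (s/2) [ gamma R^2 + Y R^2 / t + kappa s ],   s = (l-1)(l+2),  t = l(l+1).

The coefficient structure (tension ~ `gamma R^2`, stretching ~ `Y R^2`,
bending ~ `kappa` times a quartic polynomial) admits a one-parameter
family of conventions for the stretching weight; the one used here is
fixed by two requirements: (i) `A_l = 0` first occurs, for large shells,
at the classical buckling tension `gamma_c0 = -(2/R) sqrt(kappa Y)`, so
the fitted parameters are consistent with the thresholds in the buckling
module, and (ii) at large `l` the spectrum reduces to the Helfrich
`kBT/(kappa s^2)` bending decay. For a fluid membrane the difference
between the shell bending polynomial `s^2` and the fluid-membrane `s*t`
is `2s`, which is absorbed exactly by the fitted tension, so the recovered
`kappa` is convention-independent.

Fitting is weighted nonlinear least squares in log space (the spectrum
spans several decades), with `Y` and `kappa` parameterised on the log
scale so accepted fits are positive by construction. Three practical
points matter at simulation scale:

* **Propagated sampling noise**: the least-squares decomposition of a
  discrete, thermally rough mesh carries an approximately `l`-independent
  noise plateau which, untreated, biases `kappa` low by 20–40% at a few
  hundred vertices. `decompose_configuration()` propagates the weighted
  least-squares coefficient covariance, `var(c) = s² (BᵀWB)⁻¹`, into a
  per-degree noise estimate, and `fit_shell_spectrum()` subtracts it by
  default (degrees whose noise exceeds half the measured power are
  dropped as unresolved). The analytic estimate agrees with the plateau
  obtained by fitting a free floor term (`fit_floor = TRUE`, kept as a
  fallback for spectra without a noise column). Synthetic forward-model
  spectra are generated without the plateau, since it is a property of
  measuring a discrete mesh.
* **Resolution cap**: degrees with fewer than about five vertices per
  wavelength (`l > 2 pi R / 5`) sit at the mesh scale, where the residual
  excess over the shell family grows beyond the propagated-noise
  estimate; the equilibrium-rigidity workflow caps its fit window there.
* **Goodness-of-fit flag**: far from equilibrium the quasispherical shell
  description degrades; fits with reduced chi-squared above a threshold
  (default 10) are flagged `poor_fit` rather than silently reported.

The lowest degrees deserve a caveat: at `dp = 0` the enclosed volume is
unconstrained and diffuses slowly, so the `l = 2` mode mixes with a slack
(volume-exchange) mode whose integrated autocorrelation time reaches
~10^4 sweeps on a 642-vertex vesicle and whose power exceeds the shell
family's prediction. Its ensemble mean over a desk-scale sampling window
is therefore unreliable, and the equilibrium-rigidity workflow excludes
degrees 2–3 from its fit window (the driven-series fits, which target the
tension, keep them and accept the larger scatter). The wrinkling analysis
reads the peak position `l*` from the measured spectrum directly rather
than from the fit.

# Buckling thresholds

`zero_T_thresholds()` implements `P_c0 = 4 sqrt(kappa Y)/R^2` and
`gamma_c0 = -(2/R) sqrt(kappa Y)`; `elastothermal_number()` implements
`ET = (kBT/kappa) sqrt(Y R^2 / kappa)`. The finite-temperature reduction
`gamma_c = gamma_c0 * Psi(ET)` consumes `Psi` as a pluggable strategy:
`psi_zero_t()` (`Psi == 1`), a user-supplied monotone table
(`psi_table()`), or the default closed-form approximation
`Psi(x) = (1+x)^{-1/2}`, a smooth stand-in with the required limits
(`Psi(0) = 1`, monotone decreasing) for the renormalization-group curve,
which is not re-derived here. Every prediction carries its `Psi` value, so
results can be re-evaluated under a different model; the qualitative
statements (threshold magnitude reduced by fluctuations; boundary shifts
to larger drive with pressure) do not depend on the detailed form.

# Stochastic thermodynamics

Fluxes are `J(tau) = x(tau) - x(0)` per trajectory for `x = (N, V)`;
`flux_statistics()` returns means, the unbiased covariance `Xi`, the
diffusivity `D = Xi/(2 tau)` and currents `j = J/tau`. The entropy
production is estimated directly as `(dmu <dN> + dp <dV>)/kBT - tau *
eps_diss` — the relative-entropy rate `eps_diss` is a pluggable argument
defaulting to zero, and every estimate records whether it was included —
and bounded from below by the thermodynamic uncertainty relation
`2 <J>^T Xi^{-1} <J>` (in kB), for one observed flux and for the flux
pair; adding an observable can only raise the bound (exact algebraic
property, asserted in the tests). Forces are inferred as
`f = kBT D^{-1} j` with bootstrap confidence intervals (1000 resamples,
seeded), the near-equilibrium window defaults to `dmu <= 5 kBT`, and the
heuristic force laws are fit by weighted linear regression plus a hinge
(piecewise-linear) model for the volume force, whose per-pressure
thresholds `mu*(dp)` are located by profile coordinate descent (each
threshold scanned against the globally refitted `(c_p, zeta)`, which
avoids the local optima of naive alternating fits). The Heaviside
convention is `Theta(x) = 1` for `x >= 0`, 0 otherwise. The growth law
`(Ndot, Vdot) = D f / kBT` and its inverse (forces required for target
rates) are direct matrix algebra on these estimates.

# Synthetic generators

`generate_synthetic_trajectories()` produces correlated Gaussian random
walks with specified drift and diffusion — the exact oracle for every
moment-based estimator. It reproduces the first two moments of real flux
ensembles but none of the non-Gaussian, time-correlated structure of
driven growth, so passing those tests validates the estimators, not the
physics. `generate_synthetic_spectrum()` evaluates the shell spectrum
exactly with multiplicative lognormal noise — the oracle for the fitting
machinery, deliberately without the discrete-mesh noise floor.

# Study conditions at desk scale

The package's own experiments run at reduced scale, chosen once:

* Engine defaults mirror the reference conditions: `kappa = 20 kBT`,
  `pflip = 1`, `pexchange = 1`, `kBT = 1`, translation step auto-tuned to
  ~40% acceptance during equilibration only.
* The equilibrium-rigidity experiment (`measure_equilibrium_rigidity()`)
  uses a subdivision-3 icosphere (`N = 642`, `R ~ 7 l0`): the largest
  size whose slow shape modes demonstrably equilibrate within minutes
  (8 calibration rounds x 1200 sweeps, 8000 equilibration sweeps, 10000
  sampling sweeps, one configuration per 100 sweeps). A subdivision-2
  mesh (`N = 162`) resolves only degrees `l <= 6`, too few for a
  three-parameter spectral fit.
* The equilibrium-rigidity experiment samples 16 independent branches of
  ~1000 sweeps from the equilibrated state (112 configurations); driven
  elastic-fit series run at the same size with 7 branches per drive value
  and horizons of 1000 sweeps, and flux-based series use subdivision-2
  vesicles with 12–16 samples and 350–400-sweep horizons — one to two
  orders of magnitude below the reference ensembles (500 samples x 5000
  sweeps at `R = 15`). Slopes and thresholds measured at this scale carry
  correspondingly wider errors and a residual size dependence; the tests
  state their tolerances explicitly, and two of the far-from-equilibrium
  checks (the volume-force constants and the buckling-threshold crossing)
  do not reach the reference values at this scale.

# Known limitations

* Monte Carlo sweeps are not physical time; no mapping to real dynamics is
  attempted.
* Self-avoidance is enforced only through the tether well; strongly
  driven, deeply wrinkled states can in principle self-intersect, and
  non-star-shaped configurations are excluded from spectral analysis
  rather than parameterised covariantly.
* The insertion/removal construction is one exactly reversible realisation
  of particle exchange; observables tied to the exchange kinetics (for
  example the absolute exchange acceptance rate, or `mu_eq` itself) depend
  on it, while equilibrium distributions and linear-response relations do
  not.
* `Psi(ET)` is an approximate stand-in (see above); quantitative threshold
  positions inherit its uncertainty.
* At `dp = 0` the volume is diffusive and the vesicle is thermodynamically
  marginal at `mu_eq`; desk-scale equilibrium averages retain a small,
  quantified drift (see the calibration section).
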