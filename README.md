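# vesiclegrowth

Nonequilibrium Monte Carlo simulation and analysis of growing vesicles.

Biological membranes grow: cells, organelles and protocells take up surface
material and volume from their surroundings, and the interplay between that
driven uptake and membrane elasticity decides whether a vesicle grows
smoothly and quasispherically or destabilises into wrinkles. This package
implements, for computational biophysicists, the full simulation-and-
inference chain for that problem:

* a **grand-canonical Metropolis Monte Carlo engine** (compiled core) for
  dynamically triangulated vesicles of sphere topology that exchange
  surface particles (vertices), enclosed volume and heat with reservoirs
  at chemical potential μ, osmotic pressure difference Δp and temperature
  kBT. The energy is `Etot = Ebend + Etether + Earea` (discrete Helfrich
  bending with the cotangent Laplacian, a hard tether on edge lengths, a
  local area constraint), and moves — vertex translation, edge flip,
  reversible vertex insertion/removal — are accepted with
  `min(1, [Pgen(rev)/Pgen(fwd)] exp(-ΔΦ/kBT))` where
  `Φ = Etot - μN - ΔpV`, so detailed balance holds exactly at the
  equilibrium chemical potential μ_eq;
* **shape-fluctuation spectroscopy**: spherical-harmonic decomposition of
  quasispherical configurations and weighted fits of the pressurized
  elastic-shell spectrum `⟨|u_l|²⟩ = kBT / (2A_l)` with
  `A_l = (s/2)[γR² + YR²/t + κs]`, `s = (l-1)(l+2)`, `t = l(l+1)`,
  yielding the renormalized effective tension γ, 2D Young's modulus Y and
  bending rigidity κ of a driven membrane;
* **buckling theory**: the zero-temperature thresholds
  `γ_c0 = -(2/R)√(κY)`, `P_c0 = 4√(κY)/R²`, the elastothermal number
  `ET = (kBT/κ)√(YR²/κ)`, the fluctuation-reduced threshold
  `γ_c = γ_c0 Ψ(ET)` with a pluggable scaling function, and the
  morphological phase boundary Δμ*(Δp);
* a **stochastic-thermodynamics layer**: flux statistics and diffusivity
  matrices over trajectory ensembles, entropy-production estimates with
  thermodynamic-uncertainty-relation lower bounds
  `ΔS ≥ 2k_B ⟨J⟩ᵀ Ξ⁻¹ ⟨J⟩`, force inference `f = kBT D⁻¹ j`, heuristic
  force laws (including a hinge law for the volume force), and the
  low-dimensional growth law `(Ṅ, V̇) = D f / kBT` with its inverse
  design mode.

Synthetic-data generators (Gaussian flux ensembles, exact forward-model
spectra) make every analysis layer testable without simulation.

## Worked example

Simulate a small vesicle near equilibrium, drive it, and read off the
inferred thermodynamic force:

```r
library(vesiclegrowth)

mesh <- build_icosphere(2, unit_edge = TRUE)   # N = 162, R ~ 3.4 l0
p <- sim_params()                               # kappa = 20 kBT, pflip = pexchange = 1
cal <- calibrate_mu_eq(mesh, p, rounds = 6, nsweeps_round = 800, seed = 1)
cal$mu_eq
#> [1] 2.048403

ens <- run_growth_ensemble(cal$mesh, p, mu_eq = cal$mu_eq, delta_mu = 2,
                           nsamples = 16, nequil = 600, nsim = 400,
                           checkpoint_every = 100, seed = 2)
fl <- flux_statistics(ens)
fl
#> flux ensemble: 16 samples, tau = 400
#>   <J> =      N      V
#>  56.125 28.395
#>   D =
#>        N      V
#> N 0.0820 0.0432
#> V 0.0432 0.0480

infer_forces(fl, seed = 3)
#> inferred forces (kBT units):
#>   f_N = 1.774 (boot se 1.062, CI 1.082..5.279)
#>   f_V = -0.119 (boot se 1.075, CI -2.800..1.476)

entropy_bounds(fl, delta_mu = 2)
#> entropy production (kB): direct 112.250 (eps_diss not included); TUR bounds: df=1 96.061, df=2 96.204
```

The inferred particle force `f_N` is consistent with the imposed excess
chemical potential Δμ = 2 kBT while the volume force vanishes at Δp = 0;
the two-flux entropy bound improves on the single-flux bound and both lie
below the direct estimate, near saturation in this near-equilibrium
regime.

Fitting a synthetic shell spectrum with known ground truth:

```r
spec <- generate_synthetic_spectrum(gamma = -1, Y = 30, kappa = 20, R = 15,
                                    noise = 0.01, lmax = 25, seed = 1)
fit_shell_spectrum(spec)
#> elastic fit: gamma = -1.0143 (0.0247), Y = 30.240 (0.324), kappa = 19.982 (0.057), R = 15.000
#>   reduced chi^2 = 0.99; l* = none (monotone spectrum)
```

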