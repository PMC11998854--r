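# High-level experiment workflows combining the engine and the analysis
# layers. These are the procedures behind the package's headline numbers;
# the acceptance script and the test suite call them directly.

#' Prepare an equilibrated vesicle at its equilibrium chemical potential
#'
#' Builds a unit-edge icosphere, tunes the translation step, calibrates
#' mu_eq self-consistently ([calibrate_mu_eq()]) and runs a long
#' equilibration so the slow low-degree shape modes settle.
#'
#' @param seed master seed.
#' @param subdivisions icosphere level.
#' @param kappa input bending rigidity (kBT).
#' @param dp osmotic pressure difference.
#' @param nequil equilibration sweeps after calibration.
#' @param cal_rounds,cal_sweeps calibration rounds and sweeps per round.
#' @return list of class `equilibrium_state`: `mesh`, `params` (with
#'   `mu` set to mu_eq), `mu_eq`, `mu_eq_se`.
#' @export
prepare_equilibrium_state <- function(seed = 1L, subdivisions = 3L,
                                      kappa = 20, dp = 0, nequil = 8000L,
                                      cal_rounds = 8L, cal_sweeps = 1200L) {
  m <- build_icosphere(subdivisions, unit_edge = TRUE)
  p <- sim_params(energy = energy_params(kappa = kappa), dp = dp, seed = seed)
  p$mu <- 2
  pre <- run_sweeps(m, p, nsweeps = 200L, checkpoint_every = 200L,
                    seed = derive_seed(seed, 1), tune_step = TRUE)
  p$step_size <- pre$step_size
  cal <- calibrate_mu_eq(pre$mesh, p, mu_start = 2, rounds = cal_rounds,
                         nsweeps_round = cal_sweeps,
                         seed = derive_seed(seed, 2))
  p$mu <- cal$mu_eq
  eq <- run_sweeps(cal$mesh, p, nsweeps = nequil,
                   checkpoint_every = max(nequil, 1L),
                   seed = derive_seed(seed, 3))
  structure(list(mesh = eq$mesh, params = p, mu_eq = cal$mu_eq,
                 mu_eq_se = cal$se, seed = seed),
            class = "equilibrium_state")
}

#' Measure the effective bending rigidity of an equilibrium vesicle
#'
#' Samples decorrelated configurations along an equilibrium trajectory,
#' averages their spherical-harmonic spectra, and fits the elastic-shell
#' form (with the sampling-noise floor) to recover the effective bending
#' rigidity, which should agree with the input kappa of the simulation.
#'
#' @param seed master seed (used only if `state` is NULL).
#' @param state an `equilibrium_state` from [prepare_equilibrium_state()];
#'   prepared internally when NULL.
#' @param nsamples independent trajectory branches sampled from the
#'   equilibrated state. Independent branches sample the slow low-degree
#'   shape modes far better than a single long trajectory of the same
#'   cost.
#' @param nequil_branch per-branch decorrelation sweeps before sampling.
#' @param tau sampling sweeps per branch; configurations are collected
#'   every `snapshot_every` sweeps from `0.4 * tau` onwards.
#' @param snapshot_every sweeps between sampled configurations.
#' @param ... passed to [prepare_equilibrium_state()].
#' @return list with `fit` (an `elastic_fit`), `spectrum`, `mu_eq`,
#'   `records` (per-branch trajectories), `n_configs` and `ensemble` (the
#'   underlying `trajectory_ensemble`).
#' @export
measure_equilibrium_rigidity <- function(seed = 1L, state = NULL,
                                         nsamples = 16L,
                                         nequil_branch = 150L, tau = 1000L,
                                         snapshot_every = 100L, ...) {
  if (is.null(state)) state <- prepare_equilibrium_state(seed = seed, ...)
  ens <- run_growth_ensemble(state$mesh, state$params, state$mu_eq,
                             delta_mu = 0, nsamples = nsamples,
                             nequil = nequil_branch, nsim = tau,
                             checkpoint_every = snapshot_every,
                             seed = derive_seed(state$seed, 4),
                             keep_snapshots = TRUE)
  configs <- unlist(lapply(ens$snapshots, function(sn)
    sn$meshes[sn$t >= 0.4 * tau]), recursive = FALSE)
  spec <- ensemble_spectrum(configs)
  # propagated sampling noise is subtracted automatically inside the fit
  fit <- fit_shell_spectrum(spec)
  list(fit = fit, spectrum = spec, mu_eq = state$mu_eq,
       mu_eq_se = state$mu_eq_se, records = ens$records,
       n_configs = spec$n_used, ensemble = ens)
}
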