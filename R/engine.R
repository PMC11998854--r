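# Grand-canonical Metropolis Monte Carlo engine: sweep scheduling, move
# acceptance with generation-probability correction, equilibrium chemical
# potential calibration, and driven growth ensembles.

#' Simulation parameters
#'
#' One Monte Carlo sweep attempts (on average) N vertex translations,
#' E*pflip edge flips, and E*pexchange insertions and removals each, where
#' N and E are the current vertex and edge counts; the kind of each
#' individual attempt is drawn with probabilities proportional to the
#' current rates so that the generation-rate ratios entering the Metropolis
#' rule are exact while N and E fluctuate.
#'
#' @param energy an [energy_params()] list.
#' @param mu reservoir chemical potential (kBT).
#' @param dp osmotic pressure difference (kBT/l0^3).
#' @param kT thermal energy scale; the simulation works in units kBT = 1.
#' @param step_size half-width of the cubic vertex-translation proposal
#'   (l0). Can be auto-tuned during equilibration (`tune_step`) toward ~40%
#'   acceptance and is frozen during production runs.
#' @param pflip,pexchange attempt-rate factors for edge flips and for
#'   vertex insertion/removal moves (each), relative to one attempt per
#'   edge per sweep.
#' @param insert_halfwidth half-width of the cubic placement region for
#'   inserted vertices, centred on the split-edge midpoint (l0).
#' @param min_vertices removals are auto-rejected at or below this size
#'   (default 12, the icosahedron).
#' @param max_vertices insertions are auto-rejected at or above this size;
#'   0 disables the cap. Used by the detailed-balance audit.
#' @param nequil,nsim default sweep counts for equilibration and production.
#' @param checkpoint_every sweeps between trajectory records.
#' @param nsamples default ensemble size.
#' @param seed master seed; per-sample seeds are derived with
#'   [derive_seed()].
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(energy = energy_params(), mu = 0, dp = 0, kT = 1,
                       step_size = 0.12, pflip = 1, pexchange = 1,
                       insert_halfwidth = 0.35, min_vertices = 12L,
                       max_vertices = 0L, nequil = 500L, nsim = 5000L,
                       checkpoint_every = 10L, nsamples = 500L, seed = 1L) {
  stopifnot(pflip >= 0, pexchange >= 0, step_size > 0, insert_halfwidth > 0,
            nequil >= 0, nsim >= 0, kT > 0)
  structure(list(energy = energy, mu = mu, dp = dp, kT = kT,
                 step_size = step_size, pflip = pflip, pexchange = pexchange,
                 insert_halfwidth = insert_halfwidth,
                 min_vertices = as.integer(min_vertices),
                 max_vertices = as.integer(max_vertices),
                 nequil = as.integer(nequil), nsim = as.integer(nsim),
                 checkpoint_every = as.integer(checkpoint_every),
                 nsamples = as.integer(nsamples), seed = seed),
            class = "sim_params")
}

# flat parameter list for the compiled engine
flatten_params <- function(params) {
  e <- params$energy
  list(kappa = e$kappa, k_a = e$k_a, a0 = e$a0, tether_min = e$tether_min,
       tether_max = e$tether_max, mu = params$mu, dp = params$dp,
       kT = params$kT, pflip = params$pflip, pexchange = params$pexchange,
       step_size = params$step_size,
       insert_halfwidth = params$insert_halfwidth,
       min_vertices = params$min_vertices,
       max_vertices = params$max_vertices)
}

#' Derive a per-sample seed from a master seed
#'
#' Deterministic splitting scheme: `(master + 104729 * index) mod (2^31-1)`,
#' so ensembles are reproducible given the master seed.
#'
#' @param master integer master seed.
#' @param index sample index (1-based).
#' @return integer seed below 2^31.
#' @export
derive_seed <- function(master, index) {
  (as.numeric(master) + 104729 * as.numeric(index)) %% 2147483647
}

#' Metropolis acceptance with generation-probability correction
#'
#' Accepts with probability min(1, gen_ratio * exp(-delta_phi/kT)), where
#' `gen_ratio` is the ratio of reverse to forward generation probabilities
#' of the proposed move. Uses R's RNG.
#'
#' @param delta_phi change in Phi caused by the move (kBT).
#' @param gen_ratio Pgen(reverse)/Pgen(forward); 1 for symmetric proposals.
#' @param kT thermal energy (default 1).
#' @return logical: accept the move?
#' @export
metropolis_accept <- function(delta_phi, gen_ratio = 1, kT = 1) {
  stopifnot(gen_ratio > 0)
  a <- gen_ratio * exp(-delta_phi / kT)
  a >= 1 || runif(1L) < a
}

records_to_dt <- function(mat) {
  dt <- data.table::as.data.table(mat)
  dt
}

#' Run Monte Carlo sweeps on a vesicle
#'
#' Evolves the mesh for `nsweeps` sweeps under the given parameters,
#' recording a trajectory checkpoint every `checkpoint_every` sweeps
#' (particle number N, volume V, area A, mean radius R, energy breakdown,
#' Phi, and per-kind attempt/acceptance counts since the previous record).
#'
#' @param mesh a `trimesh` starting configuration.
#' @param params a [sim_params()] list.
#' @param nsweeps number of sweeps (defaults to `params$nsim`).
#' @param checkpoint_every record interval in sweeps.
#' @param seed engine seed (integer).
#' @param snapshot_every if > 0, keep a mesh snapshot every that many
#'   sweeps.
#' @param tune_step auto-tune the translation step toward ~40% acceptance
#'   (use only for equilibration; the tuned value is returned).
#' @param paranoia run a full structural validation after every topology
#'   move (slow; for tests).
#' @return list with `mesh` (final), `records` (data.table), `snapshots`
#'   (list of `trimesh`), `snapshot_t`, and `step_size` (possibly tuned).
#' @export
run_sweeps <- function(mesh, params, nsweeps = params$nsim,
                       checkpoint_every = params$checkpoint_every,
                       seed = params$seed, snapshot_every = 0L,
                       tune_step = FALSE, paranoia = FALSE,
                       log_exchange_stride = 0L) {
  out <- cpp_run_sweeps(mesh$vertices, mesh$faces, flatten_params(params),
                        as.integer(nsweeps), as.integer(checkpoint_every),
                        as.numeric(seed), as.integer(snapshot_every),
                        isTRUE(tune_step), isTRUE(paranoia),
                        as.integer(log_exchange_stride))
  snaps <- lapply(out$snapshots, function(s)
    trimesh(s$vertices, s$faces, validate = FALSE))
  list(mesh = trimesh(out$vertices, out$faces, validate = FALSE),
       records = records_to_dt(out$records), snapshots = snaps,
       snapshot_t = out$snapshot_t, step_size = out$step_size,
       log_ins = out$log_ins, log_rem = out$log_rem)
}

#' Calibrate the equilibrium chemical potential mu_eq
#'
#' Finds the chemical potential at which the mean particle flux vanishes.
#' Because the vesicle is thermodynamically marginal at mu_eq (the
#' grand-potential cost of a vertex is nearly intensive, so N performs an
#' almost free random walk there), naive flux probes resolve mu_eq very
#' poorly. Instead, every exchange attempt during a run is logged with its
#' mu-independent acceptance factor, so the instantaneous net exchange
#' rate j(mu) can be evaluated analytically for any mu by reweighting:
#'   j(mu) proportional to <min(1, a_ins e^{mu/kT})> - <min(1, a_rem e^{-mu/kT})>.
#' The root of j is found per round, the run is continued at the updated
#' mu, and the procedure iterates to self-consistency while the
#' configuration relaxes.
#'
#' @param mesh an initial `trimesh` (a short pre-equilibration helps).
#' @param params a [sim_params()] list; `params$dp` is the pressure at
#'   which to calibrate.
#' @param mu_start starting chemical potential for the first round.
#' @param rounds number of self-consistency rounds.
#' @param nsweeps_round sweeps simulated per round.
#' @param log_stride log every k-th exchange attempt (memory control).
#' @param mu_window root-search window for the reweighted flux.
#' @param seed RNG seed.
#' @return list with `mu_eq`, `se` (scatter of the last rounds), `mesh`
#'   (the relaxed configuration, useful as an equilibrated start), and
#'   `history` (per-round estimates).
#' @export
calibrate_mu_eq <- function(mesh, params, mu_start = 2, rounds = 5L,
                            nsweeps_round = 1000L, log_stride = 4L,
                            mu_window = c(-10, 20), seed = params$seed) {
  mu_hat <- mu_start
  cur <- mesh
  hist <- numeric(0)
  for (r in seq_len(rounds)) {
    p <- params
    p$mu <- mu_hat
    run <- run_sweeps(cur, p, nsweeps = nsweeps_round,
                      checkpoint_every = nsweeps_round,
                      seed = derive_seed(seed, r),
                      log_exchange_stride = log_stride)
    cur <- run$mesh
    ins <- run$log_ins
    rem <- run$log_rem
    if (length(ins) < 100L || length(rem) < 100L)
      stop("too few exchange attempts logged; increase nsweeps_round or pexchange")
    jfun <- function(mu) {
      mean(pmin(1, ins * exp(mu / params$kT))) -
        mean(pmin(1, rem * exp(-mu / params$kT)))
    }
    if (jfun(mu_window[1]) > 0 || jfun(mu_window[2]) < 0)
      stop("mu_eq not bracketed by mu_window")
    mu_hat <- uniroot(jfun, mu_window, tol = 1e-6)$root
    hist <- c(hist, mu_hat)
  }
  tail_est <- tail(hist, max(2L, ceiling(rounds / 2)))
  list(mu_eq = mu_hat, se = max(sd(tail_est), 1e-3), mesh = cur,
       history = hist)
}

#' Run an ensemble of driven growth trajectories
#'
#' For each of `nsamples` independent seeds: equilibrate `nequil` sweeps at
#' mu_eq, switch the reservoir to mu = mu_eq + delta_mu, run `nsim` sweeps
#' recording checkpoints, and keep the final configuration. Failed samples
#' are logged and excluded rather than aborting the ensemble.
#'
#' @param mesh0 initial `trimesh` (typically pre-equilibrated).
#' @param params a [sim_params()] list; `params$dp` applies throughout.
#' @param mu_eq equilibrium chemical potential (from [calibrate_mu_eq()]).
#' @param delta_mu excess chemical potential mu - mu_eq (kBT).
#' @param nsamples number of independent trajectories.
#' @param nequil,nsim,checkpoint_every sweep schedule (default from params).
#' @param seed master seed.
#' @param keep_snapshots also keep `floor(nsim/checkpoint_every)` interim
#'   meshes per sample (memory!). The final mesh is always kept.
#' @return a `trajectory_ensemble`: list with `records` (data.table keyed
#'   by sample, t), `final_meshes`, `mu_eq`, `delta_mu`, `dp`, `tau`
#'   (= nsim), `params`, `failed` (count).
#' @export
run_growth_ensemble <- function(mesh0, params, mu_eq, delta_mu,
                                nsamples = params$nsamples,
                                nequil = params$nequil, nsim = params$nsim,
                                checkpoint_every = params$checkpoint_every,
                                seed = params$seed, keep_snapshots = FALSE) {
  p_eq <- params; p_eq$mu <- mu_eq
  p_run <- params; p_run$mu <- mu_eq + delta_mu
  recs <- vector("list", nsamples)
  meshes <- vector("list", nsamples)
  snaps <- vector("list", nsamples)
  failed <- 0L
  for (i in seq_len(nsamples)) {
    res <- tryCatch({
      eq <- run_sweeps(mesh0, p_eq, nsweeps = nequil,
                       checkpoint_every = max(nequil, 1L),
                       seed = derive_seed(seed, 2L * i))
      run <- run_sweeps(eq$mesh, p_run, nsweeps = nsim,
                        checkpoint_every = checkpoint_every,
                        seed = derive_seed(seed, 2L * i + 1L),
                        snapshot_every = if (keep_snapshots) checkpoint_every else 0L)
      r <- run$records
      r[, sample := i]
      list(records = r, mesh = run$mesh,
           snaps = if (keep_snapshots)
             list(t = run$snapshot_t, meshes = run$snapshots) else NULL)
    }, error = function(e) {
      warning(sprintf("sample %d failed: %s", i, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) { failed <- failed + 1L; next }
    recs[[i]] <- res$records
    meshes[[i]] <- res$mesh
    snaps[[i]] <- res$snaps
  }
  keep <- !vapply(recs, is.null, logical(1))
  structure(list(records = data.table::rbindlist(recs[keep]),
                 final_meshes = meshes[keep],
                 snapshots = if (keep_snapshots) snaps[keep] else NULL,
                 mu_eq = mu_eq,
                 delta_mu = delta_mu, dp = params$dp, tau = nsim,
                 params = params, seed = seed, failed = failed),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  ns <- length(x$final_meshes)
  cat(sprintf(
    "trajectory ensemble: %d samples, tau = %d sweeps, dmu = %.3g, dp = %.3g\n",
    ns, x$tau, x$delta_mu, x$dp))
  fin <- x$records[t == max(t)]
  cat(sprintf("  <dN(tau)> = %.2f (se %.2f), <dV(tau)> = %.2f\n",
              mean(fin$N) - x$records[t == 0, mean(N)],
              sd(fin$N) / sqrt(ns),
              mean(fin$V) - x$records[t == 0, mean(V)]))
  invisible(x)
}
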