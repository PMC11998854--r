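# Synthetic-fixture generators with known ground truth: correlated Gaussian
# random-walk trajectory ensembles (for the flux/entropy/force machinery)
# and exact forward-model shell spectra (for the elastic fitting machinery).

#' Generate a synthetic trajectory ensemble (correlated Gaussian walk)
#'
#' Simulates `nsamples` independent random walks in (N, V) with per-sweep
#' drift vector `drift` and diffusion matrix `diffusion` (increment
#' covariance per sweep is 2 * diffusion, so the measured diffusivity
#' D = Var(J)/(2 tau) reproduces the input). Serves as the exact oracle
#' for [flux_statistics()], [entropy_bounds()] and [infer_forces()].
#'
#' @param drift length-2 drift per sweep, c(N, V).
#' @param diffusion 2x2 positive-definite diffusion matrix.
#' @param nsamples number of trajectories.
#' @param tau trajectory length (sweeps).
#' @param checkpoint_every record interval (sweeps); must divide tau.
#' @param seed RNG seed (deterministic output).
#' @return a `trajectory_ensemble`-compatible list with `records`
#'   (sample, t, N, V), `tau`, `delta_mu = NA`, `dp = NA`.
#' @export
generate_synthetic_trajectories <- function(drift, diffusion, nsamples, tau,
                                            checkpoint_every = tau,
                                            seed = 1L) {
  stopifnot(length(drift) == 2L, all(dim(diffusion) == c(2L, 2L)))
  ev <- eigen(diffusion, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("diffusion matrix must be positive definite")
  if (tau %% checkpoint_every != 0) stop("checkpoint_every must divide tau")
  set.seed(seed)
  L <- chol(2 * diffusion)  # increment covariance per sweep
  nchk <- tau %/% checkpoint_every
  recs <- vector("list", nsamples)
  for (i in seq_len(nsamples)) {
    z <- matrix(rnorm(2L * tau), tau, 2L) %*% L
    z <- sweep(z, 2L, drift, "+")
    path <- apply(z, 2L, cumsum)
    tt <- seq_len(nchk) * checkpoint_every
    recs[[i]] <- data.table::data.table(
      sample = i, t = c(0, tt),
      N = c(0, path[tt, 1L]), V = c(0, path[tt, 2L]))
  }
  structure(list(records = data.table::rbindlist(recs), tau = tau,
                 delta_mu = NA_real_, dp = NA_real_,
                 final_meshes = list(), params = NULL, seed = seed,
                 failed = 0L),
            class = "trajectory_ensemble")
}

#' Generate a synthetic shell fluctuation spectrum
#'
#' Evaluates the pressurized-shell spectrum kBT/(2 A_l) exactly for the
#' given parameters and applies multiplicative lognormal noise, giving a
#' `spectrum_estimate` with known ground truth for round-trip tests of
#' [fit_shell_spectrum()].
#'
#' @param gamma,Y,kappa,R shell parameters (Y, kappa, R > 0).
#' @param noise lognormal sigma of the multiplicative noise (0 = exact);
#'   the reported standard errors are noise * power.
#' @param lmax maximum degree (default 20).
#' @param nsamples nominal ensemble size recorded on the estimate.
#' @param kT thermal energy.
#' @param seed RNG seed.
#' @return a `spectrum_estimate`.
#' @export
generate_synthetic_spectrum <- function(gamma, Y, kappa, R, noise = 0,
                                        lmax = 20L, nsamples = 100L, kT = 1,
                                        seed = 1L) {
  stopifnot(Y > 0, kappa > 0, R > 0, noise >= 0)
  l <- 2:lmax
  mdl <- shell_spectrum(l, gamma, Y, kappa, R, kT)
  if (any(!is.finite(mdl) | mdl <= 0))
    stop("parameters are beyond the stability edge: A_l <= 0 for some degree")
  set.seed(seed)
  pw <- mdl * exp(noise * rnorm(length(l)) - noise^2 / 2)
  se <- if (noise > 0) noise * pw else pmax(pw * 1e-6, 1e-300)
  structure(list(spectrum = data.table::data.table(l = l, power = pw, se = se),
                 R = R, n_used = nsamples, n_excluded = 0L),
            class = "spectrum_estimate")
}

#' Stability edge of the shell spectrum
#'
#' The most negative tension for which every mode stiffness A_l stays
#' positive; below it the softest mode diverges. Obtained by minimising
#' over integer degrees.
#'
#' @param Y,kappa,R shell parameters.
#' @param lmax degrees scanned.
#' @return list with `gamma_edge` and the softest degree `l_soft`.
#' @export
spectrum_stability_edge <- function(Y, kappa, R, lmax = 200L) {
  l <- 2:lmax
  t <- l * (l + 1)
  s <- (l - 1) * (l + 2)
  # A_l = 0 at gamma = -(kappa * s + Y R^2 / t)/R^2; the edge is the max
  gcrit <- -(kappa * s + Y * R^2 / t) / R^2
  i <- which.max(gcrit)
  list(gamma_edge = gcrit[i], l_soft = l[i])
}
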