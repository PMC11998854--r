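# Stochastic-thermodynamics layer: flux statistics over trajectory
# ensembles, diffusivities, entropy-production estimates and
# thermodynamic-uncertainty-relation (TUR) lower bounds, inference of the
# conjugate driving forces, heuristic force laws, and the low-dimensional
# growth law linking mean rates to forces through the diffusivity matrix.

#' Flux statistics of a trajectory ensemble
#'
#' Computes, for each sample, the net flux vector J(tau) = x(tau) - x(0)
#' of the chosen observables at the checkpoint nearest (by default exactly
#' equal to) the horizon tau, then ensemble means, the flux covariance Xi
#' (unbiased), the diffusivity matrix D = Xi/(2 tau) and the mean currents
#' j = <J>/tau.
#'
#' @param ensemble a `trajectory_ensemble` (from [run_growth_ensemble()] or
#'   [generate_synthetic_trajectories()]).
#' @param observables columns of the trajectory records to treat as fluxes
#'   (default N and V).
#' @param tau flux horizon in sweeps (default the ensemble tau).
#' @param exact if TRUE (default) tau must be a recorded checkpoint;
#'   otherwise the nearest checkpoint is used.
#' @return a list of class `flux_ensemble`: `J` (matrix samples x
#'   observables), `mean_J`, `j`, `Xi`, `D`, `tau`, `nsamples`,
#'   `se_J` (delta-method standard errors of the means), plus the drive
#'   (`delta_mu`, `dp`) copied from the ensemble when present.
#' @export
flux_statistics <- function(ensemble, observables = c("N", "V"),
                            tau = ensemble$tau, exact = TRUE) {
  rec <- data.table::as.data.table(ensemble$records)
  if (!"sample" %in% names(rec)) rec$sample <- 1L
  ts <- sort(unique(rec$t))
  if (exact && !(tau %in% ts))
    stop(sprintf("tau = %s is not a recorded checkpoint", format(tau)))
  tuse <- ts[which.min(abs(ts - tau))]
  t0 <- min(ts)
  a0 <- rec[rec$t == t0, c("sample", observables), with = FALSE]
  a1 <- rec[rec$t == tuse, c("sample", observables), with = FALSE]
  mm <- merge(a0, a1, by = "sample", suffixes = c("_0", "_1"))
  if (nrow(mm) < 3L) stop("need at least 3 samples reaching the horizon")
  J <- as.matrix(mm[, paste0(observables, "_1"), with = FALSE]) -
       as.matrix(mm[, paste0(observables, "_0"), with = FALSE])
  colnames(J) <- observables
  Xi <- stats::cov(J)
  structure(list(J = J, mean_J = colMeans(J), j = colMeans(J) / tuse,
                 Xi = Xi, D = Xi / (2 * tuse), tau = tuse,
                 nsamples = nrow(J),
                 se_J = sqrt(diag(Xi) / nrow(J)),
                 delta_mu = ensemble$delta_mu, dp = ensemble$dp),
            class = "flux_ensemble")
}

#' @export
print.flux_ensemble <- function(x, ...) {
  cat(sprintf("flux ensemble: %d samples, tau = %g\n", x$nsamples, x$tau))
  cat("  <J> ="); print(round(x$mean_J, 3))
  cat("  D =\n"); print(round(x$D, 4))
  invisible(x)
}

#' Linear-response check of the particle current
#'
#' Near equilibrium the mean particle current obeys
#' j_N = (D_N / kBT) dmu, so the ratio j_N/D_N regressed on dmu/kBT has
#' slope 1. Far from equilibrium (dmu beyond the window) the relation
#' breaks down; points outside the window are reported but excluded from
#' the regression.
#'
#' @param flux_list list of `flux_ensemble`s across a dmu series.
#' @param delta_mu excess chemical potentials (kBT); defaults to the values
#'   stored in the flux ensembles.
#' @param observable flux used (default "N").
#' @param window near-equilibrium window (default 5 kBT).
#' @param kT thermal energy.
#' @param D_eq optional equilibrium diffusivity; when given, the variant
#'   normalising all currents by D_eq is also reported.
#' @return list of class `linear_response`: `table`, `slope`, `se`,
#'   `ci` (95%), `slope_eq` (D_eq variant, if applicable).
#' @export
linear_response_check <- function(flux_list, delta_mu = NULL,
                                  observable = "N", window = 5, kT = 1,
                                  D_eq = NULL) {
  if (is.null(delta_mu))
    delta_mu <- vapply(flux_list, function(f) f$delta_mu, numeric(1))
  tab <- data.table::data.table(
    dmu = delta_mu,
    j = vapply(flux_list, function(f) f$j[[observable]], numeric(1)),
    D = vapply(flux_list, function(f) f$D[observable, observable], numeric(1)),
    se_j = vapply(flux_list, function(f) f$se_J[[observable]] / f$tau, numeric(1)))
  tab$ratio <- tab$j / tab$D
  tab$in_window <- tab$dmu <= window & tab$dmu > 0
  use <- tab[tab$in_window, ]
  if (nrow(use) < 2L) stop("need at least 2 driven points inside the window")
  # regression through the origin of j/D on dmu/kT
  x <- use$dmu / kT
  y <- use$ratio
  w <- (use$D / use$se_j)^2  # se of ratio ~ se_j / D
  fit <- lm(y ~ 0 + x, weights = w)
  cf <- summary(fit)$coefficients
  slope <- cf[1, 1]; se <- cf[1, 2]
  out <- list(table = tab, slope = slope, se = se,
              ci = slope + c(-1.96, 1.96) * se)
  if (!is.null(D_eq)) {
    y2 <- use$j / D_eq
    fit2 <- lm(y2 ~ 0 + x, weights = w)
    out$slope_eq <- coef(fit2)[[1]]
  }
  structure(out, class = "linear_response")
}

#' @export
print.linear_response <- function(x, ...) {
  cat(sprintf("linear response: slope = %.3f +- %.3f (95%% CI %.3f..%.3f)\n",
              x$slope, x$se, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Entropy production estimate and TUR lower bounds
#'
#' Direct estimate (in units of kB)
#'   dS = (dmu <dN> + dp <dV>) / kBT - tau * eps_diss,
#' where eps_diss is the relative-entropy correction rate for growing
#' systems (pluggable; default 0, and the output records whether it was
#' included), together with thermodynamic-uncertainty-relation lower
#' bounds dS >= 2 kB <J>^T Xi^-1 <J> for one observed flux (dN only) and
#' for the flux vector (dN, dV). Adding observables can only increase the
#' bound.
#'
#' @param fluxes a `flux_ensemble` with observables N and V.
#' @param delta_mu,dp the thermodynamic drives (kBT, kBT/l0^3).
#' @param kT thermal energy.
#' @param eps_diss relative-entropy rate (per sweep, kB units); either a
#'   number or a function(fluxes) returning one. Default 0.
#' @param regularize if Xi is numerically singular, use a pseudo-inverse
#'   (with a warning) instead of failing.
#' @return list of class `entropy_estimate`: `dS_direct`,
#'   `dS_direct_raw` (without eps_diss), `eps_diss_included`, `bound_df1`,
#'   `bound_df2`, `df`.
#' @export
entropy_bounds <- function(fluxes, delta_mu, dp = 0, kT = 1, eps_diss = 0,
                           regularize = FALSE) {
  J <- fluxes$mean_J
  Xi <- fluxes$Xi
  eps <- if (is.function(eps_diss)) eps_diss(fluxes) else eps_diss
  raw <- (delta_mu * J[["N"]] + if ("V" %in% names(J)) dp * J[["V"]] else 0) / kT
  dS <- raw - fluxes$tau * eps
  b1 <- 2 * J[["N"]]^2 / Xi["N", "N"]
  b2 <- tryCatch({
    2 * drop(t(J) %*% solve(Xi, J))
  }, error = function(e) {
    if (!regularize) stop("flux covariance is singular; set regularize = TRUE to use a pseudo-inverse")
    warning("flux covariance singular; using pseudo-inverse")
    sv <- svd(Xi)
    pos <- sv$d > max(sv$d) * 1e-10
    Xinv <- sv$v[, pos, drop = FALSE] %*% diag(1 / sv$d[pos], sum(pos)) %*%
      t(sv$u[, pos, drop = FALSE])
    2 * drop(t(J) %*% Xinv %*% J)
  })
  structure(list(dS_direct = dS, dS_direct_raw = raw,
                 eps_diss_included = !identical(eps, 0), eps_diss = eps,
                 bound_df1 = b1, bound_df2 = b2, df = length(J)),
            class = "entropy_estimate")
}

#' @export
print.entropy_estimate <- function(x, ...) {
  cat(sprintf(
    "entropy production (kB): direct %.3f%s; TUR bounds: df=1 %.3f, df=%d %.3f\n",
    x$dS_direct,
    if (x$eps_diss_included) "" else " (eps_diss not included)",
    x$bound_df1, x$df, x$bound_df2))
  invisible(x)
}

#' Infer thermodynamic driving forces from flux statistics
#'
#' f = kBT D^-1 j: the force vector conjugate to the observed fluxes,
#' estimated from the mean currents and the measured diffusivity matrix.
#' Near equilibrium at dp = 0 the component f_N equals the excess chemical
#' potential. Confidence intervals by bootstrap over samples.
#'
#' @param fluxes a `flux_ensemble`.
#' @param kT thermal energy.
#' @param nboot bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return list of class `force_model`: `f`, `se`, `ci_lower`, `ci_upper`
#'   (2.5/97.5% bootstrap percentiles), `D`, `j`.
#' @export
infer_forces <- function(fluxes, kT = 1, nboot = 1000L, seed = 1L) {
  D <- fluxes$D
  cn <- rcond(D)
  if (!is.finite(cn) || cn < 1e-12)
    stop("diffusivity matrix is singular; reduce the observable set")
  f <- kT * solve(D, fluxes$j)
  J <- fluxes$J
  n <- nrow(J)
  set.seed(seed)
  fb <- matrix(NA_real_, nboot, ncol(J))
  for (b in seq_len(nboot)) {
    idx <- sample.int(n, n, replace = TRUE)
    Jb <- J[idx, , drop = FALSE]
    Db <- stats::cov(Jb) / (2 * fluxes$tau)
    ok <- is.finite(rcond(Db)) && rcond(Db) > 1e-12
    if (ok) fb[b, ] <- kT * solve(Db, colMeans(Jb) / fluxes$tau)
  }
  fb <- fb[stats::complete.cases(fb), , drop = FALSE]
  structure(list(f = setNames(f, colnames(J)),
                 se = apply(fb, 2L, sd),
                 ci_lower = apply(fb, 2L, quantile, 0.025),
                 ci_upper = apply(fb, 2L, quantile, 0.975),
                 D = D, j = fluxes$j, nboot = nrow(fb)),
            class = "force_model")
}

#' @export
print.force_model <- function(x, ...) {
  cat("inferred forces (kBT units):\n")
  for (i in seq_along(x$f))
    cat(sprintf("  f_%s = %.3f (boot se %.3f, CI %.3f..%.3f)\n",
                names(x$f)[i], x$f[i], x$se[i], x$ci_lower[i], x$ci_upper[i]))
  invisible(x)
}

#' Fit the heuristic force laws over a (mu, dp) grid
#'
#' Fits
#'   f_N = kBT c_gamma^-1 (gamma - gamma_eq|dp) + phi(dp)
#'   f_V = c_p dp + zeta (mu - mu*(dp)) Theta(mu - mu*(dp))
#' where c_gamma is the near-equilibrium slope of the fitted tension
#' against dmu, phi(dp) a per-pressure offset, Theta the Heaviside step
#' (Theta(x) = 1 for x >= 0, else 0), and mu*(dp) the threshold chemical
#' potential above which the volume force grows. The hinge fit alternates
#' between (c_p, zeta) by weighted linear least squares and a per-dp grid
#' scan for mu*.
#'
#' @param grid data.table/data.frame with one row per state point and
#'   columns `mu`, `dmu`, `dp`, `fN`, `fV` (and optionally `fN_se`,
#'   `fV_se`, `gamma`, `gamma_se`).
#' @param kT thermal energy.
#' @param linear_window near-equilibrium window for the c_gamma regression
#'   (default 5 kBT).
#' @return list of class `force_laws`: `c_gamma` (slope, se; NA without a
#'   gamma column), `phi` (per-dp offsets), `c_p`, `zeta` (with se),
#'   `mu_star` (per-dp, with open-threshold flag), `hinge_fit`.
#' @export
fit_force_laws <- function(grid, kT = 1, linear_window = 5) {
  g <- data.table::as.data.table(grid)
  if (!all(c("mu", "dmu", "dp", "fN", "fV") %in% names(g)))
    stop("grid needs columns mu, dmu, dp, fN, fV")
  if (is.null(g$fV_se)) g$fV_se <- pmax(abs(g$fV), 1) * 0.1
  if (is.null(g$fN_se)) g$fN_se <- pmax(abs(g$fN), 1) * 0.1
  # --- c_gamma from the tension series (near-equilibrium, per dp) ---
  c_gamma <- c(NA_real_, NA_real_)
  if (!is.null(g$gamma)) {
    gg <- g[g$dmu <= linear_window, ]
    if (is.null(gg$gamma_se)) gg$gamma_se <- pmax(abs(gg$gamma), 0.05) * 0.1
    sl <- gg[, {
      if (.N >= 2) {
        ft <- lm(gamma ~ dmu, weights = 1 / gamma_se^2)
        cf <- summary(ft)$coefficients
        list(slope = cf[2, 1], se = cf[2, 2])
      } else list(slope = NA_real_, se = NA_real_)
    }, by = "dp"]
    sl <- sl[is.finite(sl$slope), ]
    if (nrow(sl) > 0) {
      w <- 1 / sl$se^2
      c_gamma <- c(sum(sl$slope * w) / sum(w), sqrt(1 / sum(w)))
    }
  }
  # --- phi(dp): offset of fN against the tension-based estimate ---
  phi <- NULL
  if (!is.null(g$gamma) && is.finite(c_gamma[1])) {
    gam_eq <- g[, {
      o <- order(dmu)
      list(gamma_eq = gamma[o][1])
    }, by = "dp"]
    gm <- merge(g, gam_eq, by = "dp")
    gm$est <- kT / c_gamma[1] * (gm$gamma - gm$gamma_eq)
    phi <- gm[gm$dmu <= linear_window,
              list(phi = weighted.mean(fN - est, 1 / fN_se^2)), by = "dp"]
  }
  # --- hinge fit of fV over the (mu, dp) grid ---
  dps <- sort(unique(g$dp))
  mu_star <- setNames(rep(stats::median(g$mu), length(dps)), dps)
  hinge_lm <- function(ms) {
    dfh <- data.frame(fV = g$fV, dpv = g$dp,
                      h = pmax(g$mu - ms[as.character(g$dp)], 0),
                      w = 1 / g$fV_se^2)
    lm(fV ~ 0 + dpv + h, data = dfh, weights = w)
  }
  rss_of <- function(fit) sum(weights(fit) * residuals(fit)^2)
  # profile coordinate descent: each threshold is scanned against the
  # globally refitted (c_p, zeta), which avoids the local optima of naive
  # alternating fits
  for (sweep_i in 1:10) {
    changed <- FALSE
    for (d in dps) {
      sub_mu <- sort(unique(g$mu[g$dp == d]))
      cand <- unique(c(sub_mu, (head(sub_mu, -1) + tail(sub_mu, -1)) / 2))
      best <- mu_star[as.character(d)]
      best_rss <- rss_of(hinge_lm(mu_star))
      for (msc in cand) {
        trial <- mu_star
        trial[as.character(d)] <- msc
        r <- rss_of(hinge_lm(trial))
        if (r < best_rss - 1e-12) { best_rss <- r; best <- msc }
      }
      if (best != mu_star[as.character(d)]) changed <- TRUE
      mu_star[as.character(d)] <- best
    }
    if (!changed) break
  }
  fit <- hinge_lm(mu_star)
  cp <- unname(coef(fit)[["dpv"]])
  zeta <- unname(coef(fit)[["h"]])
  if (is.na(zeta)) zeta <- 0
  sm <- summary(fit)$coefficients
  cp_se <- if ("dpv" %in% rownames(sm)) sm["dpv", 2] else NA_real_
  zeta_se <- if ("h" %in% rownames(sm)) sm["h", 2] else NA_real_
  open_thr <- vapply(dps, function(d) {
    rng <- range(g$mu[g$dp == d])
    ms <- mu_star[as.character(d)]
    ms >= rng[2] - 1e-9
  }, logical(1))
  structure(list(
    c_gamma = setNames(c_gamma, c("slope", "se")),
    phi = phi,
    c_p = c(value = cp, se = unname(cp_se)),
    zeta = c(value = zeta, se = unname(zeta_se)),
    mu_star = data.table::data.table(dp = dps, mu_star = unname(mu_star[as.character(dps)]),
                                     open = open_thr),
    hinge_fit = fit),
    class = "force_laws")
}

#' @export
print.force_laws <- function(x, ...) {
  cat(sprintf("force laws: c_gamma = %.3f (%.3f), c_p = %.3f (%.3f), zeta = %.3f (%.3f)\n",
              x$c_gamma[1], x$c_gamma[2], x$c_p[1], x$c_p[2],
              x$zeta[1], x$zeta[2]))
  print(x$mu_star)
  invisible(x)
}

#' Low-dimensional growth law: rates from forces (and back)
#'
#' Forward mode: mean rates (Ndot, Vdot) = D f / kBT from a force vector
#' and the measured diffusivity matrix. Inverse mode (`rates` given):
#' returns the forces required to achieve target mean rates,
#' f = kBT D^-1 rates, the design use of the growth law.
#'
#' @param f force vector (kBT units), named as the observables.
#' @param D diffusivity matrix.
#' @param kT thermal energy.
#' @param rates optional target rates for the inverse mode.
#' @return named vector of rates (forward) or forces (inverse).
#' @export
growth_law_predict <- function(f, D, kT = 1, rates = NULL) {
  if (is.null(rates)) {
    drop(D %*% f) / kT
  } else {
    if (!is.finite(rcond(D)) || rcond(D) < 1e-12)
      stop("diffusivity matrix singular in inverse mode")
    kT * solve(D, rates)
  }
}
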