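# Spherical-harmonic shape-fluctuation spectroscopy.
#
# A quasispherical configuration r(theta, phi) = R [1 + sum_{l>=2,m} u_lm
# Y_lm(theta, phi)] is decomposed on real orthonormal spherical harmonics by
# weighted least squares over the mesh vertices (solid-angle weights), the
# degree-l power |u_l|^2 = (2l+1)^-1 sum_m u_lm^2 is averaged over a
# configurational ensemble, and the ensemble spectrum is fit to the
# pressurized elastic-shell prediction
#   <|u_l|^2> = kBT / (2 A_l),
#   A_l = (s/2) [ gamma R^2 + Y R^2 / t + kappa s ],  s = (l-1)(l+2),
#   t = l(l+1),
# which yields the renormalized effective tension gamma, 2D Young's modulus
# Y and bending rigidity kappa. The coefficients of A_l are fixed by
# requiring that A_l = 0 first occurs at the classical buckling tension
# gamma_c0 = -(2/R) sqrt(kappa Y) and that the large-l limit is the
# Helfrich kappa l^4 decay.

#' Real orthonormal spherical harmonics
#'
#' Evaluates real spherical harmonics (orthonormal on the unit sphere,
#' without the Condon-Shortley phase) for all degrees 0..lmax at the given
#' angles.
#'
#' @param theta polar angles (radians, 0..pi).
#' @param phi azimuthal angles (radians).
#' @param lmax maximum degree.
#' @return matrix with `length(theta)` rows and `(lmax+1)^2` columns,
#'   ordered by degree l and, within l, m = 0, 1c, 1s, 2c, 2s, ... (cosine
#'   then sine component for each |m|); column names like "l2m-1".
#' @export
real_spherical_harmonics <- function(theta, phi, lmax) {
  n <- length(theta)
  x <- cos(theta)
  out <- matrix(0, n, (lmax + 1)^2)
  cn <- character((lmax + 1)^2)
  col <- 0L
  for (l in 0:lmax) {
    P <- if (l == 0) matrix(1, 1, n) else pracma::legendre(l, x)
    for (m in 0:l) {
      # pracma::legendre includes the Condon-Shortley phase; strip it
      plm <- (-1)^m * P[m + 1L, ]
      nrm <- sqrt((2 * l + 1) / (4 * pi) *
                    exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
      if (m == 0) {
        col <- col + 1L
        out[, col] <- nrm * plm
        cn[col] <- sprintf("l%dm0", l)
      } else {
        col <- col + 1L
        out[, col] <- sqrt(2) * nrm * plm * cos(m * phi)
        cn[col] <- sprintf("l%dm%d", l, m)
        col <- col + 1L
        out[, col] <- sqrt(2) * nrm * plm * sin(m * phi)
        cn[col] <- sprintf("l%dm-%d", l, m)
      }
    }
  }
  colnames(out) <- cn
  out
}

#' Decompose a quasispherical configuration into spherical harmonics
#'
#' Maps each vertex to spherical coordinates about the vertex centroid and
#' estimates the real mode amplitudes u_lm of the radial field by weighted
#' least squares on real spherical harmonics up to `lmax`, with per-vertex
#' solid-angle weights (barycentric vertex area / r^2). The mean radius R
#' is the fitted monopole; degree-1 amplitudes (centroid motion) are fitted
#' and discarded.
#'
#' Configurations that are not star-shaped about the centroid (any surface
#' element facing inward radially) are flagged; their spectra are excluded
#' from ensemble averages.
#'
#' @param mesh a `trimesh`.
#' @param lmax maximum degree; default `floor(sqrt(N)/2)`, which keeps the
#'   least-squares system strongly overdetermined.
#' @return a list of class `shape_decomposition`: `R`, `lmax`,
#'   `u` (named vector of u_lm, l >= 2), `power` (data.table with l and
#'   |u_l|^2), `star_shaped`.
#' @export
decompose_configuration <- function(mesh, lmax = NULL) {
  v <- mesh$vertices
  n <- nrow(v)
  if (is.null(lmax)) lmax <- floor(sqrt(n) / 2)
  if ((lmax + 1)^2 > 0.8 * n)
    stop(sprintf(
      "lmax = %d needs %d basis functions but only %d vertices are available (limit 0.8 N)",
      lmax, (lmax + 1)^2, n))
  ctr <- colMeans(v)
  d <- sweep(v, 2L, ctr)
  r <- sqrt(rowSums(d * d))
  theta <- acos(pmin(1, pmax(-1, d[, 3L] / r)))
  ph <- atan2(d[, 2L], d[, 1L])
  # star-shape proxy: all face normals point radially outward
  f <- mesh$faces
  a <- d[f[, 1L], , drop = FALSE]
  b <- d[f[, 2L], , drop = FALSE]
  cc <- d[f[, 3L], , drop = FALSE]
  u1 <- b - a; w1 <- cc - a
  nx <- cbind(u1[, 2L] * w1[, 3L] - u1[, 3L] * w1[, 2L],
              u1[, 3L] * w1[, 1L] - u1[, 1L] * w1[, 3L],
              u1[, 1L] * w1[, 2L] - u1[, 2L] * w1[, 1L])
  fcent <- (a + b + cc) / 3
  star <- all(rowSums(nx * fcent) > 0)
  # solid-angle weights: barycentric vertex area / r^2
  fa <- face_areas(mesh)
  ab <- rowsum(rep(fa / 3, 3L), group = c(f[, 1L], f[, 2L], f[, 3L]))
  a_v <- numeric(n)
  a_v[as.integer(rownames(ab))] <- ab[, 1L]
  wts <- a_v / r^2
  B <- real_spherical_harmonics(theta, ph, lmax)
  fit <- lm.wfit(B, r, wts)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  R <- cf[["l0m0"]] / sqrt(4 * pi)
  l_of <- as.integer(sub("^l(\\d+)m.*$", "\\1", colnames(B)))
  u <- cf / R
  # propagated sampling noise of the coefficients: the finite, thermally
  # rough vertex set adds var(c) = s2 * (B' W B)^-1 to every mode, an
  # l-independent plateau that would otherwise bias high-degree power
  k <- fit$rank
  s2 <- sum(wts * fit$residuals^2) / max(length(r) - k, 1L)
  Rmat <- qr.R(fit$qr)
  covu <- tryCatch({
    cu <- s2 * diag(chol2inv(Rmat))
    cu[order(fit$qr$pivot)]
  }, error = function(e) rep(0, ncol(B)))
  keep <- l_of >= 2L
  u <- u[keep]
  lk <- l_of[keep]
  vu <- covu[keep] / R^2
  pw <- vapply(2:lmax, function(l) sum(u[lk == l]^2) / (2 * l + 1), numeric(1))
  nz <- vapply(2:lmax, function(l) sum(vu[lk == l]) / (2 * l + 1), numeric(1))
  structure(list(R = R, lmax = lmax, u = u,
                 power = data.table::data.table(l = 2:lmax, power = pw,
                                                noise = nz),
                 star_shaped = star),
            class = "shape_decomposition")
}

#' Ensemble-averaged fluctuation spectrum
#'
#' Averages the degree-l power |u_l|^2 over a configurational ensemble
#' (e.g. the final configurations of a growth ensemble at elapsed time
#' tau). Non-star-shaped configurations are excluded and counted.
#'
#' @param meshes list of `trimesh` objects (or `shape_decomposition`s).
#' @param lmax maximum degree (default from the first configuration).
#' @return a list of class `spectrum_estimate`: `spectrum` (data.table
#'   with l, power, se), `R` (mean radius), `n_used`, `n_excluded`.
#' @export
ensemble_spectrum <- function(meshes, lmax = NULL) {
  decs <- lapply(meshes, function(m) {
    if (inherits(m, "shape_decomposition")) m else decompose_configuration(m, lmax)
  })
  ok <- vapply(decs, function(d) d$star_shaped, logical(1))
  n_exc <- sum(!ok)
  decs <- decs[ok]
  if (length(decs) < 2L)
    stop("fewer than 2 usable (star-shaped) configurations")
  lmax_use <- min(vapply(decs, function(d) d$lmax, numeric(1)))
  pw <- vapply(decs, function(d) d$power$power[d$power$l <= lmax_use],
               numeric(lmax_use - 1L))
  nz <- vapply(decs, function(d) d$power$noise[d$power$l <= lmax_use],
               numeric(lmax_use - 1L))
  if (is.null(dim(pw))) { pw <- matrix(pw, nrow = 1L); nz <- matrix(nz, nrow = 1L) }
  spec <- data.table::data.table(
    l = 2:lmax_use,
    power = rowMeans(pw),
    se = apply(pw, 1L, sd) / sqrt(ncol(pw)),
    noise = rowMeans(nz))
  structure(list(spectrum = spec,
                 R = mean(vapply(decs, function(d) d$R, numeric(1))),
                 n_used = length(decs), n_excluded = n_exc),
            class = "spectrum_estimate")
}

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat(sprintf("spectrum estimate: l = 2..%d, %d configurations (%d excluded), R = %.3f\n",
              max(x$spectrum$l), x$n_used, x$n_excluded, x$R))
  print(x$spectrum)
  invisible(x)
}

#' Mode stiffness A_l of a pressurized elastic shell
#'
#' @param l spherical-harmonic degree (vectorised).
#' @param gamma effective tension (kBT/l0^2); negative under compression.
#' @param Y effective 2D Young's modulus (kBT/l0^2).
#' @param kappa effective bending rigidity (kBT).
#' @param R mean radius (l0).
#' @return A_l such that the equilibrium spectrum is kBT/(2 A_l).
#' @export
shell_mode_stiffness <- function(l, gamma, Y, kappa, R) {
  s <- (l - 1) * (l + 2)
  t <- l * (l + 1)
  0.5 * s * (gamma * R^2 + Y * R^2 / t + kappa * s)
}

#' Model shell spectrum kBT/(2 A_l)
#' @inheritParams shell_mode_stiffness
#' @param kT thermal energy (default 1).
#' @return expected |u_l|^2.
#' @export
shell_spectrum <- function(l, gamma, Y, kappa, R, kT = 1) {
  A <- shell_mode_stiffness(l, gamma, Y, kappa, R)
  ifelse(A > 0, kT / (2 * A), Inf)
}

#' Fit the pressurized-shell spectrum to an ensemble spectrum
#'
#' Weighted nonlinear least squares of <|u_l|^2> against kBT/(2 A_l),
#' performed in log space (the spectrum spans many decades) with weights
#' from the ensemble standard errors. Y and kappa are parameterised on the
#' log scale so accepted fits always satisfy Y > 0, kappa > 0.
#'
#' @param spec a `spectrum_estimate`.
#' @param kT thermal energy (default 1).
#' @param l_range degrees used in the fit (default 2..min(lmax, 40)).
#' @param gof_threshold reduced chi-squared above which the fit is flagged
#'   as poor (the far-from-equilibrium regime where the quasispherical
#'   shell description breaks down).
#' @param fit_floor additionally fit an l-independent noise floor (used
#'   when no propagated-noise column is available). The least-squares
#'   decomposition of a discrete, thermally rough mesh carries a per-mode
#'   sampling-noise plateau that otherwise biases the bending rigidity
#'   low.
#' @param subtract_noise subtract the analytically propagated per-degree
#'   sampling noise (computed by [decompose_configuration()] from the
#'   weighted least-squares coefficient covariance) before fitting;
#'   degrees whose noise exceeds half the measured power are dropped as
#'   unresolvable. Default TRUE whenever the spectrum carries a noise
#'   column.
#' @return a list of class `elastic_fit`: gamma, Y, kappa, R, standard
#'   errors, covariance, `gof` (reduced chi-squared), `poor_fit` flag,
#'   `l_star` and `lambda_star` (interior spectrum peak, NA when the
#'   spectrum is monotone), fitted table.
#' @export
fit_shell_spectrum <- function(spec, kT = 1, l_range = NULL,
                               gof_threshold = 10, fit_floor = FALSE,
                               subtract_noise = !is.null(spec$spectrum$noise)) {
  s <- spec$spectrum
  if (is.null(l_range)) l_range <- c(2L, min(max(s$l), 40L))
  s <- s[s$l >= l_range[1] & s$l <= l_range[2], ]
  if (isTRUE(subtract_noise) && !is.null(s$noise)) {
    resolvable <- s$noise < 0.5 * s$power
    s <- s[resolvable, ]
    s$power <- s$power - s$noise
  }
  if (nrow(s) < 4L) stop("need at least 4 degrees to fit 3 parameters")
  R <- spec$R
  y <- s$power
  se <- s$se
  se[se <= 0 | !is.finite(se)] <- max(min(y) * 1e-3, 1e-12)
  # starting values: kappa from the bending-dominated tail, Y moderate
  ltail <- max(s$l)
  stail <- (ltail - 1) * (ltail + 2)
  kappa0 <- max(kT / (y[which.max(s$l)] * stail^2), 1e-2)
  start <- c(gamma = 0, logY = log(max(kappa0, 1)), logkappa = log(kappa0))
  if (fit_floor) start <- c(start, logfloor = log(min(y) / 3))
  wl <- y / se  # weights for log-space residuals: d(log y) = dy / y
  resid_fn <- function(p) {
    mdl <- shell_spectrum(s$l, p[["gamma"]], exp(p[["logY"]]),
                          exp(p[["logkappa"]]), R, kT)
    if (fit_floor) mdl <- mdl + exp(p[["logfloor"]])
    mdl[!is.finite(mdl) | mdl <= 0] <- 1e-300
    (log(y) - log(mdl)) * wl
  }
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info %in% c(0L)) stop("spectrum fit failed: ", fit$message)
  p <- fit$par
  gamma <- p[["gamma"]]
  Y <- exp(p[["logY"]])
  kappa <- exp(p[["logkappa"]])
  npar <- length(p)
  sig2 <- fit$deviance / max(length(fit$fvec) - npar, 1L)
  cv <- tryCatch(sig2 * solve(fit$hessian), error = function(e) {
    # rank-deficient fit (e.g. Y pinned): pseudo-inverse, and flag the
    # flat directions with infinite standard errors
    sv <- svd(fit$hessian)
    pos <- sv$d > max(sv$d) * 1e-10
    hinv <- sv$v[, pos, drop = FALSE] %*%
      diag(1 / sv$d[pos], sum(pos)) %*% t(sv$u[, pos, drop = FALSE])
    out <- sig2 * hinv
    flat <- diag(fit$hessian) < max(diag(fit$hessian)) * 1e-8
    diag(out)[flat] <- Inf
    out
  })
  se_gamma <- sqrt(cv[1, 1])
  se_Y <- Y * sqrt(cv[2, 2])
  se_kappa <- kappa * sqrt(cv[3, 3])
  floor_val <- if (fit_floor) exp(p[["logfloor"]]) else 0
  pred <- shell_spectrum(s$l, gamma, Y, kappa, R, kT) + floor_val
  dof <- max(nrow(s) - npar, 1L)
  gof <- sum(((y - pred) / se)^2) / dof
  # interior spectrum peak (wrinkling degree)
  imax <- which.max(y)
  l_star <- if (imax > 1L && imax < nrow(s)) s$l[imax] else NA_integer_
  structure(list(gamma = gamma, Y = Y, kappa = kappa, R = R,
                 se = c(gamma = se_gamma, Y = se_Y, kappa = se_kappa),
                 noise_floor = floor_val,
                 cov = cv, gof = gof, poor_fit = gof > gof_threshold,
                 l_range = l_range, l_star = l_star,
                 lambda_star = if (is.na(l_star)) NA_real_ else 2 * pi * R / l_star,
                 table = data.table::data.table(l = s$l, power = y, se = se,
                                                fit = pred),
                 kT = kT),
            class = "elastic_fit")
}

#' @export
print.elastic_fit <- function(x, ...) {
  cat(sprintf(
    "elastic fit: gamma = %.4f (%.4f), Y = %.3f (%.3f), kappa = %.3f (%.3f), R = %.3f\n",
    x$gamma, x$se[["gamma"]], x$Y, x$se[["Y"]], x$kappa, x$se[["kappa"]], x$R))
  cat(sprintf("  reduced chi^2 = %.2f%s; l* = %s\n", x$gof,
              if (x$poor_fit) " (POOR FIT: far-from-equilibrium regime)" else "",
              ifelse(is.na(x$l_star), "none (monotone spectrum)", x$l_star)))
  invisible(x)
}

#' Near-equilibrium slopes of the renormalized elastic properties
#'
#' Weighted linear regressions of fitted gamma, Y and kappa against the
#' excess chemical potential (in kBT), restricted to the near-equilibrium
#' window, giving the proportionality constants c_gamma, c_Y, c_kappa.
#'
#' @param fits list of `elastic_fit` objects.
#' @param delta_mu excess chemical potentials (kBT), same length.
#' @param window only points with delta_mu <= window enter (default 5 kBT,
#'   the near-equilibrium regime).
#' @param kT thermal energy.
#' @return data.table with property, slope, se, intercept.
#' @export
fit_elastic_series <- function(fits, delta_mu, window = 5, kT = 1) {
  stopifnot(length(fits) == length(delta_mu))
  keep <- delta_mu <= window
  res <- lapply(c("gamma", "Y", "kappa"), function(prop) {
    yv <- vapply(fits[keep], function(f) f[[prop]], numeric(1))
    sev <- vapply(fits[keep], function(f) f$se[[prop]], numeric(1))
    sev[!is.finite(sev) | sev <= 0] <- max(abs(yv)) * 0.05 + 1e-9
    x <- delta_mu[keep] / kT
    fit <- lm(yv ~ x, weights = 1 / sev^2)
    cf <- summary(fit)$coefficients
    data.table::data.table(property = prop, slope = cf[2, 1], se = cf[2, 2],
                           intercept = cf[1, 1], intercept_se = cf[1, 2])
  })
  data.table::rbindlist(res)
}
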