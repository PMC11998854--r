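# Buckling thresholds for pressurized elastic shells and classification of
# driven state points into stable (quasispherical) and wrinkled regimes.

#' Zero-temperature buckling thresholds of a spherical shell
#'
#' A spherical elastic shell buckles at the critical external pressure
#' P_c0 = 4 sqrt(kappa Y) / R^2, equivalently at the negative critical
#' tension gamma_c0 = -(2/R) sqrt(kappa Y); the two satisfy
#' P_c0 = 2 |gamma_c0| / R.
#'
#' @param kappa bending rigidity (kBT).
#' @param Y 2D Young's modulus (kBT/l0^2).
#' @param R shell radius (l0).
#' @return list with `P_c0` and `gamma_c0`.
#' @export
zero_T_thresholds <- function(kappa, Y, R) {
  if (any(c(kappa, Y, R) <= 0)) stop("kappa, Y and R must be positive")
  list(P_c0 = 4 * sqrt(kappa * Y) / R^2,
       gamma_c0 = -2 * sqrt(kappa * Y) / R)
}

#' Elastothermal number
#'
#' ET = (kBT/kappa) sqrt(Y R^2 / kappa): the dimensionless ratio of thermal
#' to elastic resistance of a shell. ET = 0 at zero temperature; larger
#' shells and softer bending give larger ET and stronger fluctuation-induced
#' reduction of the buckling threshold.
#'
#' @inheritParams zero_T_thresholds
#' @param kT thermal energy (default 1).
#' @return dimensionless elastothermal number.
#' @export
elastothermal_number <- function(kappa, Y, R, kT = 1) {
  if (any(c(kappa, Y, R) <= 0) || kT < 0) stop("inputs must be positive (kT >= 0)")
  (kT / kappa) * sqrt(Y * R^2 / kappa)
}

#' Scaling-function models for the thermal buckling threshold
#'
#' `psi_zero_t()` returns the zero-temperature model Psi == 1.
#' `psi_default()` returns a smooth monotone approximation
#' Psi(x) = (1 + x)^(-1/2) to the renormalization-group reduction of the
#' buckling threshold with the elastothermal number (Psi(0) = 1, monotone
#' decreasing); it is an approximate stand-in for the published RG curve
#' and can be replaced by any tabulated curve via `psi_table()`.
#' `psi_table(x, y)` interpolates a user-supplied table (monotonicity and
#' Psi(0) = 1 are validated).
#'
#' @return a function Psi(ET).
#' @export
psi_zero_t <- function() function(x) rep(1, length(x))

#' @rdname psi_zero_t
#' @export
psi_default <- function() function(x) (1 + x)^(-0.5)

#' @rdname psi_zero_t
#' @param x,y tabulated elastothermal numbers and Psi values.
#' @export
psi_table <- function(x, y) {
  if (any(diff(x) <= 0)) stop("table abscissae must be increasing")
  if (any(diff(y) > 1e-12)) stop("Psi must be monotonically non-increasing")
  if (any(y <= 0) || any(y > 1)) stop("Psi values must lie in (0, 1]")
  if (x[1] > 0 && abs(y[1] - 1) > 0.05)
    warning("Psi(0) should approach 1; table starts at Psi = ", y[1])
  function(q) approx(x, y, xout = q, rule = 2)$y
}

check_psi_model <- function(psi_model) {
  xs <- seq(0, 10, length.out = 50)
  ys <- psi_model(xs)
  if (any(diff(ys) > 1e-9)) stop("psi_model must be monotonically non-increasing")
  if (abs(psi_model(0) - 1) > 0.05) stop("psi_model must satisfy Psi(0) ~ 1")
  invisible(TRUE)
}

#' Finite-temperature critical tension and buckling classification
#'
#' gamma_c = gamma_c0 * Psi(ET): thermal fluctuations reduce the magnitude
#' of the threshold (0 < Psi <= 1), so |gamma_c| <= |gamma_c0|. A state
#' with measured tension gamma <= gamma_c is classified as buckled
#' (wrinkled).
#'
#' @inheritParams elastothermal_number
#' @param psi_model a monotone non-increasing function with Psi(0) = 1;
#'   see [psi_default()].
#' @param measured_gamma optional measured effective tension; if given, the
#'   `buckled` flag is filled in.
#' @return a list of class `buckling_prediction`: `gamma_c0`, `P_c0`, `ET`,
#'   `psi`, `gamma_c`, `buckled`.
#' @export
finite_T_critical_tension <- function(kappa, Y, R, kT = 1,
                                      psi_model = psi_default(),
                                      measured_gamma = NULL) {
  check_psi_model(psi_model)
  z <- zero_T_thresholds(kappa, Y, R)
  ET <- elastothermal_number(kappa, Y, R, kT)
  psi <- psi_model(ET)
  gamma_c <- z$gamma_c0 * psi
  structure(list(gamma_c0 = z$gamma_c0, P_c0 = z$P_c0, ET = ET, psi = psi,
                 gamma_c = gamma_c,
                 buckled = if (is.null(measured_gamma)) NA else
                   measured_gamma <= gamma_c),
            class = "buckling_prediction")
}

#' @export
print.buckling_prediction <- function(x, ...) {
  cat(sprintf(
    "buckling prediction: gamma_c0 = %.4f, ET = %.3f, Psi = %.3f, gamma_c = %.4f%s\n",
    x$gamma_c0, x$ET, x$psi, x$gamma_c,
    if (is.na(x$buckled)) "" else if (x$buckled) "  [BUCKLED]" else "  [stable]"))
  invisible(x)
}

#' Morphological phase boundary in the (dp, dmu) plane
#'
#' For each osmotic pressure, locates the excess chemical potential at
#' which the measured effective tension gamma(dmu) crosses the predicted
#' finite-temperature critical tension gamma_c(dmu) (linear interpolation
#' of the sign change of gamma - gamma_c), then fits the boundary
#' dmu*(dp) linearly. The boundary shifts to larger dmu as dp increases.
#'
#' @param fit_table data.table/data.frame with columns `dmu`, `dp`,
#'   `gamma`, `gamma_c` (one row per state point).
#' @return list of class `phase_boundary`: `boundary` (data.table dp,
#'   dmu_star, open flag), `fit` (lm of dmu_star on dp or NULL).
#' @export
phase_diagram <- function(fit_table) {
  tbl <- data.table::as.data.table(fit_table)
  if (nrow(tbl) == 0L) stop("empty fit series")
  need <- c("dmu", "dp", "gamma", "gamma_c")
  if (!all(need %in% names(tbl))) stop("fit_table needs columns ", paste(need, collapse = ", "))
  boundary <- tbl[, {
    o <- order(dmu)
    x <- dmu[o]
    g <- gamma[o] - gamma_c[o]
    sgn <- which(g[-1] * g[-length(g)] <= 0 & g[-1] != g[-length(g)])
    if (length(sgn) == 0L) {
      list(dmu_star = NA_real_, open = TRUE)
    } else {
      i <- sgn[1]
      list(dmu_star = x[i] + (x[i + 1] - x[i]) * (0 - g[i]) / (g[i + 1] - g[i]),
           open = FALSE)
    }
  }, by = "dp"]
  fit <- if (sum(!boundary$open) >= 2L)
    lm(dmu_star ~ dp, data = boundary[!boundary$open, ]) else NULL
  structure(list(boundary = boundary, fit = fit), class = "phase_boundary")
}

#' @export
print.phase_boundary <- function(x, ...) {
  cat("morphological phase boundary dmu*(dp):\n")
  print(x$boundary)
  if (!is.null(x$fit))
    cat(sprintf("  linear fit: dmu* = %.3f + %.3f dp\n",
                coef(x$fit)[1], coef(x$fit)[2]))
  invisible(x)
}
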