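# Configurational energy of a triangulated vesicle:
#   Etot = Ebend + Etether + Earea
# and the grand-potential-like function Phi = Etot - mu*N - dp*V whose
# change governs Metropolis acceptance.

#' Energy parameters for the vesicle Hamiltonian
#'
#' @param kappa bending rigidity (kBT). Default 20, a typical value for
#'   lipid bilayers.
#' @param tether_min,tether_max hard square-well bounds on edge lengths
#'   (l0 units); edges outside the well cost infinite energy, which keeps
#'   the mean edge length near 1 and provides the only steric constraint.
#' @param k_a stiffness of the per-face area constraint (kBT/l0^4). The
#'   default keeps single-face area fluctuations of order
#'   sqrt(kBT/k_a) ~ 0.2 l0^2 while the relative fluctuation of the total
#'   area (and hence of the vertex density rho0 = N/A) stays well below a
#'   percent for vesicles of a few hundred vertices.
#' @param a0 target face area (l0^2); the default is the area of a unit
#'   equilateral triangle, so a freshly built unit-edge icosphere is near
#'   the minimum of the area energy.
#' @return a list of class `energy_params` with the derived target vertex
#'   density `rho0` = 1/(2*a0) (each vertex carries about two faces).
#' @export
energy_params <- function(kappa = 20, tether_min = 0.55, tether_max = 1.60,
                          k_a = 20, a0 = sqrt(3) / 4) {
  stopifnot(kappa > 0, tether_min > 0, tether_min < tether_max,
            k_a >= 0, a0 > 0)
  structure(list(kappa = kappa, tether_min = tether_min,
                 tether_max = tether_max, k_a = k_a, a0 = a0,
                 rho0 = 1 / (2 * a0)),
            class = "energy_params")
}

#' Discrete Helfrich bending energy
#'
#' Computes (kappa/2) * integral (2H)^2 dA on the triangulated surface via
#' the cotangent Laplace-Beltrami operator with barycentric vertex areas:
#' the mean-curvature vector at vertex i is
#' (1/(4 A_i)) * sum_j (cot a_ij + cot b_ij) (x_i - x_j), where a_ij, b_ij
#' are the angles opposite edge ij. The result is invariant under rigid
#' motions and under uniform dilation, and converges to the continuum value
#' 8 * pi * kappa for a sphere under mesh refinement.
#'
#' @param mesh a `trimesh`.
#' @param params an [energy_params()] list.
#' @return bending energy (kBT).
#' @export
bending_energy <- function(mesh, params = energy_params()) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(v)
  cot_at <- function(a, b, cc) {
    u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    w <- v[cc, , drop = FALSE] - v[a, , drop = FALSE]
    cr <- cbind(u[, 2L] * w[, 3L] - u[, 3L] * w[, 2L],
                u[, 3L] * w[, 1L] - u[, 1L] * w[, 3L],
                u[, 1L] * w[, 2L] - u[, 2L] * w[, 1L])
    nrm <- sqrt(rowSums(cr * cr))
    if (any(nrm < 1e-300)) {
      bad <- which(nrm < 1e-300)[1L]
      stop(sprintf("degenerate (zero-area) face involving vertices %d,%d,%d",
                   a[bad], b[bad], cc[bad]))
    }
    rowSums(u * w) / nrm
  }
  # cot at each corner weights the opposite edge
  cot1 <- cot_at(f[, 1L], f[, 2L], f[, 3L])
  cot2 <- cot_at(f[, 2L], f[, 3L], f[, 1L])
  cot3 <- cot_at(f[, 3L], f[, 1L], f[, 2L])
  w_all <- c(cot1, cot2, cot3)
  p <- c(f[, 2L], f[, 3L], f[, 1L])
  q <- c(f[, 3L], f[, 1L], f[, 2L])
  pp <- c(p, q)
  qq <- c(q, p)
  ww <- c(w_all, w_all)
  d <- v[pp, , drop = FALSE] - v[qq, , drop = FALSE]
  cvec <- rowsum(ww * d, group = pp)
  ord <- as.integer(rownames(cvec))
  # mixed Voronoi vertex areas (Meyer): circumcentric for non-obtuse
  # faces, area/2 at the obtuse corner and area/4 elsewhere for obtuse
  # faces (a negative cotangent marks an obtuse corner)
  fa <- face_areas(mesh)
  elen2 <- function(a, b) rowSums((v[a, , drop = FALSE] - v[b, , drop = FALSE])^2)
  e12 <- elen2(f[, 1L], f[, 2L])
  e23 <- elen2(f[, 2L], f[, 3L])
  e31 <- elen2(f[, 3L], f[, 1L])
  obtuse <- cot1 < 0 | cot2 < 0 | cot3 < 0
  contrib <- function(cot_self, lsq_a, cot_a, lsq_b, cot_b) {
    ifelse(!obtuse, (lsq_a * cot_a + lsq_b * cot_b) / 8,
           ifelse(cot_self < 0, fa / 2, fa / 4))
  }
  a1 <- contrib(cot1, e12, cot3, e31, cot2)  # edges at corner 1: (1,2) opp 3; (3,1) opp 2
  a2 <- contrib(cot2, e23, cot1, e12, cot3)
  a3 <- contrib(cot3, e31, cot2, e23, cot1)
  amix <- rowsum(c(a1, a2, a3), group = c(f[, 1L], f[, 2L], f[, 3L]))
  a_v <- numeric(n)
  a_v[as.integer(rownames(amix))] <- amix[, 1L]
  c2 <- numeric(n)
  c2[ord] <- rowSums(cvec * cvec)
  params$kappa / 8 * sum(c2 / a_v)
}

#' Hard tether energy
#'
#' Zero when every edge length lies strictly inside
#' (`tether_min`, `tether_max`), `Inf` otherwise (a move-rejecting
#' sentinel; the tether is a hard square well).
#'
#' @inheritParams bending_energy
#' @return 0 or `Inf`.
#' @export
tether_energy <- function(mesh, params = energy_params()) {
  l <- edge_lengths(mesh)
  if (all(l > params$tether_min & l < params$tether_max)) 0 else Inf
}

#' Local area-constraint energy
#'
#' (k_a/2) * sum over faces (A_f - a0)^2. Keeps the vertex density
#' rho0 = N/A approximately constant, so the area tracks the particle
#' number as A(t) ~ N(t)/rho0.
#'
#' @inheritParams bending_energy
#' @return area energy (kBT).
#' @export
area_energy <- function(mesh, params = energy_params()) {
  params$k_a / 2 * sum((face_areas(mesh) - params$a0)^2)
}

#' Energy breakdown and the grand-potential-like function Phi
#'
#' Assembles Ebend, Etether, Earea, their total, and
#' Phi = Etot - mu*N - dp*V for the given reservoir parameters.
#'
#' @inheritParams bending_energy
#' @param mu reservoir chemical potential (kBT per vertex).
#' @param dp osmotic pressure difference p_in - p_out (kBT/l0^3).
#' @return a list of class `energy_breakdown` with components `bend`,
#'   `tether`, `area`, `total`, `phi`, `N`, `volume`.
#' @export
phi <- function(mesh, params = energy_params(), mu = 0, dp = 0) {
  b <- bending_energy(mesh, params)
  te <- tether_energy(mesh, params)
  ar <- area_energy(mesh, params)
  vol <- enclosed_volume(mesh)
  n <- nrow(mesh$vertices)
  tot <- b + te + ar
  structure(list(bend = b, tether = te, area = ar, total = tot,
                 phi = tot - mu * n - dp * vol, N = n, volume = vol),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(
    "energy breakdown (kBT): bend %.4f + tether %g + area %.4f = %.4f\n",
    x$bend, x$tether, x$area, x$total))
  cat(sprintf("  Phi = %.4f  (N = %d, V = %.4f)\n", x$phi, x$N, x$volume))
  invisible(x)
}
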