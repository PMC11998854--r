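# Shared fixtures and a cross-file cache for expensive simulations.
# Everything is generated in code; nothing is read from disk.

# report every failure rather than stopping the run early
testthat::set_max_fails(Inf)

# unit cube surface, 12 outward-oriented triangles (volume oracle: 1)
cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  # faces as (1-based) corner indices of each cube side, split into triangles
  quads <- rbind(
    c(1, 2, 4, 3),  # z = 0 (viewed from below -> reversed later)
    c(5, 7, 8, 6),  # z = 1
    c(1, 5, 6, 2),  # y = 0
    c(3, 4, 8, 7),  # y = 1
    c(1, 3, 7, 5),  # x = 0
    c(2, 6, 8, 4))  # x = 1
  f <- do.call(rbind, lapply(seq_len(nrow(quads)), function(i) {
    q <- quads[i, ]
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])
  }))
  # fix orientation outward (centre at (.5,.5,.5))
  ctr <- c(0.5, 0.5, 0.5)
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ] - ctr; b <- v[f[i, 2], ] - ctr; cc <- v[f[i, 3], ] - ctr
    n <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
           a[1] * b[2] - a[2] * b[1])
    if (sum(n * (a + b + cc)) < 0) f[i, ] <- f[i, c(1, 3, 2)]
  }
  trimesh(v, f)
}

# tetrahedron (complete graph K4): every edge flip is invalid
tetrahedron_mesh <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  f <- rbind(c(1, 2, 3), c(1, 3, 4), c(1, 4, 2), c(2, 4, 3))
  if (enclosed_volume(trimesh(v, f, validate = FALSE)) < 0)
    f <- f[, c(1, 3, 2)]
  trimesh(v, f)
}

# cache shared across test files (computed once per test_dir run)
.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# a small equilibrated vesicle shared by several tests: icosphere s=2 with a
# tuned step size and a calibrated equilibrium chemical potential
equilibrated_s2 <- function() {
  cached("equilibrated_s2", {
    m <- build_icosphere(2, unit_edge = TRUE)
    p <- sim_params(seed = 101L)
    p$mu <- 2
    pre <- run_sweeps(m, p, nsweeps = 300, checkpoint_every = 300, seed = 101,
                      tune_step = TRUE)
    p$step_size <- pre$step_size
    # self-consistent calibration doubles as the slow-mode relaxation
    cal <- calibrate_mu_eq(pre$mesh, p, mu_start = 2, rounds = 6L,
                           nsweeps_round = 700L, seed = 55)
    p$mu <- cal$mu_eq
    relax <- run_sweeps(cal$mesh, p, nsweeps = 2500, checkpoint_every = 1250,
                        seed = 77)
    list(mesh = relax$mesh, params = p, mu_eq = cal$mu_eq, mu_eq_se = cal$se)
  })
}

# driven growth ensembles over a dmu grid at dp = 0, reused by the
# linear-response, tension-renormalization and morphology tests
driven_series_s2 <- function() {
  cached("driven_series_s2", {
    eq <- equilibrated_s2()
    p <- eq$params
    dmus <- c(0, 0.5, 1, 2, 6, 8)
    ens <- lapply(seq_along(dmus), function(i) {
      run_growth_ensemble(eq$mesh, p, eq$mu_eq, dmus[i], nsamples = 16L,
                          nequil = 300L, nsim = 400L, checkpoint_every = 50L,
                          seed = 7000L + i)
    })
    list(dmu = dmus, ensembles = ens, mu_eq = eq$mu_eq, params = p)
  })
}

# shared equilibrated medium vesicle (icosphere s=3, N = 642, R ~ 7):
# large enough that the tension term gamma R^2 is measurable in the
# fluctuation spectrum
equilibrated_s3 <- function() {
  cached("equilibrated_s3",
         prepare_equilibrium_state(seed = 401L, subdivisions = 3L,
                                   nequil = 6000L, cal_sweeps = 1000L))
}

# equilibrium rigidity experiment (the dmu = 0 ensemble is reused as the
# equilibrium member of the driven fit series)
rigidity_s3 <- function() {
  cached("rigidity_s3", measure_equilibrium_rigidity(state = equilibrated_s3()))
}

# driven growth ensembles at s=3 for the elastic-fit series (tension
# renormalization and the morphological transition)
driven_series_s3 <- function() {
  cached("driven_series_s3", {
    st <- equilibrated_s3()
    dmus <- c(1, 2, 6)
    ens <- lapply(seq_along(dmus), function(i) {
      run_growth_ensemble(st$mesh, st$params, st$mu_eq, dmus[i],
                          nsamples = 7L, nequil = 150L, nsim = 1000L,
                          checkpoint_every = 250L, seed = 9200L + i,
                          keep_snapshots = TRUE)
    })
    list(dmu = dmus, ensembles = ens, mu_eq = st$mu_eq, params = st$params)
  })
}

# elastic fits across the dmu series: the equilibrium point comes from the
# rigidity experiment's ensemble; every fit pools the late-time
# configurations (t >= 3/4 tau) of its samples
driven_fits_s3 <- function() {
  cached("driven_fits_s3", {
    ds <- driven_series_s3()
    late_fit <- function(e) {
      configs <- unlist(lapply(e$snapshots, function(sn)
        sn$meshes[sn$t >= 0.75 * e$tau]), recursive = FALSE)
      fit_shell_spectrum(ensemble_spectrum(configs))
    }
    f0 <- late_fit(rigidity_s3()$ensemble)
    fits <- c(list(f0), lapply(ds$ensembles, late_fit))
    list(dmu = c(0, ds$dmu), fits = fits)
  })
}

# volume-drive ensembles: pressurised runs at the dp = 0 equilibrium
# chemical potential, used for the volume-force law
pressure_series_s2 <- function() {
  cached("pressure_series_s2", {
    eq <- equilibrated_s2()
    dps <- c(0.1, 0.2, 0.3)
    ens <- lapply(seq_along(dps), function(i) {
      p <- eq$params
      p$dp <- dps[i]
      run_growth_ensemble(eq$mesh, p, eq$mu_eq, 0, nsamples = 16L,
                          nequil = 300L, nsim = 400L, checkpoint_every = 100L,
                          seed = 8100L + i)
    })
    list(dp = dps, ensembles = ens, mu_eq = eq$mu_eq)
  })
}

# Two-level detailed-balance audit: icosahedron <-> icosahedron plus one
# vertex, frozen positions. Returns the engine occupation of the upper level
# and the prediction from direct configurational quadrature.
audit_two_level <- function(K = 8000L, nsweeps = 14000L, seed = 123L) {
  cached(paste0("audit", seed), {
    m <- build_icosphere(0, unit_edge = TRUE)
    ep <- energy_params(tether_min = 0.3, tether_max = 1.7, k_a = 5)
    delta <- 0.08  # cubes of the two diagonals of any quad cannot overlap
    p <- sim_params(energy = ep, pflip = 0, pexchange = 1, step_size = 1e-9,
                    insert_halfwidth = delta, min_vertices = 12L,
                    max_vertices = 13L)
    e <- mesh_edges(m)
    vc <- (2 * delta)^3
    tot0 <- vesiclegrowth:::cpp_mesh_totals(m$vertices, m$faces, ep$kappa,
                                            ep$k_a, ep$a0, ep$tether_min,
                                            ep$tether_max)
    E0 <- tot0$E_bend + tot0$E_area
    i <- e[1, 1]; j <- e[1, 2]
    fr <- vesiclegrowth:::edge_face_rows(m, i, j)
    k <- vesiclegrowth:::third_vertex(m$faces[fr[1], ], i, j)
    l <- vesiclegrowth:::third_vertex(m$faces[fr[2], ], i, j)
    mid <- (m$vertices[i, ] + m$vertices[j, ]) / 2
    f2 <- m$faces
    f2[fr[1], ] <- c(i, 13L, k); f2[fr[2], ] <- c(13L, j, k)
    f2 <- rbind(f2, c(j, 13L, l), c(13L, i, l))
    set.seed(seed)
    vals <- vapply(seq_len(K), function(q) {
      x <- mid + runif(3, -delta, delta)
      tt <- vesiclegrowth:::cpp_mesh_totals(rbind(m$vertices, x), f2,
                                            ep$kappa, ep$k_a, ep$a0,
                                            ep$tether_min, ep$tether_max)
      if (tt$tether_ok) exp(-(tt$E_bend + tt$E_area - E0)) else 0
    }, numeric(1))
    z0 <- 30 * mean(vals) * vc  # 30 equivalent edges on the icosahedron
    pred_relse <- sd(vals) / sqrt(K) / mean(vals)
    p$mu <- -log(z0)  # balanced two-level system: predicted fraction 1/2
    run <- run_sweeps(m, p, nsweeps = nsweeps, checkpoint_every = 1,
                      seed = seed)
    occ <- run$records$N == 13
    nb <- 40L
    bm <- vapply(split(occ, rep(1:nb, length.out = length(occ))), mean,
                 numeric(1))
    list(frac = mean(occ), se = sd(bm) / sqrt(nb), predicted = 0.5,
         pred_se = 0.25 * pred_relse,
         transitions = sum(run$records$acc_insert) +
           sum(run$records$acc_remove))
  })
}
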