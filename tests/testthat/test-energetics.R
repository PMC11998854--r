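# Energetics: discrete Helfrich bending, hard tether, local area constraint,
# and the grand-potential-like function Phi.

test_that("bending energy is scale, rotation and kappa linear", {
  m <- build_icosphere(2, unit_edge = TRUE)
  ep <- energy_params()
  e0 <- bending_energy(m, ep)
  # uniform dilation leaves the bending energy unchanged
  m2 <- m
  m2$vertices <- m$vertices * 3.7
  expect_equal(bending_energy(m2, ep), e0, tolerance = 1e-9)
  # rigid rotation + translation
  set.seed(4)
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
  Rz <- rbind(c(cos(th[2]), -sin(th[2]), 0), c(sin(th[2]), cos(th[2]), 0), c(0, 0, 1))
  m3 <- m
  m3$vertices <- m$vertices %*% (Rx %*% Rz) + matrix(c(5, -2, 1), nrow(m$vertices), 3, byrow = TRUE)
  expect_equal(bending_energy(m3, ep), e0, tolerance = 1e-9)
  # linear in kappa
  ep2 <- ep; ep2$kappa <- 2 * ep$kappa
  expect_equal(bending_energy(m, ep2), 2 * e0, tolerance = 1e-12)
})

test_that("bending energy of a sphere converges to 8 pi kappa", {
  ep <- energy_params()
  target <- 8 * pi * ep$kappa
  errs <- vapply(1:3, function(s) {
    m <- build_icosphere(s, target_radius = 5)
    abs(bending_energy(m, ep) - target) / target
  }, numeric(1))
  expect_true(all(diff(errs) < 0))  # monotone approach under refinement
  expect_lt(errs[3], 0.05)
})

test_that("hard tether energy is a square well", {
  m <- build_icosphere(2, unit_edge = TRUE)
  ep <- energy_params(tether_min = 0.6, tether_max = 1.55)
  expect_identical(tether_energy(m, ep), 0)
  # one vertex displaced so that an edge leaves the well
  m2 <- m
  m2$vertices[1, ] <- m2$vertices[1, ] * 1.8
  expect_identical(tether_energy(m2, ep), Inf)
  # widened bounds disable the constraint
  ep2 <- energy_params(tether_min = 1e-9, tether_max = 1e9)
  expect_identical(tether_energy(m2, ep2), 0)
})

test_that("area energy is quadratic about the target face area", {
  cm <- cube_mesh()
  a <- face_areas(cm)
  ep <- energy_params(a0 = a[1], k_a = 8)
  expect_equal(area_energy(cm, ep), 0, tolerance = 1e-12)
  dlt <- 0.03
  ep2 <- energy_params(a0 = a[1] - dlt, k_a = 8)
  expect_equal(area_energy(cm, ep2), nrow(cm$faces) * 8 / 2 * dlt^2,
               tolerance = 1e-9)
})

test_that("Phi is linear in mu and dp with slopes -N and -V", {
  m <- build_icosphere(1, unit_edge = TRUE)
  ep <- energy_params()
  b0 <- phi(m, ep, mu = 0, dp = 0)
  expect_equal(b0$phi, b0$total)
  expect_equal(b0$total, b0$bend + b0$tether + b0$area, tolerance = 1e-12)
  b1 <- phi(m, ep, mu = 1, dp = 0)
  expect_equal(b0$phi - b1$phi, nrow(m$vertices), tolerance = 1e-9)
  b2 <- phi(m, ep, mu = 0, dp = 1)
  expect_equal(b0$phi - b2$phi, enclosed_volume(m), tolerance = 1e-9)
})

test_that("incremental Phi along an engine trajectory matches full recomputation", {
  m <- build_icosphere(2, unit_edge = TRUE)
  p <- sim_params(mu = 1.7, dp = 0.05, seed = 31L)
  # ~10^5 individual moves with every move kind active
  run <- run_sweeps(m, p, nsweeps = 70, checkpoint_every = 10, seed = 31,
                    snapshot_every = 10)
  rec <- run$records[run$records$t > 0, ]
  expect_equal(length(run$snapshots), nrow(rec))
  for (i in seq_along(run$snapshots)) {
    br <- phi(run$snapshots[[i]], p$energy, mu = p$mu, dp = p$dp)
    expect_equal(rec$Phi[i], br$phi, tolerance = 1e-9)
    expect_equal(rec$E_bend[i], br$bend, tolerance = 1e-9)
    expect_equal(rec$E_area[i], br$area, tolerance = 1e-9)
    expect_equal(rec$V[i], br$volume, tolerance = 1e-9)
  }
})
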