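# Spherical-harmonic decomposition and elastic-shell spectrum fitting.

test_that("real spherical harmonics are orthonormal on the sphere", {
  set.seed(1)
  n <- 8000
  z <- runif(n, -1, 1)
  th <- acos(z)
  ph <- runif(n, 0, 2 * pi)
  B <- real_spherical_harmonics(th, ph, 3)
  G <- crossprod(B) / n * 4 * pi
  expect_lt(max(abs(G - diag(ncol(B)))), 0.05)  # Monte Carlo quadrature
})

test_that("decomposition of a perfect sphere is a null spectrum", {
  m <- build_icosphere(2, target_radius = 5)
  dec <- decompose_configuration(m, lmax = 5)
  expect_equal(dec$R, 5, tolerance = 1e-10)
  expect_lt(max(abs(dec$u)), 1e-10)
  expect_true(dec$star_shaped)
})

test_that("a known Y20 deformation is recovered and rotation leaves degree power invariant", {
  m <- build_icosphere(3, target_radius = 1)
  ctr <- colMeans(m$vertices)
  d <- sweep(m$vertices, 2, ctr)
  r <- sqrt(rowSums(d^2))
  th <- acos(d[, 3] / r)
  ph <- atan2(d[, 2], d[, 1])
  Y20 <- real_spherical_harmonics(th, ph, 2)[, "l2m0"]
  R0 <- 10
  m$vertices <- d * (R0 * (1 + 0.05 * Y20) / r)
  dec <- decompose_configuration(m, lmax = 8)
  expect_equal(dec$u[["l2m0"]], 0.05, tolerance = 0.02)
  expect_lt(max(abs(dec$u[names(dec$u) != "l2m0"])), 5e-3)
  # rigid rotation: per-degree power is invariant
  th1 <- 0.83
  Rz <- rbind(c(cos(th1), -sin(th1), 0), c(sin(th1), cos(th1), 0), c(0, 0, 1))
  th2 <- 0.41
  Rx <- rbind(c(1, 0, 0), c(0, cos(th2), -sin(th2)), c(0, sin(th2), cos(th2)))
  m2 <- m
  m2$vertices <- m$vertices %*% (Rz %*% Rx)
  dec2 <- decompose_configuration(m2, lmax = 8)
  expect_equal(dec2$power$power, dec$power$power, tolerance = 1e-3)
})

test_that("Parseval consistency: vertex variance matches summed mode power", {
  m <- build_icosphere(3, target_radius = 1)
  ctr <- colMeans(m$vertices)
  d <- sweep(m$vertices, 2, ctr)
  r <- sqrt(rowSums(d^2))
  th <- acos(d[, 3] / r)
  ph <- atan2(d[, 2], d[, 1])
  B <- real_spherical_harmonics(th, ph, 4)
  amp <- c(l2m0 = 0.04, `l3m2` = 0.02, `l4m-1` = 0.015)
  u <- rowSums(sweep(B[, names(amp), drop = FALSE], 2, amp, "*"))
  m$vertices <- d * (7 * (1 + u) / r)
  dec <- decompose_configuration(m, lmax = 6)
  total_power <- sum(vapply(dec$power$l, function(l)
    dec$power$power[dec$power$l == l] * (2 * l + 1), numeric(1)))
  # sum_lm u_lm^2 = (1/4pi) * integral (r/R - 1)^2 dOmega
  expect_equal(total_power, sum(amp^2), tolerance = 0.02 * sum(amp^2))
})

test_that("under-resolved decompositions are refused", {
  m <- build_icosphere(1, target_radius = 3)  # 42 vertices
  expect_error(decompose_configuration(m, lmax = 8), "basis")
})

test_that("ensemble spectrum handles degenerate and small ensembles", {
  m <- build_icosphere(2, target_radius = 4)
  expect_error(ensemble_spectrum(list(m)), "fewer than 2")
  sp <- ensemble_spectrum(list(m, m, m))
  expect_true(all(sp$spectrum$se == 0))
})

test_that("shell-spectrum fit recovers known parameters (forward-model round trip)", {
  truth <- list(gamma = -1, Y = 30, kappa = 20, R = 15)
  # noiseless: recovery to optimizer tolerance
  sp0 <- generate_synthetic_spectrum(truth$gamma, truth$Y, truth$kappa,
                                     truth$R, noise = 0, lmax = 25)
  f0 <- fit_shell_spectrum(sp0)
  expect_equal(f0$gamma, truth$gamma, tolerance = 1e-4)
  expect_equal(f0$Y, truth$Y, tolerance = 1e-4)
  expect_equal(f0$kappa, truth$kappa, tolerance = 1e-4)
  # 1% multiplicative noise: within 3 fitted standard errors, across seeds
  for (sd_i in 1:3) {
    sp <- generate_synthetic_spectrum(truth$gamma, truth$Y, truth$kappa,
                                      truth$R, noise = 0.01,
                                      lmax = 25, seed = sd_i)
    f <- fit_shell_spectrum(sp)
    expect_lt(abs(f$gamma - truth$gamma), 3 * f$se[["gamma"]] + 1e-6)
    expect_lt(abs(f$Y - truth$Y), 3 * f$se[["Y"]] + 1e-6)
    expect_lt(abs(f$kappa - truth$kappa), 3 * f$se[["kappa"]] + 1e-6)
  }
})

test_that("more negative tension raises low-degree amplitudes and can create a peak", {
  s1 <- generate_synthetic_spectrum(-0.5, 30, 20, 15, noise = 0)
  s2 <- generate_synthetic_spectrum(-1.5, 30, 20, 15, noise = 0)
  expect_gt(s2$spectrum$power[1], s1$spectrum$power[1])
  # near the stability edge the spectrum diverges at the softest degree
  edge <- spectrum_stability_edge(30, 20, 15)
  expect_gt(edge$l_soft, 2)
  s3 <- generate_synthetic_spectrum(edge$gamma_edge * 0.995, 30, 20, 15, noise = 0)
  f3 <- fit_shell_spectrum(s3)
  expect_equal(f3$l_star, edge$l_soft, tolerance = 1)
  s4 <- generate_synthetic_spectrum(edge$gamma_edge * 0.98, 30, 20, 15, noise = 0)
  expect_true(all(is.finite(s4$spectrum$power)))
  # beyond the edge the softest mode stiffness turns negative
  expect_error(generate_synthetic_spectrum(edge$gamma_edge * 1.02, 30, 20, 15),
               "stability edge")
})

test_that("at large degree the spectrum reduces to the Helfrich bending decay", {
  l <- 30:40
  sp <- shell_spectrum(l, gamma = -1, Y = 30, kappa = 20, R = 15)
  helfrich <- 1 / (20 * ((l - 1) * (l + 2))^2)
  expect_equal(sp / helfrich, rep(1, length(l)), tolerance = 0.05)
})

test_that("fit is invariant under overall unit rescaling", {
  sp <- generate_synthetic_spectrum(-1, 30, 20, 15, noise = 0, lmax = 20)
  f1 <- fit_shell_spectrum(sp)
  # same shape measured in rescaled units: R' = lambda R, gamma, Y ~ lambda^-2
  lam <- 2.5
  sp2 <- generate_synthetic_spectrum(-1 / lam^2, 30 / lam^2, 20, 15 * lam,
                                     noise = 0, lmax = 20)
  f2 <- fit_shell_spectrum(sp2)
  expect_equal(f2$kappa, f1$kappa, tolerance = 1e-3)
  expect_equal(f2$gamma * lam^2, f1$gamma, tolerance = 1e-3)
  expect_equal(f2$Y * lam^2, f1$Y, tolerance = 1e-2)
})
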