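# Flux statistics, TUR entropy bounds, force inference, force laws and the
# growth law, validated against exact synthetic oracles.

fake_flux <- function(j, D, tau = 1000, n = 100, dmu = NA, se = 1e-4) {
  structure(list(J = NULL, mean_J = j * tau, j = j, Xi = D * 2 * tau, D = D,
                 tau = tau, nsamples = n,
                 se_J = setNames(rep(se, length(j)), names(j)),
                 delta_mu = dmu, dp = 0),
            class = "flux_ensemble")
}

test_that("flux statistics recover random-walk moments", {
  # degenerate ensemble: identical samples give a zero covariance
  rec <- data.table::rbindlist(lapply(1:5, function(i)
    data.table::data.table(sample = i, t = c(0, 100), N = c(0, 7), V = c(0, 3))))
  ens0 <- structure(list(records = rec, tau = 100), class = "trajectory_ensemble")
  fl0 <- flux_statistics(ens0)
  expect_equal(unname(fl0$Xi), matrix(0, 2, 2))
  expect_equal(unname(fl0$mean_J), c(7, 3))
  # biased walk: closed-form mean and diffusivity within 3 SE
  drift <- c(1, 0.5)
  D0 <- matrix(c(2, 0.5, 0.5, 1), 2)
  ens <- generate_synthetic_trajectories(drift, D0, nsamples = 400, tau = 500,
                                         seed = 12)
  fl <- flux_statistics(ens)
  se_mean <- sqrt(diag(fl$Xi) / fl$nsamples)
  expect_true(all(abs(fl$mean_J - drift * 500) < 3 * se_mean))
  se_D <- fl$D * sqrt(2 / (fl$nsamples - 1))
  expect_true(all(abs(fl$D - D0) < 3 * pmax(se_D, 0.05)))
  # a non-checkpoint horizon is refused in exact mode
  expect_error(flux_statistics(ens, tau = 123), "checkpoint")
})

test_that("linear response is exact on constructed fluxes and flags the far regime", {
  DN <- 1.4
  dmus <- c(0.5, 1, 2)
  fls <- lapply(dmus, function(d)
    fake_flux(c(N = DN * d, V = 0), matrix(c(DN, 0, 0, 1), 2,
                                           dimnames = list(c("N", "V"), c("N", "V"))),
              dmu = d))
  lr <- linear_response_check(fls, dmus)
  expect_equal(lr$slope, 1, tolerance = 1e-9)
  # far-from-equilibrium points excluded from the regression window
  fls2 <- c(fls, list(fake_flux(c(N = DN * 4, V = 0),  # sublinear at dmu = 8
                                matrix(c(DN, 0, 0, 1), 2,
                                       dimnames = list(c("N", "V"), c("N", "V"))),
                                dmu = 8)))
  lr2 <- linear_response_check(fls2, c(dmus, 8))
  expect_equal(lr2$slope, 1, tolerance = 1e-9)
  expect_false(lr2$table$in_window[4])
})

test_that("TUR bounds: closed form, additivity and observable monotonicity", {
  # Gaussian flux, df = 1: bound = 2 m^2 / s
  m <- 40; s <- 160
  fl <- fake_flux(c(N = m / 1000, V = 0),
                  matrix(c(s, 0, 0, 50), 2, dimnames = list(c("N", "V"), c("N", "V"))) / 2000,
                  tau = 1000)
  en <- entropy_bounds(fl, delta_mu = 1)
  expect_equal(en$bound_df1, 2 * m^2 / s, tolerance = 1e-9)
  # diagonal covariance: df = 2 bound is the sum of per-flux bounds
  fl2 <- fake_flux(c(N = 0.04, V = 0.02),
                   matrix(c(160, 0, 0, 50), 2,
                          dimnames = list(c("N", "V"), c("N", "V"))) / 2000)
  en2 <- entropy_bounds(fl2, delta_mu = 1)
  expect_equal(en2$bound_df2, 2 * (40^2 / 160 + 20^2 / 50), tolerance = 1e-9)
  # adding an observable never decreases the bound (100 random instances)
  set.seed(5)
  for (i in 1:100) {
    A <- matrix(rnorm(4), 2)
    Xi <- crossprod(A) + diag(2) * 0.1
    dimnames(Xi) <- list(c("N", "V"), c("N", "V"))
    J <- rnorm(2)
    fl3 <- structure(list(mean_J = setNames(J, c("N", "V")), Xi = Xi,
                          tau = 100, j = J / 100), class = "flux_ensemble")
    en3 <- entropy_bounds(fl3, delta_mu = 1)
    expect_gte(en3$bound_df2, en3$bound_df1 - 1e-9)
    expect_gte(en3$bound_df1, 0)
  }
})

test_that("entropy estimate applies the relative-entropy correction when supplied", {
  fl <- fake_flux(c(N = 0.05, V = 0), diag(c(1, 1)) / 20, tau = 1000)
  dimnames(fl$Xi) <- dimnames(fl$D) <- list(c("N", "V"), c("N", "V"))
  names(fl$mean_J) <- names(fl$j) <- c("N", "V")
  e0 <- entropy_bounds(fl, delta_mu = 2)
  expect_false(e0$eps_diss_included)
  e1 <- entropy_bounds(fl, delta_mu = 2, eps_diss = 0.01)
  expect_true(e1$eps_diss_included)
  expect_equal(e0$dS_direct - e1$dS_direct, 0.01 * 1000)
})

test_that("force inference inverts diagonal and correlated diffusivities", {
  ens <- generate_synthetic_trajectories(c(1, 0.4),
                                         matrix(c(2, 0.6, 0.6, 1), 2),
                                         nsamples = 300, tau = 400, seed = 31)
  fl <- flux_statistics(ens)
  fo <- infer_forces(fl, nboot = 300, seed = 2)
  # ground truth: f = kT D^-1 drift
  truth <- solve(matrix(c(2, 0.6, 0.6, 1), 2), c(1, 0.4))
  expect_true(all(abs(fo$f - truth) < 4 * fo$se))
})

test_that("growth law is consistent forwards and backwards", {
  D <- matrix(c(1.5, 0.3, 0.3, 0.8), 2,
              dimnames = list(c("N", "V"), c("N", "V")))
  f0 <- c(N = 2, V = 0.7)
  expect_equal(unname(growth_law_predict(c(N = 0, V = 0), D)), c(0, 0))
  rates <- growth_law_predict(f0, D)
  back <- growth_law_predict(NULL, D, rates = rates)
  expect_equal(unname(back), unname(f0), tolerance = 1e-10)
})

test_that("hinge regression recovers the heuristic volume-force law", {
  set.seed(6)
  cp <- 0.9; zeta <- 0.3; mu0 <- -2
  grid <- data.table::CJ(mu = seq(-6, 4, by = 1), dp = c(0, 0.5, 1))
  ms <- c("0" = mu0, "0.5" = mu0 + 1, "1" = mu0 + 2)
  grid$mu_star_true <- ms[as.character(grid$dp)]
  grid$fV <- cp * grid$dp +
    zeta * pmax(grid$mu - grid$mu_star_true, 0) + rnorm(nrow(grid), 0, 0.01)
  grid$fN <- grid$mu  # not under test here
  grid$dmu <- grid$mu - mu0
  grid$fV_se <- 0.01
  fl <- fit_force_laws(grid)
  expect_lt(abs(fl$c_p[["value"]] - cp), 3 * fl$c_p[["se"]] + 0.02)
  expect_lt(abs(fl$zeta[["value"]] - zeta), 3 * fl$zeta[["se"]] + 0.02)
  got <- fl$mu_star$mu_star[match(c(0, 0.5, 1), fl$mu_star$dp)]
  expect_equal(got, unname(ms), tolerance = 0.5)
  expect_false(any(fl$mu_star$open))
})

test_that("moment estimators converge at the 1/sqrt(n) rate", {
  drift <- c(0.5, 0.2)
  D0 <- diag(c(1, 1))
  err_at <- function(n) {
    errs <- vapply(1:20, function(r) {
      ens <- generate_synthetic_trajectories(drift, D0, nsamples = n,
                                             tau = 100, seed = 1000 + 37 * r + n)
      fl <- flux_statistics(ens)
      abs(fl$mean_J[["N"]] - drift[1] * 100)
    }, numeric(1))
    mean(errs)
  }
  e_small <- err_at(40)
  e_big <- err_at(640)
  ratio <- e_small / e_big  # expect ~ sqrt(16) = 4
  expect_gt(ratio, 2)
  expect_lt(ratio, 8)
})
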