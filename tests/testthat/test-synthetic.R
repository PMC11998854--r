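# Synthetic-fixture generators: moment correctness and determinism.

test_that("synthetic trajectory ensembles have the specified moments", {
  drift <- c(1, 0.5)
  D0 <- matrix(c(1.5, 0.2, 0.2, 0.8), 2)
  ens <- generate_synthetic_trajectories(drift, D0, nsamples = 300,
                                         tau = 1000, checkpoint_every = 100,
                                         seed = 44)
  fl <- flux_statistics(ens)
  se <- sqrt(diag(fl$Xi) / fl$nsamples)
  expect_lt(abs(fl$mean_J[["N"]] - 1000), 3 * se[1])
  expect_lt(abs(fl$mean_J[["V"]] - 500), 3 * se[2])
  # se of a covariance element: sqrt((D_ii D_jj + D_ij^2)/(n-1))
  se_D <- sqrt(outer(diag(D0), diag(D0)) + D0^2) / sqrt(fl$nsamples - 1)
  expect_true(all(abs(fl$D - D0) < 3 * se_D))
})

test_that("generators are deterministic given the seed", {
  a <- generate_synthetic_trajectories(c(1, 0), diag(2), 10, 100, seed = 7)
  b <- generate_synthetic_trajectories(c(1, 0), diag(2), 10, 100, seed = 7)
  expect_identical(a$records, b$records)
  s1 <- generate_synthetic_spectrum(-1, 30, 20, 15, noise = 0.1, seed = 9)
  s2 <- generate_synthetic_spectrum(-1, 30, 20, 15, noise = 0.1, seed = 9)
  expect_identical(s1$spectrum, s2$spectrum)
  expect_error(generate_synthetic_trajectories(c(1, 0), matrix(c(1, 2, 2, 1), 2),
                                               10, 100),
               "positive definite")
})
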