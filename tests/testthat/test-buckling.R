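# Buckling thresholds, elastothermal number, scaling-function models and
# the morphological phase boundary.

test_that("zero-temperature thresholds match hand arithmetic and scaling", {
  z <- zero_T_thresholds(kappa = 20, Y = 5, R = 10)
  expect_equal(z$gamma_c0, -2)
  expect_equal(z$P_c0, 0.4)
  # sqrt(kappa) scaling: quadrupling kappa doubles both thresholds
  z4 <- zero_T_thresholds(kappa = 80, Y = 5, R = 10)
  expect_equal(z4$gamma_c0, 2 * z$gamma_c0)
  expect_equal(z4$P_c0, 2 * z$P_c0)
  # algebraic identity P_c0 = 2 |gamma_c0| / R on random inputs
  set.seed(2)
  for (i in 1:20) {
    k <- runif(1, 1, 50); y <- runif(1, 1, 100); r <- runif(1, 2, 30)
    zz <- zero_T_thresholds(k, y, r)
    expect_equal(zz$P_c0, 2 * abs(zz$gamma_c0) / r, tolerance = 1e-12)
  }
  expect_error(zero_T_thresholds(-1, 5, 10), "positive")
})

test_that("elastothermal number: value, limits and monotonicity", {
  expect_equal(elastothermal_number(20, 5, 10, kT = 1), 0.25)
  expect_equal(elastothermal_number(20, 5, 10, kT = 0), 0)
  expect_equal(elastothermal_number(20, 5, 20, kT = 1),
               2 * elastothermal_number(20, 5, 10, kT = 1))
  expect_gt(elastothermal_number(20, 10, 10), elastothermal_number(20, 5, 10))
  expect_lt(elastothermal_number(40, 5, 10), elastothermal_number(20, 5, 10))
})

test_that("finite-temperature threshold magnitude is reduced by Psi", {
  # Psi == 1 reduces to the zero-temperature threshold
  b0 <- finite_T_critical_tension(20, 5, 10, psi_model = psi_zero_t())
  expect_equal(b0$gamma_c, b0$gamma_c0)
  # zero temperature: ET = 0 and Psi(0) = 1
  bz <- finite_T_critical_tension(20, 5, 10, kT = 0)
  expect_equal(bz$gamma_c, bz$gamma_c0)
  # default model: |gamma_c| <= |gamma_c0|, monotone in ET
  b1 <- finite_T_critical_tension(20, 5, 5)
  expect_gt(b1$ET, 0)
  expect_lte(abs(b1$gamma_c), abs(b1$gamma_c0))
  expect_gte(abs(finite_T_critical_tension(20, 5, 5)$psi),
             abs(finite_T_critical_tension(20, 5, 15)$psi))
  # classification
  bb <- finite_T_critical_tension(20, 5, 10, measured_gamma = -5)
  expect_true(bb$buckled)
  bs <- finite_T_critical_tension(20, 5, 10, measured_gamma = 0.2)
  expect_false(bs$buckled)
})

test_that("psi models are validated", {
  expect_error(psi_table(c(0, 1, 2), c(1, 1.2, 0.5)), "monotonic")
  expect_error(psi_table(c(0, 1, 2), c(1, 0.5, -0.1)), "in \\(0, 1\\]")
  pt <- psi_table(c(0, 1, 2, 5), c(1, 0.8, 0.6, 0.3))
  expect_equal(pt(1.5), 0.7)
  expect_equal(pt(100), 0.3)  # clamped beyond the table
  bad <- function(x) 1 + x   # increasing: invalid
  expect_error(finite_T_critical_tension(20, 5, 10, psi_model = bad),
               "monotonically")
})

test_that("buckling classification is invariant under unit rescaling", {
  # l0 -> lambda l0: gamma, Y scale as lambda^-2, R as lambda
  lam <- 3
  b1 <- finite_T_critical_tension(20, 8, 10, measured_gamma = -1.2)
  b2 <- finite_T_critical_tension(20, 8 / lam^2, 10 * lam,
                                  measured_gamma = -1.2 / lam^2)
  expect_equal(b2$ET, b1$ET, tolerance = 1e-12)
  expect_equal(b2$gamma_c * lam^2, b1$gamma_c, tolerance = 1e-12)
  expect_identical(b2$buckled, b1$buckled)
})

test_that("phase diagram locates a constructed linear crossing exactly", {
  # gamma = gamma_eq + c_gamma * dmu with constant gamma_c: analytic crossing
  c_gamma <- -0.5
  gamma_eq <- 0.4
  gamma_c <- -1.1
  dmu_star_true <- (gamma_c - gamma_eq) / c_gamma  # = 3
  tbl <- data.table::CJ(dmu = seq(0, 6, by = 0.5), dp = c(0, 0.3))
  tbl$gamma <- gamma_eq + c_gamma * tbl$dmu + ifelse(tbl$dp > 0, 0.25, 0)
  tbl$gamma_c <- gamma_c
  pd <- phase_diagram(tbl)
  b0 <- pd$boundary[pd$boundary$dp == 0, ]
  expect_equal(b0$dmu_star, dmu_star_true, tolerance = 1e-9)
  # higher pressure raises gamma_eq, shifting the crossing to larger dmu
  b1 <- pd$boundary[pd$boundary$dp == 0.3, ]
  expect_gt(b1$dmu_star, b0$dmu_star)
  # bracketing: the interpolated crossing separates the sign change
  g <- tbl[tbl$dp == 0, ]
  below <- max(g$dmu[g$gamma > gamma_c])
  expect_true(b0$dmu_star >= below - 0.5 && b0$dmu_star <= below + 0.5)
  # no crossing -> open boundary; empty input -> error
  tbl2 <- tbl[tbl$dmu <= 1, ]
  pd2 <- phase_diagram(tbl2)
  expect_true(all(pd2$boundary$open))
  expect_error(phase_diagram(tbl[0, ]), "empty")
})
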