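# Poroelastic constitutive relations: porosity kinematics, the
# microvascular pressure-volume law, the compaction barrier and
# permeability scaling.

test_that("Lagrangian porosity follows matrix incompressibility", {
  expect_equal(lagrangian_porosity(1, 0.06), 0.06)
  expect_equal(lagrangian_porosity(1.01, 0.06), 0.07)
  expect_equal(lagrangian_porosity(0.95, 0.06), 0.01)
  expect_error(lagrangian_porosity(0.9, 0.06), "compaction")
  # Eulerian porosity stays below 1 for any J
  for (J in c(0.95, 1, 1.5, 5, 50)) {
    jphi <- lagrangian_porosity(J, 0.06)
    expect_lt(jphi / J, 1)
  }
})

test_that("microvascular pressure matches the rest condition and direct evaluation", {
  pp <- porous_params()
  # p_o = q1 e^{q3 phi0} + q2 ln(q3 phi0), evaluated independently
  expect_equal(pp$p_o, 0.022 * exp(4.8) + 1.009 * log(4.8),
               tolerance = 1e-12)
  expect_equal(pp$p_o, 4.2560, tolerance = 1e-4)
  # zero at the reference porosity (barrier inactive there by default)
  expect_equal(microvascular_pressure(pp$phi0, pp), 0, tolerance = 1e-12)
  # direct evaluation above reference (barrier off for jphi > phi_crit)
  expect_equal(microvascular_pressure(0.066, pp),
               0.022 * exp(80 * 0.066) + 1.009 * log(80 * 0.066) - pp$p_o,
               tolerance = 1e-12)
  expect_equal(microvascular_pressure(0.066, pp), 1.7430,
               tolerance = 1e-3)
  expect_error(microvascular_pressure(-0.01, pp), "positive")
})

test_that("microvascular pressure is strictly increasing", {
  pp <- porous_params()
  grid <- seq(0.005, 0.2, length.out = 400)
  p <- microvascular_pressure(grid, pp)
  expect_true(all(diff(p) > 0))
})

test_that("compaction barrier activates below phi_crit and diverges at compaction", {
  pp <- porous_params()
  expect_equal(barrier_pressure(pp$phi_crit, pp), 0)
  expect_equal(barrier_pressure(2 * pp$phi_crit, pp), 0)
  # barrier pressure is negative when active and its magnitude grows
  # without bound as Jphi -> 0 (fluid extraction prevented)
  seqk <- pp$phi_crit / 2^(1:10)
  b <- barrier_pressure(seqk, pp)
  expect_true(all(b < 0))
  expect_true(all(diff(abs(b)) > 0))
  expect_gt(abs(b[10]), 1e3 * abs(b[1]))
  expect_lt(microvascular_pressure(pp$phi_crit / 2^10, pp),
            -1e2) # total pressure strongly negative near compaction
})

test_that("barrier keeps pressure continuous at phi_crit; derivative continuous for q_exp >= 2", {
  pp <- porous_params()
  eps <- 1e-9
  expect_equal(microvascular_pressure(pp$phi_crit - eps, pp),
               microvascular_pressure(pp$phi_crit + eps, pp),
               tolerance = 1e-6)
  pp2 <- porous_params(q_exp = 2L)
  h <- 1e-7
  dp_below <- (microvascular_pressure(pp2$phi_crit - h, pp2) -
                 microvascular_pressure(pp2$phi_crit - 2 * h, pp2)) / h
  dp_above <- (microvascular_pressure(pp2$phi_crit + 2 * h, pp2) -
                 microvascular_pressure(pp2$phi_crit + h, pp2)) / h
  expect_equal(dp_below, dp_above, tolerance = 1e-3)
})

test_that("permeability scaling matches both modes and their ordering", {
  expect_equal(permeability_scale(1, 0.06, 0.06, "isotropic"), 1)
  expect_equal(permeability_scale(1, 0.06, 0.06, "length-preserving"), 1)
  # deformed state with Jphi = 0.16 at J = 1.1
  J <- 1.1; phi <- 0.16 / 1.1
  expect_equal(permeability_scale(J, phi, 0.06, "isotropic"),
               1.1 * (0.16 / 1.1)^2 / 0.06^2, tolerance = 1e-12)
  expect_equal(permeability_scale(J, phi, 0.06, "isotropic"), 6.4646,
               tolerance = 1e-4)
  expect_equal(permeability_scale(J, phi, 0.06, "length-preserving"),
               (0.16 / 0.06)^2, tolerance = 1e-12)
  # isotropic <= length-preserving whenever J >= 1 (bounds on scaling)
  for (J in c(1, 1.05, 1.2, 2)) {
    jphi <- lagrangian_porosity(J, 0.06)
    phi <- jphi / J
    expect_lte(permeability_scale(J, phi, 0.06, "isotropic"),
               permeability_scale(J, phi, 0.06, "length-preserving") +
                 1e-12)
  }
})

test_that("added fluid mass is linear in porosity and invertible", {
  pp <- porous_params()
  expect_equal(fluid_mass(0.06, pp), 0)
  expect_equal(fluid_mass(0.07, pp), 1.05e-8, tolerance = 1e-15)
  jphi <- c(0.01, 0.06, 0.123)
  expect_equal(porosity_from_mass(fluid_mass(jphi, pp), pp), jphi,
               tolerance = 1e-12)
})

test_that("pressure-porosity inversion round-trips", {
  pp <- porous_params()
  p <- c(-0.5, 0, 2, 8, 15)
  jphi <- porosity_from_pressure(p, pp)
  expect_equal(microvascular_pressure(jphi, pp), p, tolerance = 1e-8)
})
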