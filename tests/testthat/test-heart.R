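# Ventricle, active stress, valve, windkessel and mitral models.

hp <- heart_params()

test_that("active stress twitch has the right zeros and magnitude", {
  expect_equal(active_stress(0, 0, 1, hp), 0)
  expect_equal(active_stress(hp$t_max, 0, 1, hp), 0)
  # no length-dependent activation at lambda = a7
  expect_equal(active_stress(0.15, 0, hp$a7, hp), 0)
  # direct evaluation of the twitch law at t_c = 0.15, lambda = 1
  phi <- tanh(2 * (1 - 0.7)); tr <- 0.16 + 3.2 * (1 - phi)
  ref <- 15000 * phi * tanh(0.15 / tr)^2 * tanh((0.3 - 0.15) / 0.03)^2
  expect_equal(active_stress(0.15, 0, 1, hp, scaled = FALSE), ref,
               tolerance = 1e-12)
  expect_equal(ref, 66.9, tolerance = 1e-2)
  # clipped to zero beyond the activation duration
  expect_equal(active_stress(0.35, 0, 1, hp), 0)
  # periodic wrap: same phase one period later
  expect_equal(active_stress(0.15 + hp$t_period, 0, 1, hp),
               active_stress(0.15, 0, 1, hp))
})

test_that("spherical equilibrium reproduces the closed-form uniform-stress solution", {
  eq0 <- lv_equilibrium(hp$V0_cav, rep(0, 3), hp)
  expect_equal(eq0$P_lv, 0)
  expect_equal(eq0$p_imp, rep(0, 3))

  g <- sphere_geometry(hp$V0_cav, hp)
  sig <- 40
  eq <- lv_equilibrium(hp$V0_cav, rep(sig, 3), hp)
  expect_equal(eq$P_lv, 2 * sig * log(g$r[4] / g$r[1]), tolerance = 1e-12)
  # p_imp at layer midpoints follows 2 sigma ln(r_epi / r_mid)
  expect_equal(eq$p_imp, 2 * sig * log(g$r[4] / g$r_mid),
               tolerance = 1e-12)
  # transmural gradient: subendo >= mid >= subepi, bounded by P_lv and 0
  expect_true(all(diff(eq$p_imp) < 0))
  expect_lt(eq$p_imp[1], eq$P_lv)
  expect_gt(eq$p_imp[3], 0)
  expect_error(sphere_geometry(-1, hp), "positive")
})

test_that("aortic valve relaxes exponentially and respects angle limits", {
  expect_equal(valve_area_ratio(0, hp$theta_max), 0)
  expect_equal(valve_area_ratio(hp$theta_max, hp$theta_max), 1)

  # stationary when pressures balance and the leaflet is at rest
  st <- list(theta = 0.5, dtheta = 0, Q_ao = 0)
  st2 <- aortic_valve_step(st, 10, 10, 1e-4, hp)
  expect_equal(st2$theta, 0.5, tolerance = 1e-12)

  # fully open, constant positive gradient: exact exponential relaxation
  # of Q_ao toward the orifice steady flow with time constant T_ao
  dP <- 2
  Q_ss <- hp$CQ_ao * 1 * sqrt(dP)
  st <- list(theta = hp$theta_max, dtheta = 0, Q_ao = 0)
  dt <- 1e-4
  for (k in 1:100) st <- aortic_valve_step(st, 10 + dP, 10, dt, hp,
                                           P_torque = 10 + dP)
  expect_equal(st$Q_ao, Q_ss * (1 - exp(-100 * dt / hp$T_ao)),
               tolerance = 1e-9)
  expect_equal(st$theta, hp$theta_max) # clamped at full opening
})

test_that("windkessel fixed point, decay constant and algebraic identity", {
  # steady Q = 1000 mm^3/s: P_s -> R_s Q, P_as -> (R_a + R_s) Q
  P_s <- 0
  for (k in 1:4e4) {
    wk <- windkessel_step(P_s, 1000, 1e-3, hp)
    P_s <- wk$P_s
  }
  expect_equal(P_s, 0.22, tolerance = 1e-6)
  expect_equal(wk$P_as, 0.232, tolerance = 1e-6)

  # zero flow: exponential decay with tau = R_s C = 1.54 s (exact update)
  wk <- windkessel_step(10, 0, 0.5, hp)
  expect_equal(wk$P_s, 10 * exp(-0.5 / (hp$R_s * hp$C)), tolerance = 1e-12)
  expect_equal(hp$R_s * hp$C, 1.54)

  # P_as - P_s = R_a Q_ao identically
  for (Q in c(-2e4, 0, 3e5)) {
    wk <- windkessel_step(5, Q, 1e-4, hp)
    expect_equal(wk$P_as - wk$P_s, hp$R_a * Q, tolerance = 1e-12)
  }
})

test_that("mitral flow has a dead branch, tanh shape and saturation", {
  expect_equal(mitral_flow(1, 1.5, hp), 0)
  expect_equal(mitral_flow(1, 1, hp), 0)
  expect_equal(mitral_flow(1.01, 1, hp), 2e5 * tanh(0.375),
               tolerance = 1e-9)
  expect_equal(mitral_flow(1.01, 1, hp), 7.17e4, tolerance = 1e-3)
  expect_equal(mitral_flow(100, 0, hp), 2e5, tolerance = 1e-3)
})

test_that("cavity volume balance integrates mitral and aortic flows", {
  expect_equal(cavity_volume_update(1e5, 500, 500, 1e-3), 1e5)
  expect_equal(cavity_volume_update(1e5, 0, 2e4, 0.1), 1e5 - 2e3)
  expect_error(cavity_volume_update(1, 0, 1e6, 1), "non-positive")
})

test_that("passive stiffness calibration hits the end-diastolic preload", {
  lam <- layer_stretch(hp$EDV_target, hp)
  P <- lv_pressure_from_stress(hp$EDV_target, passive_wall_stress(lam, hp),
                               hp)
  expect_equal(P, hp$P_la, tolerance = 1e-7)
  expect_equal(passive_wall_stress(1, hp), 0)
})

test_that("peak intramyocardial and cavity pressures can decouple in time", {
  # slow-relaxation parameter set: peak subendocardial p_imp occurs later
  # than peak P_lv because intramyocardial stress keeps rising while the
  # windkessel drains the ejected volume
  hps <- heart_params(t_d = 0.1, t_max = 0.4)
  st <- heart_init(hps)
  n <- round(6 * hps$t_period / 1e-4)
  plv <- numeric(8000); pimp <- numeric(8000)
  for (k in 1:n) {
    st <- heart_step(st, ((k - 1) * 1e-4) %% hps$t_period, 1e-4, hps)
    if (k > n - 8000) {
      plv[k - (n - 8000)] <- st$P_lv
      pimp[k - (n - 8000)] <- st$p_imp[1]
    }
  }
  t_peak_plv <- which.max(plv) * 1e-4
  t_peak_pimp <- which.max(pimp) * 1e-4
  expect_gt(abs(t_peak_pimp - t_peak_plv), 0.02)
})
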