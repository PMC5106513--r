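# 1D network solver: fixed points, viscous limit, linear wave theory and
# boundary treatment.

test_that("terminal flux is linear and resistive", {
  expect_equal(terminal_flux(5, 5, 1e-3), 0)
  expect_equal(terminal_flux(6, 5, 1e-3), 1000)
  expect_equal(terminal_flux(6, 5, 1e-2), 100) # tenfold R -> tenth flux
  expect_error(terminal_flux(1, 0, -1), "positive")
})

test_that("uniform equilibrium state is a fixed point of the solver", {
  net <- single_segment_network()
  fs <- flow_solver(net, dx_target = 2.5)
  fs2 <- fs
  for (k in 1:50) fs2 <- step_network(fs2, 0, 0, 1e-4)
  expect_equal(fs2$A, fs$A, tolerance = 1e-14)
  expect_equal(max(abs(fs2$Q)), 0, tolerance = 1e-12)
})

test_that("steady viscous flow reproduces the closed-form pressure gradient", {
  net <- single_segment_network(len = 200)
  fs <- flow_solver(net, dx_target = 2.5)
  # start from the approximate steady solution (linear pressure drop,
  # uniform flow) and let the solver relax the remainder
  R_tot <- fs$fluid$rho * fs$K[1] * 200 / fs$A0[1]^2 + net$R_term[1]
  Q0 <- 2 / R_tot
  x <- cumsum(c(0, fs$dx[-fs$total]))
  p_lin <- 2 - (2 - Q0 * net$R_term[1]) * x / 200
  fs$A <- (p_lin / fs$beta + fs$sqrtA0)^2
  fs$Q <- rep(Q0, fs$total)
  for (k in 1:6000) fs <- step_network(fs, 2, 0, 1e-4)
  p <- flow_pressure(fs)
  i <- 30:50 # interior nodes away from both ends
  dpdx <- (p[i + 1] - p[i - 1]) / (2 * fs$dx[i])
  pred <- -fs$fluid$rho * fs$K[i] * fs$Q[i] / fs$A[i]^2
  expect_lt(max(abs(dpdx / pred - 1)), 0.01)
  # flow is uniform along the segment at steady state
  expect_lt(stats::sd(fs$Q) / mean(fs$Q), 0.01)
})

test_that("small pulses propagate at the tube-law wave speed", {
  fl <- fluid_props(mu = 1e-12) # inviscid limit isolates wave kinematics
  net <- single_segment_network(len = 400, fluid = fl)
  fs <- flow_solver(net, fluid = fl, dx_target = 1)
  fs <- seed_forward_pulse(fs, centre = 100, width = 12, amp = 1e-4)
  qpeak <- function(fs) { # sub-grid peak location by quadratic fit
    i <- which.max(fs$A)
    a <- fs$A[(i - 1):(i + 1)]
    ((i - 1) + 0.5 * (a[1] - a[3]) / (a[1] - 2 * a[2] + a[3])) * fs$dx[1]
  }
  x0 <- qpeak(fs)
  nst <- 300; dt <- 5e-5
  for (k in 1:nst) fs <- step_network(fs, 0, 0, dt)
  speed <- (qpeak(fs) - x0) / (nst * dt)
  expect_lt(abs(speed / 15000 - 1), 0.01)
})

test_that("junction reflections agree with the linearised coefficients", {
  fl <- fluid_props(mu = 1e-12)
  run_refl <- function(dA) {
    net <- bifurcation_network(dA, fluid = fl)
    fs <- flow_solver(net, fluid = fl, dx_target = 1)
    idx1 <- fs$first[1]:fs$last[1]
    fs <- seed_forward_pulse(fs, centre = 150, width = 8, amp = 1e-4,
                             nodes = idx1)
    pk_in <- max(flow_pressure(fs))
    for (k in 1:200) fs <- step_network(fs, 0, 0, 5e-5) # 10 ms
    pp <- flow_pressure(fs)[idx1]
    w <- 121:241 # reflected wave region, clear of the seeding tail
    pp[w][which.max(abs(pp[w]))] / pk_in
  }
  # matched junction (daughters of half area): essentially no reflection
  expect_lt(abs(run_refl(0.5)), 1e-3)
  # area-doubling junction: R_f = -1/3 within 5%
  expect_equal(run_refl(1), -1 / 3, tolerance = 0.05 / 3 * 3)
})

test_that("solve_junction passes identical states through a trivial junction", {
  end <- list(A = 1.02, Q = 150, A0 = 1, beta = 472.5)
  r <- solve_junction(end, list(end))
  expect_equal(r$parent$A, 1.02, tolerance = 1e-10)
  expect_equal(r$parent$Q, 150, tolerance = 1e-6)
  expect_equal(r$daughters[[1]]$A, 1.02, tolerance = 1e-10)
  # mass and total pressure conserved at a bifurcation solve
  d <- list(A = 0.98, Q = 40, A0 = 1, beta = 472.5)
  r2 <- solve_junction(end, list(d, d))
  fl <- fluid_props()
  expect_equal(r2$parent$Q,
               r2$daughters[[1]]$Q + r2$daughters[[2]]$Q,
               tolerance = 1e-6)
  tp <- function(e) 472.5 * (sqrt(e$A) - 1) +
    0.5 * fl$rho * (e$Q / e$A)^2
  expect_equal(tp(r2$parent), tp(r2$daughters[[1]]), tolerance = 1e-9)
})

test_that("pressure-clamped inlet holds equilibrium and launches forward waves", {
  net <- single_segment_network(len = 300)
  fs <- flow_solver(net, dx_target = 2)
  # equilibrium pressurised state with matching inlet and terminal sink
  p0 <- 5
  fs$A <- (p0 / fs$beta + fs$sqrtA0)^2
  fs_eq <- fs
  for (k in 1:200) fs_eq <- step_network(fs_eq, p0, p0, 1e-4)
  expect_lt(abs(fs_eq$Q[fs_eq$root_node]), 1e-6)

  # step increase in inlet pressure: forward compression wave, dI+ > 0
  probe <- probe_node(fs, 60)
  pr <- c(); Ur <- c()
  fs2 <- fs
  for (k in 1:120) {
    fs2 <- step_network(fs2, p0 + 1, p0, 1e-4)
    pr <- c(pr, flow_pressure(fs2)[probe])
    Ur <- c(Ur, fs2$Q[probe] / fs2$A[probe])
  }
  inc <- wia_increments(pr, Ur, smoothing = "raw")
  sep <- wia_separate(inc$dp, inc$dU, 1.05e-6, 15000)
  expect_gt(max(sep$dIp), 1e-6)
  expect_gt(max(sep$dIp), 100 * max(abs(sep$dIm)))
})

test_that("network volume ledger closes over a transient", {
  net <- generate_tree(16, seed = 4)
  fs <- flow_solver(net, dx_target = 3)
  v0 <- network_volume(fs)
  inflow <- 0; outflow <- 0
  dt <- 1e-4
  for (k in 1:2000) {
    fs <- step_network(fs, 6, 1, dt)
    inflow <- inflow + fs$Q[fs$root_node] * dt
    outflow <- outflow + sum(fs$Q[fs$term_node]) * dt
  }
  dv <- network_volume(fs) - v0
  expect_lt(abs(inflow - outflow - dv) / max(abs(inflow), 1e-9), 0.01)
})
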