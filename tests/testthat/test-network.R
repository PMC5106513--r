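# Tree generation, tube-law relations, friction and reflection
# coefficients.

test_that("wave speed follows the tube-law relation", {
  expect_equal(wave_speed(472.5, 1, 1.05e-6), 15000)
  # c scales with sqrt(beta) at fixed area
  expect_equal(wave_speed(2 * 472.5, 1) / wave_speed(472.5, 1), sqrt(2))
  # quarter-power law: A -> 16 A doubles c
  expect_equal(wave_speed(472.5, 16) / wave_speed(472.5, 1), 2)
})

test_that("stiffness from wave speed inverts the wave-speed relation", {
  expect_equal(stiffness_from_wavespeed(15000, 1, 1.05e-6), 472.5)
  expect_equal(stiffness_from_wavespeed(15000, 4, 1.05e-6), 236.25)
  for (A0 in c(0.5, 1, 2, 7)) {
    beta <- stiffness_from_wavespeed(12000, A0, 1.05e-6)
    expect_equal(wave_speed(beta, A0, 1.05e-6), 12000,
                 tolerance = 1e-12)
  }
})

test_that("friction coefficient matches the profile-parameter law", {
  expect_equal(friction_coefficient(1.05, 3.2), 2 * pi * 1.05 * 3.2 / 0.05)
  expect_equal(friction_coefficient(1.05, 3.2), 422.23, tolerance = 1e-4)
  # alpha 1.05 -> 1.1 approximately halves the friction coefficient
  expect_equal(friction_coefficient(1.1, 1) / friction_coefficient(1.05, 1),
               11 / 21, tolerance = 1e-12)
  # parabolic profile recovers the classical 8 pi nu
  expect_equal(friction_coefficient(4 / 3, 2.5), 8 * pi * 2.5,
               tolerance = 1e-12)
  expect_error(friction_coefficient(1, 3.2), "alpha")
})

test_that("junction reflection coefficients match linear theory", {
  # matched junction: daughters of half the parent area, uniform c
  expect_equal(reflection_coefficient(c(1, 15000), c(0.5, 15000),
                                      c(0.5, 15000)), 0)
  # area-doubling junction
  expect_equal(reflection_coefficient(c(1, 15000), c(1, 15000),
                                      c(1, 15000)), -1 / 3)
  expect_equal(reflection_coefficient(c(1, 15000), c(1, 15000),
                                      c(1, 15000), "backward-from-d1"),
               -1 / 3)
  # any admittances give a coefficient in [-1, 1]
  set.seed(42)
  for (k in 1:20) {
    a <- runif(3, 0.2, 4)
    r <- reflection_coefficient(c(a[1], 15000), c(a[2], 15000),
                                c(a[3], 15000))
    expect_true(r >= -1 && r <= 1)
  }
})

test_that("generator reproduces morphometry targets and is deterministic", {
  # degenerate tree: one terminal, deterministic budget
  net1 <- generate_tree(1, target_mean_path = 110, target_sd_path = 0,
                        seed = 7)
  expect_equal(nrow(net1), 1L)
  expect_equal(network_morphometry(net1)$mean_path_length, 110)

  # scaled tree: mean within 5% over a few seeds (module-level check;
  # the full-scale morphometry is exercised in the acceptance suite)
  ms <- vapply(1:3, function(s)
    network_morphometry(generate_tree(256, seed = s))$mean_path_length,
    numeric(1))
  expect_lt(abs(mean(ms) / 110 - 1), 0.05)

  a <- generate_tree(64, seed = 2)
  b <- generate_tree(64, seed = 2)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # uniform unstressed area everywhere
  expect_true(all(a$A0 == a$A0[1]))
  expect_error(generate_tree(8, target_sd_path = 100), "infeasible")
})

test_that("uniform-wave-speed trees have bounded forward and mostly negative backward reflections", {
  net <- generate_tree(64, seed = 3)
  refl <- network_reflections(net)
  expect_true(all(refl$R_forward >= -1 & refl$R_forward <= 1))
  # expanding area ratio at every bifurcation: backward coefficients
  # negative
  expect_true(mean(refl$R_backward < 0) > 0.9)
})

test_that("network CSV round-trip preserves the segment table", {
  net <- generate_tree(16, seed = 5)
  f <- tempfile(fileext = ".csv")
  write_network(net, f)
  net2 <- read_network(f)
  expect_equal(as.data.frame(net)$length, net2$length, tolerance = 1e-12)
  expect_equal(attr(net2, "c0"), attr(net, "c0"))
  expect_equal(network_morphometry(net2)$mean_path_length,
               network_morphometry(net)$mean_path_length,
               tolerance = 1e-10)
  unlink(c(f, paste0(f, ".json")))
})

test_that("main path runs from the root to a terminal", {
  net <- generate_tree(32, seed = 1)
  path <- main_path(net)
  expect_equal(net$parent[net$id == path[1]], 0L)
  expect_true(net$terminal[net$id == path[length(path)]])
  # consecutive path elements are parent-child pairs
  for (i in seq_len(length(path) - 1))
    expect_equal(net$parent[net$id == path[i + 1]], path[i])
})
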