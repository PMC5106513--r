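# Hand-built miniature networks and a memoised baseline simulation shared
# across test files.

# A single straight vessel acting as both root and terminal.
single_segment_network <- function(len = 400, A0 = 1, beta = 472.5,
                                   alpha = 1.05, R_term = 0.01575,
                                   fluid = fluid_props()) {
  seg <- data.frame(id = 1L, parent = 0L, length = len, A0 = A0,
                    beta = beta, alpha = alpha, R_term = R_term,
                    terminal = TRUE, sector = 1L, layer = 1L,
                    path_length = len)
  structure(seg, class = c("coronary_network", "data.frame"),
            fluid = fluid, c0 = wave_speed(beta, A0, fluid$rho))
}

# Parent of area 1 splitting into two daughters of area `dA` each, all at
# a uniform 15 m/s wave speed. Large R_term keeps the daughters
# effectively closed so reflections can be observed cleanly.
bifurcation_network <- function(dA = 1, lengths = c(250, 200, 200),
                                fluid = fluid_props(), R_term = 1e9) {
  A0 <- c(1, dA, dA)
  seg <- data.frame(id = 1:3, parent = c(0L, 1L, 1L), length = lengths,
                    A0 = A0,
                    beta = stiffness_from_wavespeed(15000, A0, fluid$rho),
                    alpha = 1.05,
                    R_term = ifelse(c(FALSE, TRUE, TRUE), R_term, NA),
                    terminal = c(FALSE, TRUE, TRUE), sector = 1L,
                    layer = 1L, path_length = cumsum(lengths))
  structure(seg, class = c("coronary_network", "data.frame"),
            fluid = fluid, c0 = 15000)
}

# Launch a small forward-travelling simple-wave pulse into a flow state.
seed_forward_pulse <- function(fs, centre, width, amp, nodes = NULL) {
  if (is.null(nodes)) nodes <- seq_len(fs$total)
  x <- cumsum(c(0, fs$dx[nodes[-length(nodes)]]))
  fs$A[nodes] <- fs$A0[nodes] + amp * exp(-((x - centre) / width)^2)
  c0v <- fs$cwave[nodes] * fs$A0[nodes]^0.25
  fs$Q[nodes] <- fs$A[nodes] *
    4 * (fs$cwave[nodes] * fs$A[nodes]^0.25 - c0v)
  fs
}

# Memoised baseline limit-cycle simulation (32-terminal tree, default
# configuration), shared by the integrated and acceptance tests.
.corowave_test_cache <- new.env(parent = emptyenv())

baseline_sim <- function() {
  if (is.null(.corowave_test_cache$baseline)) {
    .corowave_test_cache$baseline <- suppressWarnings(
      simulate_perfusion(default_config(32, 1), n_cycles = 10))
  }
  .corowave_test_cache$baseline
}
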