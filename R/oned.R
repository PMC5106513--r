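# One-dimensional pulse-wave solver on the coronary tree.
#
# Conservation system per segment (area A, flow Q):
#   dA/dt + dQ/dx = 0
#   dQ/dt + d/dx( alpha Q^2/A + beta/(3 rho) A^{3/2} ) = -K Q/A
# with tube law p = beta (sqrt(A) - sqrt(A0)) and wave speed
# c = sqrt(beta/(2 rho)) A^{1/4}. Discretised with the two-step
# (Richtmyer) Lax-Wendroff scheme on per-segment grids; segment ends are
# coupled through characteristic invariants (u +/- 4c): a pressure-clamp
# inlet at the root (fully reflecting for backward waves), Newton solves
# enforcing mass and total-pressure continuity at junctions, and resistive
# terminal boundaries Q = (p - pbar) / R_term into the tissue.

#' Build a 1D flow solver for a coronary network
#'
#' Precomputes per-segment grids, index sets for the vectorised interior
#' update, and junction/terminal tables, and initialises the state at the
#' unstressed area with zero flow.
#'
#' @param network A [generate_tree()] / [read_network()] network.
#' @param fluid Blood properties ([fluid_props()]); defaults to the
#'   network attribute.
#' @param dx_target Target grid spacing (mm); each segment gets at least
#'   `n_min_nodes` nodes.
#' @param n_min_nodes Minimum nodes per segment (>= 3).
#' @param cfl Courant number used to derive the stable internal sub-step.
#' @return An object of class `flow_state` (a list of geometry, constants
#'   and the current `A`, `Q` fields).
#' @export
flow_solver <- function(network, fluid = attr(network, "fluid"),
                        dx_target = 2.5, n_min_nodes = 4, cfl = 0.8) {
  stopifnot(n_min_nodes >= 3)
  if (is.null(fluid)) fluid <- fluid_props()
  ns <- nrow(network)
  n_nodes <- pmax(n_min_nodes, ceiling(network$length / dx_target) + 1L)
  offset <- c(0L, cumsum(n_nodes))[seq_len(ns)]
  total <- sum(n_nodes)
  dx_seg <- network$length / (n_nodes - 1L)

  seg_of <- rep.int(seq_len(ns), n_nodes)
  dx <- dx_seg[seg_of]
  beta <- network$beta[seg_of]
  A0 <- network$A0[seg_of]
  alpha <- network$alpha[seg_of]
  K <- friction_coefficient(network$alpha, fluid$nu)[seg_of]

  first <- offset + 1L
  last <- offset + n_nodes

  # Interior nodes and the index of the pair (interface) to their left.
  # Pairs are consecutive in-segment node pairs (i, i+1).
  pairL <- unlist(lapply(seq_len(ns), function(s)
    (offset[s] + 1L):(offset[s] + n_nodes[s] - 1L)))
  int_nodes <- unlist(lapply(seq_len(ns), function(s)
    if (n_nodes[s] > 2L) (offset[s] + 2L):(offset[s] + n_nodes[s] - 1L)
    else integer(0)))
  # pair index (position within pairL) of interface (j-1, j) for node j:
  pair_pos <- integer(total)
  pair_pos[pairL + 1L] <- seq_along(pairL) # interface left of node pairL+1
  int_pL <- pair_pos[int_nodes]
  int_pR <- int_pL + 1L # next interface within the same segment

  ch <- network_children(network)
  root <- which(network$parent == 0L)
  if (length(root) != 1L) stop("network must have a single root")
  bif <- which(!network$terminal &
                 vapply(ch, length, integer(1)) == 2L)
  uni <- which(!network$terminal &
                 vapply(ch, length, integer(1)) == 1L)
  term <- which(network$terminal)

  jtab <- function(idx) {
    if (!length(idx)) return(NULL)
    d1 <- vapply(ch[idx], `[`, integer(1), 1L)
    list(pe = last[idx], pn = last[idx] - 1L,
         d1s = first[d1], d1n = first[d1] + 1L,
         d2s = if (all(vapply(ch[idx], length, integer(1)) == 2L)) {
           d2 <- vapply(ch[idx], `[`, integer(1), 2L); first[d2]
         } else NULL,
         d2n = if (!is.null(idx) && length(idx) &&
                   all(vapply(ch[idx], length, integer(1)) == 2L)) {
           d2 <- vapply(ch[idx], `[`, integer(1), 2L); first[d2] + 1L
         } else NULL)
  }

  fs <- list(
    network = network, fluid = fluid, rho = fluid$rho,
    n_seg = ns, n_nodes = n_nodes, offset = offset, total = total,
    seg_of = seg_of, dx = dx, beta = beta, A0 = A0, sqrtA0 = sqrt(A0),
    alpha = alpha, K = K,
    cwave = sqrt(beta / (2 * fluid$rho)), # c = cwave * A^(1/4)
    fcoef = beta / (3 * fluid$rho),       # pressure-flux coefficient
    first = first, last = last,
    pairL = pairL, pairR = pairL + 1L,
    int_nodes = int_nodes, int_pL = int_pL, int_pR = int_pR,
    root_node = first[root], root_nb = first[root] + 1L,
    bif = jtab(bif), uni = jtab(uni),
    term_node = last[term], term_nb = last[term] - 1L,
    term_R = network$R_term[term], term_seg = term,
    cfl = cfl,
    A = A0, # start at unstressed area
    Q = numeric(total),
    t = 0
  )
  fs$dt_stable <- cfl * min(dx) / (max(fs$cwave * fs$A0^0.25) * 1.25)
  class(fs) <- "flow_state"
  fs
}

#' Nodal pressure of a flow state
#' @param fs A `flow_state`.
#' @return Pressure (kPa) at every grid node.
#' @export
flow_pressure <- function(fs) fs$beta * (sqrt(fs$A) - fs$sqrtA0)

#' Resistive terminal flux into the tissue
#'
#' `Q = (p_1D - pbar) / R_term`; positive flux leaves the 1D network.
#'
#' @param p_1D Terminal 1D pressure (kPa).
#' @param p_bar Mean feeding (tissue) pressure (kPa).
#' @param R_term Terminal resistance (kPa s mm^-3, > 0).
#' @return Flux (mm^3 s^-1).
#' @export
terminal_flux <- function(p_1D, p_bar, R_term) {
  if (any(R_term <= 0)) stop("R_term must be positive")
  (p_1D - p_bar) / R_term
}

# Linear interpolation of (A, Q) at the foot of the characteristic
# leaving the domain through a boundary node. `node` is the boundary node,
# `nb` its interior neighbour, `lam` the (positive) distance travelled.
.char_foot <- function(fs, node, nb, lam) {
  frac <- pmin(1, lam / fs$dx[node])
  list(A = fs$A[node] * (1 - frac) + fs$A[nb] * frac,
       Q = fs$Q[node] * (1 - frac) + fs$Q[nb] * frac)
}

# Outgoing characteristic invariants at segment ends.
# Right end (flow leaves segment): W+ = u + 4c evaluated at the foot.
.invariant_right <- function(fs, node, nb, dt) {
  u <- fs$Q[node] / fs$A[node]
  c <- fs$cwave[node] * fs$A[node]^0.25
  ft <- .char_foot(fs, node, nb, pmax(0, (u + c) * dt))
  cf <- fs$cwave[node] * ft$A^0.25
  ft$Q / ft$A + 4 * cf
}
# Left end: W- = u - 4c.
.invariant_left <- function(fs, node, nb, dt) {
  u <- fs$Q[node] / fs$A[node]
  c <- fs$cwave[node] * fs$A[node]^0.25
  ft <- .char_foot(fs, node, nb, pmax(0, (c - u) * dt))
  cf <- fs$cwave[node] * ft$A^0.25
  ft$Q / ft$A - 4 * cf
}

# Vectorised Newton for bifurcations. Returns interface A (and u) for
# parent end and both daughters given outgoing invariants.
.junction_newton <- function(W1, W2, W3, cw1, cw2, cw3, b1, b2, b3,
                             sA01, sA02, sA03, A1, A2, A3, rho,
                             tol = 1e-10, max_iter = 30) {
  for (it in seq_len(max_iter)) {
    c1 <- cw1 * A1^0.25; c2 <- cw2 * A2^0.25; c3 <- cw3 * A3^0.25
    u1 <- W1 - 4 * c1; u2 <- W2 + 4 * c2; u3 <- W3 + 4 * c3
    p1 <- b1 * (sqrt(A1) - sA01); p2 <- b2 * (sqrt(A2) - sA02)
    p3 <- b3 * (sqrt(A3) - sA03)
    R1 <- A1 * u1 - A2 * u2 - A3 * u3
    R2 <- p1 + 0.5 * rho * u1^2 - p2 - 0.5 * rho * u2^2
    R3 <- p1 + 0.5 * rho * u1^2 - p3 - 0.5 * rho * u3^2
    # characteristic scales: A*c for mass flux, rho*c^2 for pressure
    scale <- pmax(A1 * c1, A2 * c2, A3 * c3)
    pscale <- rho * pmax(c1, c2, c3)^2
    if (max(abs(R1) / scale) < tol && max(abs(R2) / pscale) < tol &&
        max(abs(R3) / pscale) < tol) break
    a11 <- u1 - c1; a12 <- -(u2 + c2); a13 <- -(u3 + c3)
    a21 <- rho * c1 * (c1 - u1) / A1; a22 <- -rho * c2 * (c2 + u2) / A2
    a31 <- a21; a33 <- -rho * c3 * (c3 + u3) / A3
    # Cramer solve of [a11 a12 a13; a21 a22 0; a31 0 a33] d = R
    det <- a11 * a22 * a33 - a12 * a21 * a33 - a13 * a22 * a31
    d1 <- (R1 * a22 * a33 - a12 * R2 * a33 - a13 * a22 * R3) / det
    d2 <- (a11 * R2 * a33 - R1 * a21 * a33 + a13 * (a21 * R3 - R2 * a31)) /
      det
    d3 <- (a11 * a22 * R3 - a12 * (a21 * R3 - R2 * a31) - R1 * a22 * a31) /
      det
    A1 <- pmax(0.1 * A1, A1 - d1)
    A2 <- pmax(0.1 * A2, A2 - d2)
    A3 <- pmax(0.1 * A3, A3 - d3)
    if (it == max_iter) stop("junction Newton failed to converge")
  }
  c1 <- cw1 * A1^0.25; c2 <- cw2 * A2^0.25; c3 <- cw3 * A3^0.25
  list(A1 = A1, Q1 = A1 * (W1 - 4 * c1),
       A2 = A2, Q2 = A2 * (W2 + 4 * c2),
       A3 = A3, Q3 = A3 * (W3 + 4 * c3))
}

# Two-segment (pass-through) junction Newton.
.junction_newton2 <- function(W1, W2, cw1, cw2, b1, b2, sA01, sA02,
                              A1, A2, rho, tol = 1e-10, max_iter = 30) {
  for (it in seq_len(max_iter)) {
    c1 <- cw1 * A1^0.25; c2 <- cw2 * A2^0.25
    u1 <- W1 - 4 * c1; u2 <- W2 + 4 * c2
    p1 <- b1 * (sqrt(A1) - sA01); p2 <- b2 * (sqrt(A2) - sA02)
    R1 <- A1 * u1 - A2 * u2
    R2 <- p1 + 0.5 * rho * u1^2 - p2 - 0.5 * rho * u2^2
    scale <- pmax(A1 * c1, A2 * c2)
    pscale <- rho * pmax(c1, c2)^2
    if (max(abs(R1) / scale) < tol && max(abs(R2) / pscale) < tol) break
    a11 <- u1 - c1; a12 <- -(u2 + c2)
    a21 <- rho * c1 * (c1 - u1) / A1; a22 <- -rho * c2 * (c2 + u2) / A2
    det <- a11 * a22 - a12 * a21
    d1 <- (R1 * a22 - a12 * R2) / det
    d2 <- (a11 * R2 - a21 * R1) / det
    A1 <- pmax(0.1 * A1, A1 - d1)
    A2 <- pmax(0.1 * A2, A2 - d2)
    if (it == max_iter) stop("junction Newton failed to converge")
  }
  c1 <- cw1 * A1^0.25; c2 <- cw2 * A2^0.25
  list(A1 = A1, Q1 = A1 * (W1 - 4 * c1),
       A2 = A2, Q2 = A2 * (W2 + 4 * c2))
}

#' Solve a single junction from end states
#'
#' Enforces conservation of mass and total pressure together with the
#' outgoing characteristic invariants of each connected segment end. The
#' parent contributes its forward invariant `u + 4c`, the daughters their
#' backward invariants `u - 4c`.
#'
#' @param parent_end,daughter_ends Lists with fields `A`, `Q`, `A0`,
#'   `beta` (daughter_ends is a list of 1 or 2 such lists).
#' @param fluid A [fluid_props()] list.
#' @return List of interface states `(A, Q)` per connected end, parent
#'   first.
#' @export
solve_junction <- function(parent_end, daughter_ends, fluid = fluid_props()) {
  rho <- fluid$rho
  cw <- function(e) sqrt(e$beta / (2 * rho))
  p <- parent_end
  W1 <- p$Q / p$A + 4 * cw(p) * p$A^0.25
  if (length(daughter_ends) == 1L) {
    d <- daughter_ends[[1]]
    W2 <- d$Q / d$A - 4 * cw(d) * d$A^0.25
    r <- .junction_newton2(W1, W2, cw(p), cw(d), p$beta, d$beta,
                           sqrt(p$A0), sqrt(d$A0), p$A, d$A, rho)
    list(parent = list(A = r$A1, Q = r$Q1),
         daughters = list(list(A = r$A2, Q = r$Q2)))
  } else if (length(daughter_ends) == 2L) {
    d1 <- daughter_ends[[1]]; d2 <- daughter_ends[[2]]
    W2 <- d1$Q / d1$A - 4 * cw(d1) * d1$A^0.25
    W3 <- d2$Q / d2$A - 4 * cw(d2) * d2$A^0.25
    r <- .junction_newton(W1, W2, W3, cw(p), cw(d1), cw(d2),
                          p$beta, d1$beta, d2$beta,
                          sqrt(p$A0), sqrt(d1$A0), sqrt(d2$A0),
                          p$A, d1$A, d2$A, rho)
    list(parent = list(A = r$A1, Q = r$Q1),
         daughters = list(list(A = r$A2, Q = r$Q2),
                          list(A = r$A3, Q = r$Q3)))
  } else stop("junctions support 1 or 2 daughters")
}

# One internal sub-step of the network update (dt already stable).
.step_once <- function(fs, P_in, pbar, dt) {
  A <- fs$A; Q <- fs$Q
  u <- Q / A
  cvec <- fs$cwave * A^0.25
  # CFL guard
  crmax <- max((abs(u) + cvec) * dt / fs$dx)
  if (crmax > 1)
    stop(sprintf(
      "CFL violation (Courant %.2f); reduce dt below %.3g s", crmax,
      dt / crmax))
  if (any(A <= 0)) stop("vessel collapse beyond tube-law validity")

  F1 <- Q
  F2 <- fs$alpha * Q * u + fs$fcoef * A^1.5
  S2 <- -fs$K * u

  iL <- fs$pairL; iR <- fs$pairR
  dxp <- fs$dx[iL]
  Ah <- 0.5 * (A[iL] + A[iR]) - dt / (2 * dxp) * (F1[iR] - F1[iL])
  Qh <- 0.5 * (Q[iL] + Q[iR]) - dt / (2 * dxp) * (F2[iR] - F2[iL]) +
    dt / 4 * (S2[iL] + S2[iR])
  uh <- Qh / Ah
  F1h <- Qh
  F2h <- fs$alpha[iL] * Qh * uh + fs$fcoef[iL] * Ah^1.5
  S2h <- -fs$K[iL] * uh

  jn <- fs$int_nodes
  Anew <- A; Qnew <- Q
  Anew[jn] <- A[jn] - dt / fs$dx[jn] * (F1h[fs$int_pR] - F1h[fs$int_pL])
  Qnew[jn] <- Q[jn] - dt / fs$dx[jn] * (F2h[fs$int_pR] - F2h[fs$int_pL]) +
    dt / 2 * (S2h[fs$int_pL] + S2h[fs$int_pR])

  # Inlet: clamp pressure to P_in via the incoming forward characteristic;
  # the outgoing backward invariant is taken at its foot in the interior.
  rn <- fs$root_node
  Wm <- .invariant_left(fs, rn, fs$root_nb, dt)
  sqA_in <- P_in / fs$beta[rn] + fs$sqrtA0[rn]
  if (sqA_in <= 0) stop("inlet pressure below collapse limit")
  A_in <- sqA_in^2
  u_in <- Wm + 4 * fs$cwave[rn] * A_in^0.25
  Anew[rn] <- A_in; Qnew[rn] <- A_in * u_in

  # Terminals: resistive coupling solved with the forward invariant.
  tn <- fs$term_node
  Wp <- .invariant_right(fs, tn, fs$term_nb, dt)
  At <- A[tn]
  bt <- fs$beta[tn]; sA0t <- fs$sqrtA0[tn]; cwt <- fs$cwave[tn]
  Rt <- fs$term_R
  for (it in 1:30) {
    ct <- cwt * At^0.25
    g <- At * (Wp - 4 * ct) - (bt * (sqrt(At) - sA0t) - pbar) / Rt
    dg <- Wp - 5 * ct - bt / (2 * sqrt(At) * Rt)
    dA <- g / dg
    At <- pmax(0.5 * At, pmin(2 * At, At - dA))
    if (max(abs(dA) / At) < 1e-12) break
  }
  Anew[tn] <- At
  Qnew[tn] <- (bt * (sqrt(At) - sA0t) - pbar) / Rt

  # Junctions
  if (!is.null(fs$bif)) {
    b <- fs$bif
    W1 <- .invariant_right(fs, b$pe, b$pn, dt)
    W2 <- .invariant_left(fs, b$d1s, b$d1n, dt)
    W3 <- .invariant_left(fs, b$d2s, b$d2n, dt)
    r <- .junction_newton(W1, W2, W3,
                          fs$cwave[b$pe], fs$cwave[b$d1s], fs$cwave[b$d2s],
                          fs$beta[b$pe], fs$beta[b$d1s], fs$beta[b$d2s],
                          fs$sqrtA0[b$pe], fs$sqrtA0[b$d1s],
                          fs$sqrtA0[b$d2s],
                          A[b$pe], A[b$d1s], A[b$d2s], fs$rho)
    Anew[b$pe] <- r$A1; Qnew[b$pe] <- r$Q1
    Anew[b$d1s] <- r$A2; Qnew[b$d1s] <- r$Q2
    Anew[b$d2s] <- r$A3; Qnew[b$d2s] <- r$Q3
  }
  if (!is.null(fs$uni)) {
    ju <- fs$uni
    W1 <- .invariant_right(fs, ju$pe, ju$pn, dt)
    W2 <- .invariant_left(fs, ju$d1s, ju$d1n, dt)
    r <- .junction_newton2(W1, W2, fs$cwave[ju$pe], fs$cwave[ju$d1s],
                           fs$beta[ju$pe], fs$beta[ju$d1s],
                           fs$sqrtA0[ju$pe], fs$sqrtA0[ju$d1s],
                           A[ju$pe], A[ju$d1s], fs$rho)
    Anew[ju$pe] <- r$A1; Qnew[ju$pe] <- r$Q1
    Anew[ju$d1s] <- r$A2; Qnew[ju$d1s] <- r$Q2
  }

  fs$A <- Anew; fs$Q <- Qnew; fs$t <- fs$t + dt
  fs
}

#' Advance the 1D network by one time step
#'
#' Advances all segments by `dt`, sub-stepping internally if `dt` exceeds
#' the stable Courant limit of the grid. The inlet pressure is clamped to
#' `P_in` (aortic sinus pressure); each terminal sees its mean feeding
#' pressure `pbar` through its terminal resistance.
#'
#' @param fs A `flow_state` from [flow_solver()].
#' @param P_in Inlet pressure (kPa).
#' @param pbar Mean feeding pressure per terminal (kPa; scalar or vector
#'   over terminals, in network terminal order).
#' @param dt Time step (s).
#' @return Updated `flow_state`.
#' @export
step_network <- function(fs, P_in, pbar, dt) {
  if (!is.finite(P_in) || any(!is.finite(pbar)))
    stop("boundary data must be finite")
  pbar <- rep_len(pbar, length(fs$term_node))
  n_sub <- max(1L, ceiling(dt / fs$dt_stable))
  for (k in seq_len(n_sub)) fs <- .step_once(fs, P_in, pbar, dt / n_sub)
  fs
}

#' Terminal states of a flow state
#' @param fs A `flow_state`.
#' @return Data frame: terminal segment id, pressure (kPa), flux out of
#'   the 1D network (mm^3/s).
#' @export
terminal_state <- function(fs) {
  tn <- fs$term_node
  data.frame(segment = fs$network$id[fs$term_seg],
             p = fs$beta[tn] * (sqrt(fs$A[tn]) - fs$sqrtA0[tn]),
             Q = fs$Q[tn])
}

#' Total fluid volume of the 1D network
#'
#' Trapezoidal integral of area over all segment grids (mm^3).
#' @param fs A `flow_state`.
#' @return Volume (mm^3).
#' @export
network_volume <- function(fs) {
  iL <- fs$pairL; iR <- fs$pairR
  sum(0.5 * (fs$A[iL] + fs$A[iR]) * fs$dx[iL])
}

#' Locate a probe node at a distance along a root-to-terminal path
#'
#' @param fs A `flow_state`.
#' @param distance Distance from the inlet (mm).
#' @param path Segment ids (default [main_path()] of the network).
#' @return Global node index.
#' @export
probe_node <- function(fs, distance, path = main_path(fs$network)) {
  x0 <- 0
  for (sid in path) {
    i <- which(fs$network$id == sid)
    len <- fs$network$length[i]
    if (distance <= x0 + len || sid == path[length(path)]) {
      frac <- min(1, max(0, (distance - x0) / len))
      return(fs$first[i] + round(frac * (fs$n_nodes[i] - 1L)))
    }
    x0 <- x0 + len
  }
}
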