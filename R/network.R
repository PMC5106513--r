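# Synthetic coronary tree generation and elementary 1D wave relations:
# tube-law stiffness from a uniform wave speed, wall-friction coefficient,
# and linearised junction reflection coefficients.

#' Blood properties
#'
#' @param rho Blood density (kg mm^-3).
#' @param mu Dynamic viscosity (kPa s).
#' @return A list with `rho`, `mu` and the kinematic viscosity
#'   `nu = mu / rho` (mm^2 s^-1).
#' @export
fluid_props <- function(rho = 1.05e-6, mu = 3.36e-6) {
  stopifnot(rho > 0, mu > 0)
  list(rho = rho, mu = mu, nu = mu / rho)
}

#' Pulse wave speed of a compliant vessel
#'
#' Wave speed implied by the square-root tube law
#' `p = beta (sqrt(A) - sqrt(A0))`: `c = sqrt(beta / (2 rho)) A^(1/4)`.
#'
#' @param beta Tube-law stiffness (kPa mm^-1).
#' @param A Cross-sectional area (mm^2).
#' @param rho Blood density (kg mm^-3).
#' @return Wave speed (mm s^-1).
#' @export
wave_speed <- function(beta, A, rho = 1.05e-6) {
  stopifnot(all(beta > 0), all(A > 0), rho > 0)
  sqrt(beta / (2 * rho)) * A^0.25
}

#' Tube-law stiffness from a prescribed wave speed
#'
#' Inverse of [wave_speed()] at the unstressed area: `beta = 2 rho c^2 /
#' sqrt(A0)`. Assigning a constant `c` across the tree implies constant
#' distensibility.
#'
#' @param c Wave speed (mm s^-1).
#' @param A0 Unstressed area (mm^2).
#' @param rho Blood density (kg mm^-3).
#' @return Stiffness `beta` (kPa mm^-1).
#' @export
stiffness_from_wavespeed <- function(c, A0, rho = 1.05e-6) {
  stopifnot(all(c > 0), all(A0 > 0), rho > 0)
  2 * rho * c^2 / sqrt(A0)
}

#' Wall-friction coefficient of the 1D momentum balance
#'
#' `K = 2 pi alpha nu / (alpha - 1)`, where `alpha` is the velocity-profile
#' shape parameter (`alpha = 4/3` recovers the classical parabolic-profile
#' value `8 pi nu`).
#'
#' @param alpha Velocity-profile parameter (> 1).
#' @param nu Kinematic viscosity (mm^2 s^-1).
#' @return Friction coefficient (mm^2 s^-1).
#' @export
friction_coefficient <- function(alpha, nu) {
  if (any(alpha <= 1)) stop("alpha must exceed 1")
  2 * pi * alpha * nu / (alpha - 1)
}

#' Linearised junction reflection coefficient
#'
#' Reflection coefficient of a pressure perturbation incident on a
#' bifurcation, from the characteristic admittances `Y = A0 / c` of the
#' connected segments: `R_f = (Y_inc - sum(Y_rec)) / (Y_inc + sum(Y_rec))`.
#' In `"forward"` mode the physical parent is the incident segment; in
#' `"backward-from-d1"` mode daughter 1 is incident with the parent and
#' daughter 2 as receivers.
#'
#' @param parent,d1,d2 Numeric length-2 vectors `c(A0, c)` for the parent
#'   and daughter segments; `d2 = NULL` for a trivial (two-segment)
#'   junction.
#' @param direction `"forward"` or `"backward-from-d1"`.
#' @return Reflection coefficient in `[-1, 1]`.
#' @export
reflection_coefficient <- function(parent, d1, d2 = NULL,
                                   direction = c("forward", "backward-from-d1")) {
  direction <- match.arg(direction)
  adm <- function(s) s[[1]] / s[[2]]
  ys <- c(adm(parent), adm(d1), if (!is.null(d2)) adm(d2))
  stopifnot(all(ys > 0))
  if (direction == "forward") {
    (ys[1] - sum(ys[-1])) / sum(ys)
  } else {
    (ys[2] - (sum(ys) - ys[2])) / sum(ys)
  }
}

#' Generate a synthetic coronary tree
#'
#' Builds a binary arterial tree by recursive asymmetric bifurcation. Each
#' terminal is first assigned an independent target root-to-terminal path
#' length drawn from `N(target_mean_path, target_sd_path)` (truncated away
#' from zero); each internal segment then consumes a random fraction of the
#' smallest remaining target in its subtree, and every terminal segment
#' absorbs its own residual exactly, so the realised path-length
#' distribution reproduces the targets to within the minimum-length floor.
#' All segments share a uniform unstressed area and a uniform wave speed
#' (hence uniform distensibility); terminal segments carry a resistance
#' defaulting to the characteristic impedance `rho c / A0` (minimising
#' uncontrolled terminal reflections). Terminals are assigned nominal
#' (transmural layer, circumferential sector) positions for coupling to
#' tissue compartments: depth-first order maps to contiguous sectors and
#' layers cycle within each sector.
#'
#' @param n_terminals Number of distal termini (>= 1).
#' @param target_mean_path Target mean root-to-terminal path length (mm).
#' @param target_sd_path Target standard deviation of path lengths (mm).
#'   Use 0 for deterministic budgets (still random topology).
#' @param A0 Uniform unstressed cross-sectional area (mm^2).
#' @param c0 Uniform wave speed (mm s^-1) used to set the tube-law
#'   stiffness.
#' @param alpha Velocity-profile parameter.
#' @param fluid A [fluid_props()] list.
#' @param R_term Terminal resistance (kPa s mm^-3); default matched
#'   characteristic impedance.
#' @param n_layers,n_sectors Tissue compartment grid used for terminal
#'   placement.
#' @param seed Integer seed; the same seed yields an identical tree.
#' @param min_length Minimum segment length (mm).
#' @return An object of class `coronary_network`: a data frame of segments
#'   (`id, parent, length, A0, beta, alpha, R_term, terminal, layer,
#'   sector, path_length`) with fluid properties and generator settings as
#'   attributes.
#' @examples
#' net <- generate_tree(16, seed = 1)
#' summary(net)
#' @export
generate_tree <- function(n_terminals, target_mean_path = 110,
                          target_sd_path = 25, A0 = 2, c0 = 15000,
                          alpha = 1.05, fluid = fluid_props(),
                          R_term = NULL, n_layers = 3, n_sectors = 6,
                          seed = 1, min_length = 2) {
  stopifnot(n_terminals >= 1, target_mean_path > 0, target_sd_path >= 0)
  if (target_sd_path > 0.5 * target_mean_path)
    stop("infeasible morphometry targets: sd exceeds half the mean path length")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  n_seg <- 2L * n_terminals - 1L
  id <- integer(n_seg); parent <- integer(n_seg); len <- numeric(n_seg)
  terminal <- logical(n_seg)
  nxt <- 0L

  # Independent per-terminal path-length targets, truncated away from zero.
  targets <- stats::rnorm(n_terminals, target_mean_path, target_sd_path)
  targets <- pmax(0.25 * target_mean_path, targets)

  # Iterative depth-first construction; each stack entry carries the
  # remaining (budget) targets of the terminals in its subtree.
  stack <- list(list(T = targets, par = 0L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nxt <- nxt + 1L
    i <- nxt
    id[i] <- i; parent[i] <- top$par
    n <- length(top$T)
    if (n == 1L) {
      len[i] <- max(min_length, top$T)
      terminal[i] <- TRUE
    } else {
      f <- stats::runif(1, 0.2, 0.4)
      len[i] <- max(min_length, f * min(top$T))
      rem <- top$T - len[i]
      n1 <- round(n * stats::runif(1, 0.35, 0.65))
      n1 <- max(1L, min(n - 1L, as.integer(n1)))
      # Push the second child first so depth-first order visits child 1 first.
      stack[[length(stack) + 1L]] <- list(T = rem[(n1 + 1L):n], par = i)
      stack[[length(stack) + 1L]] <- list(T = rem[1L:n1], par = i)
    }
  }

  beta <- stiffness_from_wavespeed(c0, A0, fluid$rho)
  if (is.null(R_term)) R_term <- fluid$rho * c0 / A0

  seg <- data.frame(id = id, parent = parent, length = len, A0 = A0,
                    beta = beta, alpha = alpha,
                    R_term = ifelse(terminal, R_term, NA_real_),
                    terminal = terminal)

  # Terminal placement: contiguous sectors in depth-first order, layers
  # cycling within each sector so every sector samples all layers.
  t_idx <- which(terminal)
  ord <- seq_along(t_idx)
  sector <- ceiling(ord * n_sectors / length(t_idx))
  layer <- ((ord - 1L) %% n_layers) + 1L
  seg$sector <- NA_integer_; seg$layer <- NA_integer_
  seg$sector[t_idx] <- as.integer(sector)
  seg$layer[t_idx] <- as.integer(layer)

  # Root-to-segment-end path lengths via parent pointers (ids are in
  # depth-first order so parents precede children).
  path <- numeric(n_seg)
  for (i in seq_len(n_seg))
    path[i] <- len[i] + if (parent[i] > 0) path[parent[i]] else 0
  seg$path_length <- path

  structure(seg, class = c("coronary_network", "data.frame"),
            fluid = fluid, c0 = c0,
            generator = list(n_terminals = n_terminals,
                             target_mean_path = target_mean_path,
                             target_sd_path = target_sd_path, seed = seed,
                             n_layers = n_layers, n_sectors = n_sectors))
}

#' Morphometry summary of a coronary tree
#'
#' @param network A `coronary_network`.
#' @return A list: number of terminals, mean/sd root-to-terminal path
#'   length (mm), total segment count, and total unstressed volume (mm^3).
#' @export
network_morphometry <- function(network) {
  pl <- network$path_length[network$terminal]
  list(n_terminals = sum(network$terminal),
       mean_path_length = mean(pl),
       sd_path_length = if (length(pl) > 1) stats::sd(pl) else 0,
       total_segments = nrow(network),
       total_volume = sum(network$length * network$A0))
}

#' Children lookup for a network
#' @param network A `coronary_network`.
#' @return A list mapping each segment id to its children ids.
#' @keywords internal
network_children <- function(network) {
  ch <- vector("list", nrow(network))
  for (i in seq_len(nrow(network))) {
    p <- network$parent[i]
    if (p > 0) ch[[p]] <- c(ch[[p]], network$id[i])
  }
  ch
}

#' Main root-to-terminal path
#'
#' Follows, from the root, the daughter with the larger number of terminals
#' in its subtree (ties broken by id). This is the analogue of the main
#' epicardial vessel along which wave-intensity probes are placed.
#'
#' @param network A `coronary_network`.
#' @return Integer vector of segment ids from root to a terminal.
#' @export
main_path <- function(network) {
  ch <- network_children(network)
  nterm <- integer(nrow(network))
  for (i in rev(seq_len(nrow(network)))) # children have larger ids
    nterm[i] <- if (network$terminal[i]) 1L else sum(nterm[unlist(ch[[i]])])
  path <- integer(0)
  cur <- network$id[network$parent == 0L][1]
  repeat {
    path <- c(path, cur)
    kids <- unlist(ch[[cur]])
    if (is.null(kids) || !length(kids)) break
    cur <- kids[which.max(nterm[kids])]
  }
  path
}

#' Per-junction reflection coefficients of a network
#'
#' @param network A `coronary_network`.
#' @return Data frame with one row per bifurcation: parent id and the
#'   forward and backward (incident from daughter 1) reflection
#'   coefficients under the network's uniform wave speed.
#' @export
network_reflections <- function(network) {
  ch <- network_children(network)
  c0 <- attr(network, "c0")
  rows <- lapply(which(!network$terminal), function(i) {
    kids <- unlist(ch[[i]])
    if (length(kids) != 2) return(NULL)
    p <- c(network$A0[i], c0)
    d1 <- c(network$A0[kids[1]], c0)
    d2 <- c(network$A0[kids[2]], c0)
    data.frame(parent_id = network$id[i],
               R_forward = reflection_coefficient(p, d1, d2, "forward"),
               R_backward = reflection_coefficient(p, d1, d2,
                                                   "backward-from-d1"))
  })
  do.call(rbind, rows)
}

#' Write / read a network as a plain-text segment table
#'
#' The on-disk format is a CSV of the segment table; generator settings and
#' fluid properties travel in a JSON sidecar (`<file>.json`).
#'
#' @param network A `coronary_network`.
#' @param file Path to the CSV file.
#' @return `read_network` returns a `coronary_network`.
#' @export
write_network <- function(network, file) {
  utils::write.csv(as.data.frame(network), file, row.names = FALSE)
  meta <- list(fluid = attr(network, "fluid"), c0 = attr(network, "c0"),
               generator = attr(network, "generator"))
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname write_network
#' @export
read_network <- function(file) {
  seg <- utils::read.csv(file)
  meta_path <- paste0(file, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path,
                                                          simplifyVector = TRUE)
  else list()
  fluid <- if (!is.null(meta$fluid)) meta$fluid else fluid_props()
  c0 <- if (!is.null(meta$c0)) meta$c0
  else wave_speed(seg$beta[1], seg$A0[1], fluid$rho)
  structure(seg, class = c("coronary_network", "data.frame"),
            fluid = fluid, c0 = c0, generator = meta$generator)
}

#' @export
print.coronary_network <- function(x, ...) {
  m <- network_morphometry(x)
  cat("Coronary network:", m$total_segments, "segments,",
      m$n_terminals, "terminals\n")
  cat(sprintf("  root-to-terminal path length: %.1f +/- %.1f mm\n",
              m$mean_path_length, m$sd_path_length))
  cat(sprintf("  total unstressed volume: %.1f mm^3; uniform c = %.0f mm/s\n",
              m$total_volume, attr(x, "c0")))
  invisible(x)
}

#' @export
summary.coronary_network <- function(object, ...) {
  m <- network_morphometry(object)
  refl <- network_reflections(object)
  m$reflection_forward_range <- if (!is.null(refl)) range(refl$R_forward)
  else c(NA, NA)
  m$reflection_backward_median <- if (!is.null(refl))
    stats::median(refl$R_backward) else NA
  class(m) <- "summary.coronary_network"
  m
}

#' @export
print.summary.coronary_network <- function(x, ...) {
  cat("Coronary network morphometry\n")
  cat(sprintf("  terminals: %d   segments: %d\n", x$n_terminals,
              x$total_segments))
  cat(sprintf("  path length (mm): mean %.1f, sd %.1f\n",
              x$mean_path_length, x$sd_path_length))
  cat(sprintf("  volume: %.1f mm^3\n", x$total_volume))
  if (!anyNA(x$reflection_forward_range))
    cat(sprintf("  forward R_f in [%.3f, %.3f]; median backward R_f %.3f\n",
                x$reflection_forward_range[1], x$reflection_forward_range[2],
                x$reflection_backward_median))
  invisible(x)
}
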