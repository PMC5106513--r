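# Orchestrator: sequential coupling of the heart-valve-windkessel system,
# the 1D coronary network and the poroelastic tissue compartments, run to
# a periodic limit cycle; plus the parameter-perturbation harness used to
# study wave sensitivity.
#
# Per time step: (1) the heart system advances, yielding the aortic sinus
# pressure (1D inlet, one-way coupling: coronary flow is small relative
# to cardiac output and is not subtracted from the windkessel) and the
# per-layer intramyocardial pressure compressing the compartments;
# (2) the 1D network advances with the current mean feeding pressures;
# (3) the compartments integrate the terminal inflow; (2)-(3) are
# fixed-point iterated on the feeding pressures until converged.

#' Default simulation configuration
#'
#' All model parameters with their baseline values, grouped by module.
#' The scaled-down default network (32 terminals) keeps the full-scale
#' path-length targets so wave transit times are preserved.
#'
#' @param n_terminals Number of network terminals.
#' @param seed Generator seed.
#' @return Nested configuration list.
#' @export
default_config <- function(n_terminals = 32, seed = 1) {
  list(
    dt = 1e-4, n_cycles = 10, periodicity_tol = 0.01,
    coupling_tol = 1e-3, coupling_max_iter = 3,
    save_dt = 1e-3, probe_distance = 60,
    network = list(n_terminals = n_terminals, target_mean_path = 110,
                   target_sd_path = 25, A0 = 2, c0 = 15000, alpha = 1.05,
                   seed = seed, min_length = 2),
    solver = list(dx_target = 3, n_min_nodes = 4, cfl = 0.8),
    fluid = list(rho = 1.05e-6, mu = 3.36e-6),
    heart = list(),   # overrides for heart_params()
    porous = list(),  # overrides for porous_params()
    tissue = list(gamma = 8, p_drain = 0.5, sigma = 3, n_layers = 3,
                  n_sectors = 6),
    init = list(P_s0 = 12, p_pore0 = 8),
    wia = list(window = 11, order = 2, thresh_frac = 0.01,
               merge_gap_s = 0.005)
  )
}

#' Read a configuration from YAML, merged over the defaults
#'
#' @param path YAML file path.
#' @param base Base configuration to merge into.
#' @return Configuration list.
#' @export
read_config <- function(path, base = default_config()) {
  utils::modifyList(base, yaml::read_yaml(path))
}

# Recursive merge helper for perturbation specs.
.merge_config <- function(base, delta) utils::modifyList(base, delta)

#' Run the integrated perfusion model to a periodic limit cycle
#'
#' Integrates whole cardiac cycles until the maximum relative difference
#' of the ventricular pressure/volume, root coronary flow and compartment
#' fluid-mass traces between successive cycles drops below
#' `periodicity_tol`, or `n_cycles` is reached. Returns the final cycle's
#' time series for every subsystem together with a wave intensity
#' analysis at the probe, a perfusion report, and the final state for
#' warm restarts.
#'
#' @param config Configuration from [default_config()] (possibly
#'   modified).
#' @param network Optional pre-built `coronary_network` (otherwise
#'   generated from `config$network`).
#' @param init_state Optional final state of a previous run (warm
#'   restart).
#' @param n_cycles Override of `config$n_cycles`.
#' @param quiet Suppress per-cycle progress lines.
#' @param engine `"cpp"` (compiled inner loop, default) or `"R"` (pure-R
#'   reference stepping; identical model, used for cross-checks).
#' @return An object of class `perfusion_sim`.
#' @export
simulate_perfusion <- function(config = default_config(), network = NULL,
                               init_state = NULL, n_cycles = NULL,
                               quiet = TRUE, engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  cfg <- config
  if (!is.null(n_cycles)) cfg$n_cycles <- n_cycles
  fluid <- do.call(fluid_props, cfg$fluid)
  if (is.null(network))
    network <- do.call(generate_tree, c(cfg$network, list(
      fluid = fluid, n_layers = cfg$tissue$n_layers,
      n_sectors = cfg$tissue$n_sectors)))
  hp <- do.call(heart_params, cfg$heart)
  pp <- do.call(porous_params, cfg$porous)
  tis <- tissue_compartments(n_layers = cfg$tissue$n_layers,
                             n_sectors = cfg$tissue$n_sectors,
                             V_wall = hp$V_wall, porous = pp,
                             gamma = cfg$tissue$gamma,
                             p_drain = cfg$tissue$p_drain)
  W <- build_weights(network, tis, sigma = cfg$tissue$sigma)
  tW <- t(W)
  term_layer <- network$layer[network$terminal]
  comp_layer <- tis$comps$layer

  if (is.null(init_state)) {
    fs <- flow_solver(network, fluid, dx_target = cfg$solver$dx_target,
                      n_min_nodes = cfg$solver$n_min_nodes,
                      cfl = cfg$solver$cfl)
    heart <- heart_init(hp, P_s0 = cfg$init$P_s0)
    tis$Jphi <- rep(porosity_from_pressure(cfg$init$p_pore0, pp),
                    nrow(tis$comps))
    tis$J <- tis$Jphi + 1 - pp$phi0
    tis$phi <- tis$Jphi / tis$J
    tis$m <- fluid_mass(tis$Jphi, pp)
    # start the 1D tree pressurised near the inlet pressure
    p0 <- cfg$init$P_s0
    fs$A <- (p0 / fs$beta + fs$sqrtA0)^2
  } else {
    # warm restart: adopt the previous state but keep the freshly built
    # parameter objects (tissue carries p_drain/gamma with it)
    fs <- init_state$fs
    heart <- init_state$heart
    for (f in c("Jphi", "J", "phi", "m"))
      tis[[f]] <- init_state$tissue[[f]]
  }

  dt <- cfg$dt
  n_steps <- round(hp$t_period / dt)
  save_every <- max(1L, round(cfg$save_dt / dt))
  n_save <- floor(n_steps / save_every)
  probe <- probe_node(fs, cfg$probe_distance)
  rn <- fs$root_node

  sys_cols <- c("t", "P_lv", "P_as", "P_s", "V_lv", "Q_ao", "Q_mi",
                "theta", "Q_root", "p_probe", "U_probe")
  prev_metric <- NULL
  converged <- FALSE
  history <- list()
  coupling_iters <- 0; coupling_steps <- 0

  nl <- cfg$tissue$n_layers
  layer_names <- if (nl == 3) c("subendo", "mid", "subepi") else
    paste0("layer", seq_len(nl))
  geom_fields <- c("total", "dx", "beta", "A0", "sqrtA0", "alpha", "K",
                   "cwave", "fcoef", "term_R", "pairL", "pairR",
                   "int_nodes", "int_pL", "int_pR", "term_node",
                   "term_nb", "root_node", "root_nb", "rho", "dt_stable",
                   "bif", "uni")

  for (cyc in seq_len(cfg$n_cycles)) {
    cyc_t0 <- as.numeric(Sys.time())
    vol0 <- network_volume(fs); mass0 <- sum(tis$Jphi * tis$comps$V_ref)

    if (engine == "cpp") {
      out <- cpp_run_cycle(
        unclass(fs)[geom_fields], fs$A, fs$Q, unclass(hp),
        heart[c("V_lv", "theta", "dtheta", "Q_ao", "P_s", "P_as")],
        unclass(pp),
        list(V_ref = tis$comps$V_ref, gamma = tis$gamma,
             p_drain = tis$p_drain, perm_mode = tis$perm_mode),
        tis$Jphi, W, comp_layer, term_layer,
        list(dt = dt, n_steps = n_steps, save_every = save_every,
             coupling_tol = cfg$coupling_tol,
             coupling_max_iter = cfg$coupling_max_iter, probe = probe))
      fs$A <- out$A; fs$Q <- out$Q; fs$t <- fs$t + n_steps * dt
      heart[c("V_lv", "theta", "dtheta", "Q_ao", "P_s", "P_as")] <-
        out$heart[c("V_lv", "theta", "dtheta", "Q_ao", "P_s", "P_as")]
      heart$P_lv <- out$sys[n_save, 2]
      tis$Jphi <- out$Jphi
      tis$J <- tis$Jphi + 1 - pp$phi0
      tis$phi <- tis$Jphi / tis$J
      tis$m <- fluid_mass(tis$Jphi, pp)
      tis$Q_out <- out$Qout
      tis$p_imp <- rep(0, length(tis$Jphi)) # refreshed next cycle
      coupling_iters <- coupling_iters + out$coupling_iters
      coupling_steps <- coupling_steps + n_steps
    } else {
      out <- .run_cycle_R(fs, heart, tis, hp, pp, W, tW, comp_layer,
                          term_layer, cfg, dt, n_steps, save_every,
                          n_save, probe, rn, nl)
      fs <- out$fs; heart <- out$heart_full; tis <- out$tis
      coupling_iters <- coupling_iters + out$coupling_iters
      coupling_steps <- coupling_steps + n_steps
    }
    sys <- out$sys
    colnames(sys) <- sys_cols
    layerQ <- out$layerQ; colnames(layerQ) <- layer_names
    compJ <- out$compJ; compP <- out$compP
    Qin_sum <- out$Qin_sum
    inlet_vol <- out$inlet_vol; term_vol <- out$term_vol
    venous_vol <- out$venous_vol

    metric <- list(P_lv = sys[, "P_lv"], V_lv = sys[, "V_lv"],
                   Q_root = sys[, "Q_root"], m = compJ[n_save, ])
    if (!is.null(prev_metric)) {
      rel <- vapply(names(metric), function(nm) {
        a <- metric[[nm]]; b <- prev_metric[[nm]]
        max(abs(a - b)) / max(abs(a), 1e-12)
      }, numeric(1))
      per_metric <- max(rel)
      if (!quiet)
        message(sprintf("cycle %d: periodicity %.4f (%.2f s)", cyc,
                        per_metric, as.numeric(Sys.time()) - cyc_t0))
      if (per_metric < cfg$periodicity_tol) { converged <- TRUE }
    } else per_metric <- NA_real_
    prev_metric <- metric
    history[[cyc]] <- per_metric
    if (converged && cyc >= 3) break
  }

  sys <- as.data.frame(sys)
  Qin_mean <- Qin_sum / n_save
  dvol <- (network_volume(fs) - vol0) +
    (sum(tis$Jphi * tis$comps$V_ref) - mass0)
  throughput <- sum(abs(sys$Q_root)) * cfg$save_dt
  mass_err <- abs(inlet_vol - venous_vol - dvol) / max(throughput, 1e-9)

  A_probe_mean <- (mean(sys$p_probe) / fs$beta[probe] +
                     fs$sqrtA0[probe])^2
  w <- wia(sys$t, sys$p_probe, sys$U_probe, rho = fluid$rho,
           c = wave_speed(fs$beta[probe], A_probe_mean, fluid$rho),
           window = cfg$wia$window, order = cfg$wia$order,
           thresh_frac = cfg$wia$thresh_frac,
           merge_gap_s = cfg$wia$merge_gap_s)

  EF <- (max(sys$V_lv) - min(sys$V_lv)) / max(sys$V_lv)
  res <- list(
    config = cfg, network = network, sys = sys, layerQ = layerQ,
    compJ = compJ, compP = compP, Qin_mean = Qin_mean,
    perfusion = perfusion_report(tis, Qin_mean),
    wia = w, EF = EF,
    diastolic_fraction = mean(sys$theta < 0.01),
    cycles_run = cyc, converged = converged,
    periodicity = unlist(history),
    mass_error = mass_err,
    mean_coupling_iters = coupling_iters / max(1, coupling_steps),
    state = list(fs = fs, heart = heart, tissue = tis),
    probe_node = probe, W = W)
  class(res) <- "perfusion_sim"
  res
}

# Pure-R reference implementation of one cardiac cycle of the coupled
# model; mirrors cpp_run_cycle step for step.
.run_cycle_R <- function(fs, heart, tis, hp, pp, W, tW, comp_layer,
                         term_layer, cfg, dt, n_steps, save_every, n_save,
                         probe, rn, nl) {
  sys <- matrix(NA_real_, n_save, 11)
  layerQ <- matrix(0, n_save, nl)
  compJ <- matrix(0, n_save, length(tis$Jphi))
  compP <- matrix(0, n_save, length(tis$Jphi))
  Qin_sum <- numeric(length(tis$Jphi))
  inlet_vol <- 0; term_vol <- 0; venous_vol <- 0
  coupling_iters <- 0
  isave <- 0L
  for (k in seq_len(n_steps)) {
    t_cyc <- (k - 1) * dt
    heart <- heart_step(heart, t_cyc, dt, hp)
    tis$p_imp <- heart$p_imp[comp_layer]
    pbar <- mean_feeding_pressure(W, compartment_pressure(tis))
    fs_base <- fs
    for (ci in seq_len(cfg$coupling_max_iter)) {
      fs <- step_network(fs_base, heart$P_as, pbar, dt)
      Qt <- fs$Q[fs$term_node]
      Qin <- as.numeric(tW %*% Qt)
      tis_new <- update_compartments(tis, Qin, dt)
      pbar_new <- mean_feeding_pressure(W, compartment_pressure(tis_new))
      dmax <- max(abs(pbar_new - pbar) / pmax(1, abs(pbar)))
      pbar <- pbar_new
      coupling_iters <- coupling_iters + 1
      if (dmax < cfg$coupling_tol) break
    }
    tis <- tis_new
    inlet_vol <- inlet_vol + fs$Q[rn] * dt
    term_vol <- term_vol + sum(Qt) * dt
    venous_vol <- venous_vol + sum(tis$Q_out) * dt
    if (k %% save_every == 0L && isave < n_save) {
      isave <- isave + 1L
      sys[isave, ] <- c(t_cyc, heart$P_lv, heart$P_as, heart$P_s,
                        heart$V_lv, heart$Q_ao, heart$Q_mi, heart$theta,
                        fs$Q[rn], flow_pressure(fs)[probe],
                        fs$Q[probe] / fs$A[probe])
      layerQ[isave, ] <- vapply(seq_len(nl), function(l)
        sum(Qt[term_layer == l]), numeric(1))
      compJ[isave, ] <- tis$Jphi
      compP[isave, ] <- compartment_pressure(tis)
      Qin_sum <- Qin_sum + Qin
    }
  }
  list(fs = fs, heart_full = heart, tis = tis, sys = sys, layerQ = layerQ,
       compJ = compJ, compP = compP, Qin_sum = Qin_sum,
       inlet_vol = inlet_vol, term_vol = term_vol,
       venous_vol = venous_vol, coupling_iters = coupling_iters)
}

#' Perturbation specifications of the wave-sensitivity study
#'
#' Named single-parameter (or minimal-set) modifications around the
#' baseline: activation synchrony (QRS duration), tension transient
#' (faster contraction / slower relaxation; peak-time shifts), viscous
#' resistance (velocity-profile parameter `alpha`), venous outflow
#' pressure, aortic valve transition rate, uniform wave speed and
#' terminal resistance.
#'
#' @return Named list of configuration deltas.
#' @export
perturbation_specs <- function() {
  list(
    # QRSd changes preserve the mean activation time (timing of ejection
    # unchanged under the new activation sequence)
    qrsd_zero = list(heart = list(QRSd = 1e-6, act_delay = 0.03)),
    qrsd_double = list(heart = list(QRSd = 0.12, act_delay = -0.03)),
    tension_fast_slow = list(heart = list(t_r0 = 0.08, t_d = 0.06)),
    tension_shift_minus = list(heart = list(t_max = 0.27)),
    tension_shift_plus = list(heart = list(t_max = 0.33)),
    alpha_high = list(network = list(alpha = 1.1)),
    p_drain_high = list(tissue = list(p_drain = 5)),
    T_ao_fast = list(heart = list(T_ao = 0.001)),
    wavespeed_low = list(network = list(c0 = 10000)),
    R_term_x10 = list(network = list(R_term = 0.1575))
  )
}

#' Run a perturbation matrix around a baseline simulation
#'
#' Re-runs the model for each named configuration delta (warm-started
#' from the baseline's final state when the network is unchanged) and
#' reports, per experiment, the change in percentage wave area of the
#' dominant forward pushing wave and backward suction wave, the peak
#' intensity ratios of the six waves, and global perfusion.
#'
#' @param baseline A `perfusion_sim` from [simulate_perfusion()].
#' @param specs Named list of config deltas (default
#'   [perturbation_specs()]).
#' @param n_cycles Cycles per perturbed run.
#' @param quiet Suppress progress.
#' @return List with `table` (data frame of indices per experiment) and
#'   `runs` (the perturbed `perfusion_sim` objects).
#' @export
run_perturbation_matrix <- function(baseline, specs = perturbation_specs(),
                                    n_cycles = 4, quiet = TRUE) {
  base_cfg <- baseline$config
  base_pct <- baseline$wia$percent
  base_peaks <- .wave_peaks(baseline$wia)
  rows <- list(); runs <- list()
  for (nm in names(specs)) {
    cfg <- .merge_config(base_cfg, specs[[nm]])
    net_changed <- !identical(cfg$network, base_cfg$network)
    run <- tryCatch(
      simulate_perfusion(cfg,
                         network = if (net_changed) NULL else
                           baseline$network,
                         init_state = if (net_changed) NULL else
                           baseline$state,
                         n_cycles = if (net_changed) n_cycles + 3 else
                           n_cycles,
                         quiet = quiet),
      error = function(e) e)
    if (inherits(run, "error")) {
      rows[[nm]] <- data.frame(experiment = nm, failed = TRUE,
                               d_DFPW = NA, d_BSW = NA)
      next
    }
    runs[[nm]] <- run
    pct <- run$wia$percent
    peaks <- .wave_peaks(run$wia)
    wratios <- .window_peak_ratios(baseline, run)
    rows[[nm]] <- data.frame(
      experiment = nm, failed = FALSE,
      d_DFPW = unname(pct["DFPW"] - base_pct["DFPW"]),
      d_BSW = unname(pct["BSW"] - base_pct["BSW"]),
      peak_ratio_min = min(peaks / base_peaks, na.rm = TRUE),
      peak_ratio_max = max(peaks / base_peaks, na.rm = TRUE),
      peak_ratio_lateFPW = unname(peaks["late-FPW"] /
                                    base_peaks["late-FPW"]),
      window_ratio_min = min(wratios),
      window_ratio_max = max(wratios),
      closure_peak_ratio = .closure_fpw_peak(run) /
        .closure_fpw_peak(baseline),
      perfusion = run$perfusion$global,
      converged = run$converged)
  }
  all_cols <- unique(unlist(lapply(rows, names)))
  tab <- do.call(rbind, lapply(rows, function(r) {
    for (mcol in setdiff(all_cols, names(r))) r[[mcol]] <- NA
    r[all_cols]
  }))
  rownames(tab) <- NULL
  list(table = tab, runs = runs, baseline_percent = base_pct)
}

# Peak forward intensity in the valve-closure window (the physical home
# of the late forward pushing wave), robust to classification changes.
.closure_fpw_peak <- function(sim) {
  th <- sim$sys$theta
  open <- th > 1e-3
  # last open->closed transition
  idx <- which(open[-length(open)] & !open[-1])
  if (!length(idx)) return(NA_real_)
  t_close <- sim$sys$t[idx[length(idx)] + 1]
  w <- sim$wia
  sel <- w$t >= t_close - 0.04 & w$t <= t_close + 0.08 & w$sep$dpp > 0
  if (!any(sel)) return(NA_real_)
  max(w$sep$dIp[sel])
}

# Ratio of perturbed to baseline channel peaks within each baseline wave
# window (same time windows, so the comparison is insensitive to window
# re-segmentation in the perturbed run).
.window_peak_ratios <- function(base, run) {
  recs <- base$wia$records
  out <- numeric(nrow(recs)); names(out) <- recs$label
  for (i in seq_len(nrow(recs))) {
    sel <- base$wia$t >= recs$t_start[i] & base$wia$t <= recs$t_end[i]
    chb <- if (recs$direction[i] == "forward") base$wia$sep$dIp
    else -base$wia$sep$dIm
    chr <- if (recs$direction[i] == "forward") run$wia$sep$dIp
    else -run$wia$sep$dIm
    sel2 <- run$wia$t >= recs$t_start[i] & run$wia$t <= recs$t_end[i]
    out[i] <- max(chr[sel2]) / max(chb[sel])
  }
  out
}

# Peak |dI| per labelled wave of a cwia object.
.wave_peaks <- function(w) {
  peaks <- rep(NA_real_, 6)
  names(peaks) <- .WAVE_ORDER
  if (!nrow(w$records)) return(peaks)
  for (i in seq_len(nrow(w$records))) {
    r <- w$records[i, ]
    idx <- which(w$t >= r$t_start & w$t <= r$t_end)
    ch <- if (r$direction == "forward") w$sep$dIp else -w$sep$dIm
    peaks[r$label] <- max(ch[idx])
  }
  peaks
}

#' Grouped wave indices along a vessel path
#'
#' Re-runs the final converged cycle once with probes at several
#' distances along a root-to-terminal path and reports the grouped
#' percentage wave areas versus distance.
#'
#' @param sim A `perfusion_sim`.
#' @param distances Probe distances from the inlet (mm).
#' @return Data frame: distance plus the grouped indices of
#'   [percent_areas()].
#' @export
along_vessel_profile <- function(sim, distances = c(30, 60, 90)) {
  cfg <- sim$config
  rows <- lapply(distances, function(d) {
    cfg$probe_distance <- d
    run <- simulate_perfusion(cfg, network = sim$network,
                              init_state = sim$state, n_cycles = 1)
    data.frame(distance = d, t(run$wia$groups))
  })
  do.call(rbind, rows)
}

#' @export
print.perfusion_sim <- function(x, ...) {
  cat("Integrated coronary perfusion simulation\n")
  m <- network_morphometry(x$network)
  cat(sprintf("  network: %d terminals; probe at %.0f mm; %d cycles (%s)\n",
              m$n_terminals, x$config$probe_distance, x$cycles_run,
              if (x$converged) "periodic" else "not converged"))
  cat(sprintf("  EF %.1f%%  P_as %.0f/%.0f mmHg  diastolic fraction %.2f\n",
              100 * x$EF, max(x$sys$P_as) * 7.50062,
              min(x$sys$P_as) * 7.50062, x$diastolic_fraction))
  cat(sprintf("  global perfusion %.2f mL/g/min  cycle mass error %.2e\n",
              x$perfusion$global, x$mass_error))
  if (length(x$wia$percent)) {
    cat("  wave areas (%):\n")
    for (nm in names(x$wia$percent))
      cat(sprintf("    %-9s %5.1f\n", nm, x$wia$percent[nm]))
  }
  invisible(x)
}

#' @export
summary.perfusion_sim <- function(object, ...) {
  list(EF = object$EF, perfusion = object$perfusion$global,
       percent = object$wia$percent, groups = object$wia$groups,
       converged = object$converged, mass_error = object$mass_error,
       diastolic_fraction = object$diastolic_fraction)
}

#' @export
plot.perfusion_sim <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  s <- x$sys
  graphics::plot(s$t, s$P_lv, type = "l", xlab = "t (s)",
                 ylab = "pressure (kPa)", main = "pressures")
  graphics::lines(s$t, s$P_as, col = "red")
  graphics::lines(s$t, s$p_probe, col = "blue")
  graphics::legend("topright", c("P_lv", "P_as", "probe"), lty = 1,
                   col = c("black", "red", "blue"), bty = "n", cex = 0.7)
  graphics::plot(s$t, s$Q_root, type = "l", xlab = "t (s)",
                 ylab = "Q (mm^3/s)", main = "coronary inflow")
  graphics::matplot(s$t, x$layerQ, type = "l", lty = 1,
                    col = c("red", "black", "blue"), xlab = "t (s)",
                    ylab = "Q (mm^3/s)", main = "layer flows")
  graphics::legend("topright", colnames(x$layerQ), lty = 1,
                   col = c("red", "black", "blue"), bty = "n", cex = 0.7)
  graphics::plot(x$wia$t, x$wia$sep$dIp, type = "l", col = "blue",
                 ylim = range(c(x$wia$sep$dIp, x$wia$sep$dIm)),
                 xlab = "t (s)", ylab = "dI", main = "wave intensity")
  graphics::lines(x$wia$t, x$wia$sep$dIm, col = "red")
  invisible(x)
}
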