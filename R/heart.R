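# Reduced left ventricle: a layered incompressible thick-walled sphere
# whose wall carries passive plus active circumferential fibre stress,
# coupled to an aortic valve with leaflet-angle dynamics, a three-element
# windkessel afterload and a saturating mitral inflow law.
#
# The spherical reduction serves two purposes: it produces the cavity
# pressure P_lv driving the systemic circulation, and the transmural
# radial-stress profile -sigma_rr(r), used as the imposed intramyocardial
# pressure p_imp(layer) compressing the perfusion compartments
# (subendocardium highest, subepicardium ~ 0).

#' Heart, valve and windkessel parameters
#'
#' Defaults follow the baseline parameterisation of the integrated model:
#' active-stress twitch constants, valve/windkessel constants, and the
#' layered-sphere geometry (porcine LV: wall volume 40.6 mL, unloaded
#' cavity volume 48.5 mL). The passive stiffness scale `passive_a` is
#' calibrated at construction so the passive cavity pressure equals the
#' left-atrial preload `P_la` at the target end-diastolic volume; the
#' active scale is `T0 * T0_scale`, with `T0_scale` absorbing the
#' reduction from a transmurally distributed fibre field to a single
#' effective circumferential stress.
#'
#' @param T0 Peak active stress scale (kPa).
#' @param T0_scale Dimensionless reduction factor applied to `T0`.
#' @param t_r0,t_d,t_max,a4,a6,a7 Twitch shape constants (s, s, s, s,
#'   dimensionless, dimensionless).
#' @param t_period Heart period (s).
#' @param QRSd Endocardium-to-epicardium activation delay span (s).
#' @param act_delay Global activation delay added to every layer (s);
#'   lets QRSd be varied while preserving the mean activation time (and
#'   hence the timing of ejection).
#' @param V_wall Wall volume (mm^3).
#' @param V0_cav Unloaded cavity volume (mm^3).
#' @param n_layers Number of transmural layers.
#' @param P_la Constant left-atrial preload pressure (kPa).
#' @param EDV_target Target end-diastolic volume used to calibrate the
#'   passive stiffness (mm^3).
#' @param passive_b Dimensionless passive-law exponent.
#' @param theta_max Maximal valve opening angle (rad).
#' @param CQ_ao Aortic valve flow coefficient (mm^3 s^-1 kPa^-0.5).
#' @param K1ao Valve angular acceleration coefficient ((kPa s^2)^-1,
#'   applied as rad s^-2 per kPa).
#' @param K_fao Valve angular damping (s^-1).
#' @param T_ao Valve flow relaxation time constant (s).
#' @param R_a,R_s Proximal and systemic windkessel resistances
#'   (kPa s mm^-3).
#' @param C Systemic compliance (mm^3 kPa^-1).
#' @param CQ_mi Mitral flow scale (mm^3 s^-1).
#' @param C_mi Mitral pressure sensitivity (kPa^-1).
#' @return An object of class `heart_params`.
#' @export
heart_params <- function(T0 = 15000, T0_scale = 0.25, t_r0 = 0.16,
                         t_d = 0.03, t_max = 0.3, a4 = 3.2, a6 = 2.0,
                         a7 = 0.7, t_period = 0.8, QRSd = 0.06,
                         act_delay = 0,
                         V_wall = 40600, V0_cav = 48500, n_layers = 3,
                         P_la = 1, EDV_target = 105000, passive_b = 1,
                         theta_max = 75 * pi / 180, CQ_ao = 9.59e5,
                         K1ao = 750, K_fao = 50, T_ao = 0.01,
                         R_a = 1.2e-5, R_s = 2.2e-4, C = 7000,
                         CQ_mi = 2e5, C_mi = 37.5) {
  stopifnot(t_max < t_period, V_wall > 0, V0_cav > 0, n_layers >= 1)
  p <- list(T0 = T0, T0_scale = T0_scale, t_r0 = t_r0, t_d = t_d,
            t_max = t_max, a4 = a4, a6 = a6, a7 = a7,
            t_period = t_period, QRSd = QRSd, act_delay = act_delay,
            V_wall = V_wall,
            V0_cav = V0_cav, n_layers = n_layers, P_la = P_la,
            EDV_target = EDV_target, passive_b = passive_b, passive_a = 1,
            theta_max = theta_max, CQ_ao = CQ_ao, K1ao = K1ao,
            K_fao = K_fao, T_ao = T_ao, R_a = R_a, R_s = R_s, C = C,
            CQ_mi = CQ_mi, C_mi = C_mi)
  # Linear endo-to-epi activation delays spanning [0, QRSd].
  p$activation_offsets <- act_delay + (if (n_layers > 1)
    seq(0, QRSd, length.out = n_layers) else 0)
  class(p) <- "heart_params"
  # Calibrate passive stiffness: passive cavity pressure = P_la at EDV.
  p$passive_a <- stats::uniroot(function(a) {
    p$passive_a <- a
    lv_pressure_from_stress(EDV_target, passive_wall_stress(
      layer_stretch(EDV_target, p), p), p) - P_la
  }, c(1e-4, 100), tol = 1e-10)$root
  p
}

#' Layered-sphere geometry for a given cavity volume
#'
#' Splits the (incompressible) wall into equal-volume concentric shells.
#'
#' @param V_lv Cavity volume (mm^3).
#' @param params A [heart_params()] object.
#' @return List with boundary radii `r` (length `n_layers + 1`, endo to
#'   epi) and midwall radii `r_mid` (radius enclosing half of each
#'   layer's volume).
#' @export
sphere_geometry <- function(V_lv, params) {
  if (V_lv <= 0) stop("non-physical geometry: cavity volume must be positive")
  n <- params$n_layers
  vols <- V_lv + params$V_wall * (0:n) / n
  r <- (3 * vols / (4 * pi))^(1 / 3)
  vm <- V_lv + params$V_wall * ((0:(n - 1)) + 0.5) / n
  list(r = r, r_mid = (3 * vm / (4 * pi))^(1 / 3))
}

#' Layer circumferential stretch ratios
#'
#' Stretch of each layer's midwall circumference relative to the unloaded
#' configuration.
#'
#' @param V_lv Cavity volume (mm^3).
#' @param params A [heart_params()] object.
#' @return Numeric vector (endo to epi).
#' @export
layer_stretch <- function(V_lv, params) {
  sphere_geometry(V_lv, params)$r_mid /
    sphere_geometry(params$V0_cav, params)$r_mid
}

#' Active fibre stress twitch
#'
#' Length-dependent active stress
#' `T0 * phi * tanh^2(t_c / t_r) * tanh^2((t_max - t_c) / t_d)` with
#' `phi = tanh(a6 (lambda - a7))` and rise time
#' `t_r = t_r0 + a4 (1 - phi)`; `t_c` is the time since local activation,
#' wrapped to the heart period, and the twitch is clipped to zero outside
#' `[0, t_max]`.
#'
#' @param t Time (s); vectorised.
#' @param activation_offset Local activation delay (s).
#' @param lambda Fibre stretch ratio.
#' @param params A [heart_params()] object.
#' @param scaled Apply the calibration factor `T0_scale` (default TRUE;
#'   set FALSE to evaluate the raw twitch law).
#' @return Active stress (kPa).
#' @export
active_stress <- function(t, activation_offset = 0, lambda = 1, params,
                          scaled = TRUE) {
  stopifnot(all(lambda > 0))
  tc <- (t - activation_offset) %% params$t_period
  phi <- tanh(params$a6 * (lambda - params$a7))
  tr <- params$t_r0 + params$a4 * (1 - phi)
  s <- params$T0 * phi * tanh(tc / tr)^2 *
    tanh((params$t_max - tc) / params$t_d)^2
  s[tc >= params$t_max] <- 0
  if (scaled) s <- s * params$T0_scale
  s
}

#' Passive circumferential wall stress
#'
#' Reduced exponential fibre law
#' `a (lambda^2 - 1) exp(b (lambda^2 - 1)^2) lambda^2`, zero at the
#' unloaded state and strongly strain-stiffening; `a` is calibrated in
#' [heart_params()] against the end-diastolic preload.
#'
#' @param lambda Stretch ratio (vectorised).
#' @param params A [heart_params()] object.
#' @return Stress (kPa).
#' @export
passive_wall_stress <- function(lambda, params) {
  e <- lambda^2 - 1
  params$passive_a * e * exp(params$passive_b * e^2) * lambda^2
}

#' Cavity pressure and intramyocardial pressure from layer stresses
#'
#' Integrates the spherical radial equilibrium `dsigma_rr/dr =
#' -2 sigma_theta / r` (hoop stress dominant) from the stress-free
#' epicardium inward, with piecewise-constant hoop stress per layer.
#' The cavity pressure is `-sigma_rr` at the endocardium and the imposed
#' intramyocardial pressure of each layer is `-sigma_rr` at the layer's
#' midwall radius, so `p_imp(endo) = P_lv` and `p_imp(epi) -> 0`.
#'
#' @param V_lv Cavity volume (mm^3).
#' @param sigma_layers Total hoop stress per layer (kPa), endo to epi.
#' @param params A [heart_params()] object.
#' @return For `lv_pressure_from_stress` the cavity pressure (kPa); for
#'   [lv_equilibrium()] a list with `P_lv` and `p_imp` (per layer, kPa).
#' @export
lv_equilibrium <- function(V_lv, sigma_layers, params) {
  g <- sphere_geometry(V_lv, params)
  n <- params$n_layers
  # -sigma_rr at each boundary radius, accumulated from epi inward.
  pb <- numeric(n + 1) # pb[i] = p at boundary r[i]; pb[n+1] = 0 at epi
  for (i in n:1)
    pb[i] <- pb[i + 1] + 2 * sigma_layers[i] * log(g$r[i + 1] / g$r[i])
  p_imp <- numeric(n)
  for (i in 1:n)
    p_imp[i] <- pb[i + 1] + 2 * sigma_layers[i] * log(g$r[i + 1] / g$r_mid[i])
  list(P_lv = pb[1], p_imp = p_imp)
}

#' @rdname lv_equilibrium
#' @export
lv_pressure_from_stress <- function(V_lv, sigma_layers, params) {
  lv_equilibrium(V_lv, sigma_layers, params)$P_lv
}

#' Aortic valve orifice area ratio
#'
#' `AR = ((1 - cos(theta)) / (1 - cos(theta_max)))^2`: 0 when closed,
#' 1 at full opening.
#'
#' @param theta Leaflet angle (rad); vectorised.
#' @param theta_max Maximal opening angle (rad).
#' @return Dimensionless orifice area ratio.
#' @export
valve_area_ratio <- function(theta, theta_max) {
  ((1 - cos(theta)) / (1 - cos(theta_max)))^2
}

#' Aortic valve update (leaflet angle and relaxed orifice flow)
#'
#' Advances the leaflet angle by the damped angular ODE
#' `theta'' = K1ao (P_lv - P_as) cos(theta) - K_fao theta'` (angle clamped
#' to `[0, theta_max]`), and relaxes the valve flow toward the
#' orifice steady flow `Q_ss = sign(dP) CQ_ao AR sqrt(|dP|)` with the
#' exact first-order update `Q' = Q_ss + (Q - Q_ss) exp(-dt / T_ao)`,
#' preventing instantaneous flow changes at valve closure.
#'
#' The leaflet torque is driven by the pressure gradient evaluated
#' upstream of the proximal windkessel resistance (`P_torque`, defaulting
#' to `P_lv - P_as`): with the flow-dependent sinus pressure of the
#' three-element windkessel, a large regurgitant flow would otherwise pull
#' `P_as` down to `P_lv` and stall closure indefinitely.
#'
#' @param state List with `theta`, `dtheta`, `Q_ao`.
#' @param P_lv,P_as Ventricular and aortic-sinus pressures (kPa).
#' @param dt Time step (s).
#' @param params A [heart_params()] object.
#' @param P_torque Optional pressure (kPa) replacing `P_as` in the leaflet
#'   torque term only.
#' @return Updated state list.
#' @export
aortic_valve_step <- function(state, P_lv, P_as, dt, params,
                              P_torque = NULL) {
  dP <- P_lv - P_as
  dP_t <- if (is.null(P_torque)) dP else P_lv - P_torque
  acc <- params$K1ao * dP_t * cos(state$theta) - params$K_fao * state$dtheta
  dtheta <- state$dtheta + dt * acc
  theta <- state$theta + dt * dtheta
  if (theta < 0) { theta <- 0; dtheta <- max(0, dtheta) }
  if (theta > params$theta_max) { theta <- params$theta_max
    dtheta <- min(0, dtheta) }
  AR <- valve_area_ratio(theta, params$theta_max)
  Q_ss <- sign(dP) * params$CQ_ao * AR * sqrt(abs(dP))
  Q_ao <- Q_ss + (state$Q_ao - Q_ss) * exp(-dt / params$T_ao)
  list(theta = theta, dtheta = dtheta, Q_ao = Q_ao)
}

#' Three-element windkessel update
#'
#' `P_as = P_s + R_a Q_ao` with the stored pressure relaxing as
#' `dP_s/dt = (Q_ao - P_s / R_s) / C` (advanced exactly for the
#' within-step constant `Q_ao`, time constant `R_s C`).
#'
#' @param P_s Stored systemic pressure (kPa).
#' @param Q_ao Aortic flow (mm^3 s^-1).
#' @param dt Time step (s).
#' @param params A [heart_params()] object.
#' @return List with `P_as` and updated `P_s`.
#' @export
windkessel_step <- function(P_s, Q_ao, dt, params) {
  tau <- params$R_s * params$C
  target <- Q_ao * params$R_s
  P_s_new <- target + (P_s - target) * exp(-dt / tau)
  list(P_as = P_s_new + params$R_a * Q_ao, P_s = P_s_new)
}

#' Mitral inflow
#'
#' Saturating tanh law, zero whenever the ventricular pressure is at or
#' above the atrial pressure (continuous at the crossover).
#'
#' @param P_la,P_lv Atrial and ventricular pressures (kPa); vectorised.
#' @param params A [heart_params()] object.
#' @return Mitral flow (mm^3 s^-1).
#' @export
mitral_flow <- function(P_la, P_lv, params) {
  ifelse(P_la > P_lv,
         params$CQ_mi * tanh(params$C_mi * (P_la - P_lv)), 0)
}

#' Cavity volume balance
#'
#' `dV_lv/dt = Q_mi - Q_ao`.
#'
#' @param V_lv Cavity volume (mm^3).
#' @param Q_mi,Q_ao Mitral and aortic flows (mm^3 s^-1).
#' @param dt Time step (s).
#' @return Updated volume.
#' @export
cavity_volume_update <- function(V_lv, Q_mi, Q_ao, dt) {
  V <- V_lv + dt * (Q_mi - Q_ao)
  if (V <= 0) stop("cavity volume became non-positive")
  V
}

#' Initial heart-systemic state
#'
#' @param params A [heart_params()] object.
#' @param P_s0 Initial stored systemic pressure (kPa).
#' @return A state list (`V_lv`, `theta`, `dtheta`, `Q_ao`, `P_s`,
#'   `P_as`, `P_lv`, `p_imp`).
#' @export
heart_init <- function(params, P_s0 = 12) {
  st <- list(V_lv = params$EDV_target, theta = 0, dtheta = 0, Q_ao = 0,
             P_s = P_s0, P_as = P_s0, P_lv = params$P_la,
             p_imp = rep(0, params$n_layers))
  st
}

#' Advance the heart-valve-windkessel system by one step
#'
#' Computes layer stretches and total (passive + active) hoop stresses at
#' time `t`, derives `P_lv` and per-layer `p_imp` from spherical
#' equilibrium, then updates mitral flow, valve state, windkessel and
#' cavity volume.
#'
#' @param state State list from [heart_init()] or a previous step.
#' @param t Current time (s); layer activation offsets are relative to
#'   `t = 0` at cycle start.
#' @param dt Time step (s).
#' @param params A [heart_params()] object.
#' @return Updated state list (includes `Q_mi` of the step).
#' @export
heart_step <- function(state, t, dt, params) {
  lam <- layer_stretch(state$V_lv, params)
  sig <- passive_wall_stress(lam, params) +
    vapply(seq_len(params$n_layers), function(i)
      active_stress(t, params$activation_offsets[i], lam[i], params),
      numeric(1))
  eq <- lv_equilibrium(state$V_lv, sig, params)
  Q_mi <- mitral_flow(params$P_la, eq$P_lv, params)
  vs <- aortic_valve_step(state, eq$P_lv, state$P_as, dt, params,
                          P_torque = state$P_s)
  wk <- windkessel_step(state$P_s, vs$Q_ao, dt, params)
  V <- cavity_volume_update(state$V_lv, Q_mi, vs$Q_ao, dt)
  list(V_lv = V, theta = vs$theta, dtheta = vs$dtheta, Q_ao = vs$Q_ao,
       P_s = wk$P_s, P_as = wk$P_as, P_lv = eq$P_lv, p_imp = eq$p_imp,
       Q_mi = Q_mi)
}
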