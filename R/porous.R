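# Poroelastic fluid-side constitutive relations for the myocardial
# compartments: porosity kinematics under an incompressible solid matrix,
# the microvascular pressure-volume law, a compaction barrier and
# deformation-dependent permeability scaling.
#
# Units: kg-mm-s system throughout the package, so pressures are in kPa,
# flows in mm^3/s, densities in kg/mm^3.

#' Poroelastic constitutive parameters
#'
#' Bundles the parameters of the microvascular pressure-volume law, the
#' compaction barrier and the permeability scaling used by the tissue
#' compartments. The rest-pressure offset `p_o` is derived so that the pore
#' pressure is exactly zero at the reference porosity (`Jphi = phi0`).
#'
#' @param q1 Pressure scale of the exponential term (kPa).
#' @param q2 Pressure scale of the logarithmic term (kPa).
#' @param q3 Dimensionless volume-response scaling.
#' @param phi0 Reference Eulerian porosity, in (0, 1).
#' @param phi_crit Compaction-barrier activation threshold, in (0, phi0].
#'   The barrier contributes nothing while `Jphi >= phi_crit`.
#' @param q_exp Positive integer barrier exponent (controls smoothness of
#'   barrier onset; `q_exp >= 1` keeps pressure and its first derivative
#'   continuous at `phi_crit`).
#' @param r_exp Barrier exponent in (0, 1] controlling the divergence rate
#'   as `Jphi -> 0`.
#' @param barrier_scale Overall barrier pressure scale (kPa). The default is
#'   chosen so the barrier contributes less than 1 percent of the magnitude
#'   of the constitutive pressure at `Jphi = 0.9 * phi0`.
#' @param K0 Reference permeability scalar (mm^3 s kg^-1).
#' @param rho_f Blood density (kg mm^-3).
#'
#' @return An object of class `porous_params` (a list with the fields above
#'   plus the derived `p_o` in kPa).
#' @examples
#' pp <- porous_params()
#' microvascular_pressure(pp$phi0, pp) # 0 at rest volume
#' @export
porous_params <- function(q1 = 0.022, q2 = 1.009, q3 = 80, phi0 = 0.06,
                          phi_crit = phi0, q_exp = 1L, r_exp = 0.5,
                          barrier_scale = NULL, K0 = 2e-3, rho_f = 1.05e-6) {
  stopifnot(phi0 > 0, phi0 < 1, phi_crit > 0, phi_crit <= phi0,
            q_exp >= 1, q_exp == as.integer(q_exp), r_exp > 0, r_exp <= 1,
            q1 > 0, q3 > 0, rho_f > 0)
  p_o <- q1 * exp(q3 * phi0) + q2 * log(q3 * phi0)
  if (is.null(barrier_scale)) {
    # Mildest compliant default: barrier < 1% of |p| at Jphi = 0.9 phi0.
    jphi <- 0.9 * phi0
    p_ref <- abs(q1 * exp(q3 * jphi) + q2 * log(q3 * jphi) - p_o)
    raw <- abs(.barrier_dtheta(jphi, phi_crit, q_exp, r_exp))
    barrier_scale <- if (raw > 0) 0.01 * p_ref / raw else 1
  }
  structure(list(q1 = q1, q2 = q2, q3 = q3, phi0 = phi0,
                 phi_crit = phi_crit, q_exp = as.integer(q_exp),
                 r_exp = r_exp, barrier_scale = barrier_scale,
                 K0 = K0, rho_f = rho_f, p_o = p_o),
            class = "porous_params")
}

#' Lagrangian porosity under matrix incompressibility
#'
#' With an incompressible solid matrix the skeleton Jacobian and the
#' Lagrangian porosity are tied by `J - Jphi = 1 - phi0`, so any volume
#' change of the tissue is carried entirely by the fluid fraction.
#'
#' @param J Skeleton Jacobian (dimensionless, > 0).
#' @param phi0 Reference porosity.
#' @return Lagrangian porosity `Jphi = J - 1 + phi0`.
#' @export
lagrangian_porosity <- function(J, phi0) {
  stopifnot(all(J > 0), phi0 > 0, phi0 < 1)
  jphi <- J - 1 + phi0
  if (any(jphi <= 0))
    stop("compaction limit violated: J - 1 + phi0 <= 0 (barrier should have engaged)")
  jphi
}

# Derivative dTheta/d(Jphi) of the unscaled barrier potential
# Theta = H(phi_crit - x) (x - phi_crit)^(2q) x^(-r); <= 0 on (0, phi_crit).
.barrier_dtheta <- function(jphi, phi_crit, q_exp, r_exp) {
  out <- numeric(length(jphi))
  act <- jphi < phi_crit
  if (any(act)) {
    x <- jphi[act]
    d <- x - phi_crit # negative where active
    out[act] <- 2 * q_exp * d^(2 * q_exp - 1) * x^(-r_exp) -
      r_exp * d^(2 * q_exp) * x^(-r_exp - 1)
  }
  out
}

#' Compaction-barrier pressure contribution
#'
#' Pressure contribution `dTheta/d(Jphi)` of the barrier potential that
#' prevents fluid extraction beyond the compaction limit. It is exactly
#' zero for `Jphi >= phi_crit`, is negative when active, and its
#' magnitude diverges (total pore pressure `-> -Inf`) as `Jphi -> 0+`,
#' so that no further fluid can be drawn out of the tissue.
#'
#' @param jphi Lagrangian porosity (> 0); vectorised.
#' @param params A [porous_params()] object.
#' @return Barrier pressure contribution (kPa), added to the
#'   constitutive pore pressure.
#' @export
barrier_pressure <- function(jphi, params) {
  stopifnot(all(jphi > 0))
  params$barrier_scale *
    .barrier_dtheta(jphi, params$phi_crit, params$q_exp, params$r_exp)
}

#' Microvascular pressure-volume law
#'
#' Pore pressure of the lumped microcirculation as a function of Lagrangian
#' porosity: an exponential term dominating during large net inflow, a
#' logarithmic term dominating during small or negative inflow, an offset
#' enforcing zero pressure at the reference porosity, and the compaction
#' barrier contribution when active.
#'
#' @param jphi Lagrangian porosity (> 0); vectorised.
#' @param params A [porous_params()] object.
#' @param barrier Include the compaction-barrier term (default TRUE).
#' @return Pore pressure (kPa); strictly increasing in `jphi`, zero at
#'   `jphi = phi0`.
#' @export
microvascular_pressure <- function(jphi, params, barrier = TRUE) {
  if (any(jphi <= 0)) stop("jphi must be positive")
  p <- params$q1 * exp(params$q3 * jphi) + params$q2 * log(params$q3 * jphi) -
    params$p_o
  if (barrier) p <- p + barrier_pressure(jphi, params)
  p
}

# d p / d Jphi (needed by implicit compartment updates).
.microvascular_dp <- function(jphi, params) {
  dp <- params$q1 * params$q3 * exp(params$q3 * jphi) + params$q2 / jphi
  act <- jphi < params$phi_crit
  if (any(act)) {
    x <- jphi[act]
    d <- x - params$phi_crit
    q <- params$q_exp; r <- params$r_exp
    d2 <- 2 * q * (2 * q - 1) * d^(2 * q - 2) * x^(-r) -
      4 * q * r * d^(2 * q - 1) * x^(-r - 1) +
      r * (r + 1) * d^(2 * q) * x^(-r - 2)
    dp[act] <- dp[act] + params$barrier_scale * d2
  }
  dp
}

#' Inverse of the microvascular pressure-volume law
#'
#' Solves `microvascular_pressure(jphi) = p` for `jphi` by safeguarded
#' Newton iteration. Used to initialise compartments at a prescribed
#' diastolic pore pressure.
#'
#' @param p Target pore pressure (kPa); vectorised.
#' @param params A [porous_params()] object.
#' @return Lagrangian porosity.
#' @export
porosity_from_pressure <- function(p, params) {
  vapply(p, function(target) {
    lo <- 1e-4 * params$phi0; hi <- params$phi0
    while (microvascular_pressure(hi, params) < target) hi <- hi * 2
    stats::uniroot(function(x) microvascular_pressure(x, params) - target,
                   c(lo, hi), tol = 1e-12)$root
  }, numeric(1))
}

#' Deformation-dependent permeability scaling
#'
#' Scaling factor of the hydraulic permeability (and of the venous
#' conductance) with tissue deformation, derived from the Poiseuille
#' conductance of a representative vessel. The isotropic mode
#' (`J * phi^2 / phi0^2`) and the length-preserving mode
#' (`(J*phi / phi0)^2`) bound the admissible scaling from below and above
#' for `J >= 1`.
#'
#' @param J Skeleton Jacobian (> 0).
#' @param phi Eulerian porosity, in `[0, 1)`.
#' @param phi0 Reference porosity.
#' @param mode `"isotropic"` (default) or `"length-preserving"`.
#' @return Dimensionless scaling factor; 1 at the reference state.
#' @export
permeability_scale <- function(J, phi, phi0,
                               mode = c("isotropic", "length-preserving")) {
  mode <- match.arg(mode)
  stopifnot(all(J > 0), all(phi >= 0), all(phi < 1))
  if (mode == "isotropic") J * phi^2 / phi0^2 else (J * phi / phi0)^2
}

#' Added fluid mass per unit reference volume
#'
#' @param jphi Lagrangian porosity (>= 0).
#' @param params A [porous_params()] object (uses `rho_f`, `phi0`).
#' @return Added fluid mass `m = rho_f * (jphi - phi0)` (kg mm^-3).
#' @export
fluid_mass <- function(jphi, params) {
  stopifnot(all(jphi >= 0))
  params$rho_f * (jphi - params$phi0)
}

#' Lagrangian porosity from added fluid mass
#'
#' Inverse of [fluid_mass()].
#' @param m Added fluid mass per unit reference volume (kg mm^-3).
#' @param params A [porous_params()] object.
#' @return Lagrangian porosity.
#' @export
porosity_from_mass <- function(m, params) {
  m / params$rho_f + params$phi0
}
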