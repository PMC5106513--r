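// Compiled inner loop of the integrated perfusion model: the coupled
// heart-valve-windkessel ODEs, the two-step Lax-Wendroff update of the
// 1D network with characteristic boundary treatment and junction Newton
// solves, and the lumped poroelastic compartment update. Mirrors the R
// reference implementations in R/heart.R, R/oned.R and R/tissue.R; a
// test asserts agreement between the two paths.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double sq(double x) { return x * x; }

struct HeartPars {
  double T0s, t_r0, t_d, t_max, a4, a6, a7, t_period;
  double V_wall, V0_cav, P_la, passive_a, passive_b;
  double theta_max, CQ_ao, K1ao, K_fao, T_ao, R_a, R_s, C, CQ_mi, C_mi;
  int n_layers;
  std::vector<double> offsets, r_mid0;
};

struct PorousPars {
  double q1, q2, q3, phi0, phi_crit, r_exp, barrier_scale, p_o;
  int q_exp;
  bool iso; // permeability scaling mode
};

static void sphere_radii(double V, const HeartPars &hp,
                         std::vector<double> &r, std::vector<double> &rm) {
  const double k = 3.0 / (4.0 * M_PI);
  int n = hp.n_layers;
  for (int i = 0; i <= n; ++i)
    r[i] = std::cbrt(k * (V + hp.V_wall * i / n));
  for (int i = 0; i < n; ++i)
    rm[i] = std::cbrt(k * (V + hp.V_wall * (i + 0.5) / n));
}

static double active_stress_c(double t, double off, double lam,
                              const HeartPars &hp) {
  double x = t - off;
  double tc = x - hp.t_period * std::floor(x / hp.t_period);
  if (tc >= hp.t_max) return 0.0;
  double phi = std::tanh(hp.a6 * (lam - hp.a7));
  double tr = hp.t_r0 + hp.a4 * (1.0 - phi);
  return hp.T0s * phi * sq(std::tanh(tc / tr)) *
         sq(std::tanh((hp.t_max - tc) / hp.t_d));
}

// Pore pressure of the microvascular law incl. compaction barrier.
static double pore_pressure_c(double jphi, const PorousPars &pp) {
  double p = pp.q1 * std::exp(pp.q3 * jphi) +
             pp.q2 * std::log(pp.q3 * jphi) - pp.p_o;
  if (jphi < pp.phi_crit) {
    double d = jphi - pp.phi_crit;
    double dth = 2.0 * pp.q_exp * std::pow(d, 2 * pp.q_exp - 1) *
                     std::pow(jphi, -pp.r_exp) -
                 pp.r_exp * std::pow(d, 2 * pp.q_exp) *
                     std::pow(jphi, -pp.r_exp - 1.0);
    p += pp.barrier_scale * dth;
  }
  return p;
}

// [[Rcpp::export]]
List cpp_run_cycle(List geom, NumericVector A_in, NumericVector Q_in,
                   List heart_pars, List heart_state, List porous_pars,
                   List tissue_pars, NumericVector Jphi_in,
                   NumericMatrix W, IntegerVector comp_layer,
                   IntegerVector term_layer, List control) {
  // ---- unpack geometry -------------------------------------------------
  const int total = as<int>(geom["total"]);
  NumericVector dxv = geom["dx"], beta = geom["beta"], A0 = geom["A0"],
                sqrtA0 = geom["sqrtA0"], alpha = geom["alpha"],
                K = geom["K"], cwave = geom["cwave"], fcoef = geom["fcoef"],
                term_R = geom["term_R"];
  IntegerVector pairL = geom["pairL"], pairR = geom["pairR"],
                int_nodes = geom["int_nodes"], int_pL = geom["int_pL"],
                int_pR = geom["int_pR"], term_node = geom["term_node"],
                term_nb = geom["term_nb"];
  const int root_node = as<int>(geom["root_node"]) - 1;
  const int root_nb = as<int>(geom["root_nb"]) - 1;
  const double rho = as<double>(geom["rho"]);
  const double dt_stable = as<double>(geom["dt_stable"]);
  bool has_bif = geom.containsElementNamed("bif") &&
                 !Rf_isNull(geom["bif"]);
  IntegerVector b_pe, b_pn, b_d1s, b_d1n, b_d2s, b_d2n;
  if (has_bif) {
    List b = geom["bif"];
    b_pe = b["pe"]; b_pn = b["pn"]; b_d1s = b["d1s"]; b_d1n = b["d1n"];
    b_d2s = b["d2s"]; b_d2n = b["d2n"];
  }
  bool has_uni = geom.containsElementNamed("uni") &&
                 !Rf_isNull(geom["uni"]);
  IntegerVector u_pe, u_pn, u_d1s, u_d1n;
  if (has_uni) {
    List u = geom["uni"];
    u_pe = u["pe"]; u_pn = u["pn"]; u_d1s = u["d1s"]; u_d1n = u["d1n"];
  }
  const int n_pairs = pairL.size(), n_int = int_nodes.size(),
            n_term = term_node.size();

  // ---- heart parameters ------------------------------------------------
  HeartPars hp;
  hp.T0s = as<double>(heart_pars["T0"]) * as<double>(heart_pars["T0_scale"]);
  hp.t_r0 = as<double>(heart_pars["t_r0"]);
  hp.t_d = as<double>(heart_pars["t_d"]);
  hp.t_max = as<double>(heart_pars["t_max"]);
  hp.a4 = as<double>(heart_pars["a4"]);
  hp.a6 = as<double>(heart_pars["a6"]);
  hp.a7 = as<double>(heart_pars["a7"]);
  hp.t_period = as<double>(heart_pars["t_period"]);
  hp.V_wall = as<double>(heart_pars["V_wall"]);
  hp.V0_cav = as<double>(heart_pars["V0_cav"]);
  hp.P_la = as<double>(heart_pars["P_la"]);
  hp.passive_a = as<double>(heart_pars["passive_a"]);
  hp.passive_b = as<double>(heart_pars["passive_b"]);
  hp.theta_max = as<double>(heart_pars["theta_max"]);
  hp.CQ_ao = as<double>(heart_pars["CQ_ao"]);
  hp.K1ao = as<double>(heart_pars["K1ao"]);
  hp.K_fao = as<double>(heart_pars["K_fao"]);
  hp.T_ao = as<double>(heart_pars["T_ao"]);
  hp.R_a = as<double>(heart_pars["R_a"]);
  hp.R_s = as<double>(heart_pars["R_s"]);
  hp.C = as<double>(heart_pars["C"]);
  hp.CQ_mi = as<double>(heart_pars["CQ_mi"]);
  hp.C_mi = as<double>(heart_pars["C_mi"]);
  hp.n_layers = as<int>(heart_pars["n_layers"]);
  NumericVector offs = heart_pars["activation_offsets"];
  hp.offsets.assign(offs.begin(), offs.end());
  const int nl = hp.n_layers;
  std::vector<double> r(nl + 1), rm(nl);
  sphere_radii(hp.V0_cav, hp, r, rm);
  hp.r_mid0 = rm;

  // ---- porous / tissue -------------------------------------------------
  PorousPars pp;
  pp.q1 = as<double>(porous_pars["q1"]);
  pp.q2 = as<double>(porous_pars["q2"]);
  pp.q3 = as<double>(porous_pars["q3"]);
  pp.phi0 = as<double>(porous_pars["phi0"]);
  pp.phi_crit = as<double>(porous_pars["phi_crit"]);
  pp.q_exp = as<int>(porous_pars["q_exp"]);
  pp.r_exp = as<double>(porous_pars["r_exp"]);
  pp.barrier_scale = as<double>(porous_pars["barrier_scale"]);
  pp.p_o = as<double>(porous_pars["p_o"]);
  pp.iso = as<std::string>(tissue_pars["perm_mode"]) == "isotropic";
  NumericVector V_ref = tissue_pars["V_ref"];
  const double gamma = as<double>(tissue_pars["gamma"]);
  const double p_drain = as<double>(tissue_pars["p_drain"]);
  const int n_comp = Jphi_in.size();

  // ---- control ---------------------------------------------------------
  const double dt = as<double>(control["dt"]);
  const int n_steps = as<int>(control["n_steps"]);
  const int save_every = as<int>(control["save_every"]);
  const double coupling_tol = as<double>(control["coupling_tol"]);
  const int coupling_max_iter = as<int>(control["coupling_max_iter"]);
  const int probe = as<int>(control["probe"]) - 1;
  const int n_save = n_steps / save_every;
  const int n_sub = (int)std::ceil(dt / dt_stable);
  const double dts = dt / n_sub;

  // ---- state -----------------------------------------------------------
  std::vector<double> A(A_in.begin(), A_in.end()),
      Q(Q_in.begin(), Q_in.end());
  std::vector<double> A_base(total), Q_base(total), Anew(total),
      Qnew(total), u(total), cv(total), F1(total), F2(total), S2(total),
      Ah(n_pairs), Qh(n_pairs), F1h(n_pairs), F2h(n_pairs), S2h(n_pairs);
  double V_lv = as<double>(heart_state["V_lv"]);
  double theta = as<double>(heart_state["theta"]);
  double dtheta = as<double>(heart_state["dtheta"]);
  double Q_ao = as<double>(heart_state["Q_ao"]);
  double P_s = as<double>(heart_state["P_s"]);
  double P_as = as<double>(heart_state["P_as"]);
  std::vector<double> Jphi(Jphi_in.begin(), Jphi_in.end()),
      Jphi_new(n_comp), p_imp(n_comp), p_pore(n_comp), Qout(n_comp),
      Qin(n_comp), pbar(n_term), pbar_new(n_term), Qt(n_term);
  std::vector<double> lam(nl), sig(nl), pb(nl + 1), pimp_layer(nl);

  NumericMatrix sys(n_save, 11), layerQ(n_save, nl),
      compJ(n_save, n_comp), compP(n_save, n_comp);
  NumericVector Qin_sum(n_comp);
  double inlet_vol = 0, term_vol = 0, venous_vol = 0;
  long coupling_iters = 0;
  int isave = 0;

  for (int k = 0; k < n_steps; ++k) {
    double t_cyc = k * dt;
    // ---- heart step ----------------------------------------------------
    sphere_radii(V_lv, hp, r, rm);
    for (int i = 0; i < nl; ++i) {
      lam[i] = rm[i] / hp.r_mid0[i];
      double e = lam[i] * lam[i] - 1.0;
      double pas = hp.passive_a * e * std::exp(hp.passive_b * e * e) *
                   lam[i] * lam[i];
      sig[i] = pas + active_stress_c(t_cyc, hp.offsets[i], lam[i], hp);
    }
    pb[nl] = 0.0;
    for (int i = nl - 1; i >= 0; --i)
      pb[i] = pb[i + 1] + 2.0 * sig[i] * std::log(r[i + 1] / r[i]);
    for (int i = 0; i < nl; ++i)
      pimp_layer[i] = pb[i + 1] + 2.0 * sig[i] * std::log(r[i + 1] / rm[i]);
    double P_lv = pb[0];
    double Q_mi = (hp.P_la > P_lv)
                      ? hp.CQ_mi * std::tanh(hp.C_mi * (hp.P_la - P_lv))
                      : 0.0;
    double dP = P_lv - P_as;
    double acc = hp.K1ao * (P_lv - P_s) * std::cos(theta) -
                 hp.K_fao * dtheta;
    dtheta += dt * acc;
    theta += dt * dtheta;
    if (theta < 0) { theta = 0; if (dtheta < 0) dtheta = 0; }
    if (theta > hp.theta_max) {
      theta = hp.theta_max; if (dtheta > 0) dtheta = 0;
    }
    double AR = sq((1.0 - std::cos(theta)) / (1.0 - std::cos(hp.theta_max)));
    double Q_ss = (dP >= 0 ? 1.0 : -1.0) * hp.CQ_ao * AR *
                  std::sqrt(std::fabs(dP));
    Q_ao = Q_ss + (Q_ao - Q_ss) * std::exp(-dt / hp.T_ao);
    double tau = hp.R_s * hp.C, target = Q_ao * hp.R_s;
    P_s = target + (P_s - target) * std::exp(-dt / tau);
    P_as = P_s + hp.R_a * Q_ao;
    V_lv += dt * (Q_mi - Q_ao);
    if (V_lv <= 0) stop("cavity volume became non-positive");

    for (int c = 0; c < n_comp; ++c) p_imp[c] = pimp_layer[comp_layer[c] - 1];

    // ---- coupling: 1D network <-> compartments -------------------------
    // pore pressure and venous outflow of the pre-step state (fixed
    // across coupling iterations, matching the R reference path)
    std::vector<double> p_pore_old(n_comp);
    for (int c = 0; c < n_comp; ++c)
      p_pore_old[c] = pore_pressure_c(Jphi[c], pp) + p_imp[c];
    for (int tIdx = 0; tIdx < n_term; ++tIdx) {
      double s = 0;
      for (int c = 0; c < n_comp; ++c) s += W(tIdx, c) * p_pore_old[c];
      pbar[tIdx] = s;
    }
    A_base = A; Q_base = Q;
    for (int ci = 0; ci < coupling_max_iter; ++ci) {
      A = A_base; Q = Q_base;
      // ---- n_sub Lax-Wendroff substeps --------------------------------
      for (int sub = 0; sub < n_sub; ++sub) {
        for (int i = 0; i < total; ++i) {
          if (A[i] <= 0) stop("vessel collapse beyond tube-law validity");
          u[i] = Q[i] / A[i];
          cv[i] = cwave[i] * std::pow(A[i], 0.25);
          F1[i] = Q[i];
          F2[i] = alpha[i] * Q[i] * u[i] + fcoef[i] * A[i] * std::sqrt(A[i]);
          S2[i] = -K[i] * u[i];
          if ((std::fabs(u[i]) + cv[i]) * dts / dxv[i] > 1.0)
            stop("CFL violation in 1D solver; reduce dt");
        }
        for (int pIdx = 0; pIdx < n_pairs; ++pIdx) {
          int iL = pairL[pIdx] - 1, iR = pairR[pIdx] - 1;
          double dx = dxv[iL];
          Ah[pIdx] = 0.5 * (A[iL] + A[iR]) -
                     dts / (2 * dx) * (F1[iR] - F1[iL]);
          Qh[pIdx] = 0.5 * (Q[iL] + Q[iR]) -
                     dts / (2 * dx) * (F2[iR] - F2[iL]) +
                     dts / 4.0 * (S2[iL] + S2[iR]);
          double uh = Qh[pIdx] / Ah[pIdx];
          F1h[pIdx] = Qh[pIdx];
          F2h[pIdx] = alpha[iL] * Qh[pIdx] * uh +
                      fcoef[iL] * Ah[pIdx] * std::sqrt(Ah[pIdx]);
          S2h[pIdx] = -K[iL] * uh;
        }
        Anew = A; Qnew = Q;
        for (int j = 0; j < n_int; ++j) {
          int node = int_nodes[j] - 1, pL = int_pL[j] - 1, pR = int_pR[j] - 1;
          double dx = dxv[node];
          Anew[node] = A[node] - dts / dx * (F1h[pR] - F1h[pL]);
          Qnew[node] = Q[node] - dts / dx * (F2h[pR] - F2h[pL]) +
                       dts / 2.0 * (S2h[pL] + S2h[pR]);
        }
        // inlet: pressure clamp via backward characteristic
        {
          int nN = root_node, nb = root_nb;
          double lamfoot = std::max(0.0, (cv[nN] - u[nN]) * dts);
          double frac = std::min(1.0, lamfoot / dxv[nN]);
          double Af = A[nN] * (1 - frac) + A[nb] * frac;
          double Qf = Q[nN] * (1 - frac) + Q[nb] * frac;
          double Wm = Qf / Af - 4.0 * cwave[nN] * std::pow(Af, 0.25);
          double sqA = P_as / beta[nN] + sqrtA0[nN];
          if (sqA <= 0) stop("inlet pressure below collapse limit");
          double Ain = sqA * sqA;
          Anew[nN] = Ain;
          Qnew[nN] = Ain * (Wm + 4.0 * cwave[nN] * std::pow(Ain, 0.25));
        }
        // terminals: resistive coupling Newton
        for (int tIdx = 0; tIdx < n_term; ++tIdx) {
          int nN = term_node[tIdx] - 1, nb = term_nb[tIdx] - 1;
          double lamfoot = std::max(0.0, (u[nN] + cv[nN]) * dts);
          double frac = std::min(1.0, lamfoot / dxv[nN]);
          double Af = A[nN] * (1 - frac) + A[nb] * frac;
          double Qf = Q[nN] * (1 - frac) + Q[nb] * frac;
          double Wp = Qf / Af + 4.0 * cwave[nN] * std::pow(Af, 0.25);
          double At = A[nN], Rt = term_R[tIdx];
          for (int it = 0; it < 30; ++it) {
            double ct = cwave[nN] * std::pow(At, 0.25);
            double g = At * (Wp - 4.0 * ct) -
                       (beta[nN] * (std::sqrt(At) - sqrtA0[nN]) -
                        pbar[tIdx]) / Rt;
            double dg = Wp - 5.0 * ct -
                        beta[nN] / (2.0 * std::sqrt(At) * Rt);
            double dA = g / dg;
            double Atn = At - dA;
            if (Atn < 0.5 * At) Atn = 0.5 * At;
            if (Atn > 2.0 * At) Atn = 2.0 * At;
            At = Atn;
            if (std::fabs(dA) / At < 1e-12) break;
          }
          Anew[nN] = At;
          Qnew[nN] = (beta[nN] * (std::sqrt(At) - sqrtA0[nN]) -
                      pbar[tIdx]) / Rt;
        }
        // bifurcations
        for (int jIdx = 0; jIdx < b_pe.size(); ++jIdx) {
          int n1 = b_pe[jIdx] - 1, nb1 = b_pn[jIdx] - 1;
          int n2 = b_d1s[jIdx] - 1, nb2 = b_d1n[jIdx] - 1;
          int n3 = b_d2s[jIdx] - 1, nb3 = b_d2n[jIdx] - 1;
          // outgoing invariants at characteristic feet
          double lam1 = std::max(0.0, (u[n1] + cv[n1]) * dts);
          double f1 = std::min(1.0, lam1 / dxv[n1]);
          double Af1 = A[n1] * (1 - f1) + A[nb1] * f1;
          double Qf1 = Q[n1] * (1 - f1) + Q[nb1] * f1;
          double W1 = Qf1 / Af1 + 4.0 * cwave[n1] * std::pow(Af1, 0.25);
          double lam2 = std::max(0.0, (cv[n2] - u[n2]) * dts);
          double f2 = std::min(1.0, lam2 / dxv[n2]);
          double Af2 = A[n2] * (1 - f2) + A[nb2] * f2;
          double Qf2 = Q[n2] * (1 - f2) + Q[nb2] * f2;
          double W2 = Qf2 / Af2 - 4.0 * cwave[n2] * std::pow(Af2, 0.25);
          double lam3 = std::max(0.0, (cv[n3] - u[n3]) * dts);
          double f3 = std::min(1.0, lam3 / dxv[n3]);
          double Af3 = A[n3] * (1 - f3) + A[nb3] * f3;
          double Qf3 = Q[n3] * (1 - f3) + Q[nb3] * f3;
          double W3 = Qf3 / Af3 - 4.0 * cwave[n3] * std::pow(Af3, 0.25);
          double A1 = A[n1], A2 = A[n2], A3 = A[n3];
          double c1, c2, c3, u1, u2, u3;
          bool ok = false;
          for (int it = 0; it < 30; ++it) {
            c1 = cwave[n1] * std::pow(A1, 0.25);
            c2 = cwave[n2] * std::pow(A2, 0.25);
            c3 = cwave[n3] * std::pow(A3, 0.25);
            u1 = W1 - 4 * c1; u2 = W2 + 4 * c2; u3 = W3 + 4 * c3;
            double p1 = beta[n1] * (std::sqrt(A1) - sqrtA0[n1]);
            double p2 = beta[n2] * (std::sqrt(A2) - sqrtA0[n2]);
            double p3 = beta[n3] * (std::sqrt(A3) - sqrtA0[n3]);
            double R1 = A1 * u1 - A2 * u2 - A3 * u3;
            double R2 = p1 + 0.5 * rho * u1 * u1 - p2 - 0.5 * rho * u2 * u2;
            double R3 = p1 + 0.5 * rho * u1 * u1 - p3 - 0.5 * rho * u3 * u3;
            double scale = std::max(A1 * c1, std::max(A2 * c2, A3 * c3));
            double cmax = std::max(c1, std::max(c2, c3));
            double pscale = rho * cmax * cmax;
            if (std::fabs(R1) / scale < 1e-10 &&
                std::fabs(R2) / pscale < 1e-10 &&
                std::fabs(R3) / pscale < 1e-10) { ok = true; break; }
            double a11 = u1 - c1, a12 = -(u2 + c2), a13 = -(u3 + c3);
            double a21 = rho * c1 * (c1 - u1) / A1;
            double a22 = -rho * c2 * (c2 + u2) / A2;
            double a31 = a21, a33 = -rho * c3 * (c3 + u3) / A3;
            double det = a11 * a22 * a33 - a12 * a21 * a33 -
                         a13 * a22 * a31;
            double d1 = (R1 * a22 * a33 - a12 * R2 * a33 -
                         a13 * a22 * R3) / det;
            double d2 = (a11 * R2 * a33 - R1 * a21 * a33 +
                         a13 * (a21 * R3 - R2 * a31)) / det;
            double d3 = (a11 * a22 * R3 - a12 * (a21 * R3 - R2 * a31) -
                         R1 * a22 * a31) / det;
            A1 = std::max(0.1 * A1, A1 - d1);
            A2 = std::max(0.1 * A2, A2 - d2);
            A3 = std::max(0.1 * A3, A3 - d3);
          }
          if (!ok) stop("junction Newton failed to converge");
          Anew[n1] = A1; Qnew[n1] = A1 * (W1 - 4 * c1);
          Anew[n2] = A2; Qnew[n2] = A2 * (W2 + 4 * c2);
          Anew[n3] = A3; Qnew[n3] = A3 * (W3 + 4 * c3);
        }
        // pass-through junctions
        for (int jIdx = 0; jIdx < u_pe.size(); ++jIdx) {
          int n1 = u_pe[jIdx] - 1, nb1 = u_pn[jIdx] - 1;
          int n2 = u_d1s[jIdx] - 1, nb2 = u_d1n[jIdx] - 1;
          double lam1 = std::max(0.0, (u[n1] + cv[n1]) * dts);
          double f1 = std::min(1.0, lam1 / dxv[n1]);
          double Af1 = A[n1] * (1 - f1) + A[nb1] * f1;
          double Qf1 = Q[n1] * (1 - f1) + Q[nb1] * f1;
          double W1 = Qf1 / Af1 + 4.0 * cwave[n1] * std::pow(Af1, 0.25);
          double lam2 = std::max(0.0, (cv[n2] - u[n2]) * dts);
          double f2 = std::min(1.0, lam2 / dxv[n2]);
          double Af2 = A[n2] * (1 - f2) + A[nb2] * f2;
          double Qf2 = Q[n2] * (1 - f2) + Q[nb2] * f2;
          double W2 = Qf2 / Af2 - 4.0 * cwave[n2] * std::pow(Af2, 0.25);
          double A1 = A[n1], A2 = A[n2], c1, c2, u1, u2;
          bool ok = false;
          for (int it = 0; it < 30; ++it) {
            c1 = cwave[n1] * std::pow(A1, 0.25);
            c2 = cwave[n2] * std::pow(A2, 0.25);
            u1 = W1 - 4 * c1; u2 = W2 + 4 * c2;
            double p1 = beta[n1] * (std::sqrt(A1) - sqrtA0[n1]);
            double p2 = beta[n2] * (std::sqrt(A2) - sqrtA0[n2]);
            double R1 = A1 * u1 - A2 * u2;
            double R2 = p1 + 0.5 * rho * u1 * u1 - p2 - 0.5 * rho * u2 * u2;
            double scale = std::max(A1 * c1, A2 * c2);
            double cmax = std::max(c1, c2);
            double pscale = rho * cmax * cmax;
            if (std::fabs(R1) / scale < 1e-10 &&
                std::fabs(R2) / pscale < 1e-10) { ok = true; break; }
            double a11 = u1 - c1, a12 = -(u2 + c2);
            double a21 = rho * c1 * (c1 - u1) / A1;
            double a22 = -rho * c2 * (c2 + u2) / A2;
            double det = a11 * a22 - a12 * a21;
            double d1 = (R1 * a22 - a12 * R2) / det;
            double d2 = (a11 * R2 - a21 * R1) / det;
            A1 = std::max(0.1 * A1, A1 - d1);
            A2 = std::max(0.1 * A2, A2 - d2);
          }
          if (!ok) stop("junction Newton failed to converge");
          Anew[n1] = A1; Qnew[n1] = A1 * (W1 - 4 * c1);
          Anew[n2] = A2; Qnew[n2] = A2 * (W2 + 4 * c2);
        }
        A.swap(Anew); Q.swap(Qnew);
      } // substeps

      // compartment trial update
      for (int tIdx = 0; tIdx < n_term; ++tIdx)
        Qt[tIdx] = Q[term_node[tIdx] - 1];
      for (int c = 0; c < n_comp; ++c) {
        double s = 0;
        for (int tIdx = 0; tIdx < n_term; ++tIdx)
          s += W(tIdx, c) * Qt[tIdx];
        Qin[c] = s;
      }
      double dmax = 0;
      for (int c = 0; c < n_comp; ++c) {
        double J = Jphi[c] + 1.0 - pp.phi0;
        double phi = Jphi[c] / J;
        double scale = pp.iso ? J * phi * phi / (pp.phi0 * pp.phi0)
                              : sq(J * phi / pp.phi0);
        Qout[c] = gamma * scale * (p_pore_old[c] - p_drain);
        Jphi_new[c] = Jphi[c] + dt * (Qin[c] - Qout[c]) / V_ref[c];
        if (Jphi_new[c] <= 0)
          stop("compartment porosity collapsed; barrier misconfigured");
      }
      for (int c = 0; c < n_comp; ++c)
        p_pore[c] = pore_pressure_c(Jphi_new[c], pp) + p_imp[c];
      for (int tIdx = 0; tIdx < n_term; ++tIdx) {
        double s = 0;
        for (int c = 0; c < n_comp; ++c) s += W(tIdx, c) * p_pore[c];
        pbar_new[tIdx] = s;
        double rel = std::fabs(pbar_new[tIdx] - pbar[tIdx]) /
                     std::max(1.0, std::fabs(pbar[tIdx]));
        if (rel > dmax) dmax = rel;
        pbar[tIdx] = pbar_new[tIdx];
      }
      ++coupling_iters;
      if (dmax < coupling_tol) break;
    } // coupling
    Jphi = Jphi_new;

    inlet_vol += Q[root_node] * dt;
    double tsum = 0;
    for (int tIdx = 0; tIdx < n_term; ++tIdx) tsum += Qt[tIdx];
    term_vol += tsum * dt;
    double vsum = 0;
    for (int c = 0; c < n_comp; ++c) vsum += Qout[c];
    venous_vol += vsum * dt;

    if ((k + 1) % save_every == 0 && isave < n_save) {
      sys(isave, 0) = t_cyc; sys(isave, 1) = P_lv; sys(isave, 2) = P_as;
      sys(isave, 3) = P_s; sys(isave, 4) = V_lv; sys(isave, 5) = Q_ao;
      sys(isave, 6) = Q_mi; sys(isave, 7) = theta;
      sys(isave, 8) = Q[root_node];
      sys(isave, 9) = beta[probe] * (std::sqrt(A[probe]) - sqrtA0[probe]);
      sys(isave, 10) = Q[probe] / A[probe];
      for (int l = 0; l < nl; ++l) {
        double s = 0;
        for (int tIdx = 0; tIdx < n_term; ++tIdx)
          if (term_layer[tIdx] == l + 1) s += Qt[tIdx];
        layerQ(isave, l) = s;
      }
      for (int c = 0; c < n_comp; ++c) {
        compJ(isave, c) = Jphi[c];
        compP(isave, c) = p_pore[c];
        Qin_sum[c] += Qin[c];
      }
      ++isave;
    }
  } // steps

  return List::create(
      _["sys"] = sys, _["layerQ"] = layerQ, _["compJ"] = compJ,
      _["compP"] = compP, _["Qin_sum"] = Qin_sum,
      _["inlet_vol"] = inlet_vol, _["term_vol"] = term_vol,
      _["venous_vol"] = venous_vol,
      _["A"] = NumericVector(A.begin(), A.end()),
      _["Q"] = NumericVector(Q.begin(), Q.end()),
      _["heart"] = List::create(
          _["V_lv"] = V_lv, _["theta"] = theta, _["dtheta"] = dtheta,
          _["Q_ao"] = Q_ao, _["P_s"] = P_s, _["P_as"] = P_as),
      _["Jphi"] = NumericVector(Jphi.begin(), Jphi.end()),
      _["Qout"] = NumericVector(Qout.begin(), Qout.end()),
      _["coupling_iters"] = (double)coupling_iters);
}
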