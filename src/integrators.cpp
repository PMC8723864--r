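// Fixed-step RK4 integration of the modified Toporikova-Butera PBC neuron:
// single 5-D neuron, delay-coupled 8-D pair (method of steps, cubic Hermite
// history interpolation), and Benettin two-trajectory maximal-Lyapunov
// estimators for both. The somatic kinetics follow the standard
// Butera/Park-Rubin functional forms; the calcium subsystem is the elliptic
// rotation around (Ca_c, l_c).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Pars {
  double Cm, gNa, gK, gL, gNaP, gCAN;
  double VNa, VK, VL, Vm, Vn, Vp, Vh;
  double sm, sn, sh, smp;
  double taun, tauh;           // tau_n_bar, tau_h_bar (ms)
  double nCAN, KCAN;
  double eps, d, Cac, lc;
  double can_scale;
};

static Pars parse_pars(const List& p) {
  Pars q;
  q.Cm = p["C_m"]; q.gNa = p["g_Na"]; q.gK = p["g_K"]; q.gL = p["g_L"];
  q.gNaP = p["g_NaP"]; q.gCAN = p["g_CAN"];
  q.VNa = p["V_Na"]; q.VK = p["V_K"]; q.VL = p["V_L"];
  q.Vm = p["V_m"]; q.Vn = p["V_n"]; q.Vp = p["V_p"]; q.Vh = p["V_h"];
  q.sm = p["s_m"]; q.sn = p["s_n"]; q.sh = p["s_h"]; q.smp = p["s_mp"];
  q.taun = p["tau_n_bar"]; q.tauh = p["tau_h_bar"];
  q.nCAN = p["n_CAN"]; q.KCAN = p["K_CAN"];
  q.eps = p["eps"]; q.d = p["d"]; q.Cac = p["Ca_c"]; q.lc = p["l_c"];
  q.can_scale = p["can_scale"];
  return q;
}

static inline double boltz(double V, double V0, double s) {
  return 1.0 / (1.0 + std::exp((V - V0) / s));
}

// dstate for one somatic compartment (V, n, h) at calcium Ca
static inline void soma_rhs(const Pars& p, double V, double n, double h,
                            double Ca, double Iext, double& dV, double& dn,
                            double& dh) {
  double m = boltz(V, p.Vm, p.sm);
  double mp = boltz(V, p.Vp, p.smp);
  // continuous limit f -> 0 as Ca -> 0+ (guards RK4 stage overshoot on
  // ellipses tangent to Ca = 0)
  double fca =
      Ca > 0.0 ? p.can_scale / (1.0 + std::pow(p.KCAN / Ca, p.nCAN)) : 0.0;
  double INa = p.gNa * m * m * m * (1.0 - n) * (V - p.VNa);
  double INaP = p.gNaP * mp * h * (V - p.VNa);
  double ICAN = p.gCAN * fca * (V - p.VNa);
  double IK = p.gK * n * n * n * n * (V - p.VK);
  double IL = p.gL * (V - p.VL);
  dV = (-INa - INaP - ICAN - IK - IL - Iext) / p.Cm;
  double taunV = p.taun / std::cosh((V - p.Vn) / (2.0 * p.sn));
  double tauhV = p.tauh / std::cosh((V - p.Vh) / (2.0 * p.sh));
  dn = (boltz(V, p.Vn, p.sn) - n) / taunV;
  dh = (boltz(V, p.Vh, p.sh) - h) / tauhV;
}

static inline void single_rhs(const Pars& p, const double y[5], double Iexc,
                              double dy[5]) {
  soma_rhs(p, y[0], y[1], y[2], y[3], Iexc, dy[0], dy[1], dy[2]);
  dy[3] = -p.eps * p.d * (y[4] - p.lc);
  dy[4] = (p.eps / p.d) * (y[3] - p.Cac);
}

// [[Rcpp::export]]
NumericMatrix cpp_simulate_single(List params, double Iexc, NumericVector y0,
                                  double t_end, double dt, double dt_sample) {
  Pars p = parse_pars(params);
  int every = (int)std::lround(dt_sample / dt);
  long nstep = (long)std::lround(t_end / dt);
  long nsamp = nstep / every + 1;
  NumericMatrix out(nsamp, 6);
  double y[5], k1[5], k2[5], k3[5], k4[5], tmp[5];
  for (int i = 0; i < 5; ++i) y[i] = y0[i];
  long isamp = 0;
  out(0, 0) = 0.0;
  for (int i = 0; i < 5; ++i) out(0, i + 1) = y[i];
  ++isamp;
  for (long s = 1; s <= nstep; ++s) {
    single_rhs(p, y, Iexc, k1);
    for (int i = 0; i < 5; ++i) tmp[i] = y[i] + 0.5 * dt * k1[i];
    single_rhs(p, tmp, Iexc, k2);
    for (int i = 0; i < 5; ++i) tmp[i] = y[i] + 0.5 * dt * k2[i];
    single_rhs(p, tmp, Iexc, k3);
    for (int i = 0; i < 5; ++i) tmp[i] = y[i] + dt * k3[i];
    single_rhs(p, tmp, Iexc, k4);
    for (int i = 0; i < 5; ++i)
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    if (!std::isfinite(y[0]))
      stop("integration diverged at t = %f ms", s * dt);
    if (s % every == 0) {
      out(isamp, 0) = s * dt;
      for (int i = 0; i < 5; ++i) out(isamp, i + 1) = y[i];
      ++isamp;
    }
  }
  return out;
}

// --- delay-coupled pair -----------------------------------------------------
// state: V1, n1, h1, V2, n2, h2, Ca, l  (shared calcium subsystem)
// I_ci = g_c * (V_j(t - tau_i) - V_i(t)) enters the V_i equation with sign -I_ci.

struct History {
  // stored V and dV/dt for both neurons at integration grid times t0 + k*dt
  std::vector<double> V1, dV1, V2, dV2;
  double t0, dt;
  // cubic Hermite lookup of V_j at time tq; constant history before t0
  double lookup(int j, double tq) const {
    const std::vector<double>& V = (j == 1) ? V1 : V2;
    const std::vector<double>& dV = (j == 1) ? dV1 : dV2;
    if (tq <= t0) return V[0];
    long nseg = (long)V.size() - 1;
    if (nseg < 1)  // first step with tau < dt: linear Taylor from the node
      return V[0] + (tq - t0) * dV[0];
    double x = (tq - t0) / dt;
    long k = (long)std::floor(x);
    if (k > nseg - 1) k = nseg - 1;  // mild extrapolation for tau < dt stages
    if (k < 0) k = 0;
    double u = x - k;
    double h00 = (1 + 2 * u) * (1 - u) * (1 - u);
    double h10 = u * (1 - u) * (1 - u);
    double h01 = u * u * (3 - 2 * u);
    double h11 = u * u * (u - 1);
    return h00 * V[k] + h10 * dt * dV[k] + h01 * V[k + 1] + h11 * dt * dV[k + 1];
  }
};

struct Net {
  double gc, tau1, tau2, I1, I2;
};

// RHS of the coupled system at stage time t; delayed voltages from history,
// except tau == 0 which uses the instantaneous stage value (ODE degeneracy).
static inline void pair_rhs(const Pars& p, const Net& net, const History& H,
                            double t, const double y[8], double dy[8]) {
  double V2lag = (net.tau1 == 0.0) ? y[3] : H.lookup(2, t - net.tau1);
  double V1lag = (net.tau2 == 0.0) ? y[0] : H.lookup(1, t - net.tau2);
  double Ic1 = net.gc * (V2lag - y[0]);
  double Ic2 = net.gc * (V1lag - y[3]);
  soma_rhs(p, y[0], y[1], y[2], y[6], net.I1 + Ic1, dy[0], dy[1], dy[2]);
  soma_rhs(p, y[3], y[4], y[5], y[6], net.I2 + Ic2, dy[3], dy[4], dy[5]);
  dy[6] = -p.eps * p.d * (y[7] - p.lc);
  dy[7] = (p.eps / p.d) * (y[6] - p.Cac);
}

static inline void pair_step(const Pars& p, const Net& net, History& H,
                             double t, double dt, double y[8]) {
  double k1[8], k2[8], k3[8], k4[8], tmp[8];
  pair_rhs(p, net, H, t, y, k1);
  for (int i = 0; i < 8; ++i) tmp[i] = y[i] + 0.5 * dt * k1[i];
  pair_rhs(p, net, H, t + 0.5 * dt, tmp, k2);
  for (int i = 0; i < 8; ++i) tmp[i] = y[i] + 0.5 * dt * k2[i];
  pair_rhs(p, net, H, t + 0.5 * dt, tmp, k3);
  for (int i = 0; i < 8; ++i) tmp[i] = y[i] + dt * k3[i];
  pair_rhs(p, net, H, t + dt, tmp, k4);
  for (int i = 0; i < 8; ++i)
    y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

static void push_history(const Pars& p, const Net& net, History& H, double t,
                         const double y[8]) {
  double dy[8];
  if (H.V1.empty()) {
    // seed the constant pre-t0 history before the first derivative evaluation
    H.V1.push_back(y[0]);
    H.V2.push_back(y[3]);
    pair_rhs(p, net, H, t, y, dy);
    H.dV1.push_back(dy[0]);
    H.dV2.push_back(dy[3]);
    return;
  }
  pair_rhs(p, net, H, t, y, dy);
  H.V1.push_back(y[0]);
  H.dV1.push_back(dy[0]);
  H.V2.push_back(y[3]);
  H.dV2.push_back(dy[3]);
}

// [[Rcpp::export]]
NumericMatrix cpp_simulate_pair(List params, List network, NumericVector y0,
                                double t_end, double dt, double dt_sample) {
  Pars p = parse_pars(params);
  Net net;
  net.gc = network["g_c"]; net.tau1 = network["tau1"]; net.tau2 = network["tau2"];
  net.I1 = network["I_exc1"]; net.I2 = network["I_exc2"];
  int every = (int)std::lround(dt_sample / dt);
  long nstep = (long)std::lround(t_end / dt);
  long nsamp = nstep / every + 1;
  NumericMatrix out(nsamp, 9);
  double y[8];
  for (int i = 0; i < 8; ++i) y[i] = y0[i];
  History H;
  H.t0 = 0.0;
  H.dt = dt;
  long keep = nstep + 1;  // full history kept; <= ~8e8 bytes only if huge runs
  // bound memory: only max(tau1,tau2)/dt + margin needed, but the ring
  // bookkeeping is avoided by trimming in blocks
  double maxtau = std::max(net.tau1, net.tau2);
  long span = (long)std::ceil(maxtau / dt) + 8;
  (void)keep;
  H.V1.reserve(2 * span + 16);
  push_history(p, net, H, 0.0, y);
  long isamp = 0;
  out(0, 0) = 0.0;
  for (int i = 0; i < 8; ++i) out(0, i + 1) = y[i];
  ++isamp;
  long base = 0;  // index of H grid point at H.t0
  for (long s = 1; s <= nstep; ++s) {
    double t = (s - 1) * dt;
    pair_step(p, net, H, t, dt, y);
    if (!std::isfinite(y[0]) || !std::isfinite(y[3]))
      stop("integration diverged at t = %f ms", s * dt);
    push_history(p, net, H, s * dt, y);
    // trim history older than needed, in blocks to amortize cost
    if ((long)H.V1.size() > 2 * span + 8) {
      long drop = (long)H.V1.size() - (span + 4);
      H.V1.erase(H.V1.begin(), H.V1.begin() + drop);
      H.dV1.erase(H.dV1.begin(), H.dV1.begin() + drop);
      H.V2.erase(H.V2.begin(), H.V2.begin() + drop);
      H.dV2.erase(H.dV2.begin(), H.dV2.begin() + drop);
      base += drop;
      H.t0 = base * dt;
    }
    if (s % every == 0) {
      out(isamp, 0) = s * dt;
      for (int i = 0; i < 8; ++i) out(isamp, i + 1) = y[i];
      ++isamp;
    }
  }
  return out;
}

// --- Benettin maximal Lyapunov exponent ------------------------------------

// [[Rcpp::export]]
List cpp_benettin_single(List params, double Iexc, NumericVector y0, double d0,
                         double renorm, double duration, double discard_frac,
                         double dt) {
  Pars p = parse_pars(params);
  long nren = (long)std::lround(duration / renorm);
  long sper = (long)std::lround(renorm / dt);
  double y[5], z[5], k1[5], k2[5], k3[5], k4[5], tmp[5];
  for (int i = 0; i < 5; ++i) {
    y[i] = y0[i];
    z[i] = y0[i];
  }
  z[0] += d0;
  std::vector<double> logs;
  logs.reserve(nren);
  for (long r = 0; r < nren; ++r) {
    for (long s = 0; s < sper; ++s) {
      double* ys[2] = {y, z};
      for (int w = 0; w < 2; ++w) {
        double* u = ys[w];
        single_rhs(p, u, Iexc, k1);
        for (int i = 0; i < 5; ++i) tmp[i] = u[i] + 0.5 * dt * k1[i];
        single_rhs(p, tmp, Iexc, k2);
        for (int i = 0; i < 5; ++i) tmp[i] = u[i] + 0.5 * dt * k2[i];
        single_rhs(p, tmp, Iexc, k3);
        for (int i = 0; i < 5; ++i) tmp[i] = u[i] + dt * k3[i];
        single_rhs(p, tmp, Iexc, k4);
        for (int i = 0; i < 5; ++i)
          u[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      }
    }
    double d2 = 0.0;
    for (int i = 0; i < 5; ++i) d2 += (z[i] - y[i]) * (z[i] - y[i]);
    double d = std::sqrt(d2);
    if (d <= 0.0) stop("separation underflow: decrease renorm interval");
    logs.push_back(std::log(d / d0));
    double f = d0 / d;
    for (int i = 0; i < 5; ++i) z[i] = y[i] + (z[i] - y[i]) * f;
  }
  long skip = (long)std::floor(discard_frac * nren);
  double acc = 0.0;
  long n = 0;
  std::vector<double> series;
  series.reserve(nren - skip);
  for (long r = skip; r < nren; ++r) {
    acc += logs[r];
    ++n;
    series.push_back(acc / (n * renorm));
  }
  return List::create(_["lambda_max"] = acc / (n * renorm),
                      _["convergence_series"] = series,
                      _["renorm_interval"] = renorm);
}

// Benettin for the delay-coupled pair: reference and perturbed trajectories
// each carry their own history; the separation norm spans the current state
// and the V1/V2 history over the delay window, and renormalisation rescales
// state and history deviations together.
// [[Rcpp::export]]
List cpp_benettin_pair(List params, List network, NumericVector y0, double d0,
                       double renorm, double duration, double discard_frac,
                       double dt) {
  Pars p = parse_pars(params);
  Net net;
  net.gc = network["g_c"]; net.tau1 = network["tau1"]; net.tau2 = network["tau2"];
  net.I1 = network["I_exc1"]; net.I2 = network["I_exc2"];
  long nren = (long)std::lround(duration / renorm);
  long sper = (long)std::lround(renorm / dt);
  double maxtau = std::max(net.tau1, net.tau2);
  long span = (long)std::ceil(maxtau / dt) + 8;
  double y[8], z[8];
  for (int i = 0; i < 8; ++i) {
    y[i] = y0[i];
    z[i] = y0[i];
  }
  z[0] += d0;  // perturbation applied to V1 (history is constant = state)
  History Hy, Hz;
  Hy.t0 = Hz.t0 = 0.0;
  Hy.dt = Hz.dt = dt;
  push_history(p, net, Hy, 0.0, y);
  push_history(p, net, Hz, 0.0, z);
  std::vector<double> logs;
  logs.reserve(nren);
  long base = 0;
  double t = 0.0;
  for (long r = 0; r < nren; ++r) {
    for (long s = 0; s < sper; ++s) {
      pair_step(p, net, Hy, t, dt, y);
      pair_step(p, net, Hz, t, dt, z);
      t += dt;
      if (!std::isfinite(y[0]) || !std::isfinite(z[0]))
        stop("integration diverged at t = %f ms", t);
      push_history(p, net, Hy, t, y);
      push_history(p, net, Hz, t, z);
      if ((long)Hy.V1.size() > 2 * span + 8) {
        long drop = (long)Hy.V1.size() - (span + 4);
        base += drop;
        double nt0 = base * dt;
        Hy.V1.erase(Hy.V1.begin(), Hy.V1.begin() + drop);
        Hy.dV1.erase(Hy.dV1.begin(), Hy.dV1.begin() + drop);
        Hy.V2.erase(Hy.V2.begin(), Hy.V2.begin() + drop);
        Hy.dV2.erase(Hy.dV2.begin(), Hy.dV2.begin() + drop);
        Hz.V1.erase(Hz.V1.begin(), Hz.V1.begin() + drop);
        Hz.dV1.erase(Hz.dV1.begin(), Hz.dV1.begin() + drop);
        Hz.V2.erase(Hz.V2.begin(), Hz.V2.begin() + drop);
        Hz.dV2.erase(Hz.dV2.begin(), Hz.dV2.begin() + drop);
        Hy.t0 = Hz.t0 = nt0;
      }
    }
    // separation norm over state + history segment
    double d2 = 0.0;
    for (int i = 0; i < 8; ++i) d2 += (z[i] - y[i]) * (z[i] - y[i]);
    size_t m = Hy.V1.size();
    size_t hs = (size_t)std::min((long)m, span);
    for (size_t i = m - hs; i < m; ++i) {
      double a = Hz.V1[i] - Hy.V1[i], b = Hz.V2[i] - Hy.V2[i];
      d2 += (a * a + b * b) / (double)hs;
    }
    double d = std::sqrt(d2);
    if (d <= 0.0) stop("separation underflow: decrease renorm interval");
    logs.push_back(std::log(d / d0));
    double f = d0 / d;
    for (int i = 0; i < 8; ++i) z[i] = y[i] + (z[i] - y[i]) * f;
    for (size_t i = 0; i < m; ++i) {
      Hz.V1[i] = Hy.V1[i] + (Hz.V1[i] - Hy.V1[i]) * f;
      Hz.V2[i] = Hy.V2[i] + (Hz.V2[i] - Hy.V2[i]) * f;
      Hz.dV1[i] = Hy.dV1[i] + (Hz.dV1[i] - Hy.dV1[i]) * f;
      Hz.dV2[i] = Hy.dV2[i] + (Hz.dV2[i] - Hy.dV2[i]) * f;
    }
  }
  long skip = (long)std::floor(discard_frac * nren);
  double acc = 0.0;
  long n = 0;
  std::vector<double> series;
  series.reserve(nren - skip);
  for (long r = skip; r < nren; ++r) {
    acc += logs[r];
    ++n;
    series.push_back(acc / (n * renorm));
  }
  return List::create(_["lambda_max"] = acc / (n * renorm),
                      _["convergence_series"] = series,
                      _["renorm_interval"] = renorm);
}
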