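// Core numerics for the lumped-parameter circulation model.
//
// All closed-form pressure / resistance laws live here so that the exported
// R wrappers and the integrator share one implementation.  The network is a
// generic node/edge description:
//
//   nodes: capacitive compartments, each with a pressure law
//     law 0  linear           P = V / C                      p = {C}
//     law 1  sv_log10         P = -Kv * log10(Vmax/V - 0.99) p = {Kv, Vmax}
//     law 2  vc_piecewise     two-branch vena cava law       p = {N1, K1, Vvc0, N2, K2, Vvcmin}
//     law 3  sap_blend        active/passive mixture         p = {Fvaso, Kc, N0, Vmin, Kp1, tau_aop, Kp2}
//     law 4  log_saturating   P = -K * ln(1 - V/Vm)          p = {K, Vm}
//     law 5  chamber          time-varying elastance         p = {a, Ees, Vd, M, lambda, V0, act_slot}
//
//   edges: directed resistive connections, optionally with an inductor
//     (flow becomes a state) and/or an ideal diode (flow clamped >= 0).
//     resistance law 0 constant            R = base
//     resistance law 1 vc_volume           R = base + KR*Vmax/V_from + R0    p = {KR, Vmax, R0}
//     resistance law 2 sap_volume          R = base + Kr*(e^{4F} + (Vmax/V_from)^2)  p = {Kr, F, Vmax}
//
// Domain violations (over-filled vein, vessel at its volume limit, ...)
// return NaN from the law evaluators; the integrator translates the first
// NaN into an R error naming the node and simulation time.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double vessel_P(int law, const double* p, double V) {
  switch (law) {
  case 0:
    return V / p[0];
  case 1: {
    double arg = p[1] / V - 0.99;
    if (arg <= 0.0) return NA_REAL;
    return -p[0] * std::log10(arg);
  }
  case 2:
    if (V <= 0.0) return NA_REAL;
    if (V >= p[2]) return p[0] + p[1] * (V - p[2]);
    return p[3] + p[4] * std::exp(V / p[5]);
  case 3: {
    double x = V - p[3];
    if (x < 0.0) return NA_REAL;
    double Pa = p[1] * std::log10(x / p[2] + 1.0);
    double Pp = p[4] * std::exp(p[5] * x) + p[6] * x * x;
    return p[0] * Pa + (1.0 - p[0]) * Pp;
  }
  case 4: {
    // guard: reject states within 0.1% of the saturation volume
    if (V >= 0.999 * p[1] || V < 0.0) return NA_REAL;
    return -p[0] * std::log(1.0 - V / p[1]);
  }
  default:
    return NA_REAL;
  }
}

static inline double edge_R(int law, double base, const double* p, double Vfrom) {
  switch (law) {
  case 0:
    return base;
  case 1:
    if (Vfrom <= 0.0) return NA_REAL;
    return base + p[0] * p[1] / Vfrom + p[2];
  case 2: {
    if (Vfrom <= 0.0) return NA_REAL;
    double ratio = p[2] / Vfrom;
    return base + p[0] * (std::exp(4.0 * p[1]) + ratio * ratio);
  }
  default:
    return NA_REAL;
  }
}

static inline double activation_value(double phase, const double* A, const double* B,
                                      const double* C, int ncomp, int form,
                                      double bscale, double lin) {
  double e = 0.0;
  if (form == 0) { // ventricular: exp[-x^2], phase stretched by b(F_con)
    for (int i = 0; i < ncomp; ++i) {
      double x = (bscale * phase - C[i]) / B[i];
      e += A[i] * std::exp(-x * x);
    }
  } else {         // atrial: exp[-0.5 x^2] (+ linear term)
    for (int i = 0; i < ncomp; ++i) {
      double x = (phase - C[i]) / B[i];
      e += A[i] * std::exp(-0.5 * x * x);
    }
    e += lin;
  }
  return e;
}

static inline double chamber_P(const double* p, double V, double e) {
  double Pes = p[0] * p[1] * (V - p[2]);
  double Ped = p[3] * std::fabs(std::exp(p[4] * (V - p[5])) - 1.0);
  return e * Pes + (1.0 - e) * Ped;
}

// ---------------------------------------------------------------------------
// exported scalar/vector evaluators (single source for the R wrappers)

// [[Rcpp::export]]
NumericVector cpp_vessel_pressure(int law, NumericVector p, NumericVector V) {
  int n = V.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = vessel_P(law, p.begin(), V[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_edge_resistance(int law, double base, NumericVector p,
                                  NumericVector Vfrom) {
  int n = Vfrom.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = edge_R(law, base, p.begin(), Vfrom[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_activation(NumericVector phase, NumericVector A, NumericVector B,
                             NumericVector C, int form, double bscale, double lin) {
  int n = phase.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = activation_value(phase[i], A.begin(), B.begin(), C.begin(),
                              A.size(), form, bscale, lin);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_chamber_pressure(NumericVector V, NumericVector phase,
                                   NumericVector chp, NumericVector A,
                                   NumericVector B, NumericVector C, int form,
                                   double bscale, double lin) {
  int n = V.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double ph = phase.size() == 1 ? phase[0] : phase[i];
    double e = activation_value(ph, A.begin(), B.begin(), C.begin(),
                                A.size(), form, bscale, lin);
    out[i] = chamber_P(chp.begin(), V[i], e);
  }
  return out;
}

// ---------------------------------------------------------------------------
// network right-hand side

struct Net {
  int n, m, nq, nslot;
  const int* nlaw;
  const double* npar;        // n x 7, column-major
  int npar_nrow;
  const int* efrom;          // 0-based
  const int* eto;
  const double* eRbase;
  const int* eRlaw;
  const double* eRpar;       // m x 3, column-major
  int eRpar_nrow;
  const double* eL;
  const int* evalve;
  std::vector<int> qidx;     // per edge, index into Q or -1
};

// e_slot: activation value per chamber slot at the current stage phase
static inline int rhs(const Net& net, const double* V, const double* Q,
                      const double* e_slot, double* dV, double* dQ,
                      double* P, double* F) {
  const int n = net.n, m = net.m;
  for (int i = 0; i < n; ++i) {
    int law = net.nlaw[i];
    const double* p = net.npar + (size_t)i; // row i, stride = nrow
    double pp[7];
    for (int k = 0; k < 7; ++k) pp[k] = net.npar[i + (size_t)k * net.npar_nrow];
    if (law == 5) {
      int slot = (int)pp[6];
      P[i] = chamber_P(pp, V[i], e_slot[slot]);
    } else {
      P[i] = vessel_P(law, pp, V[i]);
    }
    if (ISNAN(P[i])) return i + 1; // 1-based offending node
    (void)p;
  }
  for (int i = 0; i < n; ++i) dV[i] = 0.0;
  for (int j = 0; j < m; ++j) {
    int a = net.efrom[j], b = net.eto[j];
    double ep[3];
    for (int k = 0; k < 3; ++k) ep[k] = net.eRpar[j + (size_t)k * net.eRpar_nrow];
    double R = edge_R(net.eRlaw[j], net.eRbase[j], ep, V[a]);
    if (ISNAN(R) || R <= 0.0) return -(j + 1); // 1-based offending edge
    double dP = P[a] - P[b];
    double q;
    if (net.qidx[j] >= 0) {
      q = Q[net.qidx[j]];
      if (net.evalve[j] && q <= 0.0 && dP <= 0.0) {
        // closed diode in an inductive branch: flow pinned at zero
        q = 0.0;
        dQ[net.qidx[j]] = 0.0;
      } else {
        dQ[net.qidx[j]] = (dP - R * q) / net.eL[j];
      }
    } else if (net.evalve[j] && dP <= 0.0) {
      q = 0.0;
    } else {
      q = dP / R;
    }
    F[j] = q;
    dV[a] -= q;
    dV[b] += q;
  }
  return 0;
}

static Net make_net(IntegerVector nlaw, NumericMatrix npar,
                    IntegerVector efrom, IntegerVector eto,
                    NumericVector eRbase, IntegerVector eRlaw, NumericMatrix eRpar,
                    NumericVector eL, IntegerVector evalve,
                    std::vector<int>& efrom0, std::vector<int>& eto0) {
  Net net;
  net.n = nlaw.size();
  net.m = efrom.size();
  net.nlaw = nlaw.begin();
  net.npar = npar.begin();
  net.npar_nrow = npar.nrow();
  efrom0.resize(net.m);
  eto0.resize(net.m);
  for (int j = 0; j < net.m; ++j) { efrom0[j] = efrom[j] - 1; eto0[j] = eto[j] - 1; }
  net.efrom = efrom0.data();
  net.eto = eto0.data();
  net.eRbase = eRbase.begin();
  net.eRlaw = eRlaw.begin();
  net.eRpar = eRpar.begin();
  net.eRpar_nrow = eRpar.nrow();
  net.eL = eL.begin();
  net.evalve = evalve.begin();
  net.qidx.assign(net.m, -1);
  net.nq = 0;
  for (int j = 0; j < net.m; ++j) if (eL[j] > 0.0) net.qidx[j] = net.nq++;
  return net;
}

static std::vector<std::vector<double> > act_tables(List act, double dt, int nsteps,
                                                    int& nslot) {
  nslot = act.size();
  std::vector<std::vector<double> > tab(nslot);
  int ngrid = 2 * nsteps + 1;
  for (int s = 0; s < nslot; ++s) {
    List a = act[s];
    NumericVector A = a["A"], B = a["B"], C = a["C"];
    int form = as<int>(a["form"]);
    double bscale = as<double>(a["bscale"]);
    double lin = as<double>(a["lin"]);
    tab[s].resize(ngrid);
    for (int g = 0; g < ngrid; ++g)
      tab[s][g] = activation_value(0.5 * dt * g, A.begin(), B.begin(), C.begin(),
                                   A.size(), form, bscale, lin);
  }
  return tab;
}

// single right-hand-side evaluation, for unit tests and toy circuits
// [[Rcpp::export]]
List cpp_derivs(NumericVector V, NumericVector Q, double phase,
                IntegerVector nlaw, NumericMatrix npar, List act,
                IntegerVector efrom, IntegerVector eto,
                NumericVector eRbase, IntegerVector eRlaw, NumericMatrix eRpar,
                NumericVector eL, IntegerVector evalve) {
  std::vector<int> efrom0, eto0;
  Net net = make_net(nlaw, npar, efrom, eto, eRbase, eRlaw, eRpar, eL, evalve,
                     efrom0, eto0);
  int nslot = act.size();
  std::vector<double> e_slot(std::max(nslot, 1), 0.0);
  for (int s = 0; s < nslot; ++s) {
    List a = act[s];
    NumericVector A = a["A"], B = a["B"], C = a["C"];
    e_slot[s] = activation_value(phase, A.begin(), B.begin(), C.begin(), A.size(),
                                 as<int>(a["form"]), as<double>(a["bscale"]),
                                 as<double>(a["lin"]));
  }
  std::vector<double> dV(net.n), dQ(std::max(net.nq, 1)), P(net.n), F(net.m);
  int bad = rhs(net, V.begin(), Q.begin(), e_slot.data(), dV.data(), dQ.data(),
                P.data(), F.data());
  if (bad > 0) stop("pressure law domain error at node %d", bad);
  if (bad < 0) stop("resistance law domain error at edge %d", -bad);
  return List::create(_["dV"] = NumericVector(dV.begin(), dV.end()),
                      _["dQ"] = NumericVector(dQ.begin(), dQ.begin() + net.nq),
                      _["P"] = NumericVector(P.begin(), P.end()),
                      _["flow"] = NumericVector(F.begin(), F.end()));
}

// integrate one cardiac cycle (parameters frozen) with classical RK4
// [[Rcpp::export]]
List cpp_sim_cycle(NumericVector V0, NumericVector Q0,
                   IntegerVector nlaw, NumericMatrix npar, List act,
                   IntegerVector efrom, IntegerVector eto,
                   NumericVector eRbase, IntegerVector eRlaw, NumericMatrix eRpar,
                   NumericVector eL, IntegerVector evalve,
                   double dt, int nsteps, int record_every, double t0,
                   int euler) {
  std::vector<int> efrom0, eto0;
  Net net = make_net(nlaw, npar, efrom, eto, eRbase, eRlaw, eRpar, eL, evalve,
                     efrom0, eto0);
  const int n = net.n, m = net.m, nq = net.nq;
  if (V0.size() != n) stop("state/topology size mismatch");
  if ((int)Q0.size() != nq) stop("inductor flow state has wrong length");

  int nslot;
  std::vector<std::vector<double> > atab = act_tables(act, dt, nsteps, nslot);
  std::vector<double> e_stage(std::max(nslot, 1), 0.0);

  std::vector<double> V(V0.begin(), V0.end()), Q(Q0.begin(), Q0.end());
  std::vector<int> valved_q; // inductor states clamped >= 0 by their diode
  for (int j = 0; j < m; ++j)
    if (net.qidx[j] >= 0 && evalve[j]) valved_q.push_back(net.qidx[j]);
  std::vector<double> k1v(n), k2v(n), k3v(n), k4v(n), Vt(n);
  int nq1 = std::max(nq, 1);
  std::vector<double> k1q(nq1), k2q(nq1), k3q(nq1), k4q(nq1), Qt(nq1);
  std::vector<double> P(n), F(m);

  // per-cycle statistics (from step-start states)
  std::vector<double> pmin(n, R_PosInf), pmax(n, R_NegInf), psum(n, 0.0);
  std::vector<double> vmin(n, R_PosInf), vmax(n, R_NegInf);
  std::vector<double> qint(m, 0.0), qmin(m, R_PosInf), qmax(m, R_NegInf);
  double volmin = R_PosInf, volmax = R_NegInf;

  int nrec = record_every > 0 ? (nsteps - 1) / record_every + 1 : 0;
  NumericVector rec_t(nrec);
  NumericMatrix rec_V(nrec, record_every > 0 ? n : 0);
  NumericMatrix rec_P(nrec, record_every > 0 ? n : 0);
  NumericMatrix rec_F(nrec, record_every > 0 ? m : 0);
  int irec = 0;

  for (int step = 0; step < nsteps; ++step) {
    int g = 2 * step;
    for (int s = 0; s < nslot; ++s) e_stage[s] = atab[s][g];
    int bad = rhs(net, V.data(), Q.data(), e_stage.data(), k1v.data(), k1q.data(),
                  P.data(), F.data());
    if (bad) stop("integration failure at t = %.4f s (%s %d): state outside law domain",
                  t0 + step * dt, bad > 0 ? "node" : "edge", bad > 0 ? bad : -bad);

    // step-start bookkeeping
    double vol = 0.0;
    for (int i = 0; i < n; ++i) {
      vol += V[i];
      if (P[i] < pmin[i]) pmin[i] = P[i];
      if (P[i] > pmax[i]) pmax[i] = P[i];
      psum[i] += P[i];
      if (V[i] < vmin[i]) vmin[i] = V[i];
      if (V[i] > vmax[i]) vmax[i] = V[i];
    }
    if (vol < volmin) volmin = vol;
    if (vol > volmax) volmax = vol;
    for (int j = 0; j < m; ++j) {
      qint[j] += F[j] * dt;
      if (F[j] < qmin[j]) qmin[j] = F[j];
      if (F[j] > qmax[j]) qmax[j] = F[j];
    }
    if (record_every > 0 && step % record_every == 0) {
      rec_t[irec] = t0 + step * dt;
      for (int i = 0; i < n; ++i) { rec_V(irec, i) = V[i]; rec_P(irec, i) = P[i]; }
      for (int j = 0; j < m; ++j) rec_F(irec, j) = F[j];
      ++irec;
    }

    if (euler) {
      for (int i = 0; i < n; ++i) V[i] += dt * k1v[i];
      for (int q = 0; q < nq; ++q) Q[q] += dt * k1q[q];
      for (size_t k = 0; k < valved_q.size(); ++k)
        if (Q[valved_q[k]] < 0.0) Q[valved_q[k]] = 0.0;
      continue;
    }

    for (int s = 0; s < nslot; ++s) e_stage[s] = atab[s][g + 1];
    for (int i = 0; i < n; ++i) Vt[i] = V[i] + 0.5 * dt * k1v[i];
    for (int q = 0; q < nq; ++q) Qt[q] = Q[q] + 0.5 * dt * k1q[q];
    bad = rhs(net, Vt.data(), Qt.data(), e_stage.data(), k2v.data(), k2q.data(),
              P.data(), F.data());
    if (!bad) {
      for (int i = 0; i < n; ++i) Vt[i] = V[i] + 0.5 * dt * k2v[i];
      for (int q = 0; q < nq; ++q) Qt[q] = Q[q] + 0.5 * dt * k2q[q];
      bad = rhs(net, Vt.data(), Qt.data(), e_stage.data(), k3v.data(), k3q.data(),
                P.data(), F.data());
    }
    if (!bad) {
      for (int s = 0; s < nslot; ++s) e_stage[s] = atab[s][g + 2];
      for (int i = 0; i < n; ++i) Vt[i] = V[i] + dt * k3v[i];
      for (int q = 0; q < nq; ++q) Qt[q] = Q[q] + dt * k3q[q];
      bad = rhs(net, Vt.data(), Qt.data(), e_stage.data(), k4v.data(), k4q.data(),
                P.data(), F.data());
    }
    if (bad) stop("integration failure at t = %.4f s (%s %d): state outside law domain",
                  t0 + step * dt, bad > 0 ? "node" : "edge", bad > 0 ? bad : -bad);

    const double w = dt / 6.0;
    for (int i = 0; i < n; ++i)
      V[i] += w * (k1v[i] + 2.0 * k2v[i] + 2.0 * k3v[i] + k4v[i]);
    for (int q = 0; q < nq; ++q)
      Q[q] += w * (k1q[q] + 2.0 * k2q[q] + 2.0 * k3q[q] + k4q[q]);
    for (size_t k = 0; k < valved_q.size(); ++k)
      if (Q[valved_q[k]] < 0.0) Q[valved_q[k]] = 0.0;
  }

  return List::create(
    _["V"] = NumericVector(V.begin(), V.end()),
    _["Q"] = NumericVector(Q.begin(), Q.begin() + nq),
    _["rec_t"] = rec_t, _["rec_V"] = rec_V, _["rec_P"] = rec_P, _["rec_F"] = rec_F,
    _["pmin"] = NumericVector(pmin.begin(), pmin.end()),
    _["pmax"] = NumericVector(pmax.begin(), pmax.end()),
    _["pmean"] = NumericVector(psum.begin(), psum.end()),
    _["vmin"] = NumericVector(vmin.begin(), vmin.end()),
    _["vmax"] = NumericVector(vmax.begin(), vmax.end()),
    _["qint"] = NumericVector(qint.begin(), qint.end()),
    _["qmin"] = NumericVector(qmin.begin(), qmin.end()),
    _["qmax"] = NumericVector(qmax.begin(), qmax.end()),
    _["volmin"] = volmin, _["volmax"] = volmax, _["nsteps"] = nsteps);
}
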