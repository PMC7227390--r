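// Network evolution core: spike-free per-neuron stepping (Heun / ETD2RK),
// exact double-exponential conductance decay, threshold detection with linear
// spike-time interpolation, end-of-step conductance recalibration, and the
// per-neuron stiff-period bookkeeping that drives the adaptive scheme switch.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

const double NEVER = -1e300; // stiff_until sentinel for never-spiked neurons

struct ModelP {
  int kind; // 0 = HH (state V,m,h,n), 1 = RTM (state V,h,n; m instantaneous)
  double C, VNa, VK, VL, GNa, GK, GL, Vth;
};

struct SynP { double VGE, VGI, srE, sdE, srI, sdI; };

struct NState { double V, m, h, n; };

// y / (1 - exp(-y)), the shared form of the singular opening rates; series
// for |y| < 1e-6 avoids 0/0 at grid-aligned voltages.
inline double ratefun(double y) {
  if (std::fabs(y) < 1e-6) return 1.0 + y * (0.5 + y / 12.0);
  return -y / std::expm1(-y);
}

// alpha/beta for gates m,h,n at voltage V; a[0..2], b[0..2].
inline void gate_rates(int kind, double V, double* a, double* b) {
  if (kind == 0) {
    a[0] = ratefun(0.1 * V + 4.0);
    b[0] = 4.0 * std::exp(-(V + 65.0) / 18.0);
    a[1] = 0.07 * std::exp(-(V + 65.0) / 20.0);
    b[1] = 1.0 / (1.0 + std::exp(-3.5 - 0.1 * V));
    a[2] = 0.1 * ratefun(0.1 * V + 5.5);
    b[2] = 0.125 * std::exp(-(V + 65.0) / 80.0);
  } else {
    a[0] = 1.28 * ratefun((V + 54.0) / 4.0);
    b[0] = 1.4 * ratefun(-(V + 27.0) / 5.0);
    a[1] = 0.128 * std::exp(-(V + 50.0) / 18.0);
    b[1] = 4.0 / (1.0 + std::exp(-(V + 27.0) / 5.0));
    a[2] = 0.16 * ratefun((V + 52.0) / 5.0);
    b[2] = 0.5 * std::exp(-(V + 57.0) / 40.0);
  }
}

inline double dVdt(const ModelP& M, const SynP& S, double V, double m,
                   double h, double n, double gE, double gI) {
  double Iin = -gE * (V - S.VGE) - gI * (V - S.VGI);
  return (-(V - M.VNa) * M.GNa * m * m * m * h
          - (V - M.VK) * M.GK * n * n * n * n
          - (V - M.VL) * M.GL + Iin) / M.C;
}

inline NState full_rhs(const ModelP& M, const SynP& S, const NState& z,
                       double gE, double gI) {
  double a[3], b[3];
  gate_rates(M.kind, z.V, a, b);
  double m = (M.kind == 0) ? z.m : a[0] / (a[0] + b[0]);
  NState d;
  d.V = dVdt(M, S, z.V, m, z.h, z.n, gE, gI);
  d.m = (M.kind == 0) ? (1.0 - z.m) * a[0] - z.m * b[0] : 0.0;
  d.h = (1.0 - z.h) * a[1] - z.h * b[1];
  d.n = (1.0 - z.n) * a[2] - z.n * b[2];
  return d;
}

// phi1(x) = (e^x - 1)/x, phi2(x) = (e^x - 1 - x)/x^2; 6-term series below
// |x| = 1e-4 to dodge cancellation.
inline double phi1(double x) {
  if (std::fabs(x) < 1e-4)
    return 1.0 + x * (1.0 / 2 + x * (1.0 / 6 + x * (1.0 / 24 + x * (1.0 / 120 + x / 720))));
  return std::expm1(x) / x;
}
inline double phi2(double x) {
  if (std::fabs(x) < 1e-4)
    return 0.5 + x * (1.0 / 6 + x * (1.0 / 24 + x * (1.0 / 120 + x * (1.0 / 720 + x / 5040))));
  return (std::expm1(x) - x) / (x * x);
}

// Heun (explicit trapezoid): the c -> 0 limit of the ETD2RK step.
inline NState heun_step(const ModelP& M, const SynP& S, const NState& z,
                        double gE0, double gI0, double gE1, double gI1,
                        double dt) {
  NState d0 = full_rhs(M, S, z, gE0, gI0);
  NState zs = {z.V + dt * d0.V, z.m + dt * d0.m, z.h + dt * d0.h, z.n + dt * d0.n};
  NState d1 = full_rhs(M, S, zs, gE1, gI1);
  NState z1 = {z.V + 0.5 * dt * (d0.V + d1.V), z.m + 0.5 * dt * (d0.m + d1.m),
               z.h + 0.5 * dt * (d0.h + d1.h), z.n + 0.5 * dt * (d0.n + d1.n)};
  return z1;
}

// ETD2RK: freeze per-step linear rates from the step-start state, propagate
// the linear part exactly, quadrature the remainder with phi1/phi2 weights.
inline NState etd2_step(const ModelP& M, const SynP& S, const NState& z,
                        double gE0, double gI0, double gE1, double gI1,
                        double dt) {
  double a[3], b[3];
  gate_rates(M.kind, z.V, a, b);
  double mk = (M.kind == 0) ? z.m : a[0] / (a[0] + b[0]);
  double cV = (-(M.GNa * mk * mk * mk * z.h)
               - M.GK * z.n * z.n * z.n * z.n - M.GL) / M.C;
  double cm = -(a[0] + b[0]), ch = -(a[1] + b[1]), cn = -(a[2] + b[2]);

  // remainders at step start; for the gates (1-z)a - z b - c z reduces to a
  double FV = dVdt(M, S, z.V, mk, z.h, z.n, gE0, gI0) - cV * z.V;
  double Fm = a[0], Fh = a[1], Fn = a[2];

  double xV = cV * dt, xm = cm * dt, xh = ch * dt, xn = cn * dt;
  double aV = z.V * std::exp(xV) + FV * dt * phi1(xV);
  double am = (M.kind == 0) ? z.m * std::exp(xm) + Fm * dt * phi1(xm) : 0.0;
  double ah = z.h * std::exp(xh) + Fh * dt * phi1(xh);
  double an = z.n * std::exp(xn) + Fn * dt * phi1(xn);

  double a1[3], b1[3];
  gate_rates(M.kind, aV, a1, b1);
  double m1 = (M.kind == 0) ? am : a1[0] / (a1[0] + b1[0]);
  double FV1 = dVdt(M, S, aV, m1, ah, an, gE1, gI1) - cV * aV;
  double Fh1 = (1.0 - ah) * a1[1] - ah * b1[1] - ch * ah;
  double Fn1 = (1.0 - an) * a1[2] - an * b1[2] - cn * an;

  NState z1;
  z1.V = aV + (FV1 - FV) * dt * phi2(xV);
  if (M.kind == 0) {
    double Fm1 = (1.0 - am) * a1[0] - am * b1[0] - cm * am;
    z1.m = am + (Fm1 - Fm) * dt * phi2(xm);
  } else {
    z1.m = 0.0;
  }
  z1.h = ah + (Fh1 - Fh) * dt * phi2(xh);
  z1.n = an + (Fn1 - Fn) * dt * phi2(xn);
  return z1;
}

inline double kernel(double sd, double sr, double t) {
  if (t <= 0.0) return 0.0;
  return sd * sr / (sd - sr) * (std::exp(-t / sd) - std::exp(-t / sr));
}

} // namespace

// Methods: 0 naive-rk2, 1 rk2, 2 etd2, 3 aetd2.
// Stiff modes: 0 post-spike window (HH), 1 |dV/dt| slope + post-spike window (RTM).
// Feedforward trains are passed flattened: times sorted per neuron,
// ff_start/ff_count give each neuron's slice (0-based).
// [[Rcpp::export]]
List cpp_simulate(int model_kind, NumericVector model_par, NumericVector syn_par,
                  NumericMatrix W, IntegerVector is_exc,
                  double FE, double FI,
                  NumericVector ff_times, IntegerVector ff_start,
                  IntegerVector ff_count,
                  NumericVector V0, NumericVector m0, NumericVector h0,
                  NumericVector n0, NumericVector GE0, NumericVector GI0,
                  NumericVector HE0, NumericVector HI0,
                  double dt, int n_steps, int method,
                  double stiff_duration, int stiff_mode, double slope_thr,
                  IntegerVector record_idx, int record_every) {
  const int N = V0.size();
  ModelP M = {model_kind, model_par[0], model_par[1], model_par[2], model_par[3],
              model_par[4], model_par[5], model_par[6], model_par[7]};
  SynP S = {syn_par[0], syn_par[1], syn_par[2], syn_par[3], syn_par[4], syn_par[5]};

  // per-run constants of the exact spike-free conductance decay
  const double eSrE = std::exp(-dt / S.srE), eSdE = std::exp(-dt / S.sdE);
  const double eSrI = std::exp(-dt / S.srI), eSdI = std::exp(-dt / S.sdI);
  const double kE = kernel(S.sdE, S.srE, dt), kI = kernel(S.sdI, S.srI, dt);

  std::vector<NState> z(N);
  std::vector<double> GE(N), GI(N), HE(N), HI(N), stiff_until(N, NEVER);
  std::vector<int> ffp(N);
  for (int i = 0; i < N; ++i) {
    z[i] = NState{V0[i], m0[i], h0[i], n0[i]};
    GE[i] = GE0[i]; GI[i] = GI0[i]; HE[i] = HE0[i]; HI[i] = HI0[i];
    ffp[i] = ff_start[i];
  }

  std::vector<double> spike_t;
  std::vector<int> spike_n;
  std::vector<double> Vold(N), Vnew(N);
  std::vector<int> step_spikers;
  std::vector<double> step_taus;

  const int nrec = record_idx.size();
  int nrows = (nrec > 0 && record_every > 0) ? 1 + n_steps / record_every : 0;
  NumericMatrix trace(nrows, nrec);
  NumericVector trace_t(nrows);
  int row = 0;
  if (nrows > 0) {
    trace_t[0] = 0.0;
    for (int c = 0; c < nrec; ++c) trace(0, c) = z[record_idx[c]].V;
    row = 1;
  }

  double ff_applied = 0.0, deliveries = 0.0;

  for (int k = 0; k < n_steps; ++k) {
    const double t = k * dt, t1 = (k + 1) * dt;
    if ((k & 8191) == 0) Rcpp::checkUserInterrupt();

    // 1) spike-free advance of every neuron with its scheme
    for (int i = 0; i < N; ++i) {
      double gE0i = GE[i], gI0i = GI[i];
      double gE1i = GE[i] * eSrE + HE[i] * kE;
      double gI1i = GI[i] * eSrI + HI[i] * kI;
      bool use_etd;
      if (method == 2) use_etd = true;
      else if (method != 3) use_etd = false;
      else if (stiff_mode == 0) use_etd = (t < stiff_until[i]);
      else {
        NState d = full_rhs(M, S, z[i], gE0i, gI0i);
        use_etd = (std::fabs(d.V) >= slope_thr) || (t < stiff_until[i]);
      }
      Vold[i] = z[i].V;
      z[i] = use_etd ? etd2_step(M, S, z[i], gE0i, gI0i, gE1i, gI1i, dt)
                     : heun_step(M, S, z[i], gE0i, gI0i, gE1i, gI1i, dt);
      Vnew[i] = z[i].V;
      if (!std::isfinite(z[i].V))
        stop("non-finite membrane potential (neuron %d, t = %.6g ms, method %d, dt = %g)",
             i + 1, t1, method, dt);
    }

    // 2) exact spike-free conductance decay to t1
    for (int i = 0; i < N; ++i) {
      double g, hh;
      g = GE[i]; hh = HE[i]; GE[i] = g * eSrE + hh * kE; HE[i] = hh * eSdE;
      g = GI[i]; hh = HI[i]; GI[i] = g * eSrI + hh * kI; HI[i] = hh * eSdI;
    }

    // 3) threshold detection with linear interpolation (refractory-gated)
    step_spikers.clear(); step_taus.clear();
    for (int i = 0; i < N; ++i) {
      if (t < stiff_until[i]) continue;
      if (Vold[i] < M.Vth && Vnew[i] >= M.Vth) {
        double tau;
        if (method == 0) tau = t1;
        else {
          double dV = Vnew[i] - Vold[i];
          tau = (dV > 0.0) ? t + dt * (M.Vth - Vold[i]) / dV : t1;
        }
        spike_t.push_back(tau); spike_n.push_back(i + 1);
        step_spikers.push_back(i); step_taus.push_back(tau);
        stiff_until[i] = tau + stiff_duration;
      }
    }

    // 4a) fold feedforward events in (t, t1] into (G,H) at t1
    for (int i = 0; i < N; ++i) {
      int end = ff_start[i] + ff_count[i];
      while (ffp[i] < end && ff_times[ffp[i]] <= t1) {
        double u = ff_times[ffp[i]++];
        double d = (method == 0) ? 0.0 : t1 - u;
        if (FE != 0.0) { HE[i] += FE * std::exp(-d / S.sdE); GE[i] += FE * kernel(S.sdE, S.srE, d); }
        if (FI != 0.0) { HI[i] += FI * std::exp(-d / S.sdI); GI[i] += FI * kernel(S.sdI, S.srI, d); }
        ff_applied += 1.0;
      }
    }

    // 4b) deliver this step's synaptic spikes, routed by presynaptic type
    for (size_t s = 0; s < step_spikers.size(); ++s) {
      int j = step_spikers[s];
      double d = (method == 0) ? 0.0 : t1 - step_taus[s];
      bool exc = is_exc[j] != 0;
      double eh = std::exp(-d / (exc ? S.sdE : S.sdI));
      double eg = kernel(exc ? S.sdE : S.sdI, exc ? S.srE : S.srI, d);
      for (int i = 0; i < N; ++i) {
        double w = W(i, j);
        if (w == 0.0) continue;
        if (exc) { HE[i] += w * eh; GE[i] += w * eg; }
        else     { HI[i] += w * eh; GI[i] += w * eg; }
        deliveries += 1.0;
      }
    }

    if (nrows > 0 && (k + 1) % record_every == 0) {
      trace_t[row] = t1;
      for (int c = 0; c < nrec; ++c) trace(row, c) = z[record_idx[c]].V;
      ++row;
    }
  }

  NumericVector Vf(N), mf(N), hf(N), nf(N), GEf(N), GIf(N), HEf(N), HIf(N), su(N);
  for (int i = 0; i < N; ++i) {
    Vf[i] = z[i].V; hf[i] = z[i].h; nf[i] = z[i].n;
    if (M.kind == 0) mf[i] = z[i].m;
    else {
      double a[3], b[3];
      gate_rates(M.kind, z[i].V, a, b);
      mf[i] = a[0] / (a[0] + b[0]);
    }
    GEf[i] = GE[i]; GIf[i] = GI[i]; HEf[i] = HE[i]; HIf[i] = HI[i];
    su[i] = stiff_until[i];
  }

  return List::create(
      _["spike_time"] = wrap(spike_t), _["spike_neuron"] = wrap(spike_n),
      _["V"] = Vf, _["m"] = mf, _["h"] = hf, _["n"] = nf,
      _["G_E"] = GEf, _["G_I"] = GIf, _["H_E"] = HEf, _["H_I"] = HIf,
      _["stiff_until"] = su,
      _["trace_t"] = trace_t, _["trace_V"] = trace,
      _["ff_events_applied"] = ff_applied, _["deliveries"] = deliveries);
}
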