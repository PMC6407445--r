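#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Backward-Euler integrator for a double-cable myelinated fibre.
//
// Unknowns are interleaved absolute potentials (Vi_0, Vp_0, Vi_1, Vp_1, ...):
// Vi = intracellular, Vp = periaxonal (under the myelin). The axolemma
// (capacitance cmem, conductance Gm, reversal mix SgE) sits between Vi and
// Vp; the myelin sheath (cmy, gmy) sits between Vp and the extracellular
// potential Ve, which is the imposed stimulus. At nodes of Ranvier gmy is
// set very large (no myelin: Vp is clamped to Ve) and the nonlinear nodal
// channels supply Gm/SgE. Axial conductances ga (intracellular) and gp
// (periaxonal) couple consecutive compartments; ends are sealed.
//
// Time stepping: the user step dt is used from just before each pulse onset
// until `margin` ms after the pulse (covering the action potential and its
// propagation to the recording node); outside those windows a coarse
// implicit step (dt_quiet, at most 0.025 ms, well below the smallest
// passive time constant) integrates the subthreshold relaxation. The
// system is symmetric positive definite and pentadiagonal; it is
// refactorised and solved by banded elimination without pivoting at every
// step. Nodal gating uses exponential Euler with rate lookup tables.
//
// Units: mV, ms, uS, nF (currents in nA).

static inline double vtrap(double a, double b) {
  // a / (1 - exp(-a/b)), finite at a -> 0
  double x = a / b;
  if (std::fabs(x) < 1e-7) return b * (1.0 + x / 2.0);
  return a / (1.0 - std::exp(-x));
}

struct Rates { double am, bm, ah, bh, ap, bp, as_, bs; };

// nodal gating rates (1/ms) at 36 degC; scale[0] multiplies m & p rates,
// scale[1] the h rates, scale[2] the s rates (Q10 adjustment hooks)
static inline Rates node_rates(double v, const double* scale) {
  Rates r;
  r.am = 6.57 * vtrap(v + 20.4, 10.3) * scale[0];
  r.bm = 0.304 * vtrap(-(v + 25.7), 9.16) * scale[0];
  r.ah = 0.34 * vtrap(-(v + 114.0), 11.0) * scale[1];
  r.bh = 12.6 / (1.0 + std::exp(-(v + 31.8) / 13.4)) * scale[1];
  r.ap = 0.0353 * vtrap(v + 27.0, 10.2) * scale[0];
  r.bp = 0.000883 * vtrap(-(v + 34.0), 10.0) * scale[0];
  r.as_ = 0.3 / (1.0 + std::exp(-(v + 53.0) / 5.0)) * scale[2];
  r.bs = 0.03 / (1.0 + std::exp(-(v + 90.0) / 1.0)) * scale[2];
  return r;
}

// [[Rcpp::export(name = ".gate_steady")]]
NumericVector gate_steady(double v, NumericVector rate_scale) {
  Rates r = node_rates(v, rate_scale.begin());
  return NumericVector::create(r.am / (r.am + r.bm), r.ah / (r.ah + r.bh),
                               r.ap / (r.ap + r.bp), r.as_ / (r.as_ + r.bs));
}

// lookup tables: steady state and per-step decay factor for the two step
// sizes, per gate, on a uniform V grid
struct GateLut {
  double vmin = -150.0, vmax = 60.0, dv = 0.05;
  int n = 0;
  double dt_fine = -1, dt_coarse = -1, sc[3] = {0, 0, 0};
  std::vector<double> inf[4], dec_f[4], dec_c[4];
  bool matches(double f, double c, const double* scale) const {
    return n > 0 && f == dt_fine && c == dt_coarse && scale[0] == sc[0] &&
           scale[1] == sc[1] && scale[2] == sc[2];
  }
  void build(double f, double c, const double* scale) {
    dt_fine = f; dt_coarse = c;
    sc[0] = scale[0]; sc[1] = scale[1]; sc[2] = scale[2];
    n = (int)((vmax - vmin) / dv) + 2;
    for (int g = 0; g < 4; ++g) {
      inf[g].assign(n, 0.0); dec_f[g].assign(n, 0.0); dec_c[g].assign(n, 0.0);
    }
    for (int i = 0; i < n; ++i) {
      const double v = vmin + i * dv;
      Rates r = node_rates(v, scale);
      const double a[4] = {r.am, r.ah, r.ap, r.as_};
      const double b[4] = {r.bm, r.bh, r.bp, r.bs};
      for (int g = 0; g < 4; ++g) {
        const double tau = 1.0 / (a[g] + b[g]);
        inf[g][i] = a[g] * tau;
        dec_f[g][i] = std::exp(-f / tau);
        dec_c[g][i] = std::exp(-c / tau);
      }
    }
  }
};
static GateLut g_lut;

// [[Rcpp::export(name = ".fiber_sim")]]
List fiber_sim(List geom,
               NumericVector ve_unit,     // mV per compartment at scale 1
               NumericVector onsets,      // pulse onset times, ms, sorted
               double pw, double duration, double dt, double amp,
               NumericVector vi0, NumericVector vp0, NumericMatrix gates0,
               IntegerVector record_nodes, // 0-based indices into node list
               double spike_thresh, double lockout,
               bool fast_forward,
               NumericVector rest_vi, NumericVector rest_vp,
               NumericMatrix rest_gates,
               bool early_abort, bool return_vm, int vm_every,
               NumericVector rate_scale, double dt_quiet) {
  const NumericVector cmem = geom["cmem"], gpas = geom["gpas"],
                      epas = geom["epas"], cmy = geom["cmy"],
                      gmy = geom["gmy"], ga = geom["ga"], gp = geom["gp"];
  const IntegerVector node_idx = geom["node_idx"];
  const NumericVector gbar = geom["gbar"]; // gnaf, gnap, gks, gl in uS/node
  const double ena = geom["ena"], ek = geom["ek"], el = geom["el"];
  const int M = cmem.size(), nnode = node_idx.size(), n = 2 * M;
  const double gnaf = gbar[0], gnap = gbar[1], gks = gbar[2], gl = gbar[3];
  const double margin = 15.0;  // ms of fine stepping after each pulse onset
  if (dt_quiet < dt) dt_quiet = dt;

  if (!g_lut.matches(dt, dt_quiet, rate_scale.begin()))
    g_lut.build(dt, dt_quiet, rate_scale.begin());

  std::vector<double> vi(vi0.begin(), vi0.end()), vp(vp0.begin(), vp0.end());
  std::vector<double> m(nnode), h(nnode), p(nnode), s(nnode);
  for (int q = 0; q < nnode; ++q) {
    m[q] = gates0(q, 0); h[q] = gates0(q, 1);
    p[q] = gates0(q, 2); s[q] = gates0(q, 3);
  }
  std::vector<double> Gm(M), SgE(M);
  for (int c = 0; c < M; ++c) { Gm[c] = gpas[c]; SgE[c] = gpas[c] * epas[c]; }

  std::vector<double> bm2(n), bm1(n), bd(n), bp1(n), bp2(n), rhs(n), u(n);

  const int nrec = record_nodes.size();
  std::vector<std::vector<double> > spikes(nrec);
  std::vector<double> last_vm(nrec), last_spike(nrec, -1e9);
  for (int q = 0; q < nrec; ++q) {
    int c = node_idx[record_nodes[q]];
    last_vm[q] = vi[c] - vp[c];
  }

  const int non = onsets.size();
  // s(t) = 1 iff some onset o satisfies o < t <= o + pw
  auto drive_on = [&](double t) -> bool {
    for (int q = non - 1; q >= 0; --q)
      if (onsets[q] < t) return (t <= onsets[q] + pw);
    return false;
  };
  std::vector<double> boundaries;
  for (int q = 1; q < non; ++q) boundaries.push_back(onsets[q]);
  boundaries.push_back(duration + 1.0);
  size_t widx = 0;
  bool aborted = false;
  auto spikes_in = [&](double a, double b) -> int {
    int cnt = 0;
    if (nrec == 0) return 0;
    for (size_t q = 0; q < spikes[0].size(); ++q)
      if (spikes[0][q] >= a && spikes[0][q] < b) ++cnt;
    return cnt;
  };

  std::vector<double> vm_times;
  std::vector<std::vector<double> > vm_rec(nrec);

  auto gate_update = [&](double vm, double step, double& x, int g) {
    // exponential Euler via the lookup table (linear interpolation in V)
    double pos = (vm - g_lut.vmin) / g_lut.dv;
    if (pos < 0) pos = 0;
    if (pos > g_lut.n - 2) pos = g_lut.n - 2;
    const int i0 = (int)pos;
    const double fr = pos - i0;
    double inf, dec;
    if (step == g_lut.dt_fine) {
      inf = g_lut.inf[g][i0] * (1 - fr) + g_lut.inf[g][i0 + 1] * fr;
      dec = g_lut.dec_f[g][i0] * (1 - fr) + g_lut.dec_f[g][i0 + 1] * fr;
    } else if (step == g_lut.dt_coarse) {
      inf = g_lut.inf[g][i0] * (1 - fr) + g_lut.inf[g][i0 + 1] * fr;
      dec = g_lut.dec_c[g][i0] * (1 - fr) + g_lut.dec_c[g][i0 + 1] * fr;
    } else {
      Rates r = node_rates(vm, rate_scale.begin());
      const double a[4] = {r.am, r.ah, r.ap, r.as_};
      const double b[4] = {r.bm, r.bh, r.bp, r.bs};
      const double tau = 1.0 / (a[g] + b[g]);
      inf = a[g] * tau;
      dec = std::exp(-step / tau);
    }
    x = inf + (x - inf) * dec;
  };

  double t = 0.0;
  long step_no = 0;
  bool done = false;

  while (!done && t < duration - 1e-9) {
    // choose the step: fine near/within pulses, coarse in quiet spans
    double last_on = -1e9, next_on = duration;
    for (int q = non - 1; q >= 0; --q)
      if (onsets[q] <= t + 1e-12) { last_on = onsets[q]; break; }
    for (int q = 0; q < non; ++q)
      if (onsets[q] > t + 1e-12) { next_on = onsets[q]; break; }
    double step = (t < last_on + pw + margin) ? dt : dt_quiet;
    if (t + step > next_on + 1e-12 && next_on > t) step = next_on - t;
    if (t + step > duration) step = duration - t;
    if (step < 1e-12) break;
    const double tn = t + step;
    const double s_old = drive_on(t) ? 1.0 : 0.0;
    const double s_new = drive_on(tn) ? 1.0 : 0.0;

    // gating update (exponential Euler at the old membrane potential)
    for (int q = 0; q < nnode; ++q) {
      const int c = node_idx[q];
      const double vm = vi[c] - vp[c];
      gate_update(vm, step, m[q], 0);
      gate_update(vm, step, h[q], 1);
      gate_update(vm, step, p[q], 2);
      gate_update(vm, step, s[q], 3);
      const double gna = gnaf * m[q] * m[q] * m[q] * h[q];
      const double gnp = gnap * p[q] * p[q] * p[q];
      const double gk = gks * s[q];
      Gm[c] = gna + gnp + gk + gl;
      SgE[c] = (gna + gnp) * ena + gk * ek + gl * el;
    }

    const double idt = 1.0 / step;
    for (int k = 0; k < M; ++k) {
      const int ri = 2 * k, rp = 2 * k + 1;
      const double gaL = (k > 0) ? ga[k - 1] : 0.0;
      const double gaR = (k < M - 1) ? ga[k] : 0.0;
      const double gpL = (k > 0) ? gp[k - 1] : 0.0;
      const double gpR = (k < M - 1) ? gp[k] : 0.0;
      const double cm_dt = cmem[k] * idt, cy_dt = cmy[k] * idt;
      const double vm_old = vi[k] - vp[k];
      const double ve_old = amp * s_old * ve_unit[k];
      const double ve_new = amp * s_new * ve_unit[k];
      bm2[ri] = -gaL; bm1[ri] = 0.0;
      bd[ri] = cm_dt + Gm[k] + gaL + gaR;
      bp1[ri] = -(cm_dt + Gm[k]); bp2[ri] = -gaR;
      rhs[ri] = cm_dt * vm_old + SgE[k];
      bm2[rp] = -gpL; bm1[rp] = -(cm_dt + Gm[k]);
      bd[rp] = cm_dt + Gm[k] + cy_dt + gmy[k] + gpL + gpR;
      bp1[rp] = 0.0; bp2[rp] = -gpR;
      rhs[rp] = -cm_dt * vm_old - SgE[k] + cy_dt * (vp[k] - ve_old) +
                (cy_dt + gmy[k]) * ve_new;
    }

    // banded elimination (no pivoting; SPD)
    for (int i = 0; i < n; ++i) {
      const double piv = bd[i];
      if (i + 1 < n && bm1[i + 1] != 0.0) {
        const double l = bm1[i + 1] / piv;
        bd[i + 1] -= l * bp1[i];
        bp1[i + 1] -= l * bp2[i];
        rhs[i + 1] -= l * rhs[i];
      }
      if (i + 2 < n && bm2[i + 2] != 0.0) {
        const double l = bm2[i + 2] / piv;
        bm1[i + 2] -= l * bp1[i];
        bd[i + 2] -= l * bp2[i];
        rhs[i + 2] -= l * rhs[i];
      }
    }
    for (int i = n - 1; i >= 0; --i) {
      double v = rhs[i];
      if (i + 1 < n) v -= bp1[i] * u[i + 1];
      if (i + 2 < n) v -= bp2[i] * u[i + 2];
      u[i] = v / bd[i];
    }
    for (int k = 0; k < M; ++k) { vi[k] = u[2 * k]; vp[k] = u[2 * k + 1]; }
    t = tn;
    ++step_no;

    // spike detection at recording nodes
    for (int q = 0; q < nrec; ++q) {
      const int c = node_idx[record_nodes[q]];
      const double vm = vi[c] - vp[c];
      if (vm >= spike_thresh && last_vm[q] < spike_thresh &&
          t - last_spike[q] >= lockout) {
        spikes[q].push_back(t);
        last_spike[q] = t;
      }
      last_vm[q] = vm;
    }
    if (return_vm && (step_no % vm_every == 0)) {
      vm_times.push_back(t);
      for (int q = 0; q < nrec; ++q) {
        const int c = node_idx[record_nodes[q]];
        vm_rec[q].push_back(vi[c] - vp[c]);
      }
    }

    // 1:1 window bookkeeping
    while (widx < boundaries.size() && t >= boundaries[widx] - 1e-9) {
      const double w0 = onsets[(int)widx];
      const double w1 = boundaries[widx];
      if (early_abort && nrec > 0 && spikes_in(w0, w1) != 1) {
        aborted = true;
        done = true;
      }
      ++widx;
    }
    if (done) break;

    // quiescence fast-forward: once everything has relaxed to within
    // 0.05 mV of rest and no drive is pending before the next onset, jump
    // there, relaxing the gating variables analytically at their resting
    // rates
    if (fast_forward && !drive_on(t) && t > last_on + pw + margin &&
        next_on > t + 2.0 * dt_quiet) {
      double dev = 0.0;
      for (int k = 0; k < M; ++k) {
        const double d0 = std::fabs((vi[k] - vp[k]) -
                                    (rest_vi[k] - rest_vp[k]));
        if (d0 > dev) dev = d0;
      }
      if (dev < 0.05) {
        const double delta = next_on - t;
        for (int q = 0; q < nnode; ++q) {
          const int c = node_idx[q];
          const double vr = rest_vi[c] - rest_vp[c];
          Rates r = node_rates(vr, rate_scale.begin());
          const double a[4] = {r.am, r.ah, r.ap, r.as_};
          const double b[4] = {r.bm, r.bh, r.bp, r.bs};
          double* gv[4] = {&m[q], &h[q], &p[q], &s[q]};
          for (int g = 0; g < 4; ++g) {
            const double tau = 1.0 / (a[g] + b[g]);
            const double inf = a[g] * tau;
            *gv[g] = inf + (*gv[g] - inf) * std::exp(-delta / tau);
          }
        }
        for (int k = 0; k < M; ++k) { vi[k] = rest_vi[k]; vp[k] = rest_vp[k]; }
        for (int q = 0; q < nrec; ++q) {
          const int c = node_idx[record_nodes[q]];
          last_vm[q] = vi[c] - vp[c];
        }
        t = next_on;
        while (widx < boundaries.size() && t >= boundaries[widx] - 1e-9) {
          const double w0 = onsets[(int)widx];
          const double w1 = boundaries[widx];
          if (early_abort && nrec > 0 && spikes_in(w0, w1) != 1) {
            aborted = true;
            done = true;
          }
          ++widx;
        }
      }
    }
  }

  List spk(nrec);
  for (int q = 0; q < nrec; ++q) spk[q] = wrap(spikes[q]);
  NumericMatrix gates_out(nnode, 4);
  for (int q = 0; q < nnode; ++q) {
    gates_out(q, 0) = m[q]; gates_out(q, 1) = h[q];
    gates_out(q, 2) = p[q]; gates_out(q, 3) = s[q];
  }
  List out = List::create(
      _["spikes"] = spk, _["aborted"] = aborted, _["t_end"] = t,
      _["vi"] = wrap(vi), _["vp"] = wrap(vp), _["gates"] = gates_out);
  if (return_vm) {
    NumericMatrix vm_out(vm_times.size(), nrec);
    for (int q = 0; q < nrec; ++q)
      for (size_t rix = 0; rix < vm_times.size(); ++rix)
        vm_out(rix, q) = vm_rec[q][rix];
    out["vm_times"] = wrap(vm_times);
    out["vm"] = vm_out;
  }
  return out;
}
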