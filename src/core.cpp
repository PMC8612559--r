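// Cable/channel integrator core.
//
// Units follow the NEURON convention used throughout the package:
//   V mV, t ms, capacitance nF, conductance uS, current nA.
// Voltage is advanced by an implicit (backward Euler) step on the coupled
// cable equation (Hines tree elimination), channel states by exponential
// Euler at the previous voltage; this staggering is unconditionally stable
// in the axial/leak terms.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct ChanPar {
  double Gco, Goc, Gic, Gci, Vco, Vic, kco, kic;
  double tauAct, tauIna, tauRelax, cf, q10;
};

ChanPar as_chanpar(const List& l) {
  ChanPar p;
  p.Gco = l["Gco"]; p.Goc = l["Goc"];
  p.Gic = l.containsElementNamed("Gic") ? double(l["Gic"]) : 0.0;
  p.Gci = l.containsElementNamed("Gci") ? double(l["Gci"]) : 0.0;
  p.Vco = l["Vco"]; p.Vic = l["Vic"];
  p.kco = l["kco"]; p.kic = l["kic"];
  p.tauAct = l["tauAct"]; p.tauIna = l["tauIna"];
  p.tauRelax = l["tauRelax"]; p.cf = l["cf"]; p.q10 = l["q10"];
  return p;
}

inline double boltz(double x) { return 1.0 / (1.0 + std::exp(x)); }

// Sigmoidal (Boltzmann) transition rates, 1/ms.
inline double alphaA(double v, const ChanPar& p) {
  return p.q10 / p.tauAct * p.Gco * boltz((p.Vco - v) / p.kco);
}
inline double betaA(double v, const ChanPar& p) {
  return p.q10 / p.tauAct * p.Goc * boltz((v - p.Vco) / p.kco);
}
inline double alphaIC(double v, const ChanPar& p) {
  return p.q10 / p.tauIna * p.Gic * boltz((p.Vic - v) / p.kic);
}
inline double betaIC(double v, const ChanPar& p) {
  return p.q10 / p.tauIna * p.Gci * boltz((v - p.Vic) / p.kic);
}

// K deactivation uses its own half-voltage/slope pair and the "ina" time
// constant (two-state scheme: alphaA opens, betaAK closes).
inline double betaAK(double v, const ChanPar& p) {
  return p.q10 / p.tauIna * p.Goc * boltz((v - p.Vic) / p.kic);
}

} // namespace

// [[Rcpp::export]]
List core_simulate(IntegerVector parent,      // 0-based, -1 for root; parent[i] < i
                   NumericVector gax,         // uS, coupling comp <-> parent
                   NumericVector cm,          // nF
                   NumericVector gpas,        // uS
                   double epas,
                   NumericVector gna,         // uS (peak), 0 = no channel
                   NumericVector gk,          // uS (peak)
                   List napar, List kpar,
                   double ena, double ek,
                   bool active,
                   IntegerVector syn_comp,    // 0-based compartment per synapse
                   NumericVector syn_tau1, NumericVector syn_tau2,
                   NumericVector syn_erev, NumericVector syn_gmax, // uS
                   NumericVector ev_time,     // sorted onset times, ms
                   IntegerVector ev_syn,      // 0-based synapse per event
                   NumericVector gton,        // uS per comp
                   double eton,
                   IntegerVector ic_comp, NumericVector ic_del,
                   NumericVector ic_dur, NumericVector ic_amp,   // nA
                   IntegerVector play_comp, NumericMatrix play_wave, // nA, rows=time
                   double dt, double tstop, double vinit,
                   IntegerVector rec, IntegerVector rec_syn,
                   double vcap) {
  const int n = parent.size();
  const int nsyn = syn_comp.size();
  const int nt = (int)std::lround(tstop / dt) + 1;
  ChanPar na = as_chanpar(napar), kk = as_chanpar(kpar);

  std::vector<double> v(n, vinit), O(n, 0.0), H(n, 0.0), OK(n, 0.0);
  // hoist inputs into plain arrays
  std::vector<int> par_(parent.begin(), parent.end());
  std::vector<double> gax_(gax.begin(), gax.end()), cm_(cm.begin(), cm.end());
  std::vector<double> gpas_(gpas.begin(), gpas.end());
  std::vector<double> gna_(gna.begin(), gna.end()), gk_(gk.begin(), gk.end());
  std::vector<double> gton_(gton.begin(), gton.end());
  std::vector<char> hasna(n), hask(n);
  for (int i = 0; i < n; ++i) { hasna[i] = gna_[i] > 0; hask[i] = gk_[i] > 0; }
  // steady channel states at vinit (few fixed-point sweeps for the cf shift)
  if (active) {
    for (int i = 0; i < n; ++i) {
      if (hasna[i]) {
        for (int it = 0; it < 25; ++it) {
          double veff = vinit + na.cf * O[i];
          double aA = alphaA(veff, na), bA = betaA(veff, na);
          double aI = alphaIC(vinit, na), bI = betaIC(vinit, na);
          double kH = aI + bI + 1.0 / na.tauRelax;
          H[i] = aI / kH;
          double kO = aA + bA + 1.0 / na.tauRelax;
          O[i] = aA * (1.0 - H[i]) / kO;
        }
      }
      if (hask[i]) {
        for (int it = 0; it < 25; ++it) {
          double veff = vinit + kk.cf * OK[i];
          double aA = alphaA(veff, kk), bA = betaAK(veff, kk);
          double kO = aA + bA + 1.0 / kk.tauRelax;
          OK[i] = aA / kO;
        }
      }
    }
  }

  // Exp2 synapse states: g = B - A, both decaying, peak-normalized increments
  std::vector<double> synA(nsyn, 0.0), synB(nsyn, 0.0), synF(nsyn, 0.0);
  std::vector<double> decA(nsyn), decB(nsyn);
  for (int s = 0; s < nsyn; ++s) {
    double t1 = syn_tau1[s], t2 = syn_tau2[s];
    double tp = t1 * t2 / (t2 - t1) * std::log(t2 / t1);
    synF[s] = syn_gmax[s] / (std::exp(-tp / t2) - std::exp(-tp / t1));
    decA[s] = std::exp(-dt / t1);
    decB[s] = std::exp(-dt / t2);
  }

  const int nrec = rec.size(), nrsyn = rec_syn.size();
  NumericMatrix vout(nrec, nt), iout(nrsyn, nt);
  for (int r = 0; r < nrec; ++r) vout(r, 0) = v[rec[r]];
  for (int r = 0; r < nrsyn; ++r) iout(r, 0) = 0.0;

  std::vector<double> diag0(n), d(n), rhs(n), gsyn_comp(n), esyn_comp(n);
  // static part of the diagonal: cm/dt + own coupling + children couplings
  for (int i = 0; i < n; ++i) diag0[i] = cm_[i] / dt + gax_[i];
  for (int i = 1; i < n; ++i) diag0[par_[i]] += gax_[i];

  int ev = 0;
  const int nev = ev_time.size();
  bool diverged = false;
  double clipmax = 0.0;
  int laststep = nt - 1;

  for (int step = 1; step < nt; ++step) {
    double tnew = step * dt;
    // 1. channel states (exponential Euler at previous V)
    if (active) {
      for (int i = 0; i < n; ++i) {
        if (hasna[i]) {
          double veff = v[i] + na.cf * O[i];
          double aA = alphaA(veff, na), bA = betaA(veff, na);
          double aI = alphaIC(v[i], na), bI = betaIC(v[i], na);
          double kO = aA + bA + 1.0 / na.tauRelax;
          double Oinf = aA * (1.0 - H[i]) / kO;
          double kH = aI + bI + 1.0 / na.tauRelax;
          double Hinf = aI / kH;
          double On = Oinf + (O[i] - Oinf) * std::exp(-dt * kO);
          double Hn = Hinf + (H[i] - Hinf) * std::exp(-dt * kH);
          // simplex guard against stiff-step overshoot
          double viol = std::max({-On, -Hn, On + Hn - 1.0, 0.0});
          if (viol > clipmax) clipmax = viol;
          if (On < 0) On = 0;
          if (Hn < 0) Hn = 0;
          if (On + Hn > 1.0) { double sc = 1.0 / (On + Hn); On *= sc; Hn *= sc; }
          O[i] = On; H[i] = Hn;
        }
        if (hask[i]) {
          double veff = v[i] + kk.cf * OK[i];
          double aA = alphaA(veff, kk), bA = betaAK(veff, kk);
          double kO = aA + bA + 1.0 / kk.tauRelax;
          double Oinf = aA / kO;
          double On = Oinf + (OK[i] - Oinf) * std::exp(-dt * kO);
          double viol = std::max({-On, On - 1.0, 0.0});
          if (viol > clipmax) clipmax = viol;
          OK[i] = std::min(1.0, std::max(0.0, On));
        }
      }
    }
    // 2. synapse states: decay, then events with onset in (t-dt, t]
    for (int s = 0; s < nsyn; ++s) { synA[s] *= decA[s]; synB[s] *= decB[s]; }
    while (ev < nev && ev_time[ev] <= tnew + 1e-9) {
      int s = ev_syn[ev];
      synA[s] += synF[s];
      synB[s] += synF[s];
      ++ev;
    }
    std::fill(gsyn_comp.begin(), gsyn_comp.end(), 0.0);
    std::fill(esyn_comp.begin(), esyn_comp.end(), 0.0);
    for (int s = 0; s < nsyn; ++s) {
      double g = synB[s] - synA[s];
      if (g < 0) g = 0;
      gsyn_comp[syn_comp[s]] += g;
      esyn_comp[syn_comp[s]] += g * syn_erev[s];
    }
    // 3. assemble and solve the implicit system
    for (int i = 0; i < n; ++i) {
      double gs = gpas_[i] + gton_[i] + gsyn_comp[i];
      double rs = cm_[i] / dt * v[i] + gpas_[i] * epas + gton_[i] * eton +
                  esyn_comp[i];
      if (active) {
        if (hasna[i]) { double go = gna_[i] * O[i]; gs += go; rs += go * ena; }
        if (hask[i])  { double gko = gk_[i] * OK[i]; gs += gko; rs += gko * ek; }
      }
      d[i] = diag0[i] + gs;
      rhs[i] = rs;
    }
    for (int c = 0; c < ic_comp.size(); ++c) {
      if (tnew >= ic_del[c] - 1e-9 && tnew <= ic_del[c] + ic_dur[c] + 1e-9)
        rhs[ic_comp[c]] += ic_amp[c];
    }
    for (int c = 0; c < play_comp.size(); ++c) {
      int idx = step < play_wave.nrow() ? step : play_wave.nrow() - 1;
      rhs[play_comp[c]] += play_wave(idx, c);
    }
    for (int i = n - 1; i >= 1; --i) {
      int p = par_[i];
      double f = gax_[i] / d[i];
      d[p] -= f * gax_[i];
      rhs[p] += f * rhs[i];
    }
    v[0] = rhs[0] / d[0];
    for (int i = 1; i < n; ++i) v[i] = (rhs[i] + gax_[i] * v[par_[i]]) / d[i];

    double vmax = 0.0;
    for (int i = 0; i < n; ++i) {
      double a = std::fabs(v[i]);
      if (a > vmax) vmax = a;
    }
    if (!(vmax <= vcap)) diverged = true;
    for (int r = 0; r < nrec; ++r) vout(r, step) = v[rec[r]];
    for (int r = 0; r < nrsyn; ++r) {
      int s = rec_syn[r];
      double g = synB[s] - synA[s];
      if (g < 0) g = 0;
      // depolarizing-positive convention: this is the current an I-clamp
      // would have to inject to reproduce the synaptic drive
      iout(r, step) = g * (syn_erev[s] - v[syn_comp[s]]);
    }
    if (diverged) { laststep = step; break; }
  }

  return List::create(_["v"] = vout, _["isyn"] = iout,
                      _["diverged"] = diverged, _["clipmax"] = clipmax,
                      _["laststep"] = laststep);
}

// Direct rate evaluation used by the R-level biophysics API (kept here so the
// R functions and the integrator share one implementation).
// [[Rcpp::export]]
NumericMatrix core_rates_k(NumericVector v, List par) {
  ChanPar p = as_chanpar(par);
  NumericMatrix out(v.size(), 2);
  for (int i = 0; i < v.size(); ++i) {
    out(i, 0) = alphaA(v[i], p);
    out(i, 1) = betaAK(v[i], p);
  }
  colnames(out) = CharacterVector::create("alphaA", "betaA");
  return out;
}

// [[Rcpp::export]]
NumericMatrix core_rates(NumericVector v, List par) {
  ChanPar p = as_chanpar(par);
  NumericMatrix out(v.size(), 4);
  for (int i = 0; i < v.size(); ++i) {
    out(i, 0) = alphaA(v[i], p);
    out(i, 1) = betaA(v[i], p);
    out(i, 2) = alphaIC(v[i], p);
    out(i, 3) = betaIC(v[i], p);
  }
  colnames(out) = CharacterVector::create("alphaA", "betaA", "alphaIC", "betaIC");
  return out;
}
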