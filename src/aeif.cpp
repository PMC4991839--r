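#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Parameter vector layout (fixed order, see as_param_vector() on the R side):
// 0 C, 1 gL, 2 EL, 3 VT, 4 DeltaT, 5 a, 6 b, 7 tau_w, 8 Vr, 9 Vspike
struct AeifP {
  double C, gL, EL, VT, DeltaT, a, b, tau_w, Vr, Vspike;
  explicit AeifP(const NumericVector& p)
    : C(p[0]), gL(p[1]), EL(p[2]), VT(p[3]), DeltaT(p[4]),
      a(p[5]), b(p[6]), tau_w(p[7]), Vr(p[8]), Vspike(p[9]) {}
};

// Exponential spike current with a capped argument: once V is far above VT the
// trajectory is on its way to the spike cut anyway; the cap only prevents
// floating-point overflow in the single step before reset.
static inline double exp_term(const AeifP& p, double V) {
  double ex = (V - p.VT) / p.DeltaT;
  if (ex > 16.0) ex = 16.0;
  return p.gL * p.DeltaT * std::exp(ex);
}

static inline void euler_step(const AeifP& p, double I, double dt,
                              double& V, double& w) {
  double dV = (-p.gL * (V - p.EL) + exp_term(p, V) - w + I) / p.C;
  double dw = (p.a * (V - p.EL) - w) / p.tau_w;
  V += dt * dV;
  w += dt * dw;
}

// Marker value stored at the spike sample when a voltage trace is recorded;
// stands in for the unresolved action-potential peak.
static const double SPIKE_PEAK_MV = 30.0;

// Exact OU update x <- mu + (x - mu) e^{-dt/tau} + sigma sqrt(1 - e^{-2dt/tau}) z
// [[Rcpp::export]]
NumericVector ou_series_cpp(int n, double dt, double mu, double sigma,
                            double tau, double x0, bool stationary_init) {
  NumericVector out(n);
  double rho = std::exp(-dt / tau);
  double sd = sigma * std::sqrt(1.0 - rho * rho);
  double x = stationary_init ? mu + sigma * norm_rand() : x0;
  for (int i = 0; i < n; ++i) {
    out[i] = x;
    x = mu + (x - mu) * rho + sd * norm_rand();
  }
  return out;
}

// Forward-Euler integration of the aEIF model driven by a supplied current
// waveform. Spikes: V exceeding Vspike after the update; V -> Vr, w -> w + b
// within the same step. Returns 1-based spike sample indices.
// [[Rcpp::export]]
List sim_aeif_cpp(NumericVector par, NumericVector I, double dt,
                  double V0, double w0, bool record) {
  AeifP p(par);
  int n = I.size();
  double V = V0, w = w0;
  std::vector<int> spikes;
  NumericVector Vout(record ? n : 0), wout(record ? n : 0);
  for (int i = 0; i < n; ++i) {
    euler_step(p, I[i], dt, V, w);
    bool sp = V > p.Vspike;
    if (record) {
      Vout[i] = sp ? SPIKE_PEAK_MV : V;
      wout[i] = w;
    }
    if (sp) {
      spikes.push_back(i + 1);
      V = p.Vr;
      w += p.b;
    }
    if (!std::isfinite(V) || !std::isfinite(w))
      stop("numerical overflow at step %d", i + 1);
  }
  return List::create(_["spikes"] = wrap(spikes), _["V"] = Vout,
                      _["w"] = wout, _["V_end"] = V, _["w_end"] = w);
}

// aEIF driven by OU noise generated on the fly (exact update) plus an
// optional deterministic component (e.g. biexponential synaptic events).
// Returns spike sample indices (1-based) and the final state.
// [[Rcpp::export]]
List sim_aeif_ou_cpp(NumericVector par, int n, double dt, double Imean,
                     double sigma, double tau, Nullable<NumericVector> Iextra,
                     double V0, double w0) {
  AeifP p(par);
  double rho = std::exp(-dt / tau);
  double sd = sigma * std::sqrt(1.0 - rho * rho);
  double x = sigma > 0 ? sigma * norm_rand() : 0.0;
  bool has_extra = Iextra.isNotNull();
  NumericVector extra;
  if (has_extra) extra = Iextra.get();
  double V = V0, w = w0;
  std::vector<int> spikes;
  for (int i = 0; i < n; ++i) {
    double I = Imean + x + (has_extra ? extra[i] : 0.0);
    euler_step(p, I, dt, V, w);
    if (V > p.Vspike) {
      spikes.push_back(i + 1);
      V = p.Vr;
      w += p.b;
    }
    x = x * rho + sd * norm_rand();
  }
  return List::create(_["spikes"] = wrap(spikes), _["V_end"] = V,
                      _["w_end"] = w);
}

// PSTH sweeps: nsweeps independent OU realizations, common deterministic
// input Iextra; per 20 ms (bin_n samples) bin, count sweeps with >= 1 spike.
// [[Rcpp::export]]
IntegerVector psth_count_cpp(NumericVector par, int nsweeps, int n, double dt,
                             double Imean, double sigma, double tau,
                             NumericVector Iextra, double V0, double w0,
                             int bin_n) {
  AeifP p(par);
  int nbins = n / bin_n;
  IntegerVector counts(nbins);
  double rho = std::exp(-dt / tau);
  double sd = sigma * std::sqrt(1.0 - rho * rho);
  std::vector<char> hit(nbins);
  for (int s = 0; s < nsweeps; ++s) {
    std::fill(hit.begin(), hit.end(), 0);
    double V = V0, w = w0;
    double x = sigma > 0 ? sigma * norm_rand() : 0.0;
    for (int i = 0; i < n; ++i) {
      euler_step(p, Imean + x + Iextra[i], dt, V, w);
      if (V > p.Vspike) {
        int b = i / bin_n;
        if (b < nbins) hit[b] = 1;
        V = p.Vr;
        w += p.b;
      }
      x = x * rho + sd * norm_rand();
    }
    for (int b = 0; b < nbins; ++b) counts[b] += hit[b];
  }
  return counts;
}

// ISR protocol: for each sigma, `reps` independent epochs of length n steps,
// all started from (V0, w0); returns the spike count matrix [reps x nsigma].
// [[Rcpp::export]]
NumericMatrix isr_counts_cpp(NumericVector par, NumericVector sigmas,
                             int reps, int n, double dt, double Imean,
                             double tau, double V0, double w0) {
  AeifP p(par);
  int ns = sigmas.size();
  NumericMatrix out(reps, ns);
  double rho = std::exp(-dt / tau);
  for (int j = 0; j < ns; ++j) {
    double sigma = sigmas[j];
    double sd = sigma * std::sqrt(1.0 - rho * rho);
    for (int r = 0; r < reps; ++r) {
      double V = V0, w = w0;
      double x = sigma > 0 ? sigma * norm_rand() : 0.0;
      int cnt = 0;
      for (int i = 0; i < n; ++i) {
        euler_step(p, Imean + x, dt, V, w);
        if (V > p.Vspike) {
          ++cnt;
          V = p.Vr;
          w += p.b;
        }
        x = x * rho + sd * norm_rand();
      }
      out(r, j) = cnt;
    }
  }
  return out;
}

// Basin-of-attraction scan: noise-free integration from each grid point;
// membership = no spike within the horizon and endpoint near the fixed point.
// [[Rcpp::export]]
LogicalMatrix basin_cpp(NumericVector par, double I, NumericVector Vg,
                        NumericVector wg, int horizon_n, double dt,
                        double Vstar, double wstar, double Vtol, double wtol) {
  AeifP p(par);
  int nv = Vg.size(), nw = wg.size();
  LogicalMatrix out(nv, nw);
  for (int j = 0; j < nw; ++j) {
    for (int i = 0; i < nv; ++i) {
      double V = Vg[i], w = wg[j];
      bool spiked = V >= p.Vspike;
      for (int k = 0; k < horizon_n && !spiked; ++k) {
        euler_step(p, I, dt, V, w);
        if (V > p.Vspike) spiked = true;
        // early accept once the trajectory is pinned at the fixed point
        if (std::fabs(V - Vstar) < 0.25 * Vtol &&
            std::fabs(w - wstar) < 0.25 * wtol)
          break;
      }
      out(i, j) = !spiked && std::fabs(V - Vstar) < Vtol &&
                  std::fabs(w - wstar) < wtol;
    }
  }
  return out;
}

// Fraction of integration time spent inside a precomputed basin mask while
// driven by OU noise (nearest-cell lookup; off-grid counts as outside).
// [[Rcpp::export]]
double occupancy_cpp(NumericVector par, LogicalMatrix mask, double Vmin,
                     double dV, double wmin, double dw, int n, double dt,
                     double Imean, double sigma, double tau,
                     double V0, double w0) {
  AeifP p(par);
  int nv = mask.nrow(), nw = mask.ncol();
  double rho = std::exp(-dt / tau);
  double sd = sigma * std::sqrt(1.0 - rho * rho);
  double x = sigma > 0 ? sigma * norm_rand() : 0.0;
  double V = V0, w = w0;
  long inside = 0;
  for (int i = 0; i < n; ++i) {
    euler_step(p, Imean + x, dt, V, w);
    if (V > p.Vspike) {
      V = p.Vr;
      w += p.b;
    }
    int iv = (int)std::lround((V - Vmin) / dV);
    int iw = (int)std::lround((w - wmin) / dw);
    if (iv >= 0 && iv < nv && iw >= 0 && iw < nw && mask(iv, iw)) ++inside;
    x = x * rho + sd * norm_rand();
  }
  return (double)inside / n;
}

// Two-compartment variant: soma follows the aEIF equations plus a coupling
// current gc (Vd - V); the dendrite is passive. Euler at the same dt.
// [[Rcpp::export]]
List sim_two_comp_cpp(NumericVector par, double gc, double Cd, double gLd,
                      NumericVector I, double dt, double V0, double w0,
                      double Vd0, bool record) {
  AeifP p(par);
  int n = I.size();
  double V = V0, w = w0, Vd = Vd0;
  std::vector<int> spikes;
  NumericVector Vout(record ? n : 0);
  for (int i = 0; i < n; ++i) {
    double dV = (-p.gL * (V - p.EL) + exp_term(p, V) - w + I[i] +
                 gc * (Vd - V)) / p.C;
    double dw = (p.a * (V - p.EL) - w) / p.tau_w;
    double dVd = (-gLd * (Vd - p.EL) + gc * (V - Vd)) / Cd;
    V += dt * dV;
    w += dt * dw;
    Vd += dt * dVd;
    bool sp = V > p.Vspike;
    if (record) Vout[i] = sp ? SPIKE_PEAK_MV : V;
    if (sp) {
      spikes.push_back(i + 1);
      V = p.Vr;
      w += p.b;
    }
  }
  return List::create(_["spikes"] = wrap(spikes), _["V"] = Vout,
                      _["V_end"] = V, _["w_end"] = w, _["Vd_end"] = Vd);
}

// Basin-occupancy PSTH: per 20 ms bin, the fraction of integration time the
// trajectory spends outside the rest-state basin, averaged across sweeps
// (the operational "probability of spiking" of the phase-space definition).
// [[Rcpp::export]]
NumericVector psth_occ_cpp(NumericVector par, int nsweeps, int n, double dt,
                           double Imean, double sigma, double tau,
                           NumericVector Iextra, double V0, double w0,
                           int bin_n, LogicalMatrix mask, double Vmin,
                           double dV, double wmin, double dw) {
  AeifP p(par);
  int nbins = n / bin_n;
  int nv = mask.nrow(), nw = mask.ncol();
  std::vector<double> outside(nbins, 0.0);
  double rho = std::exp(-dt / tau);
  double sd = sigma * std::sqrt(1.0 - rho * rho);
  for (int s = 0; s < nsweeps; ++s) {
    double V = V0, w = w0;
    double x = sigma > 0 ? sigma * norm_rand() : 0.0;
    for (int i = 0; i < n; ++i) {
      euler_step(p, Imean + x + Iextra[i], dt, V, w);
      if (V > p.Vspike) {
        V = p.Vr;
        w += p.b;
      }
      int b = i / bin_n;
      if (b < nbins) {
        int iv = (int)std::lround((V - Vmin) / dV);
        int iw = (int)std::lround((w - wmin) / dw);
        bool in = iv >= 0 && iv < nv && iw >= 0 && iw < nw && mask(iv, iw);
        if (!in) outside[b] += 1.0;
      }
      x = x * rho + sd * norm_rand();
    }
  }
  NumericVector out(nbins);
  for (int b = 0; b < nbins; ++b)
    out[b] = outside[b] / ((double)bin_n * nsweeps);
  return out;
}
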