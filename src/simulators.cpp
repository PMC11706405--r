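#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// x / (exp(x / y) - 1) with the removable singularity at x = 0 handled
static inline double vtrap(double x, double y) {
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / y / 2.0);
  return x / (std::exp(x / y) - 1.0);
}

// squid-axon rate functions (ms^-1), V in mV, resting potential near -65 mV
static inline double alpha_m(double v) { return 0.1 * vtrap(-(v + 40.0), 10.0); }
static inline double beta_m(double v)  { return 4.0 * std::exp(-(v + 65.0) / 18.0); }
static inline double alpha_h(double v) { return 0.07 * std::exp(-(v + 65.0) / 20.0); }
static inline double beta_h(double v)  { return 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0)); }
static inline double alpha_n(double v) { return 0.01 * vtrap(-(v + 55.0), 10.0); }
static inline double beta_n(double v)  { return 0.125 * std::exp(-(v + 65.0) / 80.0); }

static inline double xinf(double a, double b) { return a / (a + b); }

// total steady-state membrane current density (uA/cm^2) at voltage v, I = 0
static double hh_steady_current(double v, double gna, double gk, double gl,
                                double ena, double ek, double el) {
  double m = xinf(alpha_m(v), beta_m(v));
  double h = xinf(alpha_h(v), beta_h(v));
  double n = xinf(alpha_n(v), beta_n(v));
  return gna * 1000.0 * m * m * m * h * (v - ena) +
         gk * 1000.0 * n * n * n * n * (v - ek) +
         gl * 1000.0 * (v - el);
}

// resting potential: root of the steady-state current on [-90, -40] mV
static double hh_rest(double gna, double gk, double gl,
                      double ena, double ek, double el) {
  double lo = -90.0, hi = -40.0;
  double flo = hh_steady_current(lo, gna, gk, gl, ena, ek, el);
  for (int it = 0; it < 200; ++it) {
    double mid = 0.5 * (lo + hi);
    double fm = hh_steady_current(mid, gna, gk, gl, ena, ek, el);
    if ((flo <= 0 && fm <= 0) || (flo >= 0 && fm >= 0)) { lo = mid; flo = fm; }
    else hi = mid;
    if (hi - lo < 1e-12) break;
  }
  return 0.5 * (lo + hi);
}

// Single-compartment Hodgkin-Huxley integration.
// Gating variables use exponential Euler; the voltage update is implicit in
// the (frozen) conductances, i.e. relaxation toward the instantaneous
// steady-state voltage with the instantaneous membrane time constant.
// Units: g* S/cm^2, cm uF/cm^2, area cm^2, amp nA, times ms.
// Returns voltage at every step including t = 0 (n_steps + 1 samples).
// [[Rcpp::export(name = ".hh_sim_cpp")]]
NumericVector hh_sim_cpp(double gna, double gk, double gl,
                         double ena, double ek, double el,
                         double cm, double area,
                         double amp, double delay, double duration,
                         double total_duration, double dt) {
  const int n_steps = (int)std::lround(total_duration / dt);
  NumericVector out(n_steps + 1);
  const double gna_ms = gna * 1000.0, gk_ms = gk * 1000.0, gl_ms = gl * 1000.0;
  const double i_dens = amp * 1e-3 / area; // nA -> uA, / cm^2
  // rate tables on a fine voltage grid (the usual trick of compartmental
  // simulators): per gate, the steady state and the fixed-dt relaxation
  // factor 1 - exp(-dt (alpha + beta)), linearly interpolated in V
  const double vlo = -120.0, vhi = 70.0, dv_tab = 0.05;
  const int ntab = (int)std::lround((vhi - vlo) / dv_tab) + 1;
  std::vector<double> minf(ntab), mfac(ntab), hinf(ntab), hfac(ntab),
      ninf(ntab), nfac(ntab);
  for (int i = 0; i < ntab; ++i) {
    double vv = vlo + i * dv_tab;
    double am = alpha_m(vv), bm = beta_m(vv);
    double ah = alpha_h(vv), bh = beta_h(vv);
    double an = alpha_n(vv), bn = beta_n(vv);
    minf[i] = am / (am + bm); mfac[i] = 1.0 - std::exp(-dt * (am + bm));
    hinf[i] = ah / (ah + bh); hfac[i] = 1.0 - std::exp(-dt * (ah + bh));
    ninf[i] = an / (an + bn); nfac[i] = 1.0 - std::exp(-dt * (an + bn));
  }
  double v = hh_rest(gna, gk, gl, ena, ek, el);
  double m = xinf(alpha_m(v), beta_m(v));
  double h = xinf(alpha_h(v), beta_h(v));
  double n = xinf(alpha_n(v), beta_n(v));
  out[0] = v;
  for (int i = 1; i <= n_steps; ++i) {
    double t = (i - 1) * dt;
    double I = (t >= delay && t < delay + duration) ? i_dens : 0.0;
    // gates: exponential Euler using the tabulated rates
    double x = (v - vlo) / dv_tab;
    if (x < 0.0 || x >= ntab - 1) { out[i] = NA_REAL; return out; }
    int j = (int)x;
    double f = x - j, f1 = 1.0 - f;
    m += (f1 * minf[j] + f * minf[j + 1] - m) * (f1 * mfac[j] + f * mfac[j + 1]);
    h += (f1 * hinf[j] + f * hinf[j + 1] - h) * (f1 * hfac[j] + f * hfac[j + 1]);
    n += (f1 * ninf[j] + f * ninf[j + 1] - n) * (f1 * nfac[j] + f * nfac[j + 1]);
    double gna_t = gna_ms * m * m * m * h;
    double gk_t = gk_ms * n * n * n * n;
    double gtot = gna_t + gk_t + gl_ms;
    double vinf = (gna_t * ena + gk_t * ek + gl_ms * el + I) / gtot;
    v += (vinf - v) * (1.0 - std::exp(-dt * gtot / cm));
    if (!std::isfinite(v)) { out[i] = NA_REAL; return out; }
    out[i] = v;
  }
  return out;
}

// Spike detection core: one spike per maximal upward crossing of the
// detection threshold; per spike the peak, the dV/dt-based onset
// (threshold_v), the base width at the threshold_v level with sub-sample
// interpolation, and the AHP depth down to the next spike's onset.
// Columns: peak_time, peak_v, threshold_v, threshold_time, amplitude,
// base_width, ahp_depth.
// [[Rcpp::export(name = ".detect_spikes_cpp")]]
NumericMatrix detect_spikes_cpp(NumericVector v, double dt, double t0,
                                double detect_threshold,
                                double slope_criterion) {
  const int n = v.size();
  std::vector<int> up, down;
  if (v[0] >= detect_threshold) up.push_back(0);
  for (int i = 0; i + 1 < n; ++i) {
    if (v[i] < detect_threshold && v[i + 1] >= detect_threshold)
      up.push_back(i + 1);
    if (v[i] >= detect_threshold && v[i + 1] < detect_threshold)
      down.push_back(i);
  }
  const int ns = (int)up.size();
  NumericMatrix out(ns, 7);
  if (ns == 0) return out;
  std::vector<int> ipk(ns), ion(ns);
  size_t dptr = 0, dprev = 0;
  for (int k = 0; k < ns; ++k) {
    int i_up = up[k];
    while (dptr < down.size() && down[dptr] < i_up) ++dptr;
    int i_down = dptr < down.size() ? down[dptr] : n - 1;
    int i_peak = i_up;
    for (int i = i_up; i <= i_down; ++i)
      if (v[i] > v[i_peak]) i_peak = i;
    // onset: the foot of the contiguous fast-upstroke run (forward dV/dt at
    // or above the slope criterion) leading into the peak, bounded below by
    // the previous spike's end; falls back to the detection crossing when
    // the upstroke never reaches the criterion
    int floor_idx = 0;
    if (k > 0) {
      while (dprev < down.size() && down[dprev] < i_up) ++dprev;
      if (dprev > 0) floor_idx = down[dprev - 1] + 1;
    }
    int i_on = i_up;
    // anchor at the steepest point of the rising phase, then walk back
    int j = floor_idx;
    double dvmax = -1.0;
    for (int i = floor_idx; i < i_peak; ++i) {
      double dvi = (v[i + 1] - v[i]) / dt;
      if (dvi > dvmax) { dvmax = dvi; j = i; }
    }
    if (dvmax >= slope_criterion) {
      while (j > floor_idx && (v[j] - v[j - 1]) / dt >= slope_criterion) --j;
      i_on = j;
    }
    double tv = v[i_on];
    int jl = i_peak;
    while (jl > 0 && v[jl - 1] >= tv) --jl;
    double t_left;
    if (jl > 0 && v[jl - 1] < tv)
      t_left = t0 + (jl - 1 + (tv - v[jl - 1]) / (v[jl] - v[jl - 1])) * dt;
    else t_left = t0 + jl * dt;
    int jr = i_peak;
    while (jr + 1 < n && v[jr + 1] >= tv) ++jr;
    double t_right;
    if (jr + 1 < n && v[jr + 1] < tv)
      t_right = t0 + (jr + (v[jr] - tv) / (v[jr] - v[jr + 1])) * dt;
    else t_right = t0 + jr * dt;
    out(k, 0) = t0 + i_peak * dt;
    out(k, 1) = v[i_peak];
    out(k, 2) = tv;
    out(k, 3) = t0 + i_on * dt;
    out(k, 4) = v[i_peak] - tv;
    out(k, 5) = std::max(t_right - t_left, dt / 2.0);
    ipk[k] = i_peak; ion[k] = i_on;
  }
  for (int k = 0; k < ns; ++k) {
    int j_end = (k + 1 < ns) ? ion[k + 1] : n - 1;
    double vmin = v[ipk[k]];
    for (int i = ipk[k]; i <= j_end; ++i) if (v[i] < vmin) vmin = v[i];
    out(k, 6) = out(k, 2) - vmin;
  }
  return out;
}

// Mean squared difference between two equal-grid traces restricted to
// samples outside the given (merged, sorted) time windows, normalized by
// the squared range of the retained target samples. Returns NA when no
// samples remain or the retained target is constant.
// [[Rcpp::export(name = ".mse_excl_cpp")]]
double mse_excl_cpp(NumericVector m, NumericVector t, double dt, double t0,
                    NumericMatrix win) {
  const int n = m.size();
  const int k = win.nrow();
  int w = 0;
  long cnt = 0;
  double ssq = 0.0, tmin = R_PosInf, tmax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    double ti = t0 + i * dt;
    while (w < k && ti > win(w, 1)) ++w;
    if (w < k && ti >= win(w, 0) && ti <= win(w, 1)) continue;
    double d = m[i] - t[i];
    ssq += d * d;
    if (t[i] < tmin) tmin = t[i];
    if (t[i] > tmax) tmax = t[i];
    ++cnt;
  }
  if (cnt == 0) return NA_REAL;
  double rng = tmax - tmin;
  if (rng <= 0) return NA_REAL;
  return (ssq / cnt) / (rng * rng);
}

// Adaptive exponential integrate-and-fire neuron (forward Euler).
// Units: C pF, g_L/a nS, voltages mV, times ms, b pA, amp nA.
// Spike: V reaches the cut-off V_T + 5*Delta_T -> spike recorded, V reset,
// w += b, V clamped at V_reset for t_ref. Recorded trace clips V at the
// cut-off; spike times are returned separately.
// [[Rcpp::export(name = ".adex_sim_cpp")]]
List adex_sim_cpp(double C, double gL, double EL, double VT, double Vreset,
                  double tref, double DeltaT, double a, double b, double tauw,
                  double amp, double delay, double duration,
                  double total_duration, double dt, int record_every) {
  const int n_steps = (int)std::lround(total_duration / dt);
  const double I_pA = amp * 1000.0;
  const double cutoff = VT + 5.0 * DeltaT;
  const int n_rec = n_steps / record_every + 1;
  NumericVector out(n_rec);
  std::vector<double> spikes;
  double v = EL, w = 0.0;
  double ref_until = -1.0;
  out[0] = v;
  bool failed = false;
  for (int i = 1; i <= n_steps; ++i) {
    double t_prev = (i - 1) * dt;
    double t = i * dt;
    double I = (t_prev >= delay && t_prev < delay + duration) ? I_pA : 0.0;
    if (t_prev < ref_until) {
      v = Vreset; // voltage clamped at reset during the refractory period
      double dw = (a * (v - EL) - w) / tauw;
      w += dt * dw;
    } else {
      double ex = (v - VT) / DeltaT;
      if (ex > 30.0) ex = 30.0; // exponential blow-up is cut by the spike
      double dv = (-gL * (v - EL) + gL * DeltaT * std::exp(ex) - w + I) / C;
      double dw = (a * (v - EL) - w) / tauw;
      v += dt * dv;
      w += dt * dw;
      if (!std::isfinite(v) || !std::isfinite(w)) { failed = true; break; }
      if (v >= cutoff) {
        spikes.push_back(t);
        v = Vreset;
        w += b;
        ref_until = t + tref;
      }
    }
    if (i % record_every == 0) {
      int j = i / record_every;
      out[j] = (v > cutoff) ? cutoff : v;
    }
  }
  if (failed) out[n_rec - 1] = NA_REAL;
  return List::create(_["v"] = out, _["spikes"] = NumericVector(wrap(spikes)),
                      _["failed"] = failed);
}
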