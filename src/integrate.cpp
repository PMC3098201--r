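// Fixed-step RK4 integration of Morris-Lecar and cortical pyramidal model
// neurons, single-cell and network, with online spike detection.
//
// Units: mV, ms, uA/cm^2, mS/cm^2, uF/cm^2 throughout.
//
// Synaptic events are bound to the integration grid: a threshold crossing
// detected at the end of step k injects synaptic drive into targets at the
// start of step k+1 (latency of exactly one step).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const int ML_MODEL = 1;
static const int PYR_MODEL = 2;

// logistic steady-state activation; slope sign sets direction
static inline double sigm(double v, double half, double slope) {
  return 1.0 / (1.0 + std::exp(-(v - half) / slope));
}

struct MLPar {
  double cm, g_l, e_l, g_ca, e_ca, g_k, e_k, v1, v2, v3, v4, phi_w;
};

struct PyrPar {
  double cm, g_na, e_na, g_kdr, e_k, g_ks, g_l, e_l;
  double m_half, m_slope, h_half, h_slope;
  double tau_h0, tau_h1, tau_h_half, tau_h_slope;
  double n_half, n_slope, tau_n0, tau_n1, tau_n_half, tau_n_slope;
  double z_half, z_slope, tau_z, r_h, r_z;
};

// Parameter vectors are assembled in R (pack_params); order must match here.
static MLPar unpack_ml(const NumericVector& p) {
  MLPar q;
  q.cm = p[0]; q.g_l = p[1]; q.e_l = p[2]; q.g_ca = p[3]; q.e_ca = p[4];
  q.g_k = p[5]; q.e_k = p[6]; q.v1 = p[7]; q.v2 = p[8]; q.v3 = p[9];
  q.v4 = p[10]; q.phi_w = p[11];
  return q;
}

static PyrPar unpack_pyr(const NumericVector& p) {
  PyrPar q;
  q.cm = p[0]; q.g_na = p[1]; q.e_na = p[2]; q.g_kdr = p[3]; q.e_k = p[4];
  q.g_ks = p[5]; q.g_l = p[6]; q.e_l = p[7];
  q.m_half = p[8]; q.m_slope = p[9]; q.h_half = p[10]; q.h_slope = p[11];
  q.tau_h0 = p[12]; q.tau_h1 = p[13]; q.tau_h_half = p[14]; q.tau_h_slope = p[15];
  q.n_half = p[16]; q.n_slope = p[17];
  q.tau_n0 = p[18]; q.tau_n1 = p[19]; q.tau_n_half = p[20]; q.tau_n_slope = p[21];
  q.z_half = p[22]; q.z_slope = p[23]; q.tau_z = p[24];
  q.r_h = p[25]; q.r_z = p[26];
  return q;
}

// Morris-Lecar: state = (V, w). m_inf/w_inf are tanh sigmoids:
// 0.5*(1+tanh((V-Vh)/Vs)) == sigm(V, Vh, Vs/2).
static inline void ml_deriv(const MLPar& p, const double* s, double i_ext,
                            double i_syn, double* d) {
  double v = s[0], w = s[1];
  double minf = sigm(v, p.v1, p.v2 * 0.5);
  double winf = sigm(v, p.v3, p.v4 * 0.5);
  double tw_inv = std::cosh((v - p.v3) / (2.0 * p.v4)); // 1/tau_w
  d[0] = (i_ext + i_syn - p.g_l * (v - p.e_l) - p.g_ca * minf * (v - p.e_ca)
          - p.g_k * w * (v - p.e_k)) / p.cm;
  d[1] = p.phi_w * (winf - w) * tw_inv;
}

// Pyramidal: state = (V, h, n, z); instantaneous m = m_inf(V)^3.
static inline void pyr_deriv(const PyrPar& p, const double* s, double i_ext,
                             double i_syn, double* d) {
  double v = s[0], h = s[1], n = s[2], z = s[3];
  double minf = sigm(v, p.m_half, p.m_slope);
  double m3 = minf * minf * minf;
  double n2 = n * n;
  double hinf = sigm(v, p.h_half, p.h_slope);
  double ninf = sigm(v, p.n_half, p.n_slope);
  double zinf = sigm(v, p.z_half, p.z_slope);
  double tau_h = p.tau_h0 + p.tau_h1 * sigm(v, p.tau_h_half, -p.tau_h_slope);
  double tau_n = p.tau_n0 + p.tau_n1 * sigm(v, p.tau_n_half, -p.tau_n_slope);
  d[0] = (i_ext + i_syn - p.g_na * m3 * h * (v - p.e_na)
          - p.g_kdr * n2 * n2 * (v - p.e_k) - p.g_ks * z * (v - p.e_k)
          - p.g_l * (v - p.e_l)) / p.cm;
  d[1] = p.r_h * (hinf - h) / tau_h;
  d[2] = (ninf - n) / tau_n;
  d[3] = p.r_z * (zinf - z) / p.tau_z;
}

// square-pulse train lookup: current contribution at time t given sorted
// onsets; pointers advance monotonically across calls
struct PulseTrain {
  const double* onset;
  int n;
  double amp, dur;
  int lo; // first pulse with onset + dur > t
  int hi; // first pulse with onset > t
  PulseTrain() : onset(nullptr), n(0), amp(0), dur(0), lo(0), hi(0) {}
  double current(double t) {
    if (n == 0) return 0.0;
    while (lo < n && onset[lo] + dur <= t) ++lo;
    while (hi < n && onset[hi] <= t) ++hi;
    return amp * (hi - lo);
  }
};

class RK4 {
public:
  int model, dim;
  MLPar mlp;
  PyrPar pyp;
  RK4(int model_, const NumericVector& p) : model(model_) {
    if (model == ML_MODEL) { mlp = unpack_ml(p); dim = 2; }
    else { pyp = unpack_pyr(p); dim = 4; }
  }
  inline void deriv(const double* s, double i_ext, double i_syn, double* d) {
    if (model == ML_MODEL) ml_deriv(mlp, s, i_ext, i_syn, d);
    else pyr_deriv(pyp, s, i_ext, i_syn, d);
  }
  // one RK4 step; external current may differ at t, t+dt/2, t+dt
  // (i0, im, i1); synaptic current likewise (s0, sm, s1)
  void step(double* s, double dt, double i0, double im, double i1,
            double s0, double sm, double s1) {
    double k1[4], k2[4], k3[4], k4[4], tmp[4];
    deriv(s, i0, s0, k1);
    for (int j = 0; j < dim; ++j) tmp[j] = s[j] + 0.5 * dt * k1[j];
    deriv(tmp, im, sm, k2);
    for (int j = 0; j < dim; ++j) tmp[j] = s[j] + 0.5 * dt * k2[j];
    deriv(tmp, im, sm, k3);
    for (int j = 0; j < dim; ++j) tmp[j] = s[j] + dt * k3[j];
    deriv(tmp, i1, s1, k4);
    for (int j = 0; j < dim; ++j)
      s[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
  }
};

// [[Rcpp::export(name = ".integrate_single_cpp")]]
List integrate_single_cpp(int model, NumericVector params, NumericVector state0,
                          double dt, double t_end, double i_const,
                          NumericVector pulse_onsets, double pulse_amp,
                          double pulse_dur, double threshold,
                          bool keep_trace) {
  RK4 rk(model, params);
  int dim = rk.dim;
  if ((int)state0.size() != dim) stop("state0 has wrong dimension");
  long nstep = (long)std::ceil(t_end / dt - 1e-9);

  PulseTrain pt;
  pt.onset = pulse_onsets.begin();
  pt.n = pulse_onsets.size();
  pt.amp = pulse_amp;
  pt.dur = pulse_dur;

  double s[4];
  for (int j = 0; j < dim; ++j) s[j] = state0[j];

  NumericMatrix trace;
  if (keep_trace) trace = NumericMatrix(nstep + 1, dim + 1);
  std::vector<double> spikes, peaks;
  std::vector<double> peak_state(dim);
  bool have_peak = false;
  bool armed = s[0] < threshold; // ready to register an upward crossing
  double v_prev2 = NA_REAL, v_prev = s[0];
  double prev_state[4]; // state at the previous grid point

  if (keep_trace) {
    trace(0, 0) = 0.0;
    for (int j = 0; j < dim; ++j) trace(0, j + 1) = s[j];
  }

  for (long k = 0; k < nstep; ++k) {
    double t = k * dt;
    double i0 = i_const + pt.current(t);
    double im = i_const + pt.current(t + 0.5 * dt);
    double i1 = i_const + pt.current(t + dt);
    for (int j = 0; j < dim; ++j) prev_state[j] = s[j];
    rk.step(s, dt, i0, im, i1, 0.0, 0.0, 0.0);
    double tn = t + dt;
    double v = s[0];
    if (!R_finite(v))
      stop("integration blew up at step %ld (t = %.3f ms)", k + 1, tn);
    if (keep_trace) {
      trace(k + 1, 0) = tn;
      for (int j = 0; j < dim; ++j) trace(k + 1, j + 1) = s[j];
    }
    // upward threshold crossing, interpolated; re-arm on downward crossing
    if (armed && v_prev < threshold && v >= threshold) {
      double frac = (threshold - v_prev) / (v - v_prev);
      spikes.push_back(t + frac * dt);
      armed = false;
    } else if (!armed && v < threshold) {
      armed = true;
    }
    // local voltage maximum above threshold at the previous grid point t:
    // spike peak, time refined by quadratic interpolation; the grid-point
    // state there (prev_state) anchors phase zero for PRC runs
    if (R_finite(v_prev2) && v_prev >= v_prev2 && v_prev > v &&
        v_prev > threshold) {
      double denom = v_prev2 - 2.0 * v_prev + v;
      double off = (denom < 0) ? 0.5 * dt * (v_prev2 - v) / denom : 0.0;
      peaks.push_back(t + off);
      for (int j = 0; j < dim; ++j) peak_state[j] = prev_state[j];
      have_peak = true;
    }
    v_prev2 = v_prev;
    v_prev = v;
  }

  List out = List::create(
      _["spikes"] = NumericVector(spikes.begin(), spikes.end()),
      _["peaks"] = NumericVector(peaks.begin(), peaks.end()),
      _["final_state"] = NumericVector(s, s + dim),
      _["peak_state"] = have_peak ? NumericVector(peak_state.begin(),
                                                  peak_state.end())
                                  : NumericVector(0));
  if (keep_trace) out["trace"] = trace;
  return out;
}

// [[Rcpp::export(name = ".integrate_network_cpp")]]
List integrate_network_cpp(int model, NumericVector params,
                           NumericMatrix state0, NumericVector i_const,
                           List pulse_onsets, double pulse_amp,
                           double pulse_dur, IntegerVector adj_targets,
                           IntegerVector adj_offsets, double s_weight,
                           double syn_tau, double dt, double t_end,
                           double threshold) {
  RK4 rk(model, params);
  int dim = rk.dim;
  int n = state0.nrow();
  if (state0.ncol() != dim) stop("state0 has wrong dimension");
  if ((int)i_const.size() != n) stop("i_const length != n neurons");
  if ((int)adj_offsets.size() != n + 1)
    stop("adjacency offsets must have length n + 1");
  long nstep = (long)std::ceil(t_end / dt - 1e-9);

  bool has_pulses = pulse_onsets.size() > 0;
  std::vector<PulseTrain> pts(n);
  std::vector<NumericVector> keep; // keep R vectors alive
  if (has_pulses) {
    if (pulse_onsets.size() != n) stop("pulse_onsets must have one entry per neuron");
    keep.reserve(n);
    for (int i = 0; i < n; ++i) {
      NumericVector po = pulse_onsets[i];
      keep.push_back(po);
      pts[i].onset = keep[i].begin();
      pts[i].n = keep[i].size();
      pts[i].amp = pulse_amp;
      pts[i].dur = pulse_dur;
    }
  }

  std::vector<double> st(n * dim);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < dim; ++j) st[i * dim + j] = state0(i, j);

  // alpha-kernel synapse as two linear filters with exact exponential
  // updates: x' = -x/tau, y' = (x - y)/tau; a spike event adds s*e to x,
  // giving y(t) = s * (t/tau) * exp(1 - t/tau), peak s at t = tau
  std::vector<double> sx(n, 0.0), sy(n, 0.0);
  const double kick = s_weight * std::exp(1.0);
  double eh = std::exp(-dt / syn_tau);       // full-step decay
  double ehm = std::exp(-0.5 * dt / syn_tau); // half-step decay

  std::vector<char> armed(n);
  std::vector<double> v_prev(n);
  for (int i = 0; i < n; ++i) {
    v_prev[i] = st[i * dim];
    armed[i] = v_prev[i] < threshold;
  }
  std::vector<char> fired(n, 0);
  std::vector<std::vector<double> > spikes(n);

  for (long k = 0; k < nstep; ++k) {
    double t = k * dt;
    // deliver events detected at the end of the previous step
    for (int i = 0; i < n; ++i) {
      if (fired[i]) {
        fired[i] = 0;
        for (int e = adj_offsets[i]; e < adj_offsets[i + 1]; ++e)
          sx[adj_targets[e]] += kick;
      }
    }
    for (int i = 0; i < n; ++i) {
      double i0 = i_const[i], im = i_const[i], i1 = i_const[i];
      if (has_pulses) {
        i0 += pts[i].current(t);
        im += pts[i].current(t + 0.5 * dt);
        i1 += pts[i].current(t + dt);
      }
      // synaptic current at stage times (exact solution of the filter)
      double x0 = sx[i], y0 = sy[i];
      double s0 = y0;
      double smid = ehm * (y0 + x0 * (0.5 * dt) / syn_tau);
      double s1 = eh * (y0 + x0 * dt / syn_tau);
      double* si = &st[i * dim];
      rk.step(si, dt, i0, im, i1, s0, smid, s1);
      sx[i] = x0 * eh;
      sy[i] = s1;
      double v = si[0];
      if (!R_finite(v))
        stop("integration blew up for neuron %d at t = %.3f ms", i + 1,
             t + dt);
      if (armed[i] && v_prev[i] < threshold && v >= threshold) {
        double frac = (threshold - v_prev[i]) / (v - v_prev[i]);
        spikes[i].push_back(t + frac * dt);
        armed[i] = 0;
        fired[i] = 1;
      } else if (!armed[i] && v < threshold) {
        armed[i] = 1;
      }
      v_prev[i] = v;
    }
  }

  List sp(n);
  for (int i = 0; i < n; ++i)
    sp[i] = NumericVector(spikes[i].begin(), spikes[i].end());
  NumericMatrix fin(n, dim);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < dim; ++j) fin(i, j) = st[i * dim + j];
  return List::create(_["spikes"] = sp, _["final_state"] = fin);
}
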