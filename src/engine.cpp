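// Simulation engine: human atrial myocyte ionic model (Courtemanche-family
// formulation with SK current and chronic-AF hooks), a two-variable
// Mitchell-Schaeffer surrogate, and forward-Euler / Rush-Larsen drivers for
// single cells and 2D monodomain sheets with no-flux borders.
//
// Units: time ms, voltage mV, concentrations mM, currents pA (per-cell,
// Cm = 100 pF), stimulus pA/pF (depolarizing positive), D cm^2/ms, dx cm.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Mitchell-Schaeffer surrogate: states {v, h}, params
// {tau_in, tau_out, tau_open, tau_close, v_gate}. v is the normalized
// membrane variable; the (monotone) mV observation map lives in R.
// ---------------------------------------------------------------------------

static const int MS_NSTATE = 2;

static inline double ms_dv(const double *p, double v, double h) {
  return h * v * v * (1.0 - v) / p[0] - v / p[1];
}

// Rush-Larsen data for the single gate h: below v_gate the gate recovers
// toward 1 with tau_open, above it closes toward 0 with tau_close.
static inline void ms_gate(const double *p, double v, double *hinf, double *htau) {
  if (v < p[4]) { *hinf = 1.0; *htau = p[2]; }
  else          { *hinf = 0.0; *htau = p[3]; }
}

// ---------------------------------------------------------------------------
// Detailed atrial model (Courtemanche-family, 21 states).
// State order: 0 V, 1 m, 2 h, 3 j, 4 oa, 5 oi, 6 ua, 7 ui, 8 xr, 9 xs,
//              10 d, 11 f, 12 fca, 13 u, 14 vrel, 15 w,
//              16 Nai, 17 Ki, 18 Cai, 19 Caup, 20 Carel
// Gates are indices 1..15 (15 Hodgkin-Huxley gates, all Rush-Larsen form).
// Param order (see af_crn_params() on the R side):
// 0 gNa, 1 gK1, 2 gto, 3 gKur_scale, 4 gKr, 5 gKs, 6 gCaL, 7 gKCa,
// 8 INaK_max, 9 INaCa_max, 10 Iup_max, 11 Kup, 12 Nao, 13 Ko, 14 Cao,
// 15 gbCa, 16 gbNa, 17 ipCa_max
// ---------------------------------------------------------------------------

static const int CRN_NSTATE = 21;
static const int CRN_NGATE = 15;

static const double RGAS = 8.3143, TEMP = 310.0, FARA = 96.4867;
static const double CM = 100.0;                    // pF
static const double VI = 13668.0, VUP = 1109.52, VREL = 96.48; // um^3
static const double KREL = 30.0, TAU_TR = 180.0, CAUP_MAX = 15.0;
static const double CMDN = 0.05, KM_CMDN = 0.00238;
static const double TRPN = 0.07, KM_TRPN = 0.0005;
static const double CSQN = 10.0, KM_CSQN = 0.8;
static const double KQ10 = 3.0;
static const double KD_SK = 0.00035;               // SK half-activation (mM)

static inline double safe_ratio(double num, double den, double lim) {
  return (std::fabs(den) < 1e-10) ? lim : num / den;
}

// Computes dV/dt (mV/ms, reaction part incl. istim), concentration
// derivatives, and (winf, wtau) for all 15 gates.
static void crn_rates(const double *s, const double *p, double istim,
                      double *dvdt, double *dconc,
                      double *winf, double *wtau) {
  const double V = s[0];
  const double m = s[1], h = s[2], j = s[3], oa = s[4], oi = s[5];
  const double ua = s[6], ui = s[7], xr = s[8], xs = s[9];
  const double d = s[10], f = s[11], fca = s[12];
  const double u = s[13], vr = s[14], w = s[15];
  const double Nai = s[16], Ki = s[17], Cai = s[18];
  const double Caup = s[19], Carel = s[20];
  const double Nao = p[12], Ko = p[13], Cao = p[14];
  const double RTF = RGAS * TEMP / FARA;

  const double ENa = RTF * std::log(Nao / Nai);
  const double EK  = RTF * std::log(Ko / Ki);
  const double ECa = 0.5 * RTF * std::log(Cao / Cai);

  // Fast Na+
  const double INa = CM * p[0] * m * m * m * h * j * (V - ENa);

  // Inward rectifier (with square-root external-K dependence so that the
  // varied [K]o multiplier acts on conductance as well as on EK)
  const double IK1 = CM * p[1] * std::sqrt(Ko / 5.4) * (V - EK) /
                     (1.0 + std::exp(0.07 * (V + 80.0)));

  // Transient outward
  const double Ito = CM * p[2] * oa * oa * oa * oi * (V - EK);

  // Ultrarapid delayed rectifier (voltage-dependent conductance)
  const double gkur = 0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0));
  const double IKur = CM * p[3] * gkur * ua * ua * ua * ui * (V - EK);

  // Rapid and slow delayed rectifiers
  const double IKr = CM * p[4] * xr * (V - EK) /
                     (1.0 + std::exp((V + 15.0) / 22.4));
  const double IKs = CM * p[5] * xs * xs * (V - EK);

  // L-type Ca2+
  const double ICaL = CM * p[6] * d * f * fca * (V - 65.0);

  // SK (small-conductance Ca2+-activated K+)
  const double sk_act = Cai * Cai / (Cai * Cai + KD_SK * KD_SK);
  const double IKCa = CM * p[7] * sk_act * (V - EK);

  // Na+/K+ pump
  const double sigma = (std::exp(Nao / 67.3) - 1.0) / 7.0;
  const double fNaK = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / RTF) +
                             0.0365 * sigma * std::exp(-V / RTF));
  const double INaK = CM * p[8] * fNaK *
                      (1.0 / (1.0 + std::pow(10.0 / Nai, 1.5))) *
                      (Ko / (Ko + 1.5));

  // Na+/Ca2+ exchanger
  const double gam = 0.35;
  const double eg  = std::exp(gam * V / RTF);
  const double egm = std::exp((gam - 1.0) * V / RTF);
  const double INaCa = CM * p[9] *
      (eg * Nai * Nai * Nai * Cao - egm * Nao * Nao * Nao * Cai) /
      ((87.5 * 87.5 * 87.5 + Nao * Nao * Nao) * (1.38 + Cao) *
       (1.0 + 0.1 * egm));

  // Background and sarcolemmal pump currents
  const double IbCa = CM * p[15] * (V - ECa);
  const double IbNa = CM * p[16] * (V - ENa);
  const double IpCa = CM * p[17] * Cai / (0.0005 + Cai);

  // SR fluxes (mM/ms)
  const double Irel = KREL * u * u * vr * w * (Carel - Cai);
  const double Itr  = (Caup - Carel) / TAU_TR;
  const double Iup  = p[10] / (1.0 + p[11] / Cai);
  const double Iupleak = p[10] * Caup / CAUP_MAX;

  const double Iion = INa + IK1 + Ito + IKur + IKr + IKs + ICaL + IKCa +
                      IpCa + INaK + INaCa + IbNa + IbCa;
  *dvdt = -(Iion) / CM + istim;

  // Concentrations
  dconc[0] = (-3.0 * INaK - 3.0 * INaCa - IbNa - INa) / (FARA * VI); // Nai
  dconc[1] = (2.0 * INaK - IK1 - Ito - IKur - IKr - IKs - IKCa) /
             (FARA * VI);                                            // Ki
  const double B1 = (2.0 * INaCa - IpCa - ICaL - IbCa) / (2.0 * FARA * VI) +
                    (VUP * (Iupleak - Iup) + Irel * VREL) / VI;
  const double B2 = 1.0 +
      TRPN * KM_TRPN / ((Cai + KM_TRPN) * (Cai + KM_TRPN)) +
      CMDN * KM_CMDN / ((Cai + KM_CMDN) * (Cai + KM_CMDN));
  dconc[2] = B1 / B2;                                                // Cai
  dconc[3] = Iup - Iupleak - Itr * VREL / VUP;                       // Caup
  dconc[4] = (Itr - Irel) /
             (1.0 + CSQN * KM_CSQN / ((Carel + KM_CSQN) * (Carel + KM_CSQN)));

  // --- gate kinetics (winf, wtau) ---
  double a, b;

  // m
  a = safe_ratio(0.32 * (V + 47.13),
                 1.0 - std::exp(-0.1 * (V + 47.13)), 3.2);
  b = 0.08 * std::exp(-V / 11.0);
  winf[0] = a / (a + b); wtau[0] = 1.0 / (a + b);
  // h
  if (V >= -40.0) {
    a = 0.0;
    b = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
  } else {
    a = 0.135 * std::exp(-(V + 80.0) / 6.8);
    b = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
  }
  winf[1] = a / (a + b); wtau[1] = 1.0 / (a + b);
  // j
  if (V >= -40.0) {
    a = 0.0;
    b = 0.3 * std::exp(-2.535e-7 * V) /
        (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    a = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V)) *
        (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    b = 0.1212 * std::exp(-0.01052 * V) /
        (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  winf[2] = a / (a + b); wtau[2] = 1.0 / (a + b);
  // oa / ua share alpha-beta structure
  const double ab_a = 0.65 / (std::exp(-(V + 10.0) / 8.5) +
                              std::exp(-(V - 30.0) / 59.0));
  const double ab_b = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  wtau[3] = 1.0 / ((ab_a + ab_b) * KQ10);
  winf[3] = 1.0 / (1.0 + std::exp(-(V + 20.47) / 17.54));
  // oi
  a = 1.0 / (18.53 + std::exp((V + 113.7) / 10.95));
  b = 1.0 / (35.56 + std::exp(-(V + 1.26) / 7.44));
  wtau[4] = 1.0 / ((a + b) * KQ10);
  winf[4] = 1.0 / (1.0 + std::exp((V + 43.1) / 5.3));
  // ua
  wtau[5] = wtau[3];
  winf[5] = 1.0 / (1.0 + std::exp(-(V + 30.3) / 9.6));
  // ui
  a = 1.0 / (21.0 + std::exp(-(V - 185.0) / 28.0));
  b = std::exp((V - 158.0) / 16.0);
  wtau[6] = 1.0 / ((a + b) * KQ10);
  winf[6] = 1.0 / (1.0 + std::exp((V - 99.45) / 27.48));
  // xr
  a = safe_ratio(0.0003 * (V + 14.1),
                 1.0 - std::exp(-(V + 14.1) / 5.0), 0.0015);
  b = safe_ratio(7.3898e-5 * (V - 3.3328),
                 std::exp((V - 3.3328) / 5.1237) - 1.0, 3.7862e-4);
  wtau[7] = 1.0 / (a + b);
  winf[7] = 1.0 / (1.0 + std::exp(-(V + 14.1) / 6.5));
  // xs
  a = safe_ratio(4e-5 * (V - 19.9),
                 1.0 - std::exp(-(V - 19.9) / 17.0), 6.8e-4);
  b = safe_ratio(3.5e-5 * (V - 19.9),
                 std::exp((V - 19.9) / 9.0) - 1.0, 3.15e-4);
  wtau[8] = 0.5 / (a + b);
  winf[8] = 1.0 / std::sqrt(1.0 + std::exp(-(V - 19.9) / 12.7));
  // d
  {
    const double e1 = std::exp(-(V + 10.0) / 6.24);
    wtau[9] = safe_ratio(1.0 - e1,
                         0.035 * (V + 10.0) * (1.0 + e1),
                         1.0 / (0.035 * 6.24 * 2.0));
    winf[9] = 1.0 / (1.0 + std::exp(-(V + 10.0) / 8.0));
  }
  // f
  wtau[10] = 9.0 / (0.0197 * std::exp(-0.0337 * 0.0337 * (V + 10.0) * (V + 10.0)) + 0.02);
  winf[10] = 1.0 / (1.0 + std::exp((V + 28.0) / 6.9));
  // fca
  wtau[11] = 2.0;
  winf[11] = 1.0 / (1.0 + Cai / 0.00035);
  // u, vrel (SR release gates driven by Fn)
  {
    const double Fn = 1e-12 * VREL * Irel -
                      (5e-13 / FARA) * (0.5 * ICaL - 0.2 * INaCa);
    wtau[12] = 8.0;
    winf[12] = 1.0 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 13.67e-16));
    wtau[13] = 1.91 + 2.09 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 13.67e-16));
    winf[13] = 1.0 - 1.0 / (1.0 + std::exp(-(Fn - 6.835e-14) / 13.67e-16));
  }
  // w
  {
    const double e1 = std::exp(-(V - 7.9) / 5.0);
    wtau[14] = safe_ratio(6.0 * (1.0 - e1),
                          (1.0 + 0.3 * e1) * (V - 7.9),
                          6.0 / (5.0 * 1.3));
    winf[14] = 1.0 - 1.0 / (1.0 + std::exp(-(V - 40.0) / 17.0));
  }
}

// ---------------------------------------------------------------------------
// [[Rcpp::export]] engine entry points
// ---------------------------------------------------------------------------

// Raw derivative/gate-rate evaluation (the cell_derivatives contract).
// model: 0 = surrogate, 1 = detailed atrial.
// [[Rcpp::export]]
List cpp_cell_rhs(int model, NumericVector state, NumericVector params,
                  double istim) {
  if (model == 0) {
    double hinf, htau;
    double dv = ms_dv(REAL(params), state[0], state[1]) + istim;
    ms_gate(REAL(params), state[0], &hinf, &htau);
    return List::create(_["dvdt"] = dv,
                        _["winf"] = NumericVector::create(hinf),
                        _["wtau"] = NumericVector::create(htau),
                        _["dconc"] = NumericVector(0));
  }
  double dvdt, dconc[5], winf[CRN_NGATE], wtau[CRN_NGATE];
  crn_rates(REAL(state), REAL(params), istim, &dvdt, dconc, winf, wtau);
  return List::create(_["dvdt"] = dvdt,
                      _["winf"] = NumericVector(winf, winf + CRN_NGATE),
                      _["wtau"] = NumericVector(wtau, wtau + CRN_NGATE),
                      _["dconc"] = NumericVector(dconc, dconc + 5));
}

struct StimSet {
  std::vector<double> t0, t1, amp;
  double next_edge(double t) const {
    double e = 1e300;
    for (size_t k = 0; k < t0.size(); ++k) {
      if (t0[k] > t + 1e-12 && t0[k] < e) e = t0[k];
      if (t1[k] > t + 1e-12 && t1[k] < e) e = t1[k];
    }
    return e;
  }
  double at(double t) const {
    double a = 0.0;
    for (size_t k = 0; k < t0.size(); ++k)
      if (t >= t0[k] - 1e-12 && t < t1[k] - 1e-12) a += amp[k];
    return a;
  }
};

// Single-cell run with forward-Euler V/concentrations and Rush-Larsen gates.
// Returns Vm sampled at dt_out plus the final state and gate extrema.
// [[Rcpp::export]]
List cpp_cell_run(int model, NumericVector params, NumericVector state0,
                  double total_ms, NumericVector stim_starts,
                  double stim_dur, double stim_amp, double dt, double dt_out) {
  const int nstate = (model == 0) ? MS_NSTATE : CRN_NSTATE;
  const int ngate = (model == 0) ? 1 : CRN_NGATE;
  if (state0.size() != nstate) stop("state vector has wrong length");
  std::vector<double> s(state0.begin(), state0.end());

  StimSet st;
  for (int k = 0; k < stim_starts.size(); ++k) {
    st.t0.push_back(stim_starts[k]);
    st.t1.push_back(stim_starts[k] + stim_dur);
    st.amp.push_back(stim_amp);
  }

  const long nsteps = (long)std::llround(total_ms / dt);
  const long per_out = std::max(1L, (long)std::llround(dt_out / dt));
  const long nout = nsteps / per_out + 1;
  NumericVector tout(nout), vout(nout);
  std::vector<double> gmin(ngate, 1e300), gmax(ngate, -1e300);

  double winf[CRN_NGATE], wtau[CRN_NGATE], dconc[5], dvdt;
  long iout = 0;
  const double *p = REAL(params);
  for (long i = 0; i <= nsteps; ++i) {
    const double t = i * dt;
    if (i % per_out == 0 && iout < nout) {
      tout[iout] = t;
      vout[iout] = s[0];
      ++iout;
    }
    if (i == nsteps) break;
    const double istim = st.at(t);
    if (model == 0) {
      double hinf, htau;
      const double dv = ms_dv(p, s[0], s[1]) + istim;
      ms_gate(p, s[0], &hinf, &htau);
      s[1] = hinf + (s[1] - hinf) * std::exp(-dt / htau);
      s[0] += dt * dv;
      if (s[1] < gmin[0]) gmin[0] = s[1];
      if (s[1] > gmax[0]) gmax[0] = s[1];
    } else {
      crn_rates(s.data(), p, istim, &dvdt, dconc, winf, wtau);
      for (int g = 0; g < CRN_NGATE; ++g) {
        s[1 + g] = winf[g] + (s[1 + g] - winf[g]) * std::exp(-dt / wtau[g]);
        if (s[1 + g] < gmin[g]) gmin[g] = s[1 + g];
        if (s[1 + g] > gmax[g]) gmax[g] = s[1 + g];
      }
      s[0] += dt * dvdt;
      for (int c = 0; c < 5; ++c) s[16 + c] += dt * dconc[c];
    }
    if (!std::isfinite(s[0]))
      stop("numerical blowup at t = %f ms", t);
  }
  return List::create(_["t"] = tout, _["vm"] = vout,
                      _["state_final"] = NumericVector(s.begin(), s.end()),
                      _["gate_min"] = NumericVector(gmin.begin(), gmin.end()),
                      _["gate_max"] = NumericVector(gmax.begin(), gmax.end()));
}

// 2D monodomain run (also used for 1D-equivalent strips, ny >> nx).
// Grid is nx rows by ny cols, column-major linear index = row + col*nx.
// No-flux borders via mirrored ghost nodes. Stimuli are node-mask based.
// The diffused variable is the model's voltage variable (surrogate: the
// normalized v, its native PDE variable).
// [[Rcpp::export]]
List cpp_tissue_run(int model, NumericVector params, NumericMatrix state0,
                    int nx, int ny, double dx, double D, double dt,
                    double total_ms,
                    NumericVector stim_t0, NumericVector stim_dur,
                    NumericVector stim_amp, List stim_mask,
                    IntegerVector probe, double movie_start, double movie_dt,
                    int movie_stride) {
  const int n = nx * ny;
  const int nstate = (model == 0) ? MS_NSTATE : CRN_NSTATE;
  if (state0.nrow() != nstate || state0.ncol() != n)
    stop("state0 must be nstate x (nx*ny)");

  // state arrays, voltage separated for the diffusion stencil
  std::vector<double> V(n), Vn(n);
  std::vector<std::vector<double> > S(nstate - 1,
                                      std::vector<double>(n));
  for (int c = 0; c < n; ++c) {
    V[c] = state0(0, c);
    for (int k = 1; k < nstate; ++k) S[k - 1][c] = state0(k, c);
  }

  const int nstim = stim_t0.size();
  std::vector<std::vector<int> > masks(nstim);
  for (int k = 0; k < nstim; ++k) {
    IntegerVector mk = stim_mask[k];
    masks[k].assign(mk.begin(), mk.end());
  }

  const long nsteps = (long)std::llround(total_ms / dt);
  const double rD = D * dt / (dx * dx);

  // movie bookkeeping (strided in space, movie_dt in time)
  const int nxs = (nx + movie_stride - 1) / movie_stride;
  const int nys = (ny + movie_stride - 1) / movie_stride;
  long nframes = 0;
  if (movie_start <= total_ms)
    nframes = (long)std::floor((total_ms - movie_start) / movie_dt) + 1;
  NumericVector movie(nframes > 0 ? nframes * nxs * nys : 0);
  NumericVector movie_t(nframes > 0 ? nframes : 0);
  long iframe = 0;

  // probe traces at movie_dt
  const int nprobe = probe.size();
  const long ntr = (long)std::floor(total_ms / movie_dt) + 1;
  NumericMatrix probe_vm(nprobe > 0 ? ntr : 0, nprobe);
  NumericVector probe_t(nprobe > 0 ? ntr : 0);
  long itr = 0;

  const long per_out = std::max(1L, (long)std::llround(movie_dt / dt));
  bool blowup = false; int blow_node = -1; double blow_t = NA_REAL;
  const double *p = REAL(params);

  // surrogate fast-path constants
  const double inv_tin = (model == 0) ? 1.0 / p[0] : 0.0;
  const double inv_tout = (model == 0) ? 1.0 / p[1] : 0.0;
  const double e_open = (model == 0) ? std::exp(-dt / p[2]) : 0.0;
  const double e_close = (model == 0) ? std::exp(-dt / p[3]) : 0.0;
  const double vgate = (model == 0) ? p[4] : 0.0;

  double winf[CRN_NGATE], wtau[CRN_NGATE], dconc[5], dvdt;

  for (long i = 0; i <= nsteps; ++i) {
    const double t = i * dt;

    if (i % per_out == 0) {
      if (nprobe > 0 && itr < ntr) {
        probe_t[itr] = t;
        for (int q = 0; q < nprobe; ++q) probe_vm(itr, q) = V[probe[q]];
        ++itr;
      }
      if (nframes > 0 && t >= movie_start - 1e-9 && iframe < nframes) {
        movie_t[iframe] = t;
        double *fr = REAL(movie) + iframe * (long)nxs * nys;
        for (int cj = 0, js = 0; cj < ny; cj += movie_stride, ++js)
          for (int ci = 0, is = 0; ci < nx; ci += movie_stride, ++is)
            fr[is + js * (long)nxs] = V[ci + cj * nx];
        ++iframe;
      }
    }
    if (i == nsteps) break;

    // reaction + diffusion into Vn
    if (model == 0) {
      // fused surrogate fast path: interior columns vectorize cleanly,
      // boundary rows/cols handled by clamped-mirror indices
      double *vp = V.data(), *vn = Vn.data(), *hp = S[0].data();
      for (int cj = 0; cj < ny; ++cj) {
        // ny == 1 degenerates to a cable: the transverse mirror neighbors
        // are the node itself (zero transverse flux)
        const int jl = (cj == 0) ? (ny > 1 ? 1 : 0) : cj - 1;
        const int jr = (cj == ny - 1) ? (ny > 1 ? ny - 2 : 0) : cj + 1;
        const double *col = vp + cj * (long)nx;
        const double *cl = vp + jl * (long)nx;
        const double *cr = vp + jr * (long)nx;
        double *out = vn + cj * (long)nx;
        double *hh = hp + cj * (long)nx;
        // interior of the column is stencil-contiguous and vectorizes;
        // the gate select is an arithmetic blend so gcc can if-convert
        for (int ci = 1; ci < nx - 1; ++ci) {
          const double v = col[ci], h = hh[ci];
          const double lap = col[ci - 1] + col[ci + 1] + cl[ci] + cr[ci] -
                             4.0 * v;
          out[ci] = v + rD * lap +
                    dt * (h * v * v * (1.0 - v) * inv_tin - v * inv_tout);
          const double open_val = 1.0 + (h - 1.0) * e_open;
          const double close_val = h * e_close;
          const double sel = (v < vgate) ? 1.0 : 0.0;
          hh[ci] = close_val + sel * (open_val - close_val);
        }
        for (int ci = 0; ci < nx; ci += nx - 1) {  // mirrored borders
          const int il = (ci == 0) ? 1 : ci - 1;
          const int ir = (ci == nx - 1) ? nx - 2 : ci + 1;
          const double v = col[ci], h = hh[ci];
          const double lap = col[il] + col[ir] + cl[ci] + cr[ci] - 4.0 * v;
          out[ci] = v + rD * lap +
                    dt * (h * v * v * (1.0 - v) * inv_tin - v * inv_tout);
          const double open_val = 1.0 + (h - 1.0) * e_open;
          const double close_val = h * e_close;
          hh[ci] = (v < vgate) ? open_val : close_val;
        }
      }
    } else {
    for (int cj = 0; cj < ny; ++cj) {
      const int jl = (cj == 0) ? (ny > 1 ? 1 : 0) : cj - 1;
      const int jr = (cj == ny - 1) ? (ny > 1 ? ny - 2 : 0) : cj + 1;
      for (int ci = 0; ci < nx; ++ci) {
        const int il = (ci == 0) ? (nx > 1 ? 1 : 0) : ci - 1;
        const int ir = (ci == nx - 1) ? (nx > 1 ? nx - 2 : 0) : ci + 1;
        const int c = ci + cj * nx;
        const double lap = V[il + cj * nx] + V[ir + cj * nx] +
                           V[ci + jl * nx] + V[ci + jr * nx] - 4.0 * V[c];
        {
          double sloc[CRN_NSTATE];
          sloc[0] = V[c];
          for (int k = 1; k < CRN_NSTATE; ++k) sloc[k] = S[k - 1][c];
          crn_rates(sloc, p, 0.0, &dvdt, dconc, winf, wtau);
          Vn[c] = V[c] + rD * lap + dt * dvdt;
          for (int g = 0; g < CRN_NGATE; ++g)
            S[g][c] = winf[g] + (sloc[1 + g] - winf[g]) *
                      std::exp(-dt / wtau[g]);
          for (int cc = 0; cc < 5; ++cc)
            S[15 + cc][c] = sloc[16 + cc] + dt * dconc[cc];
        }
      }
    }
    }
    // stimuli (additive on dV/dt)
    for (int k = 0; k < nstim; ++k) {
      if (t >= stim_t0[k] - 1e-12 && t < stim_t0[k] + stim_dur[k] - 1e-12) {
        const double add = dt * stim_amp[k];
        for (size_t q = 0; q < masks[k].size(); ++q) Vn[masks[k][q]] += add;
      }
    }
    V.swap(Vn);

    if (i % 100 == 0) {
      for (int c = 0; c < n; ++c)
        if (!std::isfinite(V[c])) { blowup = true; blow_node = c; blow_t = t; break; }
      if (blowup) break;
    }
  }

  if (nframes > 0) movie.attr("dim") = IntegerVector::create(nxs, nys, nframes);
  NumericMatrix sf(nstate, n);
  for (int c = 0; c < n; ++c) {
    sf(0, c) = V[c];
    for (int k = 1; k < nstate; ++k) sf(k, c) = S[k - 1][c];
  }
  return List::create(_["movie"] = movie, _["movie_t"] = movie_t,
                      _["probe_t"] = probe_t, _["probe_vm"] = probe_vm,
                      _["state_final"] = sf,
                      _["blowup"] = blowup, _["blowup_node"] = blow_node,
                      _["blowup_t"] = blow_t,
                      _["nxs"] = nxs, _["nys"] = nys);
}
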