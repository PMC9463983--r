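// Forward-Euler integrator for the three-cell feedforward disinhibition
// circuit (OLM "O-cell" -> fast-spiking "I-cell" -> pyramidal dendritic
// compartment E_D) with kinetic receptor channels, CICR at the O-cell
// terminal and the calcium-based AMPAR plasticity rule.
//
// Units throughout: mV, ms, pA, nS, pF (pA/pF == mV/ms), transmitter and
// O-cell calcium in mM, dendritic calcium in uM.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double logistic_safe(double x) {
  if (x > 500.0) return 1.0;
  if (x < -500.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// ---------------------------------------------------------------------------
// Voltage-dependent rate functions.  Removable singularities are evaluated
// by an explicit |V - V0| < 1e-6 mV branch returning the analytic limit.
struct ORates { double an, bn, am, bm, ah, bh, ap, bp, hfi, thf, hsi, ths; };

static ORates ocell_rates_c(double V) {
  ORates r;
  if (std::fabs(V + 27.0) < 1e-6) r.an = 0.1;
  else r.an = -0.01 * (V + 27.0) / (std::exp(-0.1 * (V + 27.0)) - 1.0);
  r.bn = 0.125 * std::exp(-(V + 37.0) / 80.0);
  if (std::fabs(V + 23.0) < 1e-6) r.am = 1.0;
  else r.am = -0.1 * (V + 23.0) / (std::exp(-0.1 * (V + 23.0)) - 1.0);
  r.bm = 4.0 * std::exp(-(V + 48.0) / 18.0);
  r.ah = 0.07 * std::exp(-(V + 37.0) / 20.0);
  r.bh = 1.0 / (std::exp(-0.1 * (V + 7.0)) + 1.0);
  double e = std::exp(-(V + 38.0) / 6.5);
  r.ap = 1.0 / (0.15 * (1.0 + e));
  r.bp = e / (0.15 * (1.0 + e));
  r.hfi = 1.0 / (1.0 + std::exp((V + 79.2) / 9.78));
  r.thf = 0.51 / (std::exp((V - 1.7) / 10.0) + std::exp(-(V + 340.0) / 52.0)) + 1.0;
  r.hsi = std::pow(1.0 / (1.0 + std::exp((V + 2.83) / 15.9)), 58.0);
  r.ths = 5.6 / (std::exp((V - 1.7) / 14.0) + std::exp(-(V + 260.0) / 43.0)) + 1.0;
  return r;
}

struct IRates { double an, bn, am, bm, ah, bh; };

static IRates icell_rates_c(double V) {
  IRates r;
  if (std::fabs(V + 52.0) < 1e-6) r.an = 0.16;
  else r.an = 0.032 * (V + 52.0) / (1.0 - std::exp(-(V + 52.0) / 5.0));
  r.bn = 0.5 * std::exp(-(V + 57.0) / 40.0);
  if (std::fabs(V + 54.0) < 1e-6) r.am = 1.28;
  else r.am = 0.32 * (V + 54.0) / (1.0 - std::exp(-(V + 54.0) / 4.0));
  if (std::fabs(V + 27.0) < 1e-6) r.bm = 1.4;
  else r.bm = 0.28 * (V + 27.0) / (std::exp((V + 27.0) / 5.0) - 1.0);
  r.ah = 0.128 * std::exp(-(V + 50.0) / 18.0);
  r.bh = 4.0 / (1.0 + std::exp(-(V + 27.0) / 5.0));
  return r;
}

// ---------------------------------------------------------------------------
// Stimulus trains.  Onsets are sorted; a per-train cursor gives O(1)
// amortised evaluation as t advances monotonically.  Overlapping pulses in
// one species combine by maximum.
struct Stim {
  std::vector<double> onsets;
  double amp, dur, decay;
  int shape;   // 0 = square, 1 = alpha (instantaneous rise, exp decay)
  int cursor;  // index of last onset <= t, or -1
  Stim() : amp(0), dur(0), decay(1), shape(0), cursor(-1) {}
  double value(double t) {
    int n = (int)onsets.size();
    if (n == 0) return 0.0;
    while (cursor + 1 < n && onsets[cursor + 1] <= t) ++cursor;
    if (cursor < 0) return 0.0;
    double dtq = t - onsets[cursor];
    if (shape == 0) return (dtq < dur) ? amp : 0.0; // half-open [on, on+dur)
    return amp * std::exp(-dtq / decay);
  }
};

static std::vector<Stim> build_stims(List trains) {
  std::vector<Stim> out;
  for (int i = 0; i < trains.size(); ++i) {
    List tr = trains[i];
    Stim s;
    NumericVector on = tr["onsets"];
    s.onsets = std::vector<double>(on.begin(), on.end());
    s.amp = as<double>(tr["amplitude"]);
    std::string shape = as<std::string>(tr["shape"]);
    if (shape == "alpha") { s.shape = 1; s.decay = as<double>(tr["decay"]); }
    else { s.shape = 0; s.dur = as<double>(tr["duration"]); }
    out.push_back(s);
  }
  return out;
}

static double stim_value(std::vector<Stim>& ss, double t) {
  double v = 0.0;
  for (size_t i = 0; i < ss.size(); ++i) {
    double x = ss[i].value(t);
    if (x > v) v = x;
  }
  return v;
}

// state vector layout (length 22)
enum { S_VO, S_MO, S_HO, S_NO, S_PO, S_HFO, S_HSO, S_RA7, S_CAI, S_CAIS,
       S_VI, S_MI, S_HI, S_NI, S_RAI, S_RGI,
       S_VE, S_RAE, S_RNE, S_RGE, S_CAD, S_G, S_N };

// [[Rcpp::export]]
List engine_run(List par, List stim_glu, List stim_ach, List stim_gaba,
                List stim_cainj, NumericVector init,
                double t0, double t_end, double dt,
                bool ed_only, int gabao_mode,
                bool noise_on, double sigma_o, double sigma_i, double sigma_e,
                double clamp_ed, double record_stride) {
  if (dt <= 0) stop("dt must be > 0");
  if (t_end <= t0) stop("t_end must exceed t0");
  if (init.size() != S_N) stop("init state must have length %d", (int)S_N);

  // --- unpack parameters (flat named list of scalars) ---
  #define P(nm) as<double>(par[nm])
  const double o_C = P("o_C"), o_gl = P("o_gl"), o_El = P("o_El"),
    o_gK = P("o_gK"), o_EK = P("o_EK"), o_gNa = P("o_gNa"), o_ENa = P("o_ENa"),
    o_gp = P("o_gp"), o_gh = P("o_gh"), o_Eh = P("o_Eh"), o_Iapp = P("o_Iapp");
  const double i_C = P("i_C"), i_gl = P("i_gl"), i_El = P("i_El"),
    i_gK = P("i_gK"), i_EK = P("i_EK"), i_gNa = P("i_gNa"), i_ENa = P("i_ENa");
  const double e_C = P("e_C"), e_gl = P("e_gl"), e_El = P("e_El");
  const double aA = P("alpha_A"), bA = P("beta_A"), EA = P("E_A"),
    aN = P("alpha_N"), bN = P("beta_N"), gN = P("g_N"), EN = P("E_N"),
    Mg = P("Mg"), aG = P("alpha_G"), bG = P("beta_G"), EG = P("E_G"),
    gA_I = P("g_ampa_I"), gG_I = P("g_gaba_I"), gG_E = P("g_gaba_E");
  const double ga7 = P("g_a7"), Ea7 = P("E_a7"), ec50 = P("ec50"),
    nhill = P("n_hill"), tau_ra7 = P("tau_ra7");
  const double Tmax = P("T_max"), Kp = P("K_p"), Vp = P("V_p"),
    KCap = P("K_Ca_p"), Cap = P("Ca_p");
  const double xi_p = P("xi_prime"), al_p = P("alpha_prime"),
    tau_cao = P("tau_ca_o"), tau_is = P("tau_is"), kd = P("k_d"),
    cais_rest = P("ca_is_rest");
  const double xi = P("xi"), al_ca = P("alpha_frac"), tau_cad = P("tau_ca_d");
  const double sigma_g = P("sigma_plast"), g0 = P("g0"),
    th_up = P("theta_up"), th_dn = P("theta_down"),
    gam_up = P("gamma_up"), gam_dn = P("gamma_down"),
    P1 = P("P1"), P2 = P("P2"), P3 = P("P3"), P4 = P("P4"),
    steep = P("steepness");
  #undef P

  std::vector<Stim> glu = build_stims(stim_glu);
  std::vector<Stim> ach = build_stims(stim_ach);
  std::vector<Stim> gab = build_stims(stim_gaba);
  std::vector<Stim> cin = build_stims(stim_cainj);

  double s[S_N];
  for (int i = 0; i < S_N; ++i) s[i] = init[i];

  const long nsteps = (long)std::floor((t_end - t0) / dt + 0.5);
  const long krec = std::max(1L, (long)std::floor(record_stride / dt + 0.5));
  const long nrec = nsteps / krec + 1;
  const int NC = 14;
  NumericMatrix rec(nrec, NC);
  CharacterVector cn = CharacterVector::create(
    "t", "v_o", "v_i", "v_e", "ca_i", "ca_is", "ca_d", "g_ampa",
    "i_ampa", "i_nmda", "i_gaba", "gaba_i", "gaba_o", "r_a7");
  colnames(rec) = cn;

  const bool clamp = R_finite(clamp_ed);
  if (clamp) s[S_VE] = clamp_ed;

  long irec = 0;
  int n_ca_clip = 0;
  double gate_min = 1.0, gate_max = 0.0;
  bool diverged = false;
  double div_t = NA_REAL;
  std::string div_var = "";

  for (long i = 0; i <= nsteps; ++i) {
    double t = t0 + i * dt;

    // --- exogenous transmitter ---
    double T_glu = stim_value(glu, t);
    double T_ach = stim_value(ach, t);
    double T_gab_ex = stim_value(gab, t);
    double ca_inj = stim_value(cin, t);

    // --- release functions ---
    double gaba_o = Tmax * logistic_safe((s[S_CAI] - Cap) / KCap);
    if (gabao_mode == 1) {
      double gv = Tmax * logistic_safe((s[S_VO] - Vp) / Kp);
      gaba_o = std::min(Tmax, gaba_o + gv);
    }
    double gaba_i = Tmax * logistic_safe((s[S_VI] - Vp) / Kp);
    double T_gab_e = ed_only ? T_gab_ex : gaba_i;

    // --- E_D currents ---
    double B = 1.0 / (1.0 + std::exp(-0.062 * s[S_VE]) * Mg / 3.57);
    double i_ampa = s[S_G] * s[S_RAE] * (s[S_VE] - EA);
    double i_nmda = gN * s[S_RNE] * B * (s[S_VE] - EN);
    double i_gabaE = gG_E * s[S_RGE] * (s[S_VE] - EG);

    // --- record ---
    if (i % krec == 0 && irec < nrec) {
      rec(irec, 0) = t;      rec(irec, 1) = s[S_VO];
      rec(irec, 2) = s[S_VI]; rec(irec, 3) = s[S_VE];
      rec(irec, 4) = s[S_CAI]; rec(irec, 5) = s[S_CAIS];
      rec(irec, 6) = s[S_CAD]; rec(irec, 7) = s[S_G];
      rec(irec, 8) = i_ampa;  rec(irec, 9) = i_nmda;
      rec(irec, 10) = i_gabaE; rec(irec, 11) = gaba_i;
      rec(irec, 12) = gaba_o;  rec(irec, 13) = s[S_RA7];
      ++irec;
    }
    if (i == nsteps) break;

    double ns[S_N];
    for (int k = 0; k < S_N; ++k) ns[k] = s[k];

    if (!ed_only) {
      // ---- O-cell ----
      ORates ro = ocell_rates_c(s[S_VO]);
      double i_a7 = ga7 * s[S_RA7] * (s[S_VO] - Ea7);
      double i_leak = o_gl * (s[S_VO] - o_El);
      double i_k = o_gK * std::pow(s[S_NO], 4) * (s[S_VO] - o_EK);
      double i_na = o_gNa * std::pow(s[S_MO], 3) * s[S_HO] * (s[S_VO] - o_ENa);
      double i_p = o_gp * s[S_PO] * (s[S_VO] - o_ENa);
      double i_h = o_gh * (0.65 * s[S_HFO] + 0.35 * s[S_HSO]) * (s[S_VO] - o_Eh);
      double dv = (-i_leak - i_k - i_na - i_p - i_h - i_a7 + o_Iapp) / o_C;
      ns[S_VO] = s[S_VO] + dt * dv;
      if (noise_on) ns[S_VO] += std::sqrt(dt) * sigma_o * R::norm_rand();
      ns[S_MO] = s[S_MO] + dt * (ro.am * (1 - s[S_MO]) - ro.bm * s[S_MO]);
      ns[S_HO] = s[S_HO] + dt * (ro.ah * (1 - s[S_HO]) - ro.bh * s[S_HO]);
      ns[S_NO] = s[S_NO] + dt * (ro.an * (1 - s[S_NO]) - ro.bn * s[S_NO]);
      ns[S_PO] = s[S_PO] + dt * (ro.ap * (1 - s[S_PO]) - ro.bp * s[S_PO]);
      ns[S_HFO] = s[S_HFO] + dt * (ro.hfi - s[S_HFO]) / ro.thf;
      ns[S_HSO] = s[S_HSO] + dt * (ro.hsi - s[S_HSO]) / ro.ths;
      // alpha7 nAChR activation (Hill steady state, first-order relaxation)
      double achn = (T_ach > 0) ? std::pow(T_ach, nhill) : 0.0;
      double ra7_inf = achn / (std::pow(ec50, nhill) + achn);
      ns[S_RA7] = s[S_RA7] + dt * (ra7_inf - s[S_RA7]) / tau_ra7;
      // CICR: cytosol / internal store exchange is antisymmetric
      double w = s[S_CAI] / (s[S_CAI] + kd);
      double w3 = w * w * w;
      double exch = w3 * (s[S_CAIS] - s[S_CAI]);
      ns[S_CAI] = s[S_CAI] + dt * (-xi_p * al_p * i_a7 + exch - s[S_CAI] / tau_cao);
      ns[S_CAIS] = s[S_CAIS] + dt * (-exch - (s[S_CAIS] - cais_rest) / tau_is);
      if (ns[S_CAI] < 0) { ns[S_CAI] = 0; ++n_ca_clip; }
      if (ns[S_CAIS] < 0) { ns[S_CAIS] = 0; ++n_ca_clip; }

      // ---- I-cell ----
      IRates ri = icell_rates_c(s[S_VI]);
      double ii_ampa = gA_I * s[S_RAI] * (s[S_VI] - EA);
      double ii_gaba = gG_I * s[S_RGI] * (s[S_VI] - EG);
      double ii_leak = i_gl * (s[S_VI] - i_El);
      double ii_k = i_gK * std::pow(s[S_NI], 4) * (s[S_VI] - i_EK);
      double ii_na = i_gNa * std::pow(s[S_MI], 3) * s[S_HI] * (s[S_VI] - i_ENa);
      double dvi = (-ii_leak - ii_k - ii_na - ii_ampa - ii_gaba) / i_C;
      ns[S_VI] = s[S_VI] + dt * dvi;
      if (noise_on) ns[S_VI] += std::sqrt(dt) * sigma_i * R::norm_rand();
      ns[S_MI] = s[S_MI] + dt * (ri.am * (1 - s[S_MI]) - ri.bm * s[S_MI]);
      ns[S_HI] = s[S_HI] + dt * (ri.ah * (1 - s[S_HI]) - ri.bh * s[S_HI]);
      ns[S_NI] = s[S_NI] + dt * (ri.an * (1 - s[S_NI]) - ri.bn * s[S_NI]);
      ns[S_RAI] = s[S_RAI] + dt * (aA * T_glu * (1 - s[S_RAI]) - bA * s[S_RAI]);
      ns[S_RGI] = s[S_RGI] + dt * (aG * gaba_o * (1 - s[S_RGI]) - bG * s[S_RGI]);
    }

    // ---- E_D ----
    if (!clamp) {
      double dve = (-e_gl * (s[S_VE] - e_El) - i_ampa - i_nmda - i_gabaE) / e_C;
      ns[S_VE] = s[S_VE] + dt * dve;
      if (noise_on) ns[S_VE] += std::sqrt(dt) * sigma_e * R::norm_rand();
    }
    ns[S_RAE] = s[S_RAE] + dt * (aA * T_glu * (1 - s[S_RAE]) - bA * s[S_RAE]);
    ns[S_RNE] = s[S_RNE] + dt * (aN * T_glu * (1 - s[S_RNE]) - bN * s[S_RNE]);
    ns[S_RGE] = s[S_RGE] + dt * (aG * T_gab_e * (1 - s[S_RGE]) - bG * s[S_RGE]);
    ns[S_CAD] = s[S_CAD] + dt * (-xi * al_ca * i_nmda - s[S_CAD] / tau_cad + ca_inj);
    if (ns[S_CAD] < 0) { ns[S_CAD] = 0; ++n_ca_clip; }
    // plasticity rule: learning rate multiplies both drift and decay
    double ca = s[S_CAD];
    double eta = 1.0 / (P1 / (P2 + std::pow(ca, P3)) + P4);
    double om = gam_up * logistic_safe(steep * (ca - th_up)) -
                gam_dn * logistic_safe(steep * (ca - th_dn));
    ns[S_G] = s[S_G] + dt * eta * (om - sigma_g * (s[S_G] - g0));
    if (ns[S_G] < 0) ns[S_G] = 0;

    for (int k = 0; k < S_N; ++k) s[k] = ns[k];

    // gate-bound bookkeeping (all dimensionless open fractions)
    static const int gates[] = { S_MO, S_HO, S_NO, S_PO, S_HFO, S_HSO, S_RA7,
                                 S_MI, S_HI, S_NI, S_RAI, S_RGI,
                                 S_RAE, S_RNE, S_RGE };
    for (int k = 0; k < 15; ++k) {
      double v = s[gates[k]];
      if (v < gate_min) gate_min = v;
      if (v > gate_max) gate_max = v;
    }

    // divergence guard
    static const int volts[] = { S_VO, S_VI, S_VE };
    static const char* vnames[] = { "v_o", "v_i", "v_e" };
    for (int k = 0; k < 3; ++k) {
      double v = s[volts[k]];
      if (!R_finite(v) || std::fabs(v) > 200.0) {
        diverged = true; div_t = t + dt; div_var = vnames[k];
      }
    }
    if (diverged) break;
  }

  if (irec < nrec) {
    NumericMatrix sub = rec(Range(0, std::max(0L, irec - 1)), _);
    rec = clone(sub);
    colnames(rec) = cn;
  }

  NumericVector fin(S_N);
  for (int k = 0; k < S_N; ++k) fin[k] = s[k];
  fin.names() = CharacterVector::create(
    "v_o", "m_o", "h_o", "n_o", "p_o", "hf_o", "hs_o", "r_a7", "ca_i", "ca_is",
    "v_i", "m_i", "h_i", "n_i", "r_ampa_i", "r_gaba_i",
    "v_e", "r_ampa_e", "r_nmda_e", "r_gaba_e", "ca_d", "g_ampa");

  return List::create(
    _["trace"] = rec, _["final"] = fin,
    _["diverged"] = diverged, _["diverged_time"] = div_t,
    _["diverged_var"] = div_var,
    _["gate_range"] = NumericVector::create(gate_min, gate_max),
    _["n_ca_clip"] = n_ca_clip);
}
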