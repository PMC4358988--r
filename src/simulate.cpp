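#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Reduced conductance-based model of a layer 5 pyramidal neuron:
// soma + passive basal dendrite + active apical dendrite.
//
// Soma: leak, fast Na+, delayed-rectifier K+ (Wang-Buzsaki-style rate
// functions), slow adaptation K+ (spike-frequency adaptation).
// Basal compartment: leak and the basal NMDA/AMPA synapses; keeping the
// synapses off the spiking compartment lets the local NMDA driving force
// saturate, as it does on real basal dendrites.
// Apical compartment: leak, low-threshold voltage-gated Ca2+ current, slow
// K+ current that terminates the Ca2+ spike (with a slowly decaying tail
// standing in for Ca2+-activated K+), h-current, tuft NMDA/AMPA synapses.
// Fixed axial conductances couple basal-soma and soma-apical.
//
// Units: mV, ms, pF, nS, pA (pA/pF = mV/ms).
//
// Numerics: gating variables advance by exponential Euler; the voltage
// update is linearly implicit with conductances frozen over the step, so
// the scheme is robust at the default dt = 0.025 ms. Synaptic conductance
// time courses are carried as per-compartment kernel states (NMDA rise and
// decay exponentials, AMPA single exponential) decayed exactly each step and
// incremented at event-onset steps; this is identical to summing per-event
// dual-exponential kernels.

static inline double vtrap(double x, double y) {
  // x/(1 - exp(-x/y)) with a stable limit at x -> 0
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / y / 2.0);
  return x / (1.0 - std::exp(-x / y));
}

// [[Rcpp::export]]
List simulate_core(double dt, int n_steps, NumericVector params,
                   NumericVector i_soma, NumericVector i_dend,
                   IntegerVector ev_s_step, NumericVector ev_s_g,
                   IntegerVector ev_d_step, NumericVector ev_d_g) {
  // parameter vector layout (see biophysics.R param_vector())
  const double c_soma = params[0], c_dend = params[1];
  const double gl_soma = params[2], gl_dend = params[3];
  const double el_soma = params[4], el_dend = params[5];
  const double g_na = params[6], g_kd = params[7];
  const double g_ca = params[8] * params[15];  // g_ca * ca_scale
  const double g_ks = params[9], g_h = params[10];
  const double g_c = params[11];
  const double e_na = params[12], e_k = params[13], e_h = params[14];
  // dendritic Ca2+/slow-K kinetic constants (part of the frozen fixture)
  const double e_ca = params[16];
  const double mca_mid = params[17], mca_slope = params[18];
  const double tau_mca = params[19];
  const double q_mid = params[20], q_slope = params[21];
  // slow K+ gate: fast activation terminates the Ca2+ spike, slow
  // deactivation leaves a refractory brake that outlasts it (stands in for
  // the Ca2+-activated K+ tail of the detailed model)
  const double tau_q_on = params[22], tau_q_off = params[23];
  // somatic spike-frequency adaptation (slow AHP): fast activation during
  // each action potential, slow decay between them
  const double g_adapt = params[24], z_mid = params[25];
  const double tau_z_on = params[26], tau_z_off = params[27];
  // passive basal compartment
  const double c_bas = params[28], gl_bas = params[29];
  const double el_bas = params[30], g_cb = params[31];
  // somatic M-type slow K+: subthreshold activation with a slow time
  // constant; counteracts slow depolarizing drive (e.g. NMDA envelopes)
  // without affecting brief pulses or fast bursts
  const double g_m = params[32], tau_m = params[33];
  const double e_syn = 0.0;

  if (n_steps < 1) stop("n_steps must be >= 1");
  if ((int)i_soma.size() < n_steps + 1 || (int)i_dend.size() < n_steps + 1)
    stop("injected-current vectors shorter than the simulation");

  NumericVector vs_out(n_steps + 1), vd_out(n_steps + 1),
      vb_out(n_steps + 1), z_out(n_steps + 1), q_out(n_steps + 1),
      mca_out(n_steps + 1);

  // initial condition: leak reversal, gates at steady state
  double vs = el_soma, vd = el_dend, vb = el_bas;

  // somatic gates (Wang-Buzsaki rate functions, phi = 5)
  const double phi = 5.0;
  double ah = 0.07 * std::exp(-(vs + 58.0) / 20.0);
  double bh = 1.0 / (1.0 + std::exp(-(vs + 18.0) / 10.0));
  double h = ah / (ah + bh);
  double an = 0.01 * vtrap(vs + 34.0, 10.0);
  double bn = 0.125 * std::exp(-(vs + 44.0) / 80.0);
  double n = an / (an + bn);

  // dendritic gates
  double mca = 1.0 / (1.0 + std::exp(-(vd - mca_mid) / mca_slope));
  double q = 1.0 / (1.0 + std::exp(-(vd - q_mid) / q_slope));
  double r = 1.0 / (1.0 + std::exp((vd + 82.0) / 7.0));
  double z = 0.0;  // adaptation builds only with spiking
  double w = 1.0 / (1.0 + std::exp(-(vs + 45.0) / 5.0));  // M-current gate

  // synaptic kernel states: NMDA slow/fast exponentials, AMPA exponential
  double sA_s = 0.0, sB_s = 0.0, amp_s = 0.0;  // soma/basal
  double sA_d = 0.0, sB_d = 0.0, amp_d = 0.0;  // dendrite/tuft
  const double dec_slow = std::exp(-dt / 70.0);
  const double dec_fast = std::exp(-dt / 3.0);
  const double dec_ampa = std::exp(-dt / 0.5);

  // event lists assumed sorted by step (R side sorts)
  int is = 0, id = 0;
  const int n_ev_s = ev_s_step.size(), n_ev_d = ev_d_step.size();

  vs_out[0] = vs;
  vd_out[0] = vd;
  vb_out[0] = vb;
  z_out[0] = z; q_out[0] = q; mca_out[0] = mca;

  const double tau_r = 50.0;
  const double f_mca = 1.0 - std::exp(-dt / tau_mca);
  const double f_q_on = 1.0 - std::exp(-dt / tau_q_on);
  const double f_q_off = 1.0 - std::exp(-dt / tau_q_off);
  const double f_z_on = 1.0 - std::exp(-dt / tau_z_on);
  const double f_z_off = 1.0 - std::exp(-dt / tau_z_off);
  const double f_w = 1.0 - std::exp(-dt / tau_m);
  const double f_r = 1.0 - std::exp(-dt / tau_r);

  for (int k = 0; k < n_steps; ++k) {
    // deposit synaptic events whose onset falls on this step
    while (is < n_ev_s && ev_s_step[is] == k) {
      sA_s += ev_s_g[is];
      sB_s += ev_s_g[is];
      amp_s += ev_s_g[is];
      ++is;
    }
    while (id < n_ev_d && ev_d_step[id] == k) {
      sA_d += ev_d_g[id];
      sB_d += ev_d_g[id];
      amp_d += ev_d_g[id];
      ++id;
    }

    // --- gating updates (exponential Euler at current voltages) ---
    double am = 0.1 * vtrap(vs + 35.0, 10.0);
    double bm = 4.0 * std::exp(-(vs + 60.0) / 18.0);
    double minf = am / (am + bm);  // activation treated as instantaneous

    ah = 0.07 * std::exp(-(vs + 58.0) / 20.0);
    bh = 1.0 / (1.0 + std::exp(-(vs + 18.0) / 10.0));
    double tau_h = 1.0 / (phi * (ah + bh));
    double hinf = ah / (ah + bh);
    h += (hinf - h) * (1.0 - std::exp(-dt / tau_h));

    an = 0.01 * vtrap(vs + 34.0, 10.0);
    bn = 0.125 * std::exp(-(vs + 44.0) / 80.0);
    double tau_n = 1.0 / (phi * (an + bn));
    double ninf = an / (an + bn);
    n += (ninf - n) * (1.0 - std::exp(-dt / tau_n));

    double mca_inf = 1.0 / (1.0 + std::exp(-(vd - mca_mid) / mca_slope));
    mca += (mca_inf - mca) * f_mca;
    double q_inf = 1.0 / (1.0 + std::exp(-(vd - q_mid) / q_slope));
    q += (q_inf - q) * (q_inf > q ? f_q_on : f_q_off);
    double r_inf = 1.0 / (1.0 + std::exp((vd + 82.0) / 7.0));
    r += (r_inf - r) * f_r;
    double z_inf = 1.0 / (1.0 + std::exp(-(vs - z_mid) / 4.0));
    z += (z_inf - z) * (z_inf > z ? f_z_on : f_z_off);
    double w_inf = 1.0 / (1.0 + std::exp(-(vs + 45.0) / 5.0));
    w += (w_inf - w) * f_w;

    // --- synaptic conductances at current step (voltage gate explicit) ---
    double nmda_gate_b = 1.0 / (1.0 + 0.3 * std::exp(-0.08 * vb));
    double nmda_gate_d = 1.0 / (1.0 + 0.3 * std::exp(-0.08 * vd));
    double g_syn_b = (sA_s - sB_s) * nmda_gate_b + amp_s;
    double g_syn_d = (sA_d - sB_d) * nmda_gate_d + amp_d;

    // --- linearly implicit voltage update ---
    double g_na_now = g_na * minf * minf * minf * h;
    double g_kd_now = g_kd * n * n * n * n;
    double g_ca_now = g_ca * mca * mca;
    double g_ks_now = g_ks * q;
    double g_h_now = g_h * r;
    double g_z_now = g_adapt * z + g_m * w;

    double Gs = gl_soma + g_na_now + g_kd_now + g_z_now + g_c + g_cb;
    double Es = gl_soma * el_soma + g_na_now * e_na + g_kd_now * e_k +
                g_z_now * e_k + g_c * vd + g_cb * vb + i_soma[k];
    double Gd = gl_dend + g_ca_now + g_ks_now + g_h_now + g_syn_d + g_c;
    double Ed = gl_dend * el_dend + g_ca_now * e_ca + g_ks_now * e_k +
                g_h_now * e_h + g_syn_d * e_syn + g_c * vs + i_dend[k];
    double Gb = gl_bas + g_syn_b + g_cb;
    double Eb = gl_bas * el_bas + g_syn_b * e_syn + g_cb * vs;

    double vs_new = (vs + dt / c_soma * Es) / (1.0 + dt / c_soma * Gs);
    double vd_new = (vd + dt / c_dend * Ed) / (1.0 + dt / c_dend * Gd);
    double vb_new = (vb + dt / c_bas * Eb) / (1.0 + dt / c_bas * Gb);
    vs = vs_new;
    vd = vd_new;
    vb = vb_new;

    if (!std::isfinite(vs) || !std::isfinite(vd) || !std::isfinite(vb))
      stop("non-finite membrane potential at t = %f ms", (k + 1) * dt);

    // decay synaptic kernel states to the end of the step
    sA_s *= dec_slow; sB_s *= dec_fast; amp_s *= dec_ampa;
    sA_d *= dec_slow; sB_d *= dec_fast; amp_d *= dec_ampa;

    vs_out[k + 1] = vs;
    vd_out[k + 1] = vd;
    vb_out[k + 1] = vb;
    z_out[k + 1] = z; q_out[k + 1] = q; mca_out[k + 1] = mca;
  }

  return List::create(_["v_soma"] = vs_out, _["v_dend"] = vd_out,
                      _["v_basal"] = vb_out, _["z"] = z_out,
                      _["q"] = q_out, _["mca"] = mca_out);
}
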