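#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Mass indices: 0 PYR1, 1 PYR2, 2 PV, 3 SSTa, 4 SSTb, 5 VIP, 6 NGFC,
//               7 TC, 8 RtN1, 9 RtN2.

static inline double sigm(double v, double e0, double v0, double r) {
  return 2.0 * e0 / (1.0 + std::exp(r * (v0 - v)));
}

struct Couplings {
  double p2p1, p1p2, pg, pba, pbb, pv;
  double gp, bap, bbp, np;
  double vba, vbb, bv, bag, nv, gg;
  double tp, tg, tba, tbb, tn;
  double pt, pr1, pr2;
  double tt, tr1, tr2, gt, bt, ton;
};

static Couplings read_couplings(List cp) {
  Couplings c;
  c.p2p1 = as<double>(cp["PYR2_PYR1"]); c.p1p2 = as<double>(cp["PYR1_PYR2"]);
  c.pg = as<double>(cp["PYR1_PV"]);     c.pba = as<double>(cp["PYR1_SSTa"]);
  c.pbb = as<double>(cp["PYR1_SSTb"]);  c.pv = as<double>(cp["PYR1_VIP"]);
  c.gp = as<double>(cp["PV_PYR1"]);     c.bap = as<double>(cp["SSTa_PYR1"]);
  c.bbp = as<double>(cp["SSTb_PYR1"]);  c.np = as<double>(cp["NGFC_PYR1"]);
  c.vba = as<double>(cp["VIP_SSTa"]);   c.vbb = as<double>(cp["VIP_SSTb"]);
  c.bv = as<double>(cp["SSTa_VIP"]);    c.bag = as<double>(cp["SSTa_PV"]);
  c.nv = as<double>(cp["NGFC_VIP"]);    c.gg = as<double>(cp["PV_PV"]);
  c.tp = as<double>(cp["TC_PYR1"]);     c.tg = as<double>(cp["TC_PV"]);
  c.tba = as<double>(cp["TC_SSTa"]);    c.tbb = as<double>(cp["TC_SSTb"]);
  c.tn = as<double>(cp["TC_NGFC"]);     c.pt = as<double>(cp["PYR1_TC"]);
  c.pr1 = as<double>(cp["PYR1_RtN1"]);  c.pr2 = as<double>(cp["PYR1_RtN2"]);
  c.tt = as<double>(cp["TC_TC"]);       c.tr1 = as<double>(cp["TC_RtN1"]);
  c.tr2 = as<double>(cp["TC_RtN2"]);    c.gt = as<double>(cp["RtN1_TC"]);
  c.bt = as<double>(cp["RtN2_TC"]);     c.ton = as<double>(cp["tonic_TC"]);
  return c;
}

// total synaptic inputs of the seven neocortical masses, given their output
// PSPs y[0..6], the (delayed) thalamic relay PSP `drive`, and the plastic
// scaling kappa * gA on the TC->PYR branch. Shared by the stochastic
// simulator and the noise-free bifurcation field.
static inline void ncx_inputs(const double *y, double drive, double kgA,
                              const Couplings &c, double *v) {
  v[0] = c.p2p1 * y[1] - c.gp * y[2] - c.bap * y[3] - c.bbp * y[4]
       - c.np * y[6] + kgA * c.tp * drive;
  v[1] = c.p1p2 * y[0];
  v[2] = c.pg * y[0] - c.bag * y[3] - c.gg * y[2] + c.tg * drive;
  v[3] = c.pba * y[0] - c.vba * y[5] + c.tba * drive;
  v[4] = c.pbb * y[0] - c.vbb * y[5] + c.tbb * drive;
  v[5] = c.pv * y[0] - c.bv * y[3] - c.nv * y[6];
  v[6] = c.tn * drive;
}

// [[Rcpp::export]]
List simulate_core_cpp(List pars, NumericVector stim_wave,
                       IntegerVector stim_on, NumericMatrix noise,
                       List control) {
  NumericVector Wv = pars["W"], wv = pars["w"];
  NumericVector e0v = pars["e0"], v0v = pars["v0"], rv = pars["r"];
  Couplings c = read_couplings(pars["couplings"]);

  List stp = pars["stp"];
  List sA = stp["ACd"], sG = stp["GTh"], sB = stp["BTh"];
  const bool enA = as<bool>(sA["enabled"]), enG = as<bool>(sG["enabled"]),
             enB = as<bool>(sB["enabled"]);
  double ueA = as<double>(sA["ue"]), tfA = as<double>(sA["tau_f"]),
         tdA = as<double>(sA["tau_d"]);
  double ueG = as<double>(sG["ue"]), tfG = as<double>(sG["tau_f"]),
         tdG = as<double>(sG["tau_d"]);
  double ueB = as<double>(sB["ue"]), tfB = as<double>(sB["tau_f"]),
         tdB = as<double>(sB["tau_d"]);
  // lower clip bounds for u: the pre-engagement baselines. After the GABA-B
  // gate multiplies ue, u is transiently below the new baseline — that
  // transient IS the release-probability collapse, so it must not be clipped.
  const double ueA0 = ueA, ueG0 = ueG, ueB0 = ueB;

  List ton = pars["tonic"];
  const double ET = as<double>(ton["ET"]), eT = as<double>(ton["eT"]);
  double tauIE = as<double>(ton["tau_IE"]);
  const double c1 = as<double>(ton["c1"]), c2 = as<double>(ton["c2"]);

  List gate = pars["gate"];
  const bool gate_enabled = as<bool>(gate["enabled"]);
  const double gate_thr = as<double>(gate["threshold"]);
  const double ue_mult = as<double>(gate["ue_multiplier"]);
  const double tau_red = as<double>(gate["tau_reduction"]);

  List lfp = pars["lfp"];
  const double wa = as<double>(lfp["apical_weight"]);
  const double wb = as<double>(lfp["basal_weight"]);

  List stimc = pars["stim_coupling"];
  const double lamTC = as<double>(stimc["TC"]);
  const double lamR1 = as<double>(stimc["RtN1"]);
  const double lamR2 = as<double>(stimc["RtN2"]);

  NumericVector nmean = pars["noise_mean"], nsd = pars["noise_sd"]; // PYR1, PYR2, TC

  const double dt = as<double>(control["dt"]);
  const int n_total = as<int>(control["n_total"]);
  const int warm = as<int>(control["warm_steps"]);
  const int stride = as<int>(control["stride"]);
  int d_ct = as<int>(control["delay_ct_steps"]); // PYR1 -> thalamus
  int d_tc = as<int>(control["delay_tc_steps"]); // TC -> neocortex
  const double kappa = as<double>(control["kappa"]);
  const bool clamp = as<bool>(control["clamp_drive"]);
  const double clampv = as<double>(control["clamp_value"]);
  if (d_ct < 1) d_ct = 1;
  if (d_tc < 1) d_tc = 1;
  const double sq = std::sqrt(dt);

  if (noise.nrow() < n_total) stop("noise matrix shorter than the run");
  if (stim_wave.size() < n_total || stim_on.size() < n_total)
    stop("stimulation vectors shorter than the run");

  double W[10], w[10];
  for (int i = 0; i < 10; ++i) { W[i] = Wv[i]; w[i] = wv[i]; }

  double y[10] = {0}, z[10] = {0};
  double uA = ueA, kA = 1, uG = ueG, kG = 1, uB = ueB, kB = 1;
  double y26 = 0, y11 = 0, y24 = 0;
  bool engaged = false;
  double engage_time = NA_REAL;

  std::vector<double> buf0(d_ct, 0.0), buf7(d_tc, 0.0);
  int h0 = 0, h7 = 0;

  const int n_rec = (n_total - warm + stride - 1) / stride;
  NumericMatrix out(n_rec, 28);
  int irec = 0;

  double v[10], fr[10];
  for (int stp_i = 0; stp_i < n_total; ++stp_i) {
    const double s = stim_wave[stp_i];
    const int g = stim_on[stp_i];

    const double y0d = buf0[h0];            // delayed PYR1 PSP
    double y7d = buf7[h7];                  // delayed TC PSP
    if (clamp) y7d = clampv;

    const double gA = enA ? (uA / ueA) * kA : 1.0;
    const double gG = enG ? (uG / ueG) * kG : 1.0;
    const double gB = enB ? (uB / ueB) * kB : 1.0;

    ncx_inputs(y, y7d, kappa * gA, c, v);
    v[7] = c.tt * y[7] + c.pt * y0d - gG * c.gt * y[8] - gB * c.bt * y[9]
         - c.ton * y11 + lamTC * s;
    v[8] = c.tr1 * y[7] + c.pr1 * y0d + lamR1 * s;
    v[9] = c.tr2 * y[7] + c.pr2 * y0d + lamR2 * s;

    for (int i = 0; i < 10; ++i) fr[i] = sigm(v[i], e0v[i], v0v[i], rv[i]);

    // record before the state update so outputs align with time warm*dt + n*stride*dt
    if (stp_i >= warm && ((stp_i - warm) % stride) == 0 && irec < n_rec) {
      // field proxy built from the intracortical synaptic currents on the
      // pyramidal population; the extrinsic thalamocortical EPSP is excluded
      // so the proxy reflects local sink/source structure
      const double apical = -c.bap * y[3] - c.np * y[6];
      const double basal  = -c.gp * y[2] - c.bbp * y[4];
      out(irec, 20) = wa * apical - wb * basal;
      out(irec, 21) = v[7] - lamTC * s; // thalamic field proxy
      for (int i = 0; i < 10; ++i) { out(irec, i) = y[i]; out(irec, 10 + i) = fr[i]; }
      out(irec, 22) = gA; out(irec, 23) = gG; out(irec, 24) = gB;
      out(irec, 25) = y26; out(irec, 26) = y11; out(irec, 27) = s;
      ++irec;
    }

    // rate inputs to the filters; white noise on the excitatory masses
    double rate[10];
    for (int i = 0; i < 10; ++i) rate[i] = fr[i];
    rate[0] += nmean[0] + nsd[0] * noise(stp_i, 0) / sq;
    rate[1] += nmean[1] + nsd[1] * noise(stp_i, 1) / sq;
    rate[7] += nmean[2] + nsd[2] * noise(stp_i, 2) / sq;

    // Euler-Maruyama update of the PSP pairs
    for (int i = 0; i < 10; ++i) {
      const double zn = z[i] + dt * (W[i] * w[i] * rate[i]
                                     - 2.0 * w[i] * z[i] - w[i] * w[i] * y[i]);
      y[i] += dt * z[i];
      z[i] = zn;
    }

    // short-term plasticity (driven by the presynaptic sigmoid rates)
    if (enA) {
      const double du = (ueA - uA) / tfA + (1 - uA) * ueA * fr[7] * g;
      const double dk = (1 - kA) / tdA - uA * kA * fr[7] * g;
      uA += dt * du; kA += dt * dk;
    }
    if (enG) {
      const double du = (ueG - uG) / tfG + (1 - uG) * ueG * fr[8] * g;
      const double dk = (1 - kG) / tdG - uG * kG * fr[8] * g;
      uG += dt * du; kG += dt * dk;
    }
    if (enB) {
      const double du = (ueB - uB) / tfB + (1 - uB) * ueB * fr[9] * g;
      const double dk = (1 - kB) / tdB - uB * kB * fr[9] * g;
      uB += dt * du; kB += dt * dk;
    }
    if (uA < ueA0) uA = ueA0; if (uA > 1) uA = 1;
    if (uG < ueG0) uG = ueG0; if (uG > 1) uG = 1;
    if (uB < ueB0) uB = ueB0; if (uB > 1) uB = 1;
    if (kA < 0) kA = 0; if (kA > 1) kA = 1;
    if (kG < 0) kG = 0; if (kG > 1) kG = 1;
    if (kB < 0) kB = 0; if (kB > 1) kB = 1;

    // extrasynaptic GABA accumulation and tonic IPSP
    const double phi = c1 * (enG ? (uG / ueG) * kG : 1.0) * fr[8]
                     + c2 * (enB ? (uB / ueB) * kB : 1.0) * fr[9];
    const double y26n = y26 + dt * (-y26 / tauIE + (g ? phi : 0.0));
    const double y24n = y24 + dt * (ET * eT * y26 - 2 * eT * y24 - eT * eT * y11);
    y11 += dt * y24;
    y24 = y24n;
    y26 = y26n < 0 ? 0 : y26n;

    // presynaptic GABA-B gate (latches)
    if (gate_enabled && !engaged && g && y26 > gate_thr) {
      engaged = true;
      engage_time = (stp_i - warm) * dt;
      ueG = std::min(1.0, ueG * ue_mult);
      ueB = std::min(1.0, ueB * ue_mult);
      tauIE /= tau_red;
    }

    // push delay buffers
    buf0[h0] = y[0]; h0 = (h0 + 1) % d_ct;
    buf7[h7] = y[7]; h7 = (h7 + 1) % d_tc;

    if (!std::isfinite(y[0]) || !std::isfinite(y[7]) || !std::isfinite(y26)) {
      stop("non-finite state at t = %g s (step %d)", (stp_i - warm) * dt, stp_i);
    }
  }

  return List::create(_["traces"] = out, _["engaged"] = engaged,
                      _["engage_time"] = engage_time, _["n_rec"] = irec);
}

// Noise-free neocortical subsystem field for the bifurcation analysis:
// state (y0..y6, z0..z6), thalamic drive held constant, kappa scaling the
// TC->PYR branch.
// [[Rcpp::export]]
NumericVector ncx_field_cpp(NumericVector state, List pars, double drive,
                            double kappa) {
  NumericVector Wv = pars["W"], wv = pars["w"];
  NumericVector e0v = pars["e0"], v0v = pars["v0"], rv = pars["r"];
  Couplings c = read_couplings(pars["couplings"]);
  NumericVector nmean = pars["noise_mean"];
  double y[7], z[7], v[7];
  for (int i = 0; i < 7; ++i) { y[i] = state[i]; z[i] = state[7 + i]; }
  ncx_inputs(y, drive, kappa, c, v);
  NumericVector d(14);
  for (int i = 0; i < 7; ++i) {
    double rate = sigm(v[i], e0v[i], v0v[i], rv[i]);
    if (i == 0) rate += nmean[0];
    if (i == 1) rate += nmean[1];
    d[i] = z[i];
    d[7 + i] = Wv[i] * wv[i] * rate - 2.0 * wv[i] * z[i] - wv[i] * wv[i] * y[i];
  }
  return d;
}

// Classic dynamic-time-warping cost (symmetric step pattern, moves
// (1,0),(0,1),(1,1), local cost |a_i - b_j|) inside a Sakoe-Chiba band.
// [[Rcpp::export]]
double dtw_cost_cpp(NumericVector a, NumericVector b, int window) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty series");
  int wband = std::max(window, std::abs(n - m));
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> prev(m + 1, INF), cur(m + 1, INF);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    const int j0 = std::max(1, i - wband), j1 = std::min(m, i + wband);
    for (int j = j0; j <= j1; ++j) {
      const double cost = std::fabs(a[i - 1] - b[j - 1]);
      double best = prev[j - 1];
      if (prev[j] < best) best = prev[j];
      if (cur[j - 1] < best) best = cur[j - 1];
      cur[j] = cost + best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
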