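// Implicit (backward Euler) cable integrator for the reduced granule-cell
// model.  The tree topology is solved exactly per step with a Hines
// elimination (parent index < child index).  Units: mV, ms, nA, nF, uS.
//
// Transmembrane current of compartment i is evaluated as net axial inflow
// plus injected current, so that sum_i I_m(i) equals the injected current to
// machine precision at every step (Kirchhoff closure).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

inline double vtrap(double x, double y) {
  // x / (1 - exp(-x/y)) with the removable singularity at x = 0
  if (std::fabs(x / y) < 1e-6) return y * (1.0 + x / (2.0 * y));
  return x / (1.0 - std::exp(-x / y));
}

struct Kinetics {
  double vt;     // traub-style threshold shift
  double q;      // global rate scale (temperature-like)
  double con;    // closed-state inactivation rate scale (C_on)
  double oon;    // open-state inactivation rate scale (O_on)
  double koon;   // open-state inactivation weight
  double bh_mid; // inactivation-onset sigmoid midpoint, mV above vt
  double bh_rate;// inactivation-onset base rate, 1/ms
  double ah_rate;// inactivation recovery base rate, 1/ms

  inline double am(double v) const { return q * 0.32 * vtrap(v - vt - 13.0, 4.0); }
  inline double bm(double v) const { return q * 0.28 * vtrap(-(v - vt - 40.0), 5.0); }
  inline double ah(double v) const { return q * ah_rate * std::exp(-(v - vt - 17.0) / 18.0); }
  inline double bh(double v, double po) const {
    double base = q * bh_rate / (1.0 + std::exp(-(v - vt - bh_mid) / 5.0));
    return base * (con * (1.0 - koon * po) + oon * koon * po);
  }
  inline double an(double v) const { return q * 0.032 * vtrap(v - vt - 15.0, 5.0); }
  inline double bn(double v) const { return q * 0.5 * std::exp(-(v - vt - 10.0) / 40.0); }
  inline double mpinf(double v) const { return 1.0 / (1.0 + std::exp(-(v + 48.0) / 5.0)); }
};

inline double dexp_norm(double tr, double td) {
  // peak value of exp(-t/td) - exp(-t/tr), used to normalise event amplitude
  double tp = tr * td / (td - tr) * std::log(td / tr);
  return std::exp(-tp / td) - std::exp(-tp / tr);
}

} // namespace

// [[Rcpp::export]]
List gc_integrate_cpp(List morph, List chan, List syn, List events,
                      double dt, int nsteps, double v_init,
                      double stim_amp, double stim_t0, double stim_t1,
                      int stim_comp,
                      NumericMatrix lsa_coef,
                      bool return_currents, bool return_voltages,
                      double settle_ms, double settle_dt) {
  IntegerVector parent = morph["parent"];     // 0-based, -1 for root
  NumericVector gax    = morph["gax"];        // uS to parent
  NumericVector cap    = morph["cap"];        // nF
  const int n = parent.size();

  NumericVector gna  = chan["gna"];           // uS, per compartment
  NumericVector gnap = chan["gnap"];
  NumericVector gkdr = chan["gkdr"];
  NumericVector gl   = chan["gl"];
  const double ena = chan["ena"], ek = chan["ek"], el = chan["el"];
  const double taup = chan["taup"];

  Kinetics kin;
  kin.vt  = chan["vt"];
  kin.q   = chan["q"];
  kin.con = chan["con_scale"];
  kin.oon = chan["oon_scale"];
  kin.koon = chan["koon"];
  kin.bh_mid = chan["bh_mid"];
  kin.bh_rate = chan["bh_rate"];
  kin.ah_rate = chan["ah_rate"];

  // synapse kinetic parameters (conductances in uS per unit event weight)
  const double ag = syn["ampa_g"], atr = syn["ampa_tr"], atd = syn["ampa_td"];
  const double ng = syn["nmda_g"], ntr = syn["nmda_tr"], ntd = syn["nmda_td"];
  const double gg = syn["gaba_g"], gtr = syn["gaba_tr"], gtd = syn["gaba_td"];
  const double e_exc = syn["e_exc"], e_inh = syn["e_inh"];
  const double mg = syn["mg"];                 // mM, NMDA block
  const double anorm = dexp_norm(atr, atd);
  const double nnorm = dexp_norm(ntr, ntd);
  const double gnorm = dexp_norm(gtr, gtd);
  const double dec_ar = std::exp(-dt / atr), dec_ad = std::exp(-dt / atd);
  const double dec_nr = std::exp(-dt / ntr), dec_nd = std::exp(-dt / ntd);
  const double dec_gr = std::exp(-dt / gtr), dec_gd = std::exp(-dt / gtd);

  IntegerVector ec = events["exc_comp"];      // 0-based compartment indices
  NumericVector et = events["exc_t"];
  NumericVector ew = events["exc_w"];
  IntegerVector ic = events["inh_comp"];
  NumericVector it = events["inh_t"];
  NumericVector iw = events["inh_w"];

  const int nview = lsa_coef.ncol();

  // state
  std::vector<double> V(n, v_init), m(n), h(n), ng_(n), mp(n);
  for (int i = 0; i < n; ++i) {
    double amv = kin.am(v_init), bmv = kin.bm(v_init);
    m[i] = amv / (amv + bmv);
    double po = m[i] * m[i] * m[i];
    double ahv = kin.ah(v_init), bhv = kin.bh(v_init, po);
    h[i] = ahv / (ahv + bhv);
    double anv = kin.an(v_init), bnv = kin.bn(v_init);
    ng_[i] = anv / (anv + bnv);
    mp[i] = kin.mpinf(v_init);
  }
  std::vector<double> Aa(n, 0), Ba(n, 0), An(n, 0), Bn(n, 0), Ag(n, 0), Bg(n, 0);

  std::vector<double> d(n), rhs(n), G(n), B(n), Im(n);

  NumericVector vsoma(nsteps);
  NumericMatrix phi(nview > 0 ? nsteps : 0, nview);
  NumericMatrix imat(return_currents ? nsteps : 0, return_currents ? n : 0);
  NumericMatrix vmat(return_voltages ? nsteps : 0, return_voltages ? n : 0);
  std::vector<double> spikes;
  bool above = V[0] > 0.0;

  // event cursors (assume sorted by time on the R side)
  int pe = 0, pi = 0;
  const int ne = ec.size(), ni = ic.size();

  // settle to the resting state at a coarse step before recording starts
  // (backward Euler is unconditionally stable, so the large step is safe)
  if (settle_ms > 0.0) {
    const int ns = (int)(settle_ms / settle_dt);
    for (int s = 0; s < ns; ++s) {
      for (int i = 0; i < n; ++i) {
        const double v = V[i];
        if (gna[i] > 0.0 || gkdr[i] > 0.0) {
          const double amv = kin.am(v), bmv = kin.bm(v);
          const double po = m[i] * m[i] * m[i];
          const double ahv = kin.ah(v), bhv = kin.bh(v, po);
          const double anv = kin.an(v), bnv = kin.bn(v);
          double asum = amv + bmv;
          m[i] += (amv / asum - m[i]) * (1.0 - std::exp(-settle_dt * asum));
          asum = ahv + bhv;
          h[i] += (ahv / asum - h[i]) * (1.0 - std::exp(-settle_dt * asum));
          asum = anv + bnv;
          ng_[i] += (anv / asum - ng_[i]) * (1.0 - std::exp(-settle_dt * asum));
        }
        if (gnap[i] > 0.0)
          mp[i] += (kin.mpinf(v) - mp[i]) * (1.0 - std::exp(-settle_dt / taup));
      }
      for (int i = 0; i < n; ++i) {
        const double m3h = m[i] * m[i] * m[i] * h[i];
        const double n4 = ng_[i] * ng_[i] * ng_[i] * ng_[i];
        const double g = gl[i] + gna[i] * m3h + gnap[i] * mp[i] + gkdr[i] * n4;
        const double b = gl[i] * el + (gna[i] * m3h + gnap[i] * mp[i]) * ena +
                         gkdr[i] * n4 * ek;
        d[i] = cap[i] / settle_dt + g + gax[i];
        rhs[i] = cap[i] / settle_dt * V[i] + b;
      }
      for (int i = 1; i < n; ++i) d[parent[i]] += gax[i];
      for (int i = n - 1; i >= 1; --i) {
        const double f = gax[i] / d[i];
        d[parent[i]] -= f * gax[i];
        rhs[parent[i]] += f * rhs[i];
      }
      V[0] = rhs[0] / d[0];
      for (int i = 1; i < n; ++i) V[i] = (rhs[i] + gax[i] * V[parent[i]]) / d[i];
    }
  }
  above = V[0] > 0.0;

  for (int s = 0; s < nsteps; ++s) {
    const double t = s * dt;

    // synaptic state decay + event injection
    for (int i = 0; i < n; ++i) {
      Aa[i] *= dec_ar; Ba[i] *= dec_ad;
      An[i] *= dec_nr; Bn[i] *= dec_nd;
      Ag[i] *= dec_gr; Bg[i] *= dec_gd;
    }
    while (pe < ne && et[pe] <= t) {
      Aa[ec[pe]] += ew[pe]; Ba[ec[pe]] += ew[pe];
      An[ec[pe]] += ew[pe]; Bn[ec[pe]] += ew[pe];
      ++pe;
    }
    while (pi < ni && it[pi] <= t) {
      Ag[ic[pi]] += iw[pi]; Bg[ic[pi]] += iw[pi];
      ++pi;
    }

    // gates (Rush-Larsen on previous-step voltage)
    for (int i = 0; i < n; ++i) {
      const double v = V[i];
      if (gna[i] > 0.0 || gkdr[i] > 0.0) {
        const double amv = kin.am(v), bmv = kin.bm(v);
        const double po = m[i] * m[i] * m[i];
        const double ahv = kin.ah(v), bhv = kin.bh(v, po);
        const double anv = kin.an(v), bnv = kin.bn(v);
        double asum = amv + bmv;
        m[i] += (amv / asum - m[i]) * (1.0 - std::exp(-dt * asum));
        asum = ahv + bhv;
        h[i] += (ahv / asum - h[i]) * (1.0 - std::exp(-dt * asum));
        asum = anv + bnv;
        ng_[i] += (anv / asum - ng_[i]) * (1.0 - std::exp(-dt * asum));
      }
      if (gnap[i] > 0.0)
        mp[i] += (kin.mpinf(v) - mp[i]) * (1.0 - std::exp(-dt / taup));
    }

    const bool stim_on = (stim_amp != 0.0 && t >= stim_t0 && t < stim_t1);

    // assemble conductances and rhs
    for (int i = 0; i < n; ++i) {
      const double m3h = m[i] * m[i] * m[i] * h[i];
      const double n4 = ng_[i] * ng_[i] * ng_[i] * ng_[i];
      double g = gl[i] + gna[i] * m3h + gnap[i] * mp[i] + gkdr[i] * n4;
      double b = gl[i] * el + (gna[i] * m3h + gnap[i] * mp[i]) * ena +
                 gkdr[i] * n4 * ek;
      const double ga = ag * (Ba[i] - Aa[i]) / anorm;
      if (ga != 0.0) { g += ga; b += ga * e_exc; }
      double gn = ng * (Bn[i] - An[i]) / nnorm;
      if (gn != 0.0) {
        // magnesium block evaluated at the previous-step voltage
        gn /= (1.0 + mg / 3.57 * std::exp(-0.062 * V[i]));
        g += gn; b += gn * e_exc;
      }
      const double gb = gg * (Bg[i] - Ag[i]) / gnorm;
      if (gb != 0.0) { g += gb; b += gb * e_inh; }
      G[i] = g;
      B[i] = b;
      d[i] = cap[i] / dt + g + gax[i];
      rhs[i] = cap[i] / dt * V[i] + b;
      if (stim_on && i == stim_comp) rhs[i] += stim_amp;
    }
    for (int i = 1; i < n; ++i) d[parent[i]] += gax[i];

    // Hines elimination (children have larger indices than parents)
    for (int i = n - 1; i >= 1; --i) {
      const double f = gax[i] / d[i];
      d[parent[i]] -= f * gax[i];
      rhs[parent[i]] += f * rhs[i];
    }
    V[0] = rhs[0] / d[0];
    for (int i = 1; i < n; ++i) V[i] = (rhs[i] + gax[i] * V[parent[i]]) / d[i];

    if (!std::isfinite(V[0]) || std::fabs(V[0]) > 200.0)
      stop("integration diverged at step %d (t = %.3f ms, V_soma = %.1f mV)",
           s, t, V[0]);

    // transmembrane currents via axial balance (exact Kirchhoff closure)
    for (int i = 0; i < n; ++i)
      Im[i] = (stim_on && i == stim_comp) ? stim_amp : 0.0;
    for (int i = 1; i < n; ++i) {
      const double a = gax[i] * (V[parent[i]] - V[i]);
      Im[i] += a;
      Im[parent[i]] -= a;
    }

    for (int k = 0; k < nview; ++k) {
      double acc = 0.0;
      for (int i = 0; i < n; ++i) acc += lsa_coef(i, k) * Im[i];
      phi(s, k) = acc;
    }
    if (return_currents)
      for (int i = 0; i < n; ++i) imat(s, i) = Im[i];
    if (return_voltages)
      for (int i = 0; i < n; ++i) vmat(s, i) = V[i];

    vsoma[s] = V[0];
    if (!above && V[0] > 0.0) spikes.push_back(t);
    above = V[0] > 0.0;
  }

  return List::create(_["v_soma"] = vsoma,
                      _["spikes"] = NumericVector(spikes.begin(), spikes.end()),
                      _["phi"] = phi,
                      _["im"] = imat,
                      _["v"] = vmat);
}
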