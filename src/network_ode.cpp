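#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Compiled-network right-hand side.
//
// State vector x holds the dynamic nodes only; clamped inputs come in u.
// Regulatory nodes follow relaxation dynamics dx/dt = tau * (B - x) where B
// combines incoming edges: activating/inhibiting gates OR-combined as
// 1 - prod(1 - g), knockdown gates multiplying the result (AND-NOT).
// Each gate is the product over its sources of the normalized Hill transfer
// f(x) = x^n (1 + k^n) / (x^n + k^n) (activating) or 1 - f (inhibiting).
// Metabolic nodes follow explicit rate laws: zero-order sources, mass-action
// and product-uptake fluxes rate * prod(level^exponent), and Michaelis-Menten
// flux with competitive inhibition rate * E * S / (Km * (1 + I/Ki) + S); each
// flux feeds its target and depletes its consumed reactants, all scaled by
// the node time constant tau.

struct CompNet {
  int nd, ni;
  IntegerVector is_met, tau_idx, clamp01, src_rate;
  NumericVector src_scale;
  IntegerVector he_node, he_kd, he_tptr;
  IntegerVector ht_src, ht_sign, ht_k, ht_n;
  IntegerVector fl_type, fl_rate, fl_km, fl_ki, fl_sub, fl_has_inh, fl_inh;
  IntegerVector fl_fptr, ff_src, fl_optr, fo_node;
  NumericVector ff_exp, fo_coef;
  // workspace (sized once per simulation) and per-parameter-set caches
  mutable std::vector<double> orprod, kdprod, acc, ht_kn, ht_nv;
  mutable std::vector<int> has_or;

  void prepare(const double* pars) const {
    orprod.assign(nd, 1.0);
    kdprod.assign(nd, 1.0);
    acc.assign(nd, 0.0);
    has_or.assign(nd, 0);
    int nt = ht_src.size();
    ht_kn.resize(nt);
    ht_nv.resize(nt);
    for (int t = 0; t < nt; ++t) {
      ht_nv[t] = pars[ht_n[t]];
      ht_kn[t] = std::pow(pars[ht_k[t]], ht_nv[t]);
    }
  }

  explicit CompNet(const List& comp)
      : nd(as<int>(comp["nd"])), ni(as<int>(comp["ni"])),
        is_met(comp["is_met"]), tau_idx(comp["tau_idx"]),
        clamp01(comp["clamp01"]), src_rate(comp["src_rate"]),
        src_scale(comp["src_scale"]), he_node(comp["he_node"]),
        he_kd(comp["he_kd"]), he_tptr(comp["he_tptr"]), ht_src(comp["ht_src"]),
        ht_sign(comp["ht_sign"]), ht_k(comp["ht_k"]), ht_n(comp["ht_n"]),
        fl_type(comp["fl_type"]), fl_rate(comp["fl_rate"]),
        fl_km(comp["fl_km"]), fl_ki(comp["fl_ki"]), fl_sub(comp["fl_sub"]),
        fl_has_inh(comp["fl_has_inh"]), fl_inh(comp["fl_inh"]),
        fl_fptr(comp["fl_fptr"]), ff_src(comp["ff_src"]),
        fl_optr(comp["fl_optr"]), fo_node(comp["fo_node"]),
        ff_exp(comp["ff_exp"]), fo_coef(comp["fo_coef"]) {}
};

static inline double level_of(const double* x, const double* u, int ref) {
  return ref >= 0 ? x[ref] : u[-ref - 1];
}

static inline double clamp01d(double v) {
  return v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
}

static inline double hill_f_kn(double x, double kn, double n) {
  if (x <= 0.0) return 0.0;
  double xn = std::pow(x, n);
  return xn * (1.0 + kn) / (xn + kn);
}

// Caller must have invoked net.prepare(pars) for the current parameter set.
static void rhs(const CompNet& net, const double* pars, const double* u,
                const double* x, double* dx) {
  int nd = net.nd;
  double* orprod = net.orprod.data();
  double* kdprod = net.kdprod.data();
  double* acc = net.acc.data();
  int* has_or = net.has_or.data();
  for (int i = 0; i < nd; ++i) {
    orprod[i] = 1.0;
    kdprod[i] = 1.0;
    acc[i] = 0.0;
    has_or[i] = 0;
  }

  int nE = net.he_node.size();
  for (int e = 0; e < nE; ++e) {
    double g = 1.0;
    for (int t = net.he_tptr[e]; t < net.he_tptr[e + 1]; ++t) {
      double lv = clamp01d(level_of(x, u, net.ht_src[t]));
      double f = hill_f_kn(lv, net.ht_kn[t], net.ht_nv[t]);
      g *= (net.ht_sign[t] > 0) ? f : 1.0 - f;
    }
    int nodei = net.he_node[e];
    if (net.he_kd[e]) {
      kdprod[nodei] *= g;
    } else {
      has_or[nodei] = 1;
      orprod[nodei] *= (1.0 - g);
    }
  }

  int nF = net.fl_type.size();
  for (int f = 0; f < nF; ++f) {
    double flux = pars[net.fl_rate[f]];
    for (int q = net.fl_fptr[f]; q < net.fl_fptr[f + 1]; ++q) {
      double lv = level_of(x, u, net.ff_src[q]);
      if (lv < 0.0) lv = 0.0;
      flux *= (net.ff_exp[q] == 1.0) ? lv : std::pow(lv, net.ff_exp[q]);
    }
    if (net.fl_type[f] == 1) {  // Michaelis-Menten with competitive inhibition
      double S = level_of(x, u, net.fl_sub[f]);
      if (S < 0.0) S = 0.0;
      double km = pars[net.fl_km[f]];
      if (net.fl_has_inh[f]) {
        double I = level_of(x, u, net.fl_inh[f]);
        if (I < 0.0) I = 0.0;
        km *= (1.0 + I / pars[net.fl_ki[f]]);
      }
      flux *= S / (km + S);
    }
    for (int q = net.fl_optr[f]; q < net.fl_optr[f + 1]; ++q)
      acc[net.fo_node[q]] += net.fo_coef[q] * flux;
  }

  for (int i = 0; i < nd; ++i) {
    double tau = pars[net.tau_idx[i]];
    if (net.is_met[i]) {
      double src = 0.0;
      if (net.src_rate[i] >= 0)
        src = net.src_scale[i] * pars[net.src_rate[i]];
      dx[i] = tau * (src + acc[i]);
    } else {
      double B = (has_or[i] ? 1.0 - orprod[i] : 1.0) * kdprod[i];
      dx[i] = tau * (B - x[i]);
    }
  }
}

// [[Rcpp::export]]
NumericVector rhs_network_cpp(List comp, NumericVector pars, NumericVector u,
                              NumericVector x) {
  CompNet net(comp);
  net.prepare(pars.begin());
  NumericVector dx(net.nd);
  rhs(net, pars.begin(), u.begin(), x.begin(), dx.begin());
  return dx;
}

// Dormand-Prince 5(4) coefficients.
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                    e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

// [[Rcpp::export]]
List sim_network_cpp(List comp, NumericVector pars, NumericVector u,
                     NumericVector x0, NumericVector times, double rtol,
                     double atol, int max_steps, double ss_exit = 0.0) {
  CompNet net(comp);
  net.prepare(pars.begin());
  int nd = net.nd, nt = times.size();
  NumericMatrix out(nt, nd);
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> k1(nd), k2(nd), k3(nd), k4(nd), k5(nd), k6(nd), k7(nd),
      xt(nd), err(nd);
  bool ok = true;
  int steps = 0;

  for (int i = 0; i < nd; ++i) out(0, i) = x[i];
  double t = times[0];
  double h = (times[nt - 1] - times[0]) / 100.0;
  const double hmin = 1e-12;

  rhs(net, pars.begin(), u.begin(), x.data(), k1.data());
  for (int seg = 1; seg < nt && ok; ++seg) {
    double tend = times[seg];
    while (t < tend) {
      if (++steps > max_steps) { ok = false; break; }
      if (h > tend - t) h = tend - t;
      if (h < hmin) h = hmin;
      for (int i = 0; i < nd; ++i) xt[i] = x[i] + h * a21 * k1[i];
      rhs(net, pars.begin(), u.begin(), xt.data(), k2.data());
      for (int i = 0; i < nd; ++i)
        xt[i] = x[i] + h * (a31 * k1[i] + a32 * k2[i]);
      rhs(net, pars.begin(), u.begin(), xt.data(), k3.data());
      for (int i = 0; i < nd; ++i)
        xt[i] = x[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
      rhs(net, pars.begin(), u.begin(), xt.data(), k4.data());
      for (int i = 0; i < nd; ++i)
        xt[i] = x[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
      rhs(net, pars.begin(), u.begin(), xt.data(), k5.data());
      for (int i = 0; i < nd; ++i)
        xt[i] = x[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                            a64 * k4[i] + a65 * k5[i]);
      rhs(net, pars.begin(), u.begin(), xt.data(), k6.data());
      for (int i = 0; i < nd; ++i)
        xt[i] = x[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] + b5 * k5[i] +
                            b6 * k6[i]);
      rhs(net, pars.begin(), u.begin(), xt.data(), k7.data());

      double errnorm = 0.0;
      bool finite = true;
      for (int i = 0; i < nd; ++i) {
        double ei = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                         e6 * k6[i] + e7 * k7[i]);
        double sc = atol + rtol * std::max(std::fabs(x[i]), std::fabs(xt[i]));
        double r = ei / sc;
        errnorm += r * r;
        if (!std::isfinite(xt[i])) finite = false;
      }
      errnorm = std::sqrt(errnorm / nd);

      if (!finite) {
        h *= 0.25;
        if (h < hmin) { ok = false; break; }
        rhs(net, pars.begin(), u.begin(), x.data(), k1.data());
        continue;
      }
      if (errnorm <= 1.0 || h <= hmin * 2) {
        t += h;
        for (int i = 0; i < nd; ++i) {
          // invariant guards: regulatory states live in [0,1], metabolites >= 0
          double v = xt[i];
          if (net.clamp01[i]) v = clamp01d(v);
          else if (v < 0.0) v = 0.0;
          x[i] = v;
        }
        // FSAL property of Dormand-Prince: k7 at xt equals k1 at new x,
        // unless clamping moved the state.
        rhs(net, pars.begin(), u.begin(), x.data(), k1.data());
        if (ss_exit > 0.0) {
          // once the system is numerically at steady state, the remaining
          // trajectory is constant: copy the state to all later outputs
          double mx = 0.0;
          for (int i = 0; i < nd; ++i)
            mx = std::max(mx, std::fabs(k1[i]));
          if (mx < ss_exit) {
            for (int s2 = seg; s2 < nt; ++s2)
              for (int i = 0; i < nd; ++i) out(s2, i) = x[i];
            NumericVector dss(nd);
            for (int i = 0; i < nd; ++i) dss[i] = k1[i];
            return List::create(_["states"] = out, _["final_deriv"] = dss,
                                _["ok"] = true, _["steps"] = steps);
          }
        }
      }
      double fac = errnorm > 0.0 ? 0.9 * std::pow(errnorm, -0.2) : 5.0;
      if (fac > 5.0) fac = 5.0;
      if (fac < 0.2) fac = 0.2;
      h *= fac;
    }
    for (int i = 0; i < nd; ++i) out(seg, i) = x[i];
  }

  NumericVector dfin(nd);
  rhs(net, pars.begin(), u.begin(), x.data(), dfin.begin());
  return List::create(_["states"] = out, _["final_deriv"] = dfin,
                      _["ok"] = ok, _["steps"] = steps);
}
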