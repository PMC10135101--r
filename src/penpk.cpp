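// Analytic linear one/two-compartment IV kinetics and the per-subject
// FOCE-i marginal-likelihood contribution. All times in hours, amounts in
// mg, concentrations in mg/L.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Disp {
  double CL, V1, Q, V2;
  double k10, k12, k21, alpha, beta, p, q;
  bool mono, repeated;
  double lam, c; // repeated-eigenvalue limiting form: (1 + c*t) exp(-lam*t)
};

static Disp make_disp(double CL, double V1, double Q, double V2) {
  Disp d;
  d.CL = CL; d.V1 = V1; d.Q = Q; d.V2 = V2;
  d.k10 = CL / V1;
  d.lam = 0.0; d.c = 0.0;
  if (Q <= 0.0) {
    d.mono = true; d.repeated = false;
    d.k12 = 0.0; d.k21 = 0.0;
    d.alpha = d.beta = d.k10;
    d.p = 1.0; d.q = 0.0;
    return d;
  }
  d.mono = false;
  d.k12 = Q / V1; d.k21 = Q / V2;
  double s = d.k10 + d.k12 + d.k21, pr = d.k10 * d.k21;
  double disc = s * s - 4.0 * pr;
  if (disc < 1e-12 * s * s) {
    d.repeated = true;
    d.lam = s / 2.0;
    d.c = d.lam - d.k10 - d.k12;
    d.alpha = d.beta = d.lam;
    d.p = 1.0; d.q = 0.0;
    return d;
  }
  d.repeated = false;
  double sq = std::sqrt(disc);
  d.alpha = (s + sq) / 2.0;
  d.beta = (s - sq) / 2.0;
  d.p = (d.alpha - d.k21) / (d.alpha - d.beta);
  d.q = 1.0 - d.p;
  return d;
}

// central concentration at u >= 0 after a unit bolus at u = 0
static inline double bolus_u(const Disp& d, double u) {
  if (d.mono) return std::exp(-d.k10 * u) / d.V1;
  if (d.repeated) return std::exp(-d.lam * u) * (1.0 + d.c * u) / d.V1;
  return (d.p * std::exp(-d.alpha * u) + d.q * std::exp(-d.beta * u)) / d.V1;
}

// central concentration at u > 0 under a unit-rate zero-order input running
// since u = 0 (integral of bolus_u)
static inline double step_u(const Disp& d, double u) {
  if (d.mono) return (1.0 - std::exp(-d.k10 * u)) / (d.V1 * d.k10);
  if (d.repeated) {
    double e = std::exp(-d.lam * u);
    return ((1.0 - e) / d.lam +
            d.c * (1.0 - e * (1.0 + d.lam * u)) / (d.lam * d.lam)) / d.V1;
  }
  return (d.p * (1.0 - std::exp(-d.alpha * u)) / d.alpha +
          d.q * (1.0 - std::exp(-d.beta * u)) / d.beta) / d.V1;
}

static double conc_at(const Disp& d, double t,
                      const NumericVector& et, const NumericVector& ea,
                      const NumericVector& ed, bool pre_dose) {
  double c = 0.0;
  for (R_xlen_t i = 0; i < et.size(); ++i) {
    double u = t - et[i];
    if (ed[i] <= 0.0) { // instantaneous bolus
      if (u < 0.0) continue;
      if (u == 0.0 && pre_dose) continue;
      c += ea[i] * bolus_u(d, u);
    } else {            // zero-order infusion = +step at start, -step at end
      if (u <= 0.0) continue;
      double rate = ea[i] / ed[i];
      c += rate * step_u(d, u);
      if (u > ed[i]) c -= rate * step_u(d, u - ed[i]);
    }
  }
  return c;
}

// [[Rcpp::export]]
NumericVector cpp_conc(NumericVector times, NumericVector ev_time,
                       NumericVector ev_amt, NumericVector ev_dur,
                       double CL, double V1, double Q, double V2,
                       bool pre_dose) {
  Disp d = make_disp(CL, V1, Q, V2);
  NumericVector out(times.size());
  for (R_xlen_t j = 0; j < times.size(); ++j)
    out[j] = conc_at(d, times[j], ev_time, ev_amt, ev_dur, pre_dose);
  return out;
}

// ---------------------------------------------------------------------------
// per-subject conditional objective: -2 log joint density (up to the 2*pi
// terms handled in the marginal assembly below)
class SubjNLL {
public:
  arma::vec times, y;
  NumericVector et, ea, ed;
  double tvCL, tvV1, tvQ, tvV2, s2p, s2a;
  arma::vec om2;   // length 3: CL, V1, V2; zero => eta fixed at 0
  arma::uvec act;  // active eta indices

  arma::vec expand(const arma::vec& e) const {
    arma::vec eta3(3, arma::fill::zeros);
    for (arma::uword k = 0; k < act.n_elem; ++k) eta3[act[k]] = e[k];
    return eta3;
  }

  arma::vec predict(const arma::vec& eta3) const {
    Disp d = make_disp(tvCL * std::exp(eta3[0]), tvV1 * std::exp(eta3[1]),
                       tvQ, tvV2 * std::exp(eta3[2]));
    arma::vec f(times.n_elem);
    for (arma::uword j = 0; j < times.n_elem; ++j)
      f[j] = conc_at(d, times[j], et, ea, ed, true);
    return f;
  }

  double nll(const arma::vec& e) const {
    arma::vec f = predict(expand(e));
    double l = 0.0;
    for (arma::uword j = 0; j < f.n_elem; ++j) {
      double g = s2p * f[j] * f[j] + s2a;
      if (!(g > 0.0) || !std::isfinite(f[j])) return 1e10;
      double r = y[j] - f[j];
      l += std::log(g) + r * r / g;
    }
    for (arma::uword k = 0; k < act.n_elem; ++k)
      l += e[k] * e[k] / om2[act[k]];
    return std::isfinite(l) ? l : 1e10;
  }
};

static void fd_grad_hess(const SubjNLL& s, const arma::vec& eta, double l0,
                         arma::vec& g, arma::mat& H) {
  const double h = 1e-4;
  int d = eta.n_elem;
  for (int i = 0; i < d; ++i) {
    arma::vec e1 = eta;
    e1[i] += h; double lp = s.nll(e1);
    e1[i] -= 2.0 * h; double lm = s.nll(e1);
    g[i] = (lp - lm) / (2.0 * h);
    H(i, i) = (lp + lm - 2.0 * l0) / (h * h);
  }
  for (int i = 0; i < d; ++i)
    for (int j = i + 1; j < d; ++j) {
      arma::vec e1 = eta;
      e1[i] += h; e1[j] += h; double a = s.nll(e1);
      e1[j] -= 2.0 * h;       double b = s.nll(e1);
      e1[i] -= 2.0 * h;       double c = s.nll(e1);
      e1[j] += 2.0 * h;       double dd = s.nll(e1);
      H(i, j) = H(j, i) = (a - b - dd + c) / (4.0 * h * h);
    }
}

// modified Newton with ridge and backtracking; gradient tolerance per the
// estimation contract
static bool inner_newton(const SubjNLL& s, arma::vec& eta, double tol,
                         int maxit) {
  int d = eta.n_elem;
  if (d == 0) return true;
  double l0 = s.nll(eta);
  arma::vec g(d);
  arma::mat H(d, d);
  for (int it = 0; it < maxit; ++it) {
    fd_grad_hess(s, eta, l0, g, H);
    double gn = arma::norm(g, "inf");
    if (gn < tol) return true;
    double ridge = 0.0;
    bool stepped = false;
    for (int tr = 0; tr < 8 && !stepped; ++tr) {
      arma::mat Hr = H + ridge * arma::eye(d, d);
      arma::vec stp;
      bool ok = arma::solve(stp, Hr, -g, arma::solve_opts::no_approx);
      if (ok && arma::dot(stp, g) < 0.0) {
        // a Newton step at floating-point resolution is a stationary point
        if (arma::norm(stp, "inf") < 1e-9) return true;
        double t = 1.0;
        for (int ls = 0; ls < 15; ++ls) {
          double lnew = s.nll(eta + t * stp);
          if (lnew < l0) {
            eta += t * stp; l0 = lnew; stepped = true; break;
          }
          t *= 0.5;
        }
      }
      if (!stepped)
        ridge = (ridge == 0.0)
          ? std::max(1e-4, arma::norm(H, "inf") * 1e-3) : ridge * 10.0;
    }
    // no achievable descent: the objective is flat to machine precision
    if (!stepped) return gn < 1e-5;
  }
  fd_grad_hess(s, eta, l0, g, H);
  return arma::norm(g, "inf") < 1e-5;
}

class SubjNLL;
static double foce_one(SubjNLL& s, bool laplace, arma::vec& eta_io,
                       bool& conv_out);

// [[Rcpp::export]]
List cpp_foce_subject(NumericVector times, NumericVector y,
                      NumericVector ev_time, NumericVector ev_amt,
                      NumericVector ev_dur,
                      double tvCL, double tvV1, double tvQ, double tvV2,
                      NumericVector omega2, double sigma2_prop,
                      double sigma2_add, bool laplace,
                      NumericVector eta_start) {
  SubjNLL s;
  s.times = arma::vec(times.begin(), times.size());
  s.y = arma::vec(y.begin(), y.size());
  s.et = ev_time; s.ea = ev_amt; s.ed = ev_dur;
  s.tvCL = tvCL; s.tvV1 = tvV1; s.tvQ = tvQ; s.tvV2 = tvV2;
  s.s2p = sigma2_prop; s.s2a = sigma2_add;
  s.om2 = arma::vec(omega2.begin(), omega2.size());
  arma::vec e3 = arma::vec(eta_start.begin(), eta_start.size());
  bool conv = true;
  double ofv = foce_one(s, laplace, e3, conv);
  return List::create(_["ofv"] = ofv,
                      _["eta"] = NumericVector(e3.begin(), e3.end()),
                      _["converged"] = conv);
}

// one subject's contribution, shared by the scalar and batched entry points
static double foce_one(SubjNLL& s, bool laplace, arma::vec& eta_io,
                       bool& conv_out) {
  std::vector<arma::uword> ai;
  for (arma::uword k = 0; k < s.om2.n_elem; ++k)
    if (s.om2[k] > 0.0) ai.push_back(k);
  s.act = arma::uvec(ai);
  const int d = s.act.n_elem;
  arma::vec eta(d, arma::fill::zeros);
  for (int k = 0; k < d; ++k) eta[k] = eta_io[s.act[k]];
  bool conv = inner_newton(s, eta, 1e-8, 100);
  if (!conv) {
    double lbest = s.nll(eta);
    arma::vec best = eta;
    for (int r = 0; r < 2; ++r) {
      arma::vec e0(d);
      for (int k = 0; k < d; ++k) e0[k] = (r == 0 ? 0.3 : -0.3);
      bool c2 = inner_newton(s, e0, 1e-8, 100);
      double l2 = s.nll(e0);
      if (l2 < lbest) { lbest = l2; best = e0; conv = c2; }
    }
    eta = best;
  }
  arma::vec eta3 = s.expand(eta);
  arma::vec f = s.predict(eta3);
  const double LOG2PI = std::log(2.0 * M_PI);
  double ofv = 0.0;
  arma::vec gv(f.n_elem);
  for (arma::uword j = 0; j < f.n_elem; ++j) {
    double g = s.s2p * f[j] * f[j] + s.s2a;
    gv[j] = g;
    double r = s.y[j] - f[j];
    ofv += std::log(g) + LOG2PI + r * r / g;
  }
  if (d > 0) {
    for (int k = 0; k < d; ++k)
      ofv += std::log(s.om2[s.act[k]]) + eta[k] * eta[k] / s.om2[s.act[k]];
    arma::mat H(d, d, arma::fill::zeros);
    bool used_gn = !laplace;
    if (laplace) {
      arma::vec g0(d);
      fd_grad_hess(s, eta, s.nll(eta), g0, H);
      H *= 0.5;
      if (!H.is_sympd()) used_gn = true;
    }
    if (used_gn) {
      H.zeros();
      for (int k = 0; k < d; ++k) H(k, k) = 1.0 / s.om2[s.act[k]];
      const double h = 1e-4;
      arma::mat J(f.n_elem, d);
      for (int k = 0; k < d; ++k) {
        arma::vec e1 = eta;
        e1[k] += h; arma::vec fp = s.predict(s.expand(e1));
        e1[k] -= 2.0 * h; arma::vec fm = s.predict(s.expand(e1));
        J.col(k) = (fp - fm) / (2.0 * h);
      }
      for (arma::uword j = 0; j < f.n_elem; ++j)
        H += J.row(j).t() * J.row(j) / gv[j];
    }
    double ld, sign;
    arma::log_det(ld, sign, H);
    if (sign <= 0.0 || !std::isfinite(ld)) { conv = false; ld = 0.0; }
    ofv += ld;
  }
  eta_io = eta3;
  conv_out = conv;
  return ofv;
}

// batched objective over a whole study: flat observation/event arrays with
// 0-based subject offsets (ptr, length n+1) and an n x 4 matrix of typical
// values (CL, V1, Q, V2)
// [[Rcpp::export]]
List cpp_foce_study(NumericVector obs_time, NumericVector obs_y,
                    IntegerVector obs_ptr,
                    NumericVector ev_time, NumericVector ev_amt,
                    NumericVector ev_dur, IntegerVector ev_ptr,
                    NumericMatrix tv, NumericVector omega2,
                    double sigma2_prop, double sigma2_add, bool laplace,
                    NumericMatrix eta_start) {
  const int n = tv.nrow();
  NumericMatrix etas(n, 3);
  LogicalVector conv(n);
  NumericVector contrib(n);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    SubjNLL s;
    int o0 = obs_ptr[i], o1 = obs_ptr[i + 1];
    int e0 = ev_ptr[i], e1 = ev_ptr[i + 1];
    s.times = arma::vec(o1 - o0);
    s.y = arma::vec(o1 - o0);
    for (int j = o0; j < o1; ++j) {
      s.times[j - o0] = obs_time[j];
      s.y[j - o0] = obs_y[j];
    }
    s.et = NumericVector(ev_time.begin() + e0, ev_time.begin() + e1);
    s.ea = NumericVector(ev_amt.begin() + e0, ev_amt.begin() + e1);
    s.ed = NumericVector(ev_dur.begin() + e0, ev_dur.begin() + e1);
    s.tvCL = tv(i, 0); s.tvV1 = tv(i, 1); s.tvQ = tv(i, 2);
    s.tvV2 = tv(i, 3);
    s.s2p = sigma2_prop; s.s2a = sigma2_add;
    s.om2 = arma::vec(omega2.begin(), omega2.size());
    arma::vec e3(3);
    for (int k = 0; k < 3; ++k) e3[k] = eta_start(i, k);
    bool cv = true;
    double o = foce_one(s, laplace, e3, cv);
    contrib[i] = o;
    total += o;
    conv[i] = cv;
    for (int k = 0; k < 3; ++k) etas(i, k) = e3[k];
  }
  return List::create(_["ofv"] = total, _["etas"] = etas,
                      _["converged"] = conv, _["by_subject"] = contrib);
}
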