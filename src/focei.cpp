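// FOCE-with-interaction likelihood core for compartmental IV-bolus models.
//
// The structural model is evaluated in closed form (one- or two-compartment,
// superposed boluses).  Derivatives of the prediction with respect to the
// random effects are taken by complex-step differentiation, so the outer
// objective is smooth to machine precision; the inner eta problem is solved
// by a damped Newton iteration per subject.
#include <RcppArmadillo.h>
#include <complex>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454835606594728112;

// real part, generic over double / complex<double>
static inline double re_of(const double& x) { return x; }
static inline double re_of(const std::complex<double>& x) { return x.real(); }

// sqrt of the discriminant: clamp tiny negative round-off for the real path
static inline double disc_sqrt(const double& d) {
  return std::sqrt(d > 0.0 ? d : 0.0);
}
static inline std::complex<double> disc_sqrt(const std::complex<double>& d) {
  return std::sqrt(d);
}

// Superposed-bolus concentration profile.  ncmt 1: mono-exponential with
// k = cl1/v1.  ncmt 2: biexponential with hybrid rate constants alpha/beta;
// near-degenerate roots (alpha ~ beta) switch to the repeated-root form.
template <typename T>
static void conc_profile(const double* t, int nt,
                         const double* dt, const double* da, int nd,
                         T v1, T v2, T cl1, T cl2, int ncmt, T* out) {
  if (ncmt == 1) {
    T k = cl1 / v1;
    for (int j = 0; j < nt; ++j) {
      T c = T(0.0);
      for (int d = 0; d < nd; ++d) {
        double tau = t[j] - dt[d];
        if (tau < 0.0) continue;
        c += (da[d] / v1) * std::exp(-k * tau);
      }
      out[j] = c;
    }
    return;
  }
  T k10 = cl1 / v1, k12 = cl2 / v1, k21 = cl2 / v2;
  T s = k10 + k12 + k21, p = k10 * k21;
  T rt = disc_sqrt(s * s - 4.0 * p);
  T alpha = 0.5 * (s + rt), beta = 0.5 * (s - rt);
  bool degen = (re_of(alpha) - re_of(beta)) < 1e-10 * re_of(alpha);
  T A = T(0.0), B = T(0.0);
  if (!degen) {
    A = (alpha - k21) / (alpha - beta);
    B = (k21 - beta) / (alpha - beta);
  }
  for (int j = 0; j < nt; ++j) {
    T c = T(0.0);
    for (int d = 0; d < nd; ++d) {
      double tau = t[j] - dt[d];
      if (tau < 0.0) continue;
      if (degen)
        c += (da[d] / v1) * std::exp(-alpha * tau) * (1.0 - (alpha - k21) * tau);
      else
        c += (da[d] / v1) * (A * std::exp(-alpha * tau) + B * std::exp(-beta * tau));
    }
    out[j] = c;
  }
}

// [[Rcpp::export]]
NumericVector cpp_conc(NumericVector t, NumericVector dose_t, NumericVector dose_a,
                       double v1, double v2, double cl1, double cl2, int ncmt) {
  NumericVector out(t.size());
  conc_profile<double>(t.begin(), t.size(), dose_t.begin(), dose_a.begin(),
                       dose_t.size(), v1, v2, cl1, cl2, ncmt, out.begin());
  return out;
}

namespace {

struct SubjData {
  const double* y;  const double* t;  int n;
  const double* dt; const double* da; int nd;
  double typ[4];          // typical (covariate-adjusted) v1, v2, cl1, cl2
  const int* eta_idx;     // 0-based index into typ per eta
  int neta;
  const double* omega2;
  double s1, s2;          // additive / proportional residual SDs
  int ncmt;
};

// prediction at eta (real path)
static void pred_at(const SubjData& sd, const arma::vec& eta, double* f) {
  double p[4];
  for (int k = 0; k < 4; ++k) p[k] = sd.typ[k];
  for (int k = 0; k < sd.neta; ++k) p[sd.eta_idx[k]] *= std::exp(eta(k));
  conc_profile<double>(sd.t, sd.n, sd.dt, sd.da, sd.nd,
                       p[0], p[1], p[2], p[3], sd.ncmt, f);
}

// prediction + Jacobian df/deta by complex step (exact to machine precision)
static void pred_jac(const SubjData& sd, const arma::vec& eta,
                     double* f, arma::mat& F) {
  pred_at(sd, eta, f);
  const double h = 1e-20;
  std::vector<std::complex<double> > fc(sd.n);
  for (int k = 0; k < sd.neta; ++k) {
    std::complex<double> p[4];
    for (int j = 0; j < 4; ++j) p[j] = sd.typ[j];
    for (int m = 0; m < sd.neta; ++m) {
      std::complex<double> e = std::exp(std::complex<double>(eta(m), m == k ? h : 0.0));
      p[sd.eta_idx[m]] *= e;
    }
    conc_profile<std::complex<double> >(sd.t, sd.n, sd.dt, sd.da, sd.nd,
                                        p[0], p[1], p[2], p[3], sd.ncmt, fc.data());
    for (int j = 0; j < sd.n; ++j) F(j, k) = fc[j].imag() / h;
  }
}

// joint -2 log density (obs part + eta penalty), without 2*pi constants
static double g_value(const SubjData& sd, const arma::vec& eta, bool& ok) {
  std::vector<double> f(sd.n);
  pred_at(sd, eta, f.data());
  double g = 0.0;
  for (int j = 0; j < sd.n; ++j) {
    if (!std::isfinite(f[j])) { ok = false; return 1e100; }
    double v = sd.s1 * sd.s1 + f[j] * f[j] * sd.s2 * sd.s2;
    double r = sd.y[j] - f[j];
    g += r * r / v + std::log(v);
  }
  for (int k = 0; k < sd.neta; ++k)
    g += eta(k) * eta(k) / sd.omega2[k] + std::log(sd.omega2[k]);
  ok = std::isfinite(g);
  return g;
}

// analytic gradient of g (uses complex-step Jacobian of f)
static arma::vec g_grad(const SubjData& sd, const arma::vec& eta) {
  std::vector<double> f(sd.n);
  arma::mat F(sd.n, sd.neta);
  pred_jac(sd, eta, f.data(), F);
  arma::vec grad(sd.neta, arma::fill::zeros);
  for (int j = 0; j < sd.n; ++j) {
    double v = sd.s1 * sd.s1 + f[j] * f[j] * sd.s2 * sd.s2;
    double r = sd.y[j] - f[j];
    double vp = 2.0 * f[j] * sd.s2 * sd.s2;           // dv/df
    double w = -2.0 * r / v + (1.0 / v - r * r / (v * v)) * vp;
    for (int k = 0; k < sd.neta; ++k) grad(k) += w * F(j, k);
  }
  for (int k = 0; k < sd.neta; ++k) grad(k) += 2.0 * eta(k) / sd.omega2[k];
  return grad;
}

// damped Newton on g; Hessian by central differences of the analytic gradient
static bool inner_solve(const SubjData& sd, arma::vec& eta,
                        double gtol, int maxit) {
  if (sd.neta == 0) return true;
  bool ok = true;
  double g = g_value(sd, eta, ok);
  if (!ok) { eta.zeros(); g = g_value(sd, eta, ok); if (!ok) return false; }
  const double he = 1e-5;
  for (int it = 0; it < maxit; ++it) {
    arma::vec grad = g_grad(sd, eta);
    if (!grad.is_finite()) return false;
    if (arma::abs(grad).max() < gtol) return true;
    arma::mat H(sd.neta, sd.neta);
    for (int k = 0; k < sd.neta; ++k) {
      arma::vec ep = eta, em = eta;
      ep(k) += he; em(k) -= he;
      H.col(k) = (g_grad(sd, ep) - g_grad(sd, em)) / (2.0 * he);
    }
    H = 0.5 * (H + H.t());
    arma::vec step;
    double lam = 0.0;
    for (int tries = 0; tries < 12; ++tries) {
      arma::mat Hd = H + lam * arma::eye(sd.neta, sd.neta);
      if (arma::solve(step, Hd, -grad, arma::solve_opts::no_approx) &&
          arma::dot(step, grad) < 0.0) break;
      lam = (lam == 0.0) ? 1e-4 * std::max(1.0, arma::abs(H.diag()).max()) : 10.0 * lam;
      step.reset();
    }
    if (step.n_elem == 0) step = -grad;  // damping failed: gradient descent
    double tstep = 1.0, gnew = 0.0;
    arma::vec enew;
    bool improved = false;
    for (int ls = 0; ls < 40; ++ls) {
      enew = eta + tstep * step;
      gnew = g_value(sd, enew, ok);
      if (ok && gnew <= g) { improved = true; break; }
      tstep *= 0.5;
    }
    if (!improved) return arma::abs(grad).max() < 1e-4;  // stalled near optimum
    double moved = arma::abs(enew - eta).max();
    eta = enew; g = gnew;
    if (moved < 1e-12) return true;
  }
  return arma::abs(g_grad(sd, eta)).max() < 1e-4;
}

}  // namespace

// FOCE-I objective over a dataset packed as concatenated per-subject arrays.
// optr/dptr are 0-based offsets of length n_sub+1 into the obs / dose arrays.
// Returns total OFV (includes n*log(2*pi)), per-subject OFV, conditional
// eta estimates, and (if detail) PRED / IPRED / marginal mean / CWRES.
// [[Rcpp::export]]
List cpp_focei(NumericVector y, NumericVector obst, IntegerVector optr,
               NumericVector doset, NumericVector dosea, IntegerVector dptr,
               NumericMatrix typ, IntegerVector eta_idx, NumericVector omega2,
               double s1, double s2, int ncmt,
               NumericMatrix eta_start, double gtol, int maxit, bool detail) {
  const int nsub = typ.nrow(), neta = eta_idx.size(), nobs = y.size();
  NumericVector ofv_i(nsub);
  NumericMatrix eta_hat(nsub, neta);
  LogicalVector inner_ok(nsub);
  NumericVector pred, ipred, yhat, cwres;
  if (detail) {
    pred = NumericVector(nobs); ipred = NumericVector(nobs);
    yhat = NumericVector(nobs); cwres = NumericVector(nobs);
  }
  arma::mat Om(neta, neta, arma::fill::zeros);
  for (int k = 0; k < neta; ++k) Om(k, k) = omega2[k];
  double total = 0.0;
  bool all_finite = true;

  for (int i = 0; i < nsub; ++i) {
    SubjData sd;
    sd.y = &y[0] + optr[i];   sd.t = &obst[0] + optr[i];
    sd.n = optr[i + 1] - optr[i];
    sd.dt = &doset[0] + dptr[i]; sd.da = &dosea[0] + dptr[i];
    sd.nd = dptr[i + 1] - dptr[i];
    for (int k = 0; k < 4; ++k) sd.typ[k] = typ(i, k);
    sd.eta_idx = neta ? &eta_idx[0] : nullptr;
    sd.neta = neta;
    sd.omega2 = neta ? &omega2[0] : nullptr;
    sd.s1 = s1; sd.s2 = s2; sd.ncmt = ncmt;

    arma::vec eta(neta, arma::fill::zeros);
    for (int k = 0; k < neta; ++k) eta(k) = eta_start(i, k);
    bool ok = true;
    if (sd.n > 0) ok = inner_solve(sd, eta, gtol, maxit);
    else eta.zeros();
    inner_ok[i] = ok;
    for (int k = 0; k < neta; ++k) eta_hat(i, k) = eta(k);

    if (sd.n == 0) { ofv_i[i] = 0.0; continue; }

    std::vector<double> f(sd.n);
    arma::mat F(sd.n, std::max(neta, 1), arma::fill::zeros);
    if (neta > 0) pred_jac(sd, eta, f.data(), F);
    else pred_at(sd, eta, f.data());

    arma::vec r(sd.n);
    arma::mat V(sd.n, sd.n, arma::fill::zeros);
    bool fin = true;
    for (int j = 0; j < sd.n; ++j) {
      if (!std::isfinite(f[j])) fin = false;
      double v = s1 * s1 + f[j] * f[j] * s2 * s2;
      V(j, j) = v;
      double mean_j = f[j];
      for (int k = 0; k < neta; ++k) mean_j -= F(j, k) * eta(k);
      r(j) = sd.y[j] - mean_j;
    }
    if (!fin) { all_finite = false; ofv_i[i] = R_PosInf; total = R_PosInf; continue; }
    if (neta > 0) V += F.cols(0, neta - 1) * Om * F.cols(0, neta - 1).t();

    arma::mat L;
    if (!arma::chol(L, V, "lower")) {
      all_finite = false; ofv_i[i] = R_PosInf; total = R_PosInf; continue;
    }
    arma::vec z = arma::solve(arma::trimatl(L), r);
    double ldet = 2.0 * arma::sum(arma::log(L.diag()));
    double o = sd.n * LOG2PI + ldet + arma::dot(z, z);
    ofv_i[i] = o;
    if (std::isfinite(total)) total += o;

    if (detail) {
      std::vector<double> f0(sd.n);
      arma::vec z0(neta, arma::fill::zeros);
      arma::vec eta0(neta, arma::fill::zeros);
      SubjData sd0 = sd;
      pred_at(sd0, eta0, f0.data());
      for (int j = 0; j < sd.n; ++j) {
        int jj = optr[i] + j;
        pred[jj]  = f0[j];
        ipred[jj] = f[j];
        yhat[jj]  = sd.y[j] - r(j);
        cwres[jj] = z(j);
      }
    }
  }

  List out = List::create(_["ofv"] = total, _["ofv_i"] = ofv_i,
                          _["eta"] = eta_hat, _["inner_ok"] = inner_ok,
                          _["finite"] = all_finite);
  if (detail) {
    out["pred"] = pred; out["ipred"] = ipred;
    out["yhat"] = yhat; out["cwres"] = cwres;
  }
  return out;
}
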