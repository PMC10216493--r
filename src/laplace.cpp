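#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Marginal -2 log-likelihood of the log-normal mixed-effects survival model
// by per-trial Laplace approximation.
//
// Model, trial i, observation j (digitized KM point):
//   y_ij      = logit(observed survival fraction)
//   mu_i      = mu_g(i)    * exp(eta_mu,i),    eta_mu,i    ~ N(0, om_m^2)
//   sigma_i   = sigma_g(i) * exp(eta_sigma,i), eta_sigma,i ~ N(0, om_s^2)
//   S_ij      = S0(t_ij; mu_i, sigma_i)^(m_i)   (PH covariate multiplier m_i)
//   y_ij      ~ N(logit(S_ij), eps^2)
//
// The two etas are integrated out per trial with a Laplace approximation
// around the conditional mode (damped Newton, Gauss-Newton curvature); the
// log-determinant uses the exact analytic Hessian of the penalized
// objective at the mode.

// logit predictions are kept finite at very early times by clamping
// A = m * log S0 away from zero.
static const double A_CLAMP = -1e-12;

// log of the standard-normal upper tail, log(1 - Phi(z)), via erfc with a
// fallback to R's pnorm when erfc underflows (|z| beyond ~26)
static inline double log_surv_norm(double z) {
  double e = std::erfc(z * M_SQRT1_2);
  if (e > 0.0) return std::log(0.5 * e);
  return R::pnorm(z, 0.0, 1.0, 0, 1);
}

static inline double log_dnorm(double z) {
  return -0.5 * z * z - 0.5 * M_LN_2PI;
}

struct TrialView {
  const double *y, *logt;
  int n;
  double mu0, sig0, m;
};

// penalized conditional -log-likelihood h(eta) for one trial
static double h_fun(const TrialView &tv, double es, double em,
                    double om_s, double om_m, double eps,
                    bool pen_s, bool pen_m) {
  const double mu = tv.mu0 * std::exp(em);
  const double sig = tv.sig0 * std::exp(es);
  const double le = std::log(eps);
  double h = 0.0;
  for (int j = 0; j < tv.n; ++j) {
    double z = (tv.logt[j] - mu) / sig;
    double logS0 = log_surv_norm(z);
    double A = tv.m * logS0;
    if (A > A_CLAMP) A = A_CLAMP;
    double yh = A - std::log(-std::expm1(A));
    double r = tv.y[j] - yh;
    h += 0.5 * M_LN_2PI + le + 0.5 * r * r / (eps * eps);
  }
  if (pen_s) h += 0.5 * M_LN_2PI + std::log(om_s) + 0.5 * es * es / (om_s * om_s);
  if (pen_m) h += 0.5 * M_LN_2PI + std::log(om_m) + 0.5 * em * em / (om_m * om_m);
  return h;
}

// gradient of h wrt (eta_sigma, eta_mu); optionally the Gauss-Newton
// curvature gn[] = {Hss, Hsm, Hmm} and/or the exact Hessian hx[].
static void grad_fun(const TrialView &tv, double es, double em,
                     double om_s, double om_m, double eps,
                     bool pen_s, bool pen_m,
                     double *g, double *gn, double *hx) {
  const double mu = tv.mu0 * std::exp(em);
  const double sig = tv.sig0 * std::exp(es);
  const double ie2 = 1.0 / (eps * eps);
  double gs = 0.0, gm = 0.0;
  double gnv[3] = {0, 0, 0}, hxv[3] = {0, 0, 0};
  for (int j = 0; j < tv.n; ++j) {
    double z = (tv.logt[j] - mu) / sig;
    double logS0 = log_surv_norm(z);
    double A = tv.m * logS0;
    if (A > A_CLAMP) A = A_CLAMP;
    double eA = std::expm1(A);                // e^A - 1  (negative)
    double yh = A - std::log(-eA);
    double r = tv.y[j] - yh;
    double D = 1.0 / (-eA);                   // dyh/dA
    double IM = std::exp(log_dnorm(z) - logS0);  // phi(z)/S0
    // z derivatives in (es, em):  dz/des = -z, dz/dem = -mu/sig
    double zs = -z, zm = -mu / sig;
    // dlogS0/d. = -IM * dz/d.
    double As = tv.m * (-IM) * zs;            // dA/des
    double Am = tv.m * (-IM) * zm;            // dA/dem
    double ds = D * As, dm = D * Am;
    gs -= r * ie2 * ds;
    gm -= r * ie2 * dm;
    if (gn) {
      gnv[0] += ds * ds * ie2; gnv[1] += ds * dm * ie2; gnv[2] += dm * dm * ie2;
    }
    if (hx) {
      // second derivatives of z:  d2z/des2 = z, d2z/desdem = mu/sig,
      // d2z/dem2 = -mu/sig
      double zss = z, zsm = mu / sig, zmm = -mu / sig;
      double c1 = IM * (IM - z);              // d(IM)/dz
      // d2logS0/da db = -(c1 * za * zb + IM * zab)
      double Lss = -(c1 * zs * zs + IM * zss);
      double Lsm = -(c1 * zs * zm + IM * zsm);
      double Lmm = -(c1 * zm * zm + IM * zmm);
      double D2 = (eA + 1.0) * D * D;         // d2yh/dA2 = e^A/(1-e^A)^2
      double Yss = D2 * As * As + D * tv.m * Lss;
      double Ysm = D2 * As * Am + D * tv.m * Lsm;
      double Ymm = D2 * Am * Am + D * tv.m * Lmm;
      hxv[0] += ie2 * (ds * ds - r * Yss);
      hxv[1] += ie2 * (ds * dm - r * Ysm);
      hxv[2] += ie2 * (dm * dm - r * Ymm);
    }
  }
  if (pen_s) {
    gs += es / (om_s * om_s);
    if (gn) gnv[0] += 1.0 / (om_s * om_s);
    if (hx) hxv[0] += 1.0 / (om_s * om_s);
  }
  if (pen_m) {
    gm += em / (om_m * om_m);
    if (gn) gnv[2] += 1.0 / (om_m * om_m);
    if (hx) hxv[2] += 1.0 / (om_m * om_m);
  }
  g[0] = gs; g[1] = gm;
  if (gn) { gn[0] = gnv[0]; gn[1] = gnv[1]; gn[2] = gnv[2]; }
  if (hx) { hx[0] = hxv[0]; hx[1] = hxv[1]; hx[2] = hxv[2]; }
}

// [[Rcpp::export]]
List laplace_ofv_cpp(NumericVector y, NumericVector logt,
                     IntegerVector start, IntegerVector len,
                     NumericVector mu_t, NumericVector sig_t,
                     NumericVector mscale,
                     double om_s, double om_m, double eps,
                     bool want_eb,
                     Nullable<NumericMatrix> eta_init = R_NilValue) {
  const int ntr = start.size();
  const bool pen_s = om_s > 0.0, pen_m = om_m > 0.0;
  const int d = (pen_s ? 1 : 0) + (pen_m ? 1 : 0);
  double ofv = 0.0;
  NumericMatrix eta(ntr, 2);
  NumericMatrix hess(want_eb ? ntr : 0, 3);
  bool ok = true;
  int bad_trial = -1;
  NumericMatrix e0(0, 0);
  bool have_init = eta_init.isNotNull();
  if (have_init) e0 = NumericMatrix(eta_init);

  for (int i = 0; i < ntr; ++i) {
    TrialView tv;
    tv.y = &y[0] + start[i];
    tv.logt = &logt[0] + start[i];
    tv.n = len[i];
    tv.mu0 = mu_t[i];
    tv.sig0 = sig_t[i];
    tv.m = mscale[i];

    double es = 0.0, em = 0.0;
    if (have_init && i < e0.nrow()) {
      if (pen_s) es = e0(i, 0);
      if (pen_m) em = e0(i, 1);
    }
    double h = h_fun(tv, es, em, om_s, om_m, eps, pen_s, pen_m);
    if (!R_finite(h)) { es = em = 0.0; h = h_fun(tv, 0, 0, om_s, om_m, eps, pen_s, pen_m); }
    if (d > 0) {
      double g[2], gn[3];
      for (int it = 0; it < 100; ++it) {
        grad_fun(tv, es, em, om_s, om_m, eps, pen_s, pen_m, g, gn, 0);
        double ss = 0.0, sm = 0.0;
        if (pen_s && pen_m) {
          double det = gn[0] * gn[2] - gn[1] * gn[1];
          if (det <= 1e-300) det = 1e-300;
          ss = -(gn[2] * g[0] - gn[1] * g[1]) / det;
          sm = -(gn[0] * g[1] - gn[1] * g[0]) / det;
        } else if (pen_s) {
          ss = -g[0] / gn[0];
        } else {
          sm = -g[1] / gn[2];
        }
        double gmax = std::max(pen_s ? std::fabs(g[0]) : 0.0,
                               pen_m ? std::fabs(g[1]) : 0.0);
        if (gmax < 1e-9) break;
        double step = 1.0, hnew = 0.0;
        int k = 0;
        for (; k < 40; ++k) {
          hnew = h_fun(tv, es + step * ss, em + step * sm,
                       om_s, om_m, eps, pen_s, pen_m);
          if (R_finite(hnew) && hnew <= h + 1e-12) break;
          step *= 0.5;
        }
        if (k == 40) break;  // cannot improve further
        es += step * ss; em += step * sm;
        if (h - hnew < 1e-12 && k == 0) { h = hnew; break; }
        h = hnew;
      }
      // exact analytic Hessian at the mode for the log-determinant
      double g2[2], H[3];
      grad_fun(tv, es, em, om_s, om_m, eps, pen_s, pen_m, g2, gn, H);
      double logdet;
      if (pen_s && pen_m) {
        double det = H[0] * H[2] - H[1] * H[1];
        if (!(det > 0.0)) {  // fall back to the PD Gauss-Newton curvature
          H[0] = gn[0]; H[1] = gn[1]; H[2] = gn[2];
          det = H[0] * H[2] - H[1] * H[1];
        }
        logdet = std::log(det);
      } else {
        double Hd = pen_s ? H[0] : H[2];
        if (!(Hd > 0.0)) Hd = pen_s ? gn[0] : gn[2];
        logdet = std::log(Hd);
      }
      ofv += 2.0 * h + logdet - d * M_LN_2PI;
      eta(i, 0) = es; eta(i, 1) = em;
      if (want_eb) { hess(i, 0) = H[0]; hess(i, 1) = H[1]; hess(i, 2) = H[2]; }
    } else {
      ofv += 2.0 * h;
    }
    if (!R_finite(ofv)) { ok = false; bad_trial = i; break; }
  }

  List out = List::create(_["ofv"] = ofv, _["ok"] = ok,
                          _["bad_trial"] = bad_trial + 1, _["eta"] = eta);
  if (want_eb) out["cond_hessian"] = hess;
  return out;
}

// Predicted logit-survival for given per-trial parameters (used for GOF,
// VPC and residual computation from R without duplicating the clamping).
// [[Rcpp::export]]
NumericVector predict_logit_surv_cpp(NumericVector logt, IntegerVector trial,
                                     NumericVector mu_i, NumericVector sig_i,
                                     NumericVector mscale) {
  const int n = logt.size();
  NumericVector out(n);
  for (int j = 0; j < n; ++j) {
    int i = trial[j] - 1;
    double z = (logt[j] - mu_i[i]) / sig_i[i];
    double logS0 = log_surv_norm(z);
    double A = mscale[i] * logS0;
    if (A > A_CLAMP) A = A_CLAMP;
    out[j] = A - std::log(-std::expm1(A));
  }
  return out;
}
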