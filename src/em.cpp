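// Two-component EM inner loop (Gaussian or t family). Mirrors the
// documented algorithm: responsibilities, weighted location/scale updates,
// Liu-Rubin digamma equation for the t degrees of freedom (bounded), scale
// floor, absolute log-likelihood convergence tolerance.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double SIGMA_FLOOR = 1e-6;
static const double NU_LO = 2.1, NU_HI = 100.0;

static inline double t_logdens(double x, double mu, double sigma, double nu) {
  double z = (x - mu) / sigma;
  return R::lgammafn((nu + 1) / 2) - R::lgammafn(nu / 2) -
         0.5 * std::log(nu * M_PI) - std::log(sigma) -
         (nu + 1) / 2 * std::log1p(z * z / nu);
}

static inline double g_logdens(double x, double mu, double sigma) {
  return R::dnorm(x, mu, sigma, 1);
}

// decreasing in nu; root of the Liu-Rubin nu update equation
static inline double nu_equation(double v, double cst) {
  return -R::digamma(v / 2) + std::log(v / 2) + 1 + cst;
}

// [[Rcpp::export(name = ".em_two_cpp")]]
List em_two_cpp(NumericVector x, bool family_t, NumericVector pi0,
                NumericVector mu0, NumericVector sigma0, NumericVector nu0,
                int maxit, double tol) {
  int n = x.size();
  double pi2[2] = {pi0[0], pi0[1]};
  double mu[2] = {mu0[0], mu0[1]};
  double sigma[2] = {std::max(sigma0[0], SIGMA_FLOOR),
                     std::max(sigma0[1], SIGMA_FLOOR)};
  double nu[2] = {nu0[0], nu0[1]};
  std::vector<double> tau(2 * (size_t)n);
  double ll = R_NegInf, ll_old = R_NegInf;
  bool ok = true;
  for (int it = 0; it < maxit; ++it) {
    ll = 0.0;
    double nk[2] = {0, 0};
    for (int i = 0; i < n; ++i) {
      double l1 = std::log(pi2[0]) +
        (family_t ? t_logdens(x[i], mu[0], sigma[0], nu[0])
                  : g_logdens(x[i], mu[0], sigma[0]));
      double l2 = std::log(pi2[1]) +
        (family_t ? t_logdens(x[i], mu[1], sigma[1], nu[1])
                  : g_logdens(x[i], mu[1], sigma[1]));
      double mx = std::max(l1, l2);
      double lse = mx + std::log(std::exp(l1 - mx) + std::exp(l2 - mx));
      ll += lse;
      double t1 = std::exp(l1 - lse);
      tau[i] = t1; tau[n + i] = 1 - t1;
      nk[0] += t1; nk[1] += 1 - t1;
    }
    if (std::isfinite(ll) && ll - ll_old < tol && it > 2) break;
    ll_old = ll;
    if (nk[0] < 1e-8 || nk[1] < 1e-8) { ok = false; break; }
    pi2[0] = nk[0] / n; pi2[1] = nk[1] / n;
    for (int kk = 0; kk < 2; ++kk) {
      const double* tk = &tau[(size_t)kk * n];
      if (!family_t) {
        double sw = 0, swx = 0;
        for (int i = 0; i < n; ++i) { sw += tk[i]; swx += tk[i] * x[i]; }
        mu[kk] = swx / sw;
        double ss = 0;
        for (int i = 0; i < n; ++i)
          ss += tk[i] * (x[i] - mu[kk]) * (x[i] - mu[kk]);
        sigma[kk] = std::max(std::sqrt(ss / sw), SIGMA_FLOOR);
      } else {
        double swu = 0, swux = 0;
        for (int i = 0; i < n; ++i) {
          double z = (x[i] - mu[kk]) / sigma[kk];
          double u = (nu[kk] + 1) / (nu[kk] + z * z);
          swu += tk[i] * u; swux += tk[i] * u * x[i];
        }
        double mu_new = swux / swu;
        double ss = 0;
        for (int i = 0; i < n; ++i) {
          double z = (x[i] - mu[kk]) / sigma[kk];
          double u = (nu[kk] + 1) / (nu[kk] + z * z);
          ss += tk[i] * u * (x[i] - mu_new) * (x[i] - mu_new);
        }
        mu[kk] = mu_new;
        sigma[kk] = std::max(std::sqrt(ss / nk[kk]), SIGMA_FLOOR);
        // nu update from fresh latent scale weights
        double acc = 0;
        for (int i = 0; i < n; ++i) {
          double z = (x[i] - mu[kk]) / sigma[kk];
          double u = (nu[kk] + 1) / (nu[kk] + z * z);
          acc += tk[i] * (std::log(u) - u);
        }
        double cst = acc / nk[kk] + R::digamma((nu[kk] + 1) / 2) -
                     std::log((nu[kk] + 1) / 2);
        double flo = nu_equation(NU_LO, cst), fhi = nu_equation(NU_HI, cst);
        if (flo <= 0) nu[kk] = NU_LO;
        else if (fhi >= 0) nu[kk] = NU_HI;
        else {
          double a = NU_LO, b = NU_HI;
          for (int s = 0; s < 60; ++s) {
            double mid = (a + b) / 2;
            if (nu_equation(mid, cst) > 0) a = mid; else b = mid;
          }
          nu[kk] = (a + b) / 2;
        }
      }
    }
  }
  // hard assignment sizes for the degenerate-spike guard
  int h1 = 0;
  for (int i = 0; i < n; ++i) if (tau[i] >= 0.5) ++h1;
  if (std::min(h1, n - h1) < 2) ok = false;
  return List::create(_["weight"] = NumericVector::create(pi2[0], pi2[1]),
                      _["mu"] = NumericVector::create(mu[0], mu[1]),
                      _["sigma"] = NumericVector::create(sigma[0], sigma[1]),
                      _["nu"] = NumericVector::create(nu[0], nu[1]),
                      _["loglik"] = ll, _["ok"] = ok);
}
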