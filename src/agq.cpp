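#include <Rcpp.h>
using namespace Rcpp;

// Marginal (negative) log-likelihood of a random-intercept logistic model,
// integrated by adaptive Gauss-Hermite quadrature, plus its gradient.
//
// par         : c(beta, log_sigma) where beta has ncol(X) elements
// X           : fixed-effect design matrix, rows ordered by cluster
// y           : 0/1 outcome
// grp_start   : 0-based first row of each cluster
// grp_size    : rows per cluster
// z, w        : Gauss-Hermite nodes/weights for weight exp(-z^2)
//               (a single node z=0, w=sqrt(pi) gives the Laplace
//               approximation)
//
// Per cluster the integrand mode u* is found by Newton iterations on
// h(u) = sum_j [y eta - log(1+exp(eta))] - u^2/(2 sigma^2) - log(sigma)
//        - 0.5 log(2 pi),
// then  log int exp(h(u)) du
//    ~= log(sqrt(2) s) + logsumexp_k( log w_k + z_k^2 + h(u* + sqrt(2) s z_k) )
// with s = (-h''(u*))^{-1/2}.

static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// mode of the cluster integrand; returns u*, sets H = -h''(u*)
static double cluster_mode(const std::vector<double>& eta0,
                           const NumericVector& y, int a, int m,
                           double inv_s2, double& H) {
  double u = 0.0;
  H = inv_s2;
  for (int it = 0; it < 50; ++it) {
    double s1 = 0.0, s2 = 0.0;
    for (int j = a; j < a + m; ++j) {
      double pr = 1.0 / (1.0 + std::exp(-(eta0[j] + u)));
      s1 += y[j] - pr;
      s2 += pr * (1.0 - pr);
    }
    double grad = s1 - u * inv_s2;
    H = s2 + inv_s2;
    double step = grad / H;
    u += step;
    if (std::fabs(step) < 1e-11) break;
  }
  return u;
}

static double nll_impl(const double* par, const NumericMatrix& X,
                       const NumericVector& y,
                       const IntegerVector& grp_start,
                       const IntegerVector& grp_size,
                       const NumericVector& z, const NumericVector& w) {
  const int n = X.nrow(), p = X.ncol(), G = grp_start.size(), K = z.size();
  const double log_sigma = par[p];
  const double sigma = std::exp(log_sigma);
  const double inv_s2 = 1.0 / (sigma * sigma);
  const double l2pi = std::log(2.0 * M_PI);

  std::vector<double> eta0(n);
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += X(i, j) * par[j];
    eta0[i] = e;
  }

  double nll = 0.0;
  std::vector<double> lk(K);
  for (int g = 0; g < G; ++g) {
    const int a = grp_start[g], m = grp_size[g];
    double H;
    const double u = cluster_mode(eta0, y, a, m, inv_s2, H);
    const double s = 1.0 / std::sqrt(H);

    double lmax = -INFINITY;
    for (int k = 0; k < K; ++k) {
      const double uk = u + M_SQRT2 * s * z[k];
      double h = -0.5 * uk * uk * inv_s2 - log_sigma - 0.5 * l2pi;
      for (int j = a; j < a + m; ++j) {
        const double eta = eta0[j] + uk;
        h += y[j] * eta - softplus(eta);
      }
      lk[k] = std::log(w[k]) + z[k] * z[k] + h;
      if (lk[k] > lmax) lmax = lk[k];
    }
    double acc = 0.0;
    for (int k = 0; k < K; ++k) acc += std::exp(lk[k] - lmax);
    nll -= 0.5 * std::log(2.0) + std::log(s) + lmax + std::log(acc);
  }
  return nll;
}

// [[Rcpp::export]]
double agq_nll(NumericVector par, NumericMatrix X, NumericVector y,
               IntegerVector grp_start, IntegerVector grp_size,
               NumericVector z, NumericVector w) {
  return nll_impl(REAL(par), X, y, grp_start, grp_size, z, w);
}

// Exact gradient of the negative log-likelihood, differentiating through
// the adaptive nodes u_k = u* + sqrt(2) s z_k. With
// pi_k = softmax(log w_k + z_k^2 + h(u_k)) the cluster contribution is
//   d ll / d theta = sum_k pi_k [ h'(u_k) (du*/dtheta + sqrt(2) z_k ds/dtheta)
//                                 + (dh/dtheta)(u_k) ] + (1/s) ds/dtheta,
// where du*/dtheta follows from the mode equation h'(u*) = 0,
// ds/dtheta = -(s / 2H) dH/dtheta, and dH/dtheta is the total derivative of
// the curvature at the mode. For K = 1 (z = 0, h'(u*) = 0) this reduces to
// the familiar Laplace gradient.
// [[Rcpp::export]]
NumericVector agq_nll_grad(NumericVector par, NumericMatrix X,
                           NumericVector y, IntegerVector grp_start,
                           IntegerVector grp_size, NumericVector z,
                           NumericVector w) {
  const int n = X.nrow(), p = X.ncol(), G = grp_start.size(), K = z.size();
  const double log_sigma = par[p];
  const double sigma = std::exp(log_sigma);
  const double inv_s2 = 1.0 / (sigma * sigma);
  NumericVector grad(p + 1);

  std::vector<double> eta0(n);
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += X(i, j) * par[j];
    eta0[i] = e;
  }

  std::vector<double> lk(K), hp(K), dls(K);
  std::vector<double> db(K * p);

  for (int g = 0; g < G; ++g) {
    const int a = grp_start[g], m = grp_size[g];
    double H;
    const double u = cluster_mode(eta0, y, a, m, inv_s2, H);
    const double s = 1.0 / std::sqrt(H);

    // sums at the mode, for du*/dtheta and dH/dtheta
    double Wp = 0.0; // sum p(1-p)(1-2p)
    std::vector<double> sw(p, 0.0), swp(p, 0.0);
    for (int j = a; j < a + m; ++j) {
      const double pr = 1.0 / (1.0 + std::exp(-(eta0[j] + u)));
      const double wj = pr * (1.0 - pr);
      const double wpj = wj * (1.0 - 2.0 * pr);
      Wp += wpj;
      for (int k = 0; k < p; ++k) {
        sw[k] += wj * X(j, k);
        swp[k] += wpj * X(j, k);
      }
    }

    // per-node log-integrand, h'(u_k), and partials of h at fixed u_k
    double lmax = -INFINITY;
    for (int k = 0; k < K; ++k) {
      const double uk = u + M_SQRT2 * s * z[k];
      double h = -0.5 * uk * uk * inv_s2 - log_sigma -
        0.5 * std::log(2.0 * M_PI);
      double hprime = -uk * inv_s2;
      for (int c = 0; c < p; ++c) db[k * p + c] = 0.0;
      for (int j = a; j < a + m; ++j) {
        const double eta = eta0[j] + uk;
        const double pr = 1.0 / (1.0 + std::exp(-eta));
        h += y[j] * eta - softplus(eta);
        hprime += y[j] - pr;
        for (int c = 0; c < p; ++c) db[k * p + c] += (y[j] - pr) * X(j, c);
      }
      lk[k] = std::log(w[k]) + z[k] * z[k] + h;
      hp[k] = hprime;
      dls[k] = uk * uk * inv_s2 - 1.0;
      if (lk[k] > lmax) lmax = lk[k];
    }
    double norm = 0.0;
    for (int k = 0; k < K; ++k) {
      lk[k] = std::exp(lk[k] - lmax);
      norm += lk[k];
    }

    // assemble: beta directions, then log-sigma
    for (int c = 0; c < p; ++c) {
      const double dustar = -sw[c] / H;
      const double dH = swp[c] + Wp * dustar;
      const double ds = -0.5 * s * dH / H;
      double acc = 0.0;
      for (int k = 0; k < K; ++k) {
        const double duk = dustar + M_SQRT2 * z[k] * ds;
        acc += lk[k] * (hp[k] * duk + db[k * p + c]);
      }
      grad[c] -= acc / norm + ds / s;
    }
    {
      const double dustar = (2.0 * u * inv_s2) / H;
      const double dH = -2.0 * inv_s2 + Wp * dustar;
      const double ds = -0.5 * s * dH / H;
      double acc = 0.0;
      for (int k = 0; k < K; ++k) {
        const double duk = dustar + M_SQRT2 * z[k] * ds;
        acc += lk[k] * (hp[k] * duk + dls[k]);
      }
      grad[p] -= acc / norm + ds / s;
    }
  }
  return grad;
}

// Ordinary (no random intercept) Bernoulli negative log-likelihood,
// used as the sigma -> 0 limit and for cheap warm starts.
// [[Rcpp::export]]
double logistic_nll(NumericVector beta, NumericMatrix X, NumericVector y) {
  const int n = X.nrow(), p = X.ncol();
  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
    nll -= y[i] * e - softplus(e);
  }
  return nll;
}
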