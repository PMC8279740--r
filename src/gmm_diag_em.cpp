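#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Diagonal-covariance Gaussian mixture fitted by EM with k-means++
// initialization, run over many replicates; the replicate with the largest
// log-likelihood wins. RNG is R's own stream, so set.seed() in R controls
// every draw.

// squared Euclidean distance
static double sqdist(const double *a, const double *b, int d) {
  double s = 0.0;
  for (int j = 0; j < d; ++j) {
    double z = a[j] - b[j];
    s += z * z;
  }
  return s;
}

// k-means++ seeding: first center uniform, then proportional to squared
// distance to the nearest chosen center.
static void kmeanspp(const std::vector<double> &X, int n, int d, int K,
                     std::vector<double> &centers) {
  std::vector<double> d2(n);
  int first = (int)std::floor(unif_rand() * n);
  if (first >= n) first = n - 1;
  for (int j = 0; j < d; ++j) centers[j] = X[first * d + j];
  for (int i = 0; i < n; ++i)
    d2[i] = sqdist(&X[i * d], &centers[0], d);
  for (int k = 1; k < K; ++k) {
    double tot = 0.0;
    for (int i = 0; i < n; ++i) tot += d2[i];
    int pick;
    if (tot <= 0.0) {
      pick = (int)std::floor(unif_rand() * n);
      if (pick >= n) pick = n - 1;
    } else {
      double u = unif_rand() * tot, cum = 0.0;
      pick = n - 1;
      for (int i = 0; i < n; ++i) {
        cum += d2[i];
        if (u <= cum) { pick = i; break; }
      }
    }
    for (int j = 0; j < d; ++j) centers[k * d + j] = X[pick * d + j];
    for (int i = 0; i < n; ++i) {
      double dd = sqdist(&X[i * d], &centers[k * d], d);
      if (dd < d2[i]) d2[i] = dd;
    }
  }
}

// [[Rcpp::export(name = ".gmm_diag_em")]]
List gmm_diag_em(NumericMatrix X_, int K, int n_replicates, int max_iter,
                 double tol, double var_floor) {
  const int n = X_.nrow(), d = X_.ncol();
  if (K < 1) stop("K must be >= 1");
  if (K > n) stop("K exceeds the number of data points");

  std::vector<double> X(n * d);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j) X[i * d + j] = X_(i, j);

  // overall per-dimension variance as a fallback/floor reference
  std::vector<double> gvar(d, 0.0), gmean(d, 0.0);
  for (int j = 0; j < d; ++j) {
    for (int i = 0; i < n; ++i) gmean[j] += X[i * d + j];
    gmean[j] /= n;
    for (int i = 0; i < n; ++i) {
      double z = X[i * d + j] - gmean[j];
      gvar[j] += z * z;
    }
    gvar[j] = std::max(gvar[j] / std::max(n - 1, 1), var_floor);
  }

  std::vector<double> best_mu, best_var, best_w;
  double best_ll = -std::numeric_limits<double>::infinity();
  bool best_floored = false;
  int best_iters = 0;

  std::vector<double> mu(K * d), var(K * d), w(K);
  std::vector<double> logresp(n * K);
  std::vector<int> assign(n);

  for (int rep = 0; rep < n_replicates; ++rep) {
    // --- initialization ---
    kmeanspp(X, n, d, K, mu);
    for (int i = 0; i < n; ++i) {
      double dmin = std::numeric_limits<double>::infinity();
      int amin = 0;
      for (int k = 0; k < K; ++k) {
        double dd = sqdist(&X[i * d], &mu[k * d], d);
        if (dd < dmin) { dmin = dd; amin = k; }
      }
      assign[i] = amin;
    }
    std::vector<int> cnt(K, 0);
    std::fill(var.begin(), var.end(), 0.0);
    std::vector<double> cmean(K * d, 0.0);
    for (int i = 0; i < n; ++i) {
      cnt[assign[i]]++;
      for (int j = 0; j < d; ++j) cmean[assign[i] * d + j] += X[i * d + j];
    }
    for (int k = 0; k < K; ++k) {
      if (cnt[k] > 0)
        for (int j = 0; j < d; ++j) {
          cmean[k * d + j] /= cnt[k];
          mu[k * d + j] = cmean[k * d + j];
        }
      w[k] = std::max(cnt[k], 1) / (double)n;
    }
    {
      double wsum = 0.0;
      for (int k = 0; k < K; ++k) wsum += w[k];
      for (int k = 0; k < K; ++k) w[k] /= wsum;
    }
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < d; ++j) {
        double z = X[i * d + j] - mu[assign[i] * d + j];
        var[assign[i] * d + j] += z * z;
      }
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < d; ++j) {
        if (cnt[k] > 1)
          var[k * d + j] = std::max(var[k * d + j] / (cnt[k] - 1), var_floor);
        else
          var[k * d + j] = gvar[j];
      }

    // --- EM iterations ---
    double ll_prev = -std::numeric_limits<double>::infinity(), ll = ll_prev;
    bool floored = false;
    int it = 0;
    std::vector<double> lconst(K), ivar(K * d);
    for (it = 0; it < max_iter; ++it) {
      // per-component constants hoisted out of the point loop
      for (int k = 0; k < K; ++k) {
        double c = std::log(w[k]);
        for (int j = 0; j < d; ++j) {
          c -= 0.5 * std::log(2.0 * M_PI * var[k * d + j]);
          ivar[k * d + j] = 1.0 / var[k * d + j];
        }
        lconst[k] = c;
      }
      // E step with log-sum-exp
      ll = 0.0;
      for (int i = 0; i < n; ++i) {
        double m = -std::numeric_limits<double>::infinity();
        for (int k = 0; k < K; ++k) {
          double q = 0.0;
          for (int j = 0; j < d; ++j) {
            double z = X[i * d + j] - mu[k * d + j];
            q += z * z * ivar[k * d + j];
          }
          double lr = lconst[k] - 0.5 * q;
          logresp[i * K + k] = lr;
          if (lr > m) m = lr;
        }
        double s = 0.0;
        for (int k = 0; k < K; ++k) s += std::exp(logresp[i * K + k] - m);
        double lse = m + std::log(s);
        ll += lse;
        for (int k = 0; k < K; ++k)
          logresp[i * K + k] = std::exp(logresp[i * K + k] - lse);
      }
      if (std::abs(ll - ll_prev) < tol * (1.0 + std::abs(ll))) { ll_prev = ll; break; }
      ll_prev = ll;
      // M step
      for (int k = 0; k < K; ++k) {
        double nk = 0.0;
        for (int i = 0; i < n; ++i) nk += logresp[i * K + k];
        w[k] = std::max(nk, 1e-300) / n;
        for (int j = 0; j < d; ++j) {
          double m1 = 0.0;
          for (int i = 0; i < n; ++i) m1 += logresp[i * K + k] * X[i * d + j];
          m1 /= std::max(nk, 1e-300);
          double v = 0.0;
          for (int i = 0; i < n; ++i) {
            double z = X[i * d + j] - m1;
            v += logresp[i * K + k] * z * z;
          }
          v /= std::max(nk, 1e-300);
          mu[k * d + j] = m1;
          if (v < var_floor) { v = var_floor; floored = true; }
          var[k * d + j] = v;
        }
      }
      double wsum = 0.0;
      for (int k = 0; k < K; ++k) wsum += w[k];
      for (int k = 0; k < K; ++k) w[k] /= wsum;
    }

    if (ll_prev > best_ll) {
      best_ll = ll_prev;
      best_mu = mu;
      best_var = var;
      best_w = w;
      best_floored = floored;
      best_iters = it;
    }
  }

  NumericMatrix mu_out(K, d), var_out(K, d);
  NumericVector w_out(K);
  for (int k = 0; k < K; ++k) {
    w_out[k] = best_w[k];
    for (int j = 0; j < d; ++j) {
      mu_out(k, j) = best_mu[k * d + j];
      var_out(k, j) = best_var[k * d + j];
    }
  }
  return List::create(_["means"] = mu_out, _["variances"] = var_out,
                      _["weights"] = w_out, _["loglik"] = best_ll,
                      _["n_iter"] = best_iters,
                      _["variance_floored"] = best_floored);
}
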