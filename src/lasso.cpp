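#include <Rcpp.h>
using namespace Rcpp;

// L1-penalised weighted logistic regression path by IRLS + cyclic
// coordinate descent on the working (quadratic) approximation, with warm
// starts along a descending penalty grid and active-set iteration.
//
// Objective at lambda: (1/W) * sum_i wobs_i * nll_i(b0, beta) +
//                      lambda * sum_j |beta_j|,   W = sum_i wobs_i.
// The intercept is unpenalised. lambda = 0 gives the (weighted) MLE.
// Binary design columns are exploited: per-coordinate sums run over the
// rows where x_ij = 1 only (a general dense fallback covers other X).

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// [[Rcpp::export]]
List cpp_logistic_lasso_path(NumericMatrix X, NumericVector y,
                             NumericVector wobs, NumericVector lambdas,
                             double tol, int maxit) {
  const int n = X.nrow(), k = X.ncol(), L = lambdas.size();
  double W = 0.0;
  for (int i = 0; i < n; ++i) W += wobs[i];
  if (W <= 0) stop("observation weights must sum to a positive value");

  // binary-column row lists (empty list -> dense fallback for that column)
  std::vector<std::vector<int>> rows(k);
  std::vector<bool> is01(k, true);
  for (int j = 0; j < k; ++j) {
    for (int i = 0; i < n; ++i) {
      double v = X(i, j);
      if (v == 1.0) rows[j].push_back(i);
      else if (v != 0.0) { is01[j] = false; break; }
    }
    if (!is01[j]) rows[j].clear();
  }

  NumericMatrix betas(k, L);
  NumericVector b0s(L), logliks(L);
  IntegerVector iters(L);
  LogicalVector conv(L), diverged(L);

  std::vector<double> beta(k, 0.0), eta(n), w(n), z(n), r(n), dj(k);
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += wobs[i] * y[i];
  ybar /= W;
  ybar = std::min(std::max(ybar, 1e-10), 1.0 - 1e-10);
  double b0 = std::log(ybar / (1.0 - ybar));
  for (int i = 0; i < n; ++i) eta[i] = b0;
  const double outer_tol = std::max(10.0 * tol, 1e-13);

  for (int l = 0; l < L; ++l) {
    const double lam = lambdas[l];
    bool ok = false;
    int used = 0;
    const int max_outer = 50;
    for (int outer = 0; outer < max_outer; ++outer) {
      // quadratic approximation at the current eta
      double sw = 0.0;
      for (int i = 0; i < n; ++i) {
        double p = 1.0 / (1.0 + std::exp(-eta[i]));
        double v = p * (1.0 - p);
        if (v < 1e-9) v = 1e-9;
        w[i] = wobs[i] * v;
        z[i] = eta[i] + (y[i] - p) / v;
        r[i] = z[i] - eta[i];
        sw += w[i];
      }
      for (int j = 0; j < k; ++j) {
        double d = 0.0;
        if (is01[j]) {
          for (int i : rows[j]) d += w[i];
        } else {
          for (int i = 0; i < n; ++i) d += w[i] * X(i, j) * X(i, j);
        }
        dj[j] = d;
      }
      // coordinate descent
      std::vector<char> active(k, 0);
      for (int j = 0; j < k; ++j) active[j] = (beta[j] != 0.0);
      bool cd_ok = false, full_pass = true;
      int cycles = 0;
      while (cycles < maxit) {
        // convergence metric: weighted quadratic change dj * delta^2 / W
        double maxd = 0.0;
        {
          double num = 0.0;
          for (int i = 0; i < n; ++i) num += w[i] * r[i];
          double delta = num / sw;
          if (delta != 0.0) {
            b0 += delta;
            for (int i = 0; i < n; ++i) r[i] -= delta;
            maxd = std::max(maxd, sw * delta * delta / W);
          }
        }
        for (int j = 0; j < k; ++j) {
          if (!full_pass && !active[j]) continue;
          if (dj[j] <= 0.0) { beta[j] = 0.0; continue; }
          double num = 0.0;
          if (is01[j]) {
            for (int i : rows[j]) num += w[i] * r[i];
          } else {
            for (int i = 0; i < n; ++i) num += w[i] * X(i, j) * r[i];
          }
          num += beta[j] * dj[j];
          double bnew = soft(num, lam * W) / dj[j];
          double delta = bnew - beta[j];
          if (delta != 0.0) {
            beta[j] = bnew;
            if (is01[j]) {
              for (int i : rows[j]) r[i] -= delta;
            } else {
              for (int i = 0; i < n; ++i) r[i] -= delta * X(i, j);
            }
            maxd = std::max(maxd, dj[j] * delta * delta / W);
          }
          active[j] = (beta[j] != 0.0);
        }
        ++cycles;
        if (maxd < tol) {
          if (full_pass) { cd_ok = true; break; }
          full_pass = true;          // verify KKT with one full pass
        } else {
          full_pass = false;         // iterate the active set
        }
      }
      used += cycles;
      // new linear predictor; outer convergence on its change
      double out_delta = 0.0;
      for (int i = 0; i < n; ++i) {
        double e = z[i] - r[i];
        double d = e - eta[i];
        out_delta = std::max(out_delta, w[i] * d * d / W);
        eta[i] = e;
      }
      if (cd_ok && out_delta < outer_tol) { ok = true; break; }
      if (used >= maxit) break;
    }
    // clamp numerical dust (KKT equality at lambda_max leaves O(eps)
    // coefficients that would otherwise masquerade as edges)
    for (int j = 0; j < k; ++j) {
      if (beta[j] != 0.0 && std::fabs(beta[j]) < 1e-8) {
        double delta = -beta[j];
        beta[j] = 0.0;
        if (is01[j]) {
          for (int i : rows[j]) { r[i] -= delta; eta[i] += delta; }
        } else {
          for (int i = 0; i < n; ++i) {
            r[i] -= delta * X(i, j);
            eta[i] += delta * X(i, j);
          }
        }
      }
    }
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double p = 1.0 / (1.0 + std::exp(-eta[i]));
      p = std::min(std::max(p, 1e-12), 1.0 - 1e-12);
      ll += wobs[i] * (y[i] * std::log(p) + (1.0 - y[i]) * std::log(1.0 - p));
    }
    for (int j = 0; j < k; ++j) betas(j, l) = beta[j];
    b0s[l] = b0;
    logliks[l] = ll;
    iters[l] = used;
    conv[l] = ok;
    double mx = std::fabs(b0);
    for (int j = 0; j < k; ++j) mx = std::max(mx, std::fabs(beta[j]));
    diverged[l] = (mx > 30.0);
  }
  return List::create(_["beta0"] = b0s, _["beta"] = betas,
                      _["loglik"] = logliks, _["iterations"] = iters,
                      _["converged"] = conv, _["diverged"] = diverged);
}
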