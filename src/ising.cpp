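#include <Rcpp.h>
using namespace Rcpp;

// Binary {0,1} Ising model, log-odds parameterisation:
//   P(x) proportional to exp(sum_i tau_i x_i + sum_{i<j} omega_ij x_i x_j)
// Enumeration walks states in Gray-code order (one bit flip per step, the
// energy updated in O(#active nodes)); states are tracked as bitmasks.

static inline int trailing_zeros(unsigned long k) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_ctzl(k);
#else
  int b = 0;
  while (!(k & 1UL)) { k >>= 1; ++b; }
  return b;
#endif
}

// Energy change when bit b of state `mask` flips.
static inline double flip_delta(unsigned long mask, int b,
                                const double* tau, const double* om, int p) {
  double d = tau[b];
  const double* row = om + (size_t)b * p;
  unsigned long m = mask & ~(1UL << b);
  while (m) {
    int j = trailing_zeros(m);
    d += row[j];
    m &= m - 1;
  }
  return (mask >> b) & 1UL ? -d : d;
}

// [[Rcpp::export]]
NumericVector cpp_ising_pmf(NumericVector tau, NumericMatrix omega) {
  const int p = tau.size();
  if (p < 1 || p > 21) stop("enumeration limited to 1 <= p <= 21");
  const unsigned long S = 1UL << p;
  NumericVector out((R_xlen_t)S);
  const double* tp = tau.begin();
  const double* om = omega.begin();   // column-major == row-major (symmetric)
  double E = 0.0, Z = 1.0;
  unsigned long g = 0;
  out[0] = 1.0;
  for (unsigned long k = 1; k < S; ++k) {
    int b = trailing_zeros(k);
    E += flip_delta(g, b, tp, om, p);
    g ^= (1UL << b);
    double w = std::exp(E);
    out[(R_xlen_t)g] = w;
    Z += w;
  }
  for (R_xlen_t i = 0; i < (R_xlen_t)S; ++i) out[i] /= Z;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_ising_marginals(NumericVector tau, NumericMatrix omega) {
  const int p = tau.size();
  if (p < 1 || p > 21) stop("enumeration limited to 1 <= p <= 21");
  const unsigned long S = 1UL << p;
  const double* tp = tau.begin();
  const double* om = omega.begin();
  std::vector<double> M(p, 0.0);
  double E = 0.0, Z = 1.0;
  unsigned long g = 0;
  for (unsigned long k = 1; k < S; ++k) {
    int b = trailing_zeros(k);
    E += flip_delta(g, b, tp, om, p);
    g ^= (1UL << b);
    double w = std::exp(E);
    Z += w;
    unsigned long m = g;
    while (m) {
      int i = trailing_zeros(m);
      M[i] += w;
      m &= m - 1;
    }
  }
  NumericVector out(p);
  for (int i = 0; i < p; ++i) out[i] = M[i] / Z;
  return out;
}

// Marginal of a single node by enumeration over the other p-1 nodes:
// P(x_i = 1) = e^{tau_i} A / (e^{tau_i} A + B), where A and B sum
// exp(energy of the others + coupling to i) and exp(energy of the others).
static double marginal_node(const NumericVector& tau,
                            const NumericMatrix& omega, int node) {
  const int p = tau.size();
  std::vector<double> t2(p - 1), orow(p - 1);
  std::vector<int> map(p - 1);
  int q = 0;
  for (int j = 0; j < p; ++j)
    if (j != node) { t2[q] = tau[j]; orow[q] = omega(node, j); map[q] = j; ++q; }
  // reduced omega (others x others), row-major
  std::vector<double> om2((size_t)(p - 1) * (p - 1));
  for (int a = 0; a < p - 1; ++a)
    for (int b = 0; b < p - 1; ++b)
      om2[(size_t)a * (p - 1) + b] = omega(map[a], map[b]);
  const int m = p - 1;
  const unsigned long S = 1UL << m;
  double E = 0.0, C = 0.0, A = 1.0, B = 1.0;  // empty state: E=0, C=0
  A = 1.0; B = 1.0;                           // exp(0+0), exp(0)
  unsigned long g = 0;
  for (unsigned long k = 1; k < S; ++k) {
    int b = trailing_zeros(k);
    double d = t2[b];
    const double* row = om2.data() + (size_t)b * m;
    unsigned long mm = g & ~(1UL << b);
    while (mm) {
      int j = trailing_zeros(mm);
      d += row[j];
      mm &= mm - 1;
    }
    if ((g >> b) & 1UL) { E -= d; C -= orow[b]; }
    else { E += d; C += orow[b]; }
    g ^= (1UL << b);
    double w = std::exp(E);
    B += w;
    A += w * std::exp(C);
  }
  double et = std::exp(tau[node]);
  return et * A / (et * A + B);
}

// Rounds of exact monotone coordinate updates on tau so that each node's
// marginal endorsement rate reaches its target (the closed-form limit of a
// per-node bisection: the node's marginal is logistic in its own tau).
// Marginals are recomputed by enumeration once per round.
// [[Rcpp::export]]
List cpp_calibrate_tau(NumericVector tau, NumericMatrix omega,
                       NumericVector target, double tol, int max_rounds) {
  const int p = tau.size();
  NumericVector t = clone(tau);
  NumericVector marg(p);
  double worst = R_PosInf;
  int round = 0;
  // Gauss-Seidel sweeps: each node's threshold is solved exactly in turn
  // (its marginal is logistic in tau_i, so the monotone bisection limit
  // has the closed form below), the marginal refreshed per node.
  for (round = 0; round < max_rounds; ++round) {
    marg = cpp_ising_marginals(t, omega);
    worst = 0.0;
    for (int i = 0; i < p; ++i)
      worst = std::max(worst, std::fabs(marg[i] - target[i]));
    if (worst <= tol) break;
    for (int i = 0; i < p; ++i) {
      double m = (p > 1) ? marginal_node(t, omega, i) : (double)marg[i];
      m = std::min(std::max(m, 1e-12), 1.0 - 1e-12);
      double ti = std::min(std::max((double)target[i], 1e-12), 1.0 - 1e-12);
      t[i] += std::log(ti / (1.0 - ti)) - std::log(m / (1.0 - m));
    }
  }
  return List::create(_["tau"] = t, _["marginals"] = marg,
                      _["rounds"] = round, _["worst"] = worst,
                      _["converged"] = (worst <= tol));
}

// Single-site Gibbs sampler using R's RNG (deterministic under set.seed()).
// [[Rcpp::export]]
IntegerMatrix cpp_ising_gibbs(NumericVector tau, NumericMatrix omega,
                              int n, int burnin, int thin) {
  const int p = tau.size();
  if (thin < 1) stop("thin must be >= 1");
  IntegerMatrix out(n, p);
  std::vector<int> x(p);
  // neighbour lists: couplings are typically sparse
  std::vector<std::vector<std::pair<int, double>>> nb(p);
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (j != i && omega(i, j) != 0.0) nb[i].push_back({j, omega(i, j)});
  for (int i = 0; i < p; ++i) x[i] = (unif_rand() < 0.5) ? 1 : 0;
  auto sweep = [&]() {
    for (int i = 0; i < p; ++i) {
      double eta = tau[i];
      for (auto& e : nb[i])
        if (x[e.first]) eta += e.second;
      double pr = 1.0 / (1.0 + std::exp(-eta));
      x[i] = (unif_rand() < pr) ? 1 : 0;
    }
  };
  for (int b = 0; b < burnin; ++b) sweep();
  for (int s = 0; s < n; ++s) {
    for (int tt = 0; tt < thin; ++tt) sweep();
    for (int i = 0; i < p; ++i) out(s, i) = x[i];
  }
  return out;
}
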