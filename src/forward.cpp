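#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward recursion on a log-density matrix.
// logdens: T x K per-observation emission log densities (missing metrics
// already marginalized out in R); Gamma: K x K row-stochastic TPM;
// delta: initial state distribution. Returns the sequence log likelihood.
// [[Rcpp::export]]
double forward_loglik_cpp(NumericMatrix logdens, NumericMatrix Gamma,
                          NumericVector delta) {
  int T = logdens.nrow(), K = logdens.ncol();
  std::vector<double> phi(K), tmp(K);
  double ll = 0.0;
  // rescale emission weights by their row max for numerical stability
  double m0 = logdens(0, 0);
  for (int k = 1; k < K; ++k) m0 = std::max(m0, logdens(0, k));
  double s = 0.0;
  for (int k = 0; k < K; ++k) {
    phi[k] = delta[k] * std::exp(logdens(0, k) - m0);
    s += phi[k];
  }
  if (s <= 0.0) return R_NegInf;
  ll += std::log(s) + m0;
  for (int k = 0; k < K; ++k) phi[k] /= s;
  for (int t = 1; t < T; ++t) {
    double mt = logdens(t, 0);
    for (int k = 1; k < K; ++k) mt = std::max(mt, logdens(t, k));
    s = 0.0;
    for (int j = 0; j < K; ++j) {
      double a = 0.0;
      for (int i = 0; i < K; ++i) a += phi[i] * Gamma(i, j);
      tmp[j] = a * std::exp(logdens(t, j) - mt);
      s += tmp[j];
    }
    if (s <= 0.0) return R_NegInf;
    ll += std::log(s) + mt;
    for (int k = 0; k < K; ++k) phi[k] = tmp[k] / s;
  }
  return ll;
}

// Viterbi decoding in log space. Returns 1-based state indices.
// [[Rcpp::export]]
IntegerVector viterbi_cpp(NumericMatrix logdens, NumericMatrix Gamma,
                          NumericVector delta) {
  int T = logdens.nrow(), K = logdens.ncol();
  NumericMatrix v(T, K);
  IntegerMatrix bp(T, K);
  const double NEG = -1e300;
  for (int k = 0; k < K; ++k) {
    double ld = delta[k] > 0 ? std::log(delta[k]) : NEG;
    v(0, k) = ld + logdens(0, k);
  }
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = NEG;
      int arg = 0;
      for (int i = 0; i < K; ++i) {
        double lg = Gamma(i, j) > 0 ? std::log(Gamma(i, j)) : NEG;
        double cand = v(t - 1, i) + lg;
        if (cand > best) { best = cand; arg = i; }
      }
      v(t, j) = best + logdens(t, j);
      bp(t, j) = arg;
    }
  }
  IntegerVector path(T);
  double best = NEG;
  int arg = 0;
  for (int k = 0; k < K; ++k) {
    if (v(T - 1, k) > best) { best = v(T - 1, k); arg = k; }
  }
  path[T - 1] = arg + 1;
  for (int t = T - 1; t > 0; --t) {
    arg = bp(t, arg);
    path[t - 1] = arg + 1;
  }
  return path;
}

// Full mixed-HMM log likelihood for one animal from cached data.
// X: n x M metric matrix (NA = missing); fam: 0 gaussian, 1 beta,
// 2 bernoulli per metric; pars: list of parameter matrices (rows:
// mean/sd, shape1/shape2 or prob; one column per state); Gammas/deltas:
// per-context transition matrices and initial distributions; logw:
// log context weights. Per-metric terms are floored at `floor_nats`.
// [[Rcpp::export]]
double mixedhmm_loglik_cpp(NumericMatrix X, IntegerVector fam, List pars,
                           List Gammas, List deltas, NumericVector logw,
                           double floor_nats) {
  const int n = X.nrow(), M = X.ncol();
  const int C = Gammas.size();
  NumericMatrix par0 = pars[0];
  const int K = par0.ncol();
  const double LOG2PI_2 = 0.9189385332046727;
  NumericMatrix ld(n, K);
  for (int m = 0; m < M; ++m) {
    NumericMatrix p = pars[m];
    for (int k = 0; k < K; ++k) {
      double a = p(0, k);
      double b = (p.nrow() > 1) ? p(1, k) : 0.0;
      double lga = 0.0, lp = 0.0, l1p = 0.0;
      if (fam[m] == 1) lga = R::lbeta(a, b);
      if (fam[m] == 2) { lp = std::log(a); l1p = std::log1p(-a); }
      for (int t = 0; t < n; ++t) {
        double x = X(t, m);
        if (ISNAN(x)) continue;
        double term;
        if (fam[m] == 0) {
          double z = (x - a) / b;
          term = -0.5 * z * z - std::log(b) - LOG2PI_2;
        } else if (fam[m] == 1) {
          term = (a - 1.0) * std::log(x) + (b - 1.0) * std::log1p(-x) - lga;
        } else {
          term = (x == 1.0) ? lp : l1p;
        }
        ld(t, k) += (term > floor_nats) ? term : floor_nats;
      }
    }
  }
  // log sum over contexts of (log weight + forward loglik)
  double best = R_NegInf;
  std::vector<double> lls(C);
  for (int c = 0; c < C; ++c) {
    NumericMatrix G = Gammas[c];
    NumericVector d = deltas[c];
    lls[c] = logw[c] + forward_loglik_cpp(ld, G, d);
    if (lls[c] > best) best = lls[c];
  }
  if (!R_FINITE(best)) return best;
  double s = 0.0;
  for (int c = 0; c < C; ++c) s += std::exp(lls[c] - best);
  return best + std::log(s);
}

// Stationary distribution of a small row-stochastic matrix by Gaussian
// elimination on (I - G + 1)^T x = 1.
// [[Rcpp::export]]
NumericVector stationary_cpp(NumericMatrix G) {
  const int K = G.nrow();
  std::vector<std::vector<double>> A(K, std::vector<double>(K + 1));
  for (int i = 0; i < K; ++i) {
    for (int j = 0; j < K; ++j) {
      A[i][j] = ((i == j) ? 1.0 : 0.0) - G(j, i) + 1.0;
    }
    A[i][K] = 1.0;
  }
  for (int col = 0; col < K; ++col) {
    int piv = col;
    for (int r = col + 1; r < K; ++r) {
      if (std::fabs(A[r][col]) > std::fabs(A[piv][col])) piv = r;
    }
    std::swap(A[col], A[piv]);
    double d = A[col][col];
    if (d == 0.0) return NumericVector(K, 1.0 / K);
    for (int j = col; j <= K; ++j) A[col][j] /= d;
    for (int r = 0; r < K; ++r) {
      if (r == col) continue;
      double f = A[r][col];
      if (f == 0.0) continue;
      for (int j = col; j <= K; ++j) A[r][j] -= f * A[col][j];
    }
  }
  NumericVector out(K);
  double s = 0.0;
  for (int i = 0; i < K; ++i) { out[i] = A[i][K]; s += out[i]; }
  for (int i = 0; i < K; ++i) out[i] /= s;
  return out;
}

// Sum of mixedhmm_loglik_cpp over a list of per-animal metric matrices.
// [[Rcpp::export]]
double mixedhmm_total_loglik_cpp(List Xs, IntegerVector fam, List pars,
                                 List Gammas, List deltas, NumericVector logw,
                                 double floor_nats) {
  double total = 0.0;
  const int A = Xs.size();
  for (int a = 0; a < A; ++a) {
    NumericMatrix X = Xs[a];
    double ll = mixedhmm_loglik_cpp(X, fam, pars, Gammas, deltas, logw,
                                    floor_nats);
    if (!R_FINITE(ll)) return ll;
    total += ll;
  }
  return total;
}
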