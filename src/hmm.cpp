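#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for one contiguous observation block.
// logB: T x K emission log-densities, logpi: K initial log-probs,
// logA: K x K transition log-probs. Returns posteriors gamma (T x K),
// summed transition posteriors xi (K x K) and the block log-likelihood.
// [[Rcpp::export(name = ".fb_block")]]
List fb_block(NumericMatrix logB, NumericVector logpi, NumericMatrix logA) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix B(T, K);
  for (int t = 0; t < T; ++t) {
    double m = logB(t, 0);
    for (int k = 1; k < K; ++k) if (logB(t, k) > m) m = logB(t, k);
    for (int k = 0; k < K; ++k) B(t, k) = std::exp(logB(t, k) - m);
  }
  NumericMatrix A(K, K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) A(i, j) = std::exp(logA(i, j));

  NumericMatrix alpha(T, K), beta(T, K);
  NumericVector c(T);          // scaling factors
  double ll = 0.0;

  // forward
  double s = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha(0, k) = std::exp(logpi[k]) * B(0, k);
    s += alpha(0, k);
  }
  if (!(s > 0)) stop("non-finite likelihood in forward pass");
  c[0] = 1.0 / s;
  for (int k = 0; k < K; ++k) alpha(0, k) *= c[0];
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * A(j, k);
      a *= B(t, k);
      alpha(t, k) = a;
      s += a;
    }
    if (!(s > 0)) stop("non-finite likelihood in forward pass");
    c[t] = 1.0 / s;
    for (int k = 0; k < K; ++k) alpha(t, k) *= c[t];
  }
  // log-likelihood: sum of unscaled normalizers plus the row maxima
  for (int t = 0; t < T; ++t) {
    double m = logB(t, 0);
    for (int k = 1; k < K; ++k) if (logB(t, k) > m) m = logB(t, k);
    ll += -std::log(c[t]) + m;
  }

  // backward
  for (int k = 0; k < K; ++k) beta(T - 1, k) = c[T - 1];
  for (int t = T - 2; t >= 0; --t)
    for (int k = 0; k < K; ++k) {
      double b = 0.0;
      for (int j = 0; j < K; ++j) b += A(k, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, k) = b * c[t];
    }

  NumericMatrix gamma(T, K), xi(K, K);
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(t, k) = alpha(t, k) * beta(t, k) / c[t];
      g += gamma(t, k);
    }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }
  for (int t = 0; t < T - 1; ++t) {
    double z = 0.0;
    NumericMatrix x(K, K);
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j) {
        x(i, j) = alpha(t, i) * A(i, j) * B(t + 1, j) * beta(t + 1, j);
        z += x(i, j);
      }
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j) xi(i, j) += x(i, j) / z;
  }
  return List::create(_["gamma"] = gamma, _["xi"] = xi, _["loglik"] = ll);
}

// Viterbi decoding of one contiguous block; ties broken toward the lowest
// state index. Returns 1-based state labels.
// [[Rcpp::export(name = ".viterbi_block")]]
IntegerVector viterbi_block(NumericMatrix logB, NumericVector logpi,
                            NumericMatrix logA) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix d(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k) d(0, k) = logpi[k] + logB(0, k);
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf;
      int arg = 0;
      for (int j = 0; j < K; ++j) {
        double cand = d(t - 1, j) + logA(j, k);
        if (cand > best) { best = cand; arg = j; }   // strict: lowest j wins ties
      }
      d(t, k) = best + logB(t, k);
      psi(t, k) = arg;
    }
  IntegerVector path(T);
  double best = R_NegInf;
  int arg = 0;
  for (int k = 0; k < K; ++k)
    if (d(T - 1, k) > best) { best = d(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < T; ++t) path[t] += 1;
  return path;
}

// Markov chain driven by externally supplied uniforms (R's RNG), so that
// set.seed() in R controls the draw. Returns 1-based states.
// [[Rcpp::export(name = ".markov_chain")]]
IntegerVector markov_chain(NumericVector u, NumericVector pi, NumericMatrix A) {
  const int T = u.size(), K = pi.size();
  IntegerVector s(T);
  double acc = 0.0;
  int k = K - 1;
  for (int j = 0; j < K; ++j) { acc += pi[j]; if (u[0] <= acc) { k = j; break; } }
  s[0] = k;
  for (int t = 1; t < T; ++t) {
    acc = 0.0;
    int nk = K - 1;
    for (int j = 0; j < K; ++j) { acc += A(k, j); if (u[t] <= acc) { nk = j; break; } }
    k = nk;
    s[t] = k;
  }
  for (int t = 0; t < T; ++t) s[t] += 1;
  return s;
}

// Pairwise Hamming counts between rows of an integer matrix (signatures).
// [[Rcpp::export(name = ".hamming_matrix")]]
NumericMatrix hamming_matrix(IntegerMatrix x) {
  const int n = x.nrow(), R = x.ncol();
  NumericMatrix d(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int h = 0;
      for (int r = 0; r < R; ++r) if (x(i, r) != x(j, r)) ++h;
      d(i, j) = h;
      d(j, i) = h;
    }
  return d;
}
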