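#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for one observation sequence.
// B: T x K matrix of emission densities b_k(x_t); A: K x K transition
// probabilities; pi: initial distribution. Returns per-frame posteriors
// (gamma), summed pairwise posteriors (xi), and the log-likelihood.
// Rows of B that are all equal (e.g. masked frames set to 1) contribute
// nothing to parameter posteriors beyond the transition structure.
// [[Rcpp::export(name = ".fb_cpp")]]
List fb_cpp(NumericMatrix B, NumericMatrix A, NumericVector pi) {
  int T = B.nrow(), K = B.ncol();
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K);
  NumericVector c(T);
  double ll = 0.0;

  for (int k = 0; k < K; ++k) alpha(0, k) = pi[k] * B(0, k);
  double s = 0.0;
  for (int k = 0; k < K; ++k) s += alpha(0, k);
  if (s <= 0) stop("zero forward probability at frame 1");
  c[0] = 1.0 / s;
  for (int k = 0; k < K; ++k) alpha(0, k) *= c[0];
  ll -= std::log(c[0]);

  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * A(j, k);
      a *= B(t, k);
      alpha(t, k) = a;
      s += a;
    }
    if (s <= 0) stop("zero forward probability at frame %d", t + 1);
    c[t] = 1.0 / s;
    for (int k = 0; k < K; ++k) alpha(t, k) *= c[t];
    ll -= std::log(c[t]);
  }

  for (int k = 0; k < K; ++k) beta(T - 1, k) = c[T - 1];
  for (int t = T - 2; t >= 0; --t)
    for (int k = 0; k < K; ++k) {
      double b = 0.0;
      for (int j = 0; j < K; ++j) b += A(k, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, k) = b * c[t];
    }

  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(t, k) = alpha(t, k) * beta(t, k) / c[t];
      g += gamma(t, k);
    }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }

  NumericMatrix xi(K, K);
  for (int t = 0; t < T - 1; ++t) {
    double z = 0.0;
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        z += alpha(t, j) * A(j, k) * B(t + 1, k) * beta(t + 1, k);
    if (z <= 0) continue;
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi(j, k) += alpha(t, j) * A(j, k) * B(t + 1, k) * beta(t + 1, k) / z;
  }

  return List::create(_["gamma"] = gamma, _["xi"] = xi, _["loglik"] = ll);
}

// Viterbi decoding in log space. logB: T x K log emission densities;
// logA: K x K log transition probabilities; logpi: log initial probs.
// Ties are broken toward the lower state index (deterministic).
// [[Rcpp::export(name = ".viterbi_cpp")]]
IntegerVector viterbi_cpp(NumericMatrix logB, NumericMatrix logA,
                          NumericVector logpi) {
  int T = logB.nrow(), K = logB.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);

  for (int k = 0; k < K; ++k) delta(0, k) = logpi[k] + logB(0, k);
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf;
      int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta(t - 1, j) + logA(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + logB(t, k);
      psi(t, k) = arg;
    }

  IntegerVector path(T);
  double best = R_NegInf;
  int arg = 0;
  for (int k = 0; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}
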