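#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward E-step for a 2-state HMM.
// B: T x 2 emission densities, A: 2x2 transition matrix, pi: initial probs.
// Returns log-likelihood, posteriors gamma (T x 2) and summed transition
// posteriors xi_sum (2x2).
// [[Rcpp::export(name = ".hmm_estep")]]
List hmm_estep(NumericMatrix B, NumericMatrix A, NumericVector pi) {
  int T = B.nrow();
  NumericMatrix alpha(T, 2), beta(T, 2), gamma(T, 2);
  NumericVector c(T);
  double ll = 0.0;

  // forward with per-step scaling
  for (int j = 0; j < 2; ++j) alpha(0, j) = pi[j] * B(0, j);
  c[0] = alpha(0, 0) + alpha(0, 1);
  if (c[0] <= 0) stop("zero forward probability at t = 1");
  alpha(0, 0) /= c[0]; alpha(0, 1) /= c[0];
  ll += std::log(c[0]);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < 2; ++j) {
      alpha(t, j) = (alpha(t - 1, 0) * A(0, j) +
                     alpha(t - 1, 1) * A(1, j)) * B(t, j);
    }
    c[t] = alpha(t, 0) + alpha(t, 1);
    if (c[t] <= 0) stop("zero forward probability at t = %d", t + 1);
    alpha(t, 0) /= c[t]; alpha(t, 1) /= c[t];
    ll += std::log(c[t]);
  }

  // backward, same scaling
  beta(T - 1, 0) = 1.0; beta(T - 1, 1) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < 2; ++i) {
      beta(t, i) = (A(i, 0) * B(t + 1, 0) * beta(t + 1, 0) +
                    A(i, 1) * B(t + 1, 1) * beta(t + 1, 1)) / c[t + 1];
    }
  }

  NumericMatrix xi(2, 2);
  for (int t = 0; t < T; ++t) {
    double s = alpha(t, 0) * beta(t, 0) + alpha(t, 1) * beta(t, 1);
    gamma(t, 0) = alpha(t, 0) * beta(t, 0) / s;
    gamma(t, 1) = alpha(t, 1) * beta(t, 1) / s;
  }
  for (int t = 0; t < T - 1; ++t) {
    for (int i = 0; i < 2; ++i) {
      for (int j = 0; j < 2; ++j) {
        xi(i, j) += alpha(t, i) * A(i, j) * B(t + 1, j) *
                    beta(t + 1, j) / c[t + 1];
      }
    }
  }
  return List::create(_["loglik"] = ll, _["gamma"] = gamma,
                      _["xi_sum"] = xi);
}

// Forward log-likelihood only.
// [[Rcpp::export(name = ".hmm_loglik")]]
double hmm_loglik(NumericMatrix B, NumericMatrix A, NumericVector pi) {
  int T = B.nrow();
  double a0 = pi[0] * B(0, 0), a1 = pi[1] * B(0, 1);
  double c = a0 + a1;
  if (c <= 0) stop("zero forward probability at t = 1");
  double ll = std::log(c);
  a0 /= c; a1 /= c;
  for (int t = 1; t < T; ++t) {
    double b0 = (a0 * A(0, 0) + a1 * A(1, 0)) * B(t, 0);
    double b1 = (a0 * A(0, 1) + a1 * A(1, 1)) * B(t, 1);
    c = b0 + b1;
    if (c <= 0) stop("zero forward probability at t = %d", t + 1);
    ll += std::log(c);
    a0 = b0 / c; a1 = b1 / c;
  }
  return ll;
}

// Viterbi decoding in log space; ties broken toward staying in the
// previous state (hysteresis).
// [[Rcpp::export(name = ".hmm_viterbi")]]
IntegerVector hmm_viterbi(NumericMatrix logB, NumericMatrix logA,
                          NumericVector logpi) {
  int T = logB.nrow();
  NumericMatrix d(T, 2);
  IntegerMatrix psi(T, 2);
  for (int j = 0; j < 2; ++j) d(0, j) = logpi[j] + logB(0, j);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < 2; ++j) {
      double stay = d(t - 1, j) + logA(j, j);      // j -> j
      int other = 1 - j;
      double sw = d(t - 1, other) + logA(other, j);
      if (sw > stay) {                              // strict: tie stays
        d(t, j) = sw + logB(t, j);
        psi(t, j) = other;
      } else {
        d(t, j) = stay + logB(t, j);
        psi(t, j) = j;
      }
    }
  }
  IntegerVector path(T);
  path[T - 1] = (d(T - 1, 1) > d(T - 1, 0)) ? 1 : 0;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path;
}
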