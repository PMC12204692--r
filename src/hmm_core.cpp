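#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward over one sequence.
// emiss: K x N matrix of (unnormalised, strictly positive) emission values.
// Returns gamma (K x N), xi flattened ((K-1) x N*N, column-major in (i,j)),
// per-step scaling factors and the log pseudo-likelihood (sum of log scales).
// [[Rcpp::export(name = ".fb_core")]]
List fb_core(NumericMatrix emiss, NumericVector nu, NumericMatrix A) {
  const int K = emiss.nrow(), N = emiss.ncol();
  NumericMatrix alpha(K, N), beta(K, N), gamma(K, N);
  NumericVector scale(K);

  // forward
  double c0 = 0.0;
  for (int i = 0; i < N; ++i) {
    alpha(0, i) = nu[i] * emiss(0, i);
    c0 += alpha(0, i);
  }
  if (c0 <= 0.0) stop("all emissions vanished at step 1");
  scale[0] = c0;
  for (int i = 0; i < N; ++i) alpha(0, i) /= c0;
  for (int k = 1; k < K; ++k) {
    double ck = 0.0;
    for (int j = 0; j < N; ++j) {
      double s = 0.0;
      for (int i = 0; i < N; ++i) s += alpha(k - 1, i) * A(i, j);
      alpha(k, j) = s * emiss(k, j);
      ck += alpha(k, j);
    }
    if (ck <= 0.0) stop("all emissions vanished at step %d", k + 1);
    scale[k] = ck;
    for (int j = 0; j < N; ++j) alpha(k, j) /= ck;
  }

  // backward (scaled by the forward normalisers)
  for (int i = 0; i < N; ++i) beta(K - 1, i) = 1.0;
  for (int k = K - 2; k >= 0; --k) {
    for (int i = 0; i < N; ++i) {
      double s = 0.0;
      for (int j = 0; j < N; ++j)
        s += A(i, j) * emiss(k + 1, j) * beta(k + 1, j);
      beta(k, i) = s / scale[k + 1];
    }
  }

  // gamma, renormalised per step for numerical hygiene
  for (int k = 0; k < K; ++k) {
    double s = 0.0;
    for (int i = 0; i < N; ++i) { gamma(k, i) = alpha(k, i) * beta(k, i); s += gamma(k, i); }
    for (int i = 0; i < N; ++i) gamma(k, i) /= s;
  }

  NumericMatrix xi(std::max(K - 1, 0), N * N);
  for (int k = 0; k + 1 < K; ++k) {
    double s = 0.0;
    for (int j = 0; j < N; ++j)
      for (int i = 0; i < N; ++i) {
        double v = alpha(k, i) * A(i, j) * emiss(k + 1, j) * beta(k + 1, j);
        xi(k, i + N * j) = v;
        s += v;
      }
    for (int c = 0; c < N * N; ++c) xi(k, c) /= s;
  }

  double ll = 0.0;
  for (int k = 0; k < K; ++k) ll += std::log(scale[k]);

  return List::create(_["gamma"] = gamma, _["xi"] = xi,
                      _["scaling_factors"] = scale,
                      _["log_pseudo_likelihood"] = ll);
}

// One full E-step over many sequences sharing one model. emiss stacks the
// sequences row-wise; starts (0-based) and lens delimit them. Returns the
// pooled Baum-Welch accumulators and the full gamma matrix.
// [[Rcpp::export(name = ".fb_multi")]]
List fb_multi(NumericMatrix emiss, IntegerVector starts, IntegerVector lens,
              NumericVector nu, NumericMatrix A) {
  const int N = emiss.ncol(), S = starts.size();
  const int Kmax = *std::max_element(lens.begin(), lens.end());
  NumericMatrix gamma_all(emiss.nrow(), N);
  NumericVector nu_acc(N), gden_acc(N);
  NumericMatrix xi_acc(N, N);
  double ll = 0.0;
  std::vector<double> alpha(Kmax * N), beta(Kmax * N), scale(Kmax);

  for (int s = 0; s < S; ++s) {
    const int off = starts[s], K = lens[s];
    // forward
    double c0 = 0.0;
    for (int i = 0; i < N; ++i) { alpha[i] = nu[i] * emiss(off, i); c0 += alpha[i]; }
    if (c0 <= 0.0) stop("all emissions vanished");
    scale[0] = c0;
    for (int i = 0; i < N; ++i) alpha[i] /= c0;
    for (int k = 1; k < K; ++k) {
      double ck = 0.0;
      for (int j = 0; j < N; ++j) {
        double v = 0.0;
        for (int i = 0; i < N; ++i) v += alpha[(k - 1) * N + i] * A(i, j);
        v *= emiss(off + k, j);
        alpha[k * N + j] = v;
        ck += v;
      }
      if (ck <= 0.0) stop("all emissions vanished");
      scale[k] = ck;
      for (int j = 0; j < N; ++j) alpha[k * N + j] /= ck;
    }
    // backward
    for (int i = 0; i < N; ++i) beta[(K - 1) * N + i] = 1.0;
    for (int k = K - 2; k >= 0; --k)
      for (int i = 0; i < N; ++i) {
        double v = 0.0;
        for (int j = 0; j < N; ++j)
          v += A(i, j) * emiss(off + k + 1, j) * beta[(k + 1) * N + j];
        beta[k * N + i] = v / scale[k + 1];
      }
    // gamma + accumulators
    for (int k = 0; k < K; ++k) {
      double sg = 0.0;
      for (int i = 0; i < N; ++i) {
        double v = alpha[k * N + i] * beta[k * N + i];
        gamma_all(off + k, i) = v;
        sg += v;
      }
      for (int i = 0; i < N; ++i) gamma_all(off + k, i) /= sg;
    }
    for (int i = 0; i < N; ++i) nu_acc[i] += gamma_all(off, i);
    for (int k = 0; k + 1 < K; ++k) {
      double sx = 0.0;
      for (int j = 0; j < N; ++j)
        for (int i = 0; i < N; ++i)
          sx += alpha[k * N + i] * A(i, j) * emiss(off + k + 1, j) *
                beta[(k + 1) * N + j];
      for (int j = 0; j < N; ++j)
        for (int i = 0; i < N; ++i)
          xi_acc(i, j) += alpha[k * N + i] * A(i, j) * emiss(off + k + 1, j) *
                          beta[(k + 1) * N + j] / sx;
      for (int i = 0; i < N; ++i) gden_acc[i] += gamma_all(off + k, i);
    }
    for (int k = 0; k < K; ++k) ll += std::log(scale[k]);
  }
  return List::create(_["gamma"] = gamma_all, _["nu_acc"] = nu_acc,
                      _["xi_acc"] = xi_acc, _["gden_acc"] = gden_acc,
                      _["log_pseudo_likelihood"] = ll);
}

// Viterbi in log space. log_emiss: K x N; ties broken toward the lowest
// state index (strict > comparison keeps the first maximum).
// [[Rcpp::export(name = ".viterbi_core")]]
List viterbi_core(NumericMatrix log_emiss, NumericVector log_nu,
                  NumericMatrix log_A) {
  const int K = log_emiss.nrow(), N = log_emiss.ncol();
  NumericMatrix delta(K, N);
  IntegerMatrix psi(K, N);
  for (int i = 0; i < N; ++i) delta(0, i) = log_nu[i] + log_emiss(0, i);
  for (int k = 1; k < K; ++k) {
    for (int j = 0; j < N; ++j) {
      double best = R_NegInf; int arg = 0;
      for (int i = 0; i < N; ++i) {
        double v = delta(k - 1, i) + log_A(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(k, j) = best + log_emiss(k, j);
      psi(k, j) = arg;
    }
  }
  IntegerVector states(K);
  double best = R_NegInf; int arg = 0;
  for (int i = 0; i < N; ++i)
    if (delta(K - 1, i) > best) { best = delta(K - 1, i); arg = i; }
  states[K - 1] = arg;
  for (int k = K - 2; k >= 0; --k) states[k] = psi(k + 1, states[k + 1]);
  for (int k = 0; k < K; ++k) states[k] += 1;  // 1-based labels
  return List::create(_["states"] = states, _["path_log_score"] = best);
}
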