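#include <Rcpp.h>
using namespace Rcpp;

// Exact distribution of the number of "matching" disks in a uniformly random
// size-N subset of n disks, where disk i matches independently with
// probability p[i]. Dynamic programming over disks with state
// (selected so far, matches so far); transitions count subsets, so the final
// layer is normalized by choose(n, N).
// [[Rcpp::export]]
NumericVector cpp_match_count_dist(NumericVector p, int N) {
  int n = p.size();
  if (N < 0 || N > n) stop("N must be between 0 and length(p)");
  int W = N + 1;
  std::vector<double> f(W * W, 0.0), g(W * W, 0.0);
  f[0] = 1.0;
  for (int i = 0; i < n; ++i) {
    double pi = p[i];
    int smax = std::min(i, N);
    std::fill(g.begin(), g.end(), 0.0);
    for (int s = 0; s <= smax; ++s) {
      for (int k = 0; k <= s; ++k) {
        double v = f[s * W + k];
        if (v == 0.0) continue;
        g[s * W + k] += v; // disk i not selected
        if (s < N) {
          g[(s + 1) * W + k] += v * (1.0 - pi); // selected, no match
          g[(s + 1) * W + k + 1] += v * pi;     // selected, match
        }
      }
    }
    std::swap(f, g);
  }
  double cnk = ::Rf_choose((double)n, (double)N);
  NumericVector out(N + 1);
  for (int k = 0; k <= N; ++k) out[k] = f[N * W + k] / cnk;
  return out;
}

// Mix a match-count distribution over the uniform integer multiplier
// m in {1, ..., M}; responses k * m are clipped to the slider range [0, 8].
// [[Rcpp::export]]
NumericVector cpp_multiplier_mix(NumericVector matchdist, int M) {
  if (M < 1) stop("M must be >= 1");
  int N = matchdist.size() - 1;
  NumericVector pmf(9);
  for (int m = 1; m <= M; ++m) {
    for (int k = 0; k <= N; ++k) {
      int r = k * m;
      if (r > 8) r = 8;
      pmf[r] += matchdist[k] / M;
    }
  }
  return pmf;
}

// Negative log-likelihood of a session for the sub-sampling observer.
// Trials are grouped into profiles (distinct condition x test-offset cells);
// column g of `didx` holds 1-based indices into `pvals` giving each disk's
// match probability, and column g of `counts` holds how many trials in that
// cell produced each response 0..8.
// [[Rcpp::export]]
double cpp_session_nll(NumericVector pvals, IntegerMatrix didx,
                       IntegerMatrix counts, int N, int M, double eps) {
  int ndisks = didx.nrow(), G = didx.ncol();
  if (counts.nrow() != 9 || counts.ncol() != G)
    stop("counts must be 9 x ncol(didx)");
  if (N < 1 || N > ndisks) stop("N out of range");
  NumericVector p(ndisks);
  double nll = 0.0;
  for (int g = 0; g < G; ++g) {
    for (int i = 0; i < ndisks; ++i) p[i] = pvals[didx(i, g) - 1];
    NumericVector md = cpp_match_count_dist(p, N);
    NumericVector pmf = cpp_multiplier_mix(md, M);
    for (int r = 0; r < 9; ++r) {
      int c = counts(r, g);
      if (c > 0) nll -= c * std::log(pmf[r] + eps);
    }
  }
  return nll;
}
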