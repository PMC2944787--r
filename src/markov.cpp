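#include <Rcpp.h>
using namespace Rcpp;

// First-order Markov chain sampler over a small state space.
// trans is row-stochastic; uses R's RNG so set.seed() governs output.
// [[Rcpp::export]]
IntegerVector markov_sample_cpp(int n, NumericMatrix trans, int init) {
  int k = trans.nrow();
  if (trans.ncol() != k) stop("transition matrix must be square");
  if (init < 1 || init > k) stop("init state out of range");
  IntegerVector out(n);
  int s = init - 1;
  for (int i = 0; i < n; ++i) {
    double u = R::unif_rand();
    double acc = 0.0;
    int j = 0;
    for (; j < k - 1; ++j) {
      acc += trans(s, j);
      if (u < acc) break;
    }
    s = j;
    out[i] = s + 1;
  }
  return out;
}
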