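#include <Rcpp.h>
using namespace Rcpp;

// Sample n bases from an order-k Markov chain over {A,C,G,T}.
// trans: 4^k x 4 row-stochastic matrix; row index is the base-4 encoding
// of the k preceding bases (A=0, C=1, G=2, T=3). Uses R's RNG so draws
// are reproducible under set.seed(). Returns 0-based base codes.
// [[Rcpp::export]]
IntegerVector markov_sample_cpp(int n, NumericMatrix trans, int k) {
  if (n < 0) stop("n must be non-negative");
  int nstate = trans.nrow();
  IntegerVector out(n);
  int state = 0;
  int warm = (k < n) ? k : n;
  for (int i = 0; i < warm; ++i) {
    int b = (int)(unif_rand() * 4.0);
    if (b > 3) b = 3;
    out[i] = b;
    state = (state * 4 + b) % nstate;
  }
  for (int i = k; i < n; ++i) {
    double u = unif_rand();
    double acc = 0.0;
    int b = 3;
    for (int j = 0; j < 4; ++j) {
      acc += trans(state, j);
      if (u < acc) { b = j; break; }
    }
    out[i] = b;
    state = (state * 4 + b) % nstate;
  }
  return out;
}
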