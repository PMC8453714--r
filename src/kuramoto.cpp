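#include <Rcpp.h>
using namespace Rcpp;

// Discrete-time noisy phase-oscillator network. Each node advances by its
// deterministic increment omega[i] = 2*pi*f_i/fs plus Gaussian jitter, and
// is pulled toward its neighbours' phases through the coupling matrix K
// (per-sample units). Uses R's RNG so runs are reproducible via set.seed().
//
// Returns an n_steps x n matrix of unwrapped phases.
// [[Rcpp::export]]
NumericMatrix kuramoto_phases(int n_steps, NumericVector theta0,
                              NumericMatrix K, NumericVector omega,
                              double jitter) {
  int n = theta0.size();
  if (K.nrow() != n || K.ncol() != n)
    stop("coupling matrix dimension does not match theta0");
  if (omega.size() != n)
    stop("omega must have one natural frequency per node");
  NumericMatrix out(n_steps, n);
  std::vector<double> th(theta0.begin(), theta0.end());
  std::vector<double> nxt(n);
  for (int t = 0; t < n_steps; ++t) {
    for (int i = 0; i < n; ++i) out(t, i) = th[i];
    NumericVector eps = rnorm(n, 0.0, jitter);
    for (int i = 0; i < n; ++i) {
      double pull = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double k = K(i, j);
        if (k != 0.0) pull += k * std::sin(th[j] - th[i]);
      }
      nxt[i] = th[i] + omega[i] + pull + eps[i];
    }
    std::swap(th, nxt);
  }
  return out;
}
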