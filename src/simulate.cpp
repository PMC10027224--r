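#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Batched simulation of the probabilistic excitable lattice.
//
// Each of `runs` replicate simulations starts from the all-zero state and
// is advanced `max_t` synchronous steps. The firing probability of neuron i
// is the clamped weighted input sum(w[i,j] * s_j(t)) (0 below 0, 1 above 1);
// states are drawn independently Bernoulli(p_i), after which one uniformly
// random neuron is forced active every `drive_every` steps (background
// drive). Active neurons are kept as sorted index lists so the per-step
// cost scales with N * n_active rather than N^2, which is what makes large
// subcritical sweeps affordable.
//
// Uses R's RNG (seed with set.seed for reproducibility). Draw order per
// step and run: Bernoulli draws for neurons with fractional probability in
// index order, then the drive draw.
// [[Rcpp::export]]
List simulate_lattice_cpp(NumericMatrix w, int max_t, int runs,
                          IntegerVector monitor, int drive_every) {
  const int N = w.nrow();
  const int nm = monitor.size();
  if (w.ncol() != N) stop("weight matrix must be square");
  NumericMatrix S(max_t, runs);
  IntegerVector mon(static_cast<R_xlen_t>(max_t) * nm * runs);
  mon.attr("dim") = IntegerVector::create(max_t, nm, runs);
  const double *wp = REAL(w);
  std::vector< std::vector<int> > active(runs);
  std::vector<double> input(N);
  std::vector<int> na;
  RNGScope scope;
  for (int t = 0; t < max_t; ++t) {
    for (int r = 0; r < runs; ++r) {
      std::fill(input.begin(), input.end(), 0.0);
      for (size_t a = 0; a < active[r].size(); ++a) {
        const double *col = wp + static_cast<size_t>(active[r][a]) * N;
        for (int i = 0; i < N; ++i) input[i] += col[i];
      }
      na.clear();
      for (int i = 0; i < N; ++i) {
        const double p = input[i];
        if (p <= 0.0) continue;
        if (p >= 1.0 || unif_rand() < p) na.push_back(i);
      }
      if (drive_every > 0 && t % drive_every == 0) {
        int d = static_cast<int>(unif_rand() * N);
        if (d >= N) d = N - 1;
        std::vector<int>::iterator it =
          std::lower_bound(na.begin(), na.end(), d);
        if (it == na.end() || *it != d) na.insert(it, d);
      }
      active[r] = na;
      S(t, r) = static_cast<double>(na.size()) / N;
      for (int m = 0; m < nm; ++m) {
        const int id = monitor[m] - 1;
        mon[t + static_cast<R_xlen_t>(max_t) *
                (m + static_cast<R_xlen_t>(nm) * r)] =
          std::binary_search(na.begin(), na.end(), id) ? 1 : 0;
      }
    }
  }
  return List::create(_["S"] = S, _["monitor"] = mon);
}
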