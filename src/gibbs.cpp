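#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler over a q-state Potts model.
// J is an L x L x q x q array (R column-major): J[i + L*j + L*L*a + L*L*q*b].
// One long chain: random initialization, burn_in full sweeps, then one
// recorded sample every `thin` sweeps. Uses R's RNG so set.seed() governs
// reproducibility. Returns an n x L matrix of 0-based states.
// [[Rcpp::export]]
IntegerMatrix gibbs_sample_potts_cpp(NumericMatrix h, NumericVector J,
                                     int L, int q, int n,
                                     int burn_in, int thin) {
  IntegerMatrix out(n, L);
  std::vector<int> x(L);
  std::vector<double> logit(q), p(q);
  const double *Jp = J.begin();
  const long LL = (long)L * L;

  for (int i = 0; i < L; ++i) {
    x[i] = (int)(unif_rand() * q);
    if (x[i] >= q) x[i] = q - 1;
  }

  int recorded = 0;
  long sweep = 0;
  while (recorded < n) {
    // one full sweep
    for (int r = 0; r < L; ++r) {
      double mx = -1e300;
      for (int a = 0; a < q; ++a) {
        double e = h(r, a);
        for (int j = 0; j < L; ++j) {
          if (j == r) continue;
          e += Jp[r + (long)L * j + LL * a + LL * q * (long)x[j]];
        }
        logit[a] = e;
        if (e > mx) mx = e;
      }
      double s = 0.0;
      for (int a = 0; a < q; ++a) {
        p[a] = std::exp(logit[a] - mx);
        s += p[a];
      }
      double u = unif_rand() * s, c = 0.0;
      int pick = q - 1;
      for (int a = 0; a < q; ++a) {
        c += p[a];
        if (u <= c) { pick = a; break; }
      }
      x[r] = pick;
    }
    ++sweep;
    if (sweep > burn_in && ((sweep - burn_in) % thin == 0)) {
      for (int i = 0; i < L; ++i) out(recorded, i) = x[i];
      ++recorded;
    }
  }
  return out;
}
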