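#include <Rcpp.h>
using namespace Rcpp;

// Kingman coalescent for one window, no recombination, infinite-sites
// mutation at window-scaled rate M (theta per window): mutations arrive at
// rate M/2 per lineage per unit of coalescent time (time in units of 2N
// generations for diploids / N for haploids, so that the expected pairwise
// coalescence time is 1 and E[k] = M, E[S] = M * a1).
//
// growth > 0 is the exponential growth rate in coalescent time units:
// looking backwards the population size shrinks as N(t) = N0 * exp(-g t),
// so the pair coalescence rate at backward time t is choose(i,2)*exp(g t).
//
// Only the per-window summaries are kept: k (mean pairwise differences),
// S (segregating sites), and tbar2 (the tree's mean pairwise coalescence
// time, so that E[k | tree] = M * tbar2 — used to rescale M when growth
// changes the realised diversity).

// [[Rcpp::export]]
NumericMatrix sim_windows_cpp(int reps, int n, double M, double growth) {
  if (reps < 1) stop("'reps' must be >= 1");
  if (n < 2) stop("'n' must be >= 2");
  if (!(M > 0)) stop("'M' must be > 0");
  if (growth < 0) stop("'growth' must be >= 0");
  NumericMatrix out(reps, 3);
  colnames(out) = CharacterVector::create("k", "S", "tbar2");
  const double nC2 = (double)n * (n - 1) / 2.0;
  std::vector<double> counts(n);
  RNGScope scope;
  for (int r = 0; r < reps; ++r) {
    for (int j = 0; j < n; ++j) counts[j] = 1.0;
    double t = 0.0, k = 0.0, tbar2 = 0.0;
    int S = 0;
    double sumc = (double)n * (n - 1);  // sum_j c_j * (n - c_j), all c_j = 1
    for (int i = n; i >= 2; --i) {
      const double rate = (double)i * (i - 1) / 2.0;
      const double E = exp_rand();
      double T;
      if (growth == 0.0) T = E / rate;
      else T = log1p(growth * E * std::exp(-growth * t) / rate) / growth;
      const int m = (int)R::rpois(0.5 * M * i * T);
      for (int mm = 0; mm < m; ++mm) {
        int j = (int)(unif_rand() * i); if (j >= i) j = i - 1;
        const double c = counts[j];
        S += 1;
        k += c * (n - c) / nC2;
      }
      tbar2 += sumc * T / (2.0 * nC2);
      t += T;
      int a = (int)(unif_rand() * i); if (a >= i) a = i - 1;
      int b = (int)(unif_rand() * (i - 1)); if (b >= i - 1) b = i - 2;
      if (b >= a) b += 1;
      const double ca = counts[a], cb = counts[b];
      sumc += (ca + cb) * (n - ca - cb) - ca * (n - ca) - cb * (n - cb);
      counts[a] = ca + cb;
      counts[b] = counts[i - 1];
    }
    out(r, 0) = k;
    out(r, 1) = (double)S;
    out(r, 2) = tbar2;
  }
  return out;
}

// Same genealogy process, but returning the derived-allele carrier sets of
// every mutation so that a full haplotype matrix can be assembled. Used by
// the synthetic-window generator; heavier than sim_windows_cpp, so it runs
// one window per call. Returns a list of integer vectors (1-based carrier
// indices), one per mutation, in no particular order.

// [[Rcpp::export]]
List sim_window_carriers_cpp(int n, double M, double growth) {
  if (n < 2) stop("'n' must be >= 2");
  if (!(M > 0)) stop("'M' must be > 0");
  if (growth < 0) stop("'growth' must be >= 0");
  std::vector< std::vector<int> > members(n);
  for (int j = 0; j < n; ++j) members[j].assign(1, j + 1);
  std::vector< std::vector<int> > muts;
  RNGScope scope;
  double t = 0.0;
  for (int i = n; i >= 2; --i) {
    const double rate = (double)i * (i - 1) / 2.0;
    const double E = exp_rand();
    double T;
    if (growth == 0.0) T = E / rate;
    else T = log1p(growth * E * std::exp(-growth * t) / rate) / growth;
    const int m = (int)R::rpois(0.5 * M * i * T);
    for (int mm = 0; mm < m; ++mm) {
      int j = (int)(unif_rand() * i); if (j >= i) j = i - 1;
      muts.push_back(members[j]);
    }
    t += T;
    int a = (int)(unif_rand() * i); if (a >= i) a = i - 1;
    int b = (int)(unif_rand() * (i - 1)); if (b >= i - 1) b = i - 2;
    if (b >= a) b += 1;
    members[a].insert(members[a].end(), members[b].begin(), members[b].end());
    members[b].swap(members[i - 1]);
    members[i - 1].clear();
  }
  List out(muts.size());
  for (size_t z = 0; z < muts.size(); ++z) out[z] = wrap(muts[z]);
  return out;
}
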