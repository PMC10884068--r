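#include <Rcpp.h>
using namespace Rcpp;

// Single-count bond convention: total lattice energy is -J * sum over bonds of
// delta(q_i, q_j). The per-site energy (sum over a site's 4 neighbours) double
// counts bonds, so a single-site update changes the total energy by
// -(n_new - n_old) where n is the number of matching nearest neighbours.

static inline int matching_neighbours(const IntegerMatrix &g, int L, int k, int l, int q) {
  int n = 0;
  n += (g((k + L - 1) % L, l) == q);
  n += (g((k + 1) % L, l) == q);
  n += (g(k, (l + L - 1) % L) == q);
  n += (g(k, (l + 1) % L) == q);
  return n;
}

// One or more full Metropolis sweeps (L^2 single-site attempts each) over a
// periodic L x L lattice. Uses R's RNG so results are reproducible under
// set.seed(). Optionally records the states of selected sites after every
// sweep. Returns the updated grid, the cumulative energy change, and the
// recorded node time courses (nodes x sweeps).
// [[Rcpp::export]]
List potts_sweeps_cpp(IntegerMatrix grid, int Q, double T, int nsweeps,
                      IntegerVector rec_rows, IntegerVector rec_cols,
                      bool record) {
  int L = grid.nrow();
  int nrec = rec_rows.size();
  IntegerMatrix recorded(record ? nrec : 0, record ? nsweeps : 0);
  double dE_total = 0.0;
  for (int sweep = 0; sweep < nsweeps; ++sweep) {
    for (int a = 0; a < L * L; ++a) {
      int k = (int)(unif_rand() * L); if (k == L) k = L - 1;
      int l = (int)(unif_rand() * L); if (l == L) l = L - 1;
      int q = grid(k, l);
      int qn = (int)(unif_rand() * Q); if (qn == Q) qn = Q - 1;
      if (qn == q) continue;  // self-proposal: dE = 0, always accepted
      int n_old = matching_neighbours(grid, L, k, l, q);
      int n_new = matching_neighbours(grid, L, k, l, qn);
      double dE = -(double)(n_new - n_old);
      if (dE <= 0.0 || unif_rand() < std::exp(-dE / T)) {
        grid(k, l) = qn;
        dE_total += dE;
      }
    }
    if (record) {
      for (int r = 0; r < nrec; ++r)
        recorded(r, sweep) = grid(rec_rows[r], rec_cols[r]);
    }
  }
  return List::create(_["grid"] = grid, _["dE_total"] = dE_total,
                      _["recorded"] = recorded);
}

// LZ-76 exhaustive-history parsing. Scanning left to right, each new phrase is
// the shortest prefix of the remaining suffix that cannot be reproduced by
// copying from a start position strictly before the current one (the copy may
// run self-referentially into the phrase being produced). The final phrase may
// be reproducible and is counted once. Returns 0-based phrase start indices.
// [[Rcpp::export]]
IntegerVector lz76_boundaries_cpp(IntegerVector x) {
  int n = x.size();
  std::vector<int> bounds;
  int p = 0;
  while (p < n) {
    bounds.push_back(p);
    if (p == 0) { p = 1; continue; }
    int best = 0;
    int limit = n - p;
    for (int i = 0; i < p; ++i) {
      // a candidate can only improve on `best` if it matches there too
      if (p + best < n && x[i + best] != x[p + best]) continue;
      int j = 0;
      while (p + j < n && x[i + j] == x[p + j]) ++j;
      if (j > best) best = j;
      if (best >= limit) break;
    }
    int len = (best >= limit) ? limit : best + 1;
    p += len;
  }
  return wrap(bounds);
}

// First-order Markov synthesis by inverse-CDF lookup. cum_p is the row-wise
// cumulative transition matrix, cum_init the cumulative initial distribution,
// u a vector of n uniforms drawn in R (so set.seed() governs the output).
// Returns 0-based state codes.
// [[Rcpp::export]]
IntegerVector markov_synth_cpp(NumericMatrix cum_p, NumericVector cum_init,
                               NumericVector u) {
  int n = u.size();
  int A = cum_p.nrow();
  IntegerVector out(n);
  int s = 0;
  while (s < A - 1 && u[0] > cum_init[s]) ++s;
  out[0] = s;
  for (int t = 1; t < n; ++t) {
    int prev = out[t - 1];
    int j = 0;
    while (j < A - 1 && u[t] > cum_p(prev, j)) ++j;
    out[t] = j;
  }
  return out;
}
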