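#include <Rcpp.h>
using namespace Rcpp;

// Metropolis kernel over protonation microstates, flat integer-indexed
// system layout produced by compile_system():
//   off[i]  0-based start of site i's tautomer block
//   nt[i]   tautomer count of site i
//   g, np   flat intrinsic terms (pK units) and proton counts
//   ph[i]   bath pH of site i
//   adjacency: adj_ptr (CSR), adj_j (0-based partner site), adj_woff
//   (start into wdata of an own-tautomer-major block of nt_i * nt_j doubles)
//   cp_i/cp_j: 0-based coupled pairs visited by the pair-move sweep
// One cycle = single-site sweep in freshly shuffled order, then the
// coupled-pair sweep. Uses R's RNG so set.seed() governs everything.

static inline double wlook(const NumericVector &wdata, int woff, int nti_j,
                           int ti, int tj) {
  return wdata[woff + ti * nti_j + tj];
}

// Energy delta of changing site i from t to t2 (0-based local indices),
// all other sites fixed at state[].
static double delta_single(int i, int t, int t2, const IntegerVector &state,
                           const IntegerVector &off, const IntegerVector &nt,
                           const NumericVector &g, const IntegerVector &np,
                           const NumericVector &ph,
                           const IntegerVector &adj_ptr,
                           const IntegerVector &adj_j,
                           const IntegerVector &adj_woff,
                           const NumericVector &wdata) {
  double d = g[off[i] + t2] - g[off[i] + t] +
             (np[off[i] + t2] - np[off[i] + t]) * ph[i];
  for (int e = adj_ptr[i]; e < adj_ptr[i + 1]; ++e) {
    int j = adj_j[e];
    int tj = state[j];
    d += wlook(wdata, adj_woff[e], nt[j], t2, tj) -
         wlook(wdata, adj_woff[e], nt[j], t, tj);
  }
  return d;
}

static inline bool metropolis_accept(double dG) {
  if (dG <= 0.0) return true;
  return unif_rand() < std::pow(10.0, -dG);
}

// [[Rcpp::export(name = ".mc_run_cpp")]]
List mc_run_cpp(IntegerVector off, IntegerVector nt, NumericVector g,
                IntegerVector np, NumericVector ph, IntegerVector adj_ptr,
                IntegerVector adj_j, IntegerVector adj_woff,
                NumericVector wdata, IntegerVector cp_i, IntegerVector cp_j,
                IntegerVector state0, int n_cycles, bool record,
                int n_batches) {
  int n = off.size();
  IntegerVector state = clone(state0);  // 0-based local tautomer indices
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  std::vector<double> sum_ind(n, 0.0), sum_np(n, 0.0);
  int nb = record ? std::min(n_batches, n_cycles) : 1;
  NumericMatrix batch(record ? nb : 1, record ? n : 1);
  std::vector<int> batch_n(nb, 0);

  for (int cyc = 0; cyc < n_cycles; ++cyc) {
    // Fisher-Yates shuffle of the site visit order
    for (int k = n - 1; k > 0; --k) {
      int j = (int)(unif_rand() * (k + 1));
      if (j > k) j = k;
      std::swap(order[k], order[j]);
    }
    // single-site sweep
    for (int k = 0; k < n; ++k) {
      int i = order[k];
      if (nt[i] < 2) continue;
      int t = state[i];
      int r = (int)(unif_rand() * (nt[i] - 1));
      if (r > nt[i] - 2) r = nt[i] - 2;
      int t2 = (r >= t) ? r + 1 : r;
      double dG = delta_single(i, t, t2, state, off, nt, g, np, ph, adj_ptr,
                               adj_j, adj_woff, wdata);
      if (metropolis_accept(dG)) state[i] = t2;
    }
    // coupled-pair sweep: joint uniform re-draw of both members
    for (int p = 0; p < cp_i.size(); ++p) {
      int i = cp_i[p], j = cp_j[p];
      int ti = state[i], tj = state[j];
      int ti2 = (int)(unif_rand() * nt[i]); if (ti2 >= nt[i]) ti2 = nt[i] - 1;
      int tj2 = (int)(unif_rand() * nt[j]); if (tj2 >= nt[j]) tj2 = nt[j] - 1;
      if (ti2 == ti && tj2 == tj) continue;
      // delta of moving i with j fixed, then j with i already moved;
      // exact because the shared W term is re-read from state[].
      double dG = delta_single(i, ti, ti2, state, off, nt, g, np, ph,
                               adj_ptr, adj_j, adj_woff, wdata);
      state[i] = ti2;
      dG += delta_single(j, tj, tj2, state, off, nt, g, np, ph, adj_ptr,
                         adj_j, adj_woff, wdata);
      state[i] = ti;
      if (metropolis_accept(dG)) { state[i] = ti2; state[j] = tj2; }
    }
    if (record) {
      int b = (int)((long long)cyc * nb / n_cycles);
      if (b >= nb) b = nb - 1;
      batch_n[b]++;
      for (int i = 0; i < n; ++i) {
        double ind = (np[off[i] + state[i]] > 0) ? 1.0 : 0.0;
        sum_ind[i] += ind;
        sum_np[i] += np[off[i] + state[i]];
        batch(b, i) += ind;
      }
    }
  }

  NumericVector mean_ind(n), mean_np(n);
  if (record) {
    for (int i = 0; i < n; ++i) {
      mean_ind[i] = sum_ind[i] / n_cycles;
      mean_np[i] = sum_np[i] / n_cycles;
    }
    for (int b = 0; b < nb; ++b)
      for (int i = 0; i < n; ++i) batch(b, i) /= batch_n[b];
  }
  return List::create(_["state"] = state, _["mean_ind"] = mean_ind,
                      _["mean_np"] = mean_np, _["batch"] = batch);
}
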