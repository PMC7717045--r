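#include <Rcpp.h>
using namespace Rcpp;

// Random-sequential exclusion process on a 1-D lattice.  Each time step the
// current agents are visited in a uniformly shuffled order; each agent is
// classified isolated (both nearest neighbours vacant) or grouped at its
// action time, then attempts a move to a uniformly chosen nearest neighbour
// (aborted if occupied or off-lattice), a proliferation event depositing a
// daughter at a uniformly chosen nearest neighbour (same abort rule), and
// death, with its type's probabilities.  Uses R's RNG so runs are
// reproducible under set.seed().

// off-lattice ghost sites are treated as vacant for classification
static inline bool is_isolated(const std::vector<int>& occ, int i, int n) {
  bool left_vacant = (i == 0) || (occ[i - 1] == 0);
  bool right_vacant = (i == n - 1) || (occ[i + 1] == 0);
  return left_vacant && right_vacant;
}

// [[Rcpp::export]]
IntegerMatrix cpp_lattice_run(IntegerVector init, double pmi, double pmg,
                              double ppi, double ppg, double pdi, double pdg,
                              int n_steps, IntegerVector record_steps) {
  int n = init.size();
  std::vector<int> occ(init.begin(), init.end());
  int n_rec = record_steps.size();
  IntegerMatrix out(n_rec, n);
  std::vector<int> agents;
  agents.reserve(n);
  int rec_idx = 0;
  for (int r = 0; r < n_rec; ++r) {
    if (record_steps[r] == 0) {
      for (int j = 0; j < n; ++j) out(r, j) = occ[j];
      rec_idx = r + 1;
    }
  }
  RNGScope scope;
  for (int step = 1; step <= n_steps; ++step) {
    agents.clear();
    for (int j = 0; j < n; ++j) if (occ[j]) agents.push_back(j);
    int m = agents.size();
    // Fisher-Yates shuffle with R's RNG
    for (int k = m - 1; k > 0; --k) {
      int j = (int)(unif_rand() * (k + 1));
      if (j > k) j = k;
      std::swap(agents[k], agents[j]);
    }
    for (int k = 0; k < m; ++k) {
      int i = agents[k];
      if (!occ[i]) continue; // died earlier this step
      bool iso = is_isolated(occ, i, n);
      double pm = iso ? pmi : pmg;
      double pp = iso ? ppi : ppg;
      double pd = iso ? pdi : pdg;
      int pos = i;
      if (pm > 0.0 && unif_rand() < pm) {
        int dir = (unif_rand() < 0.5) ? -1 : 1;
        int tgt = pos + dir;
        if (tgt >= 0 && tgt < n && !occ[tgt]) {
          occ[pos] = 0;
          occ[tgt] = 1;
          pos = tgt;
        }
      }
      if (pp > 0.0 && unif_rand() < pp) {
        int dir = (unif_rand() < 0.5) ? -1 : 1;
        int tgt = pos + dir;
        if (tgt >= 0 && tgt < n && !occ[tgt]) occ[tgt] = 1;
      }
      if (pd > 0.0 && unif_rand() < pd) occ[pos] = 0;
    }
    if (rec_idx < n_rec && record_steps[rec_idx] == step) {
      for (int j = 0; j < n; ++j) out(rec_idx, j) = occ[j];
      ++rec_idx;
    }
  }
  return out;
}

// Thomas algorithm for tridiagonal systems (sub, diag, super, rhs).
// [[Rcpp::export]]
NumericVector cpp_tridiag_solve(NumericVector sub, NumericVector diag,
                                NumericVector sup, NumericVector rhs) {
  int n = diag.size();
  std::vector<double> b(diag.begin(), diag.end());
  std::vector<double> d(rhs.begin(), rhs.end());
  for (int i = 1; i < n; ++i) {
    double w = sub[i] / b[i - 1];
    b[i] -= w * sup[i - 1];
    d[i] -= w * d[i - 1];
  }
  NumericVector x(n);
  x[n - 1] = d[n - 1] / b[n - 1];
  for (int i = n - 2; i >= 0; --i) x[i] = (d[i] - sup[i] * x[i + 1]) / b[i];
  return x;
}
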