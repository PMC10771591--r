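#include <Rcpp.h>
using namespace Rcpp;

// union-find with path halving
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// Max cluster mass of one sign for one statistic vector.
// mask: element is supra-threshold for this sign; edges are 0-based pairs of
// the fixed element graph. Mass = sum of t over a connected component.
static double max_mass_one(const double* t, const std::vector<char>& mask,
                           const IntegerVector& ea, const IntegerVector& eb,
                           std::vector<int>& parent,
                           std::vector<double>& mass, int n_elem) {
  for (int i = 0; i < n_elem; ++i) parent[i] = i;
  const int n_edge = ea.size();
  for (int e = 0; e < n_edge; ++e) {
    int a = ea[e], b = eb[e];
    if (mask[a] && mask[b]) {
      int ra = uf_find(parent, a), rb = uf_find(parent, b);
      if (ra != rb) parent[ra] = rb;
    }
  }
  std::fill(mass.begin(), mass.end(), 0.0);
  double best = 0.0;
  for (int i = 0; i < n_elem; ++i) {
    if (!mask[i]) continue;
    int r = uf_find(parent, i);
    mass[r] += t[i];
    double a = std::fabs(mass[r]);
    if (a > best) best = a;
  }
  return best;
}

// For each row of tmat (one permutation's t-map over elements), the maximum
// positive-cluster mass and maximum |negative-cluster mass| under the given
// threshold and element graph. Non-finite t values never enter a cluster.
// [[Rcpp::export]]
NumericMatrix perm_max_cluster_mass(const NumericMatrix& tmat, double thr,
                                    const IntegerVector& edge_a,
                                    const IntegerVector& edge_b) {
  const int n_perm = tmat.nrow(), n_elem = tmat.ncol();
  NumericMatrix out(n_perm, 2);
  std::vector<int> parent(n_elem);
  std::vector<double> mass(n_elem);
  std::vector<char> mask(n_elem);
  std::vector<double> row(n_elem);
  for (int p = 0; p < n_perm; ++p) {
    for (int i = 0; i < n_elem; ++i) {
      double v = tmat(p, i);
      row[i] = R_finite(v) ? v : 0.0;
    }
    for (int i = 0; i < n_elem; ++i) mask[i] = row[i] > thr;
    out(p, 0) = max_mass_one(row.data(), mask, edge_a, edge_b, parent, mass,
                             n_elem);
    for (int i = 0; i < n_elem; ++i) mask[i] = row[i] < -thr;
    out(p, 1) = max_mass_one(row.data(), mask, edge_a, edge_b, parent, mass,
                             n_elem);
  }
  return out;
}
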