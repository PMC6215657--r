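#include <Rcpp.h>
using namespace Rcpp;

// Shared kernel for the GRP / aGRP statistics over arbitrary labelings.
//
// Each gene row is pre-sorted in R (values ascending); `xs` holds the sorted
// values and `ord` the 0-based sample indices in that order. Walking the
// sorted row in tie-runs gives, for every sample, the exceedance counts that
// define the statistics:
//   - a tumor sample in a tie-run has  #{normal <= value} = cn_before + cn_in
//     (ties count as exceedance, per the >= indicator),
//   - a normal sample has              #{tumor  >= value} = n - ct_before.
// aGRP accumulates the pair count U = sum_i #{j : tumor_i >= normal_j} and
// T = 2U/(nm) - 1; GRP thresholds the per-sample proportions at tau.
//
// The comparison epsilon guards the tau boundary: proportions are exact
// multiples of 1/n or 1/m, so 1e-9 is far below the grid spacing.

static const double EPS = 1e-9;

struct StatResult {
  double T;
  double p_up;
  double p_down;
};

// lab: 0/1 per sample (1 = tumor class), length N, for one labeling.
static inline StatResult gene_stat(const double* xs, const int* ord,
                                   const int* lab, int N, int n, int m,
                                   bool agrp, double tau) {
  int ct_before = 0, cn_before = 0;
  long long U = 0;
  int su = 0, sd = 0;
  int p = 0;
  while (p < N) {
    int pe = p;
    double v = xs[p];
    while (pe + 1 < N && xs[pe + 1] == v) ++pe;
    int ct_in = 0;
    for (int q = p; q <= pe; ++q) ct_in += lab[ord[q]];
    int cn_in = (pe - p + 1) - ct_in;
    if (agrp) {
      U += (long long)ct_in * (cn_before + cn_in);
    } else {
      if (ct_in > 0) {
        double l = (cn_before + cn_in) / (double)m;
        if (l >= tau - EPS) su += ct_in;
        else if (l < 1.0 - tau - EPS) sd += ct_in;
      }
      if (cn_in > 0) {
        double k = (n - ct_before) / (double)n;
        if (k >= tau - EPS) su += cn_in;
        else if (k < 1.0 - tau - EPS) sd += cn_in;
      }
    }
    ct_before += ct_in;
    cn_before += cn_in;
    p = pe + 1;
  }
  StatResult res;
  if (agrp) {
    res.p_up = (double)U / ((double)n * (double)m);
    res.p_down = 1.0 - res.p_up;
    res.T = 2.0 * res.p_up - 1.0;
  } else {
    res.p_up = (double)su / (double)N;
    res.p_down = (double)sd / (double)N;
    res.T = res.p_up - res.p_down;
  }
  return res;
}

// Observed statistics for every gene under one labeling.
// Returns a G x 3 matrix: columns T, p_up, p_down.
// [[Rcpp::export]]
NumericMatrix stat_matrix_cpp(NumericMatrix xs, IntegerMatrix ord,
                              IntegerVector lab, int n, int m,
                              bool agrp, double tau) {
  int G = xs.nrow(), N = xs.ncol();
  if (ord.nrow() != G || ord.ncol() != N || lab.size() != N)
    stop("dimension mismatch in stat_matrix_cpp");
  NumericMatrix out(G, 3);
  std::vector<double> row(N);
  std::vector<int> orow(N);
  const int* labp = INTEGER(lab);
  for (int g = 0; g < G; ++g) {
    for (int j = 0; j < N; ++j) { row[j] = xs(g, j); orow[j] = ord(g, j); }
    StatResult r = gene_stat(row.data(), orow.data(), labp, N, n, m, agrp, tau);
    out(g, 0) = r.T; out(g, 1) = r.p_up; out(g, 2) = r.p_down;
  }
  return out;
}

// Full permutation statistic matrix (G x B); intended for small problems
// (diagnostics, exact-null cross-checks).
// [[Rcpp::export]]
NumericMatrix perm_T_cpp(NumericMatrix xs, IntegerMatrix ord,
                         IntegerMatrix labmat, int n, int m,
                         bool agrp, double tau) {
  int G = xs.nrow(), N = xs.ncol(), B = labmat.ncol();
  if (ord.nrow() != G || ord.ncol() != N || labmat.nrow() != N)
    stop("dimension mismatch in perm_T_cpp");
  NumericMatrix out(G, B);
  std::vector<double> row(N);
  std::vector<int> orow(N);
  for (int g = 0; g < G; ++g) {
    for (int j = 0; j < N; ++j) { row[j] = xs(g, j); orow[j] = ord(g, j); }
    for (int b = 0; b < B; ++b) {
      const int* labp = INTEGER(labmat) + (R_xlen_t)b * N;
      out(g, b) = gene_stat(row.data(), orow.data(), labp, N, n, m, agrp, tau).T;
    }
  }
  return out;
}

// Permutation exceedance counts: for each gene, #{b : |T_b| >= |T_obs|}.
// Avoids materialising the G x B matrix for large permutation runs.
// [[Rcpp::export]]
IntegerVector perm_count_cpp(NumericMatrix xs, IntegerMatrix ord,
                             IntegerMatrix labmat, int n, int m,
                             bool agrp, double tau, NumericVector tobs) {
  int G = xs.nrow(), N = xs.ncol(), B = labmat.ncol();
  if (ord.nrow() != G || ord.ncol() != N || labmat.nrow() != N ||
      tobs.size() != G)
    stop("dimension mismatch in perm_count_cpp");
  IntegerVector out(G);
  std::vector<double> row(N);
  std::vector<int> orow(N);
  for (int g = 0; g < G; ++g) {
    for (int j = 0; j < N; ++j) { row[j] = xs(g, j); orow[j] = ord(g, j); }
    double thr = std::fabs(tobs[g]) - 1e-12;
    int cnt = 0;
    for (int b = 0; b < B; ++b) {
      const int* labp = INTEGER(labmat) + (R_xlen_t)b * N;
      double T = gene_stat(row.data(), orow.data(), labp, N, n, m, agrp, tau).T;
      if (std::fabs(T) >= thr) ++cnt;
    }
    out[g] = cnt;
  }
  return out;
}
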