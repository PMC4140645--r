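#include <Rcpp.h>
using namespace Rcpp;

// Closed-form single-site occupancy probabilities.
static inline void occ_probs(double t, double birth, double death,
                             double &p1, double &p0) {
  double r = birth + death;
  if (r <= 0.0) { p1 = 1.0; p0 = 0.0; return; }
  double pi0 = birth / r;
  double e = std::exp(-r * t);
  p1 = pi0 + (1.0 - pi0) * e;
  p0 = pi0 * (1.0 - e);
}

// dbinom(k, n, p) for k = 0..S-1 via the ratio recurrence; exact to
// rounding for the small k this kernel needs.
static void binom_head(double *out, int S, int n, double p) {
  double q = 1.0 - p;
  if (p <= 0.0) {
    for (int k = 0; k < S; ++k) out[k] = (k == 0) ? 1.0 : 0.0;
    return;
  }
  if (q <= 0.0) {
    for (int k = 0; k < S; ++k) out[k] = (k == n) ? 1.0 : 0.0;
    return;
  }
  double v = std::pow(q, n);
  double ratio = p / q;
  for (int k = 0; k < S; ++k) {
    out[k] = (k <= n) ? v : 0.0;
    if (k < n) v *= ratio * (double)(n - k) / (double)(k + 1);
  }
}

// Row-stochastic count transition matrix over states 0..n_max for a
// region of W sites: convolution of binomial survival (m occupied) and
// binomial gain (W - m unoccupied) distributions, rows renormalized
// after truncation.
static void transition_fill(std::vector<double> &T, int S, int W,
                            double t, double birth, double death) {
  double p1, p0;
  occ_probs(t, birth, death, p1, p0);
  int n_max = S - 1;
  std::vector<double> surv(S), gain(S);
  for (int m = 0; m <= n_max; ++m) {
    binom_head(surv.data(), S, m, p1);
    binom_head(gain.data(), S, W - m, p0);
    double rowsum = 0.0;
    for (int n = 0; n <= n_max; ++n) {
      double s = 0.0;
      int jlo = std::max(0, n - (W - m));
      int jhi = std::min(m, n);
      for (int j = jlo; j <= jhi; ++j) s += surv[j] * gain[n - j];
      T[m * S + n] = s;
      rowsum += s;
    }
    if (rowsum > 0.0)
      for (int n = 0; n <= n_max; ++n) T[m * S + n] /= rowsum;
  }
}

// Felsenstein pruning over count states for all regions of one width.
// obs: R x n_tip matrix of leaf counts, NA = missing (marginalized).
// postorder/parent: 1-based node indexing as in the bd_tree object.
// Returns per-region log-likelihoods under the given root prior.
// [[Rcpp::export(name = ".bd_loglik_cpp")]]
NumericVector bd_loglik_cpp(IntegerMatrix obs, int W, int n_max,
                            IntegerVector postorder, IntegerVector parent,
                            int root, int n_tip, NumericVector blen,
                            NumericVector birth, NumericVector death,
                            NumericVector prior) {
  const int S = n_max + 1;
  const int R_n = obs.nrow();
  const int n_nodes = parent.size();
  std::vector<std::vector<double>> T(n_nodes);
  for (int v = 0; v < n_nodes; ++v) {
    if (v + 1 == root) continue;
    T[v].assign(S * S, 0.0);
    transition_fill(T[v], S, W, blen[v], birth[v], death[v]);
  }
  // initialize every node's conditional likelihood table
  std::vector<std::vector<double>> L(n_nodes);
  std::vector<std::vector<double>> logscale(n_nodes);
  for (int v = 0; v < n_nodes; ++v) {
    logscale[v].assign(R_n, 0.0);
    if (v < n_tip) {
      L[v].assign((size_t)S * R_n, 0.0);
      for (int r = 0; r < R_n; ++r) {
        int o = obs(r, v);
        if (o == NA_INTEGER) {
          for (int x = 0; x < S; ++x) L[v][(size_t)r * S + x] = 1.0;
        } else {
          if (o > n_max) stop("observed count exceeds n_max");
          L[v][(size_t)r * S + o] = 1.0;
        }
      }
    } else {
      L[v].assign((size_t)S * R_n, 1.0);
    }
  }
  // postorder: fold each non-root node into its parent with scaling;
  // observed tips contribute a single transition-matrix column
  std::vector<double> buf(S);
  for (int k = 0; k < postorder.size(); ++k) {
    int v = postorder[k] - 1;
    int p = parent[v] - 1;
    if (p < 0) continue;                 // root
    std::vector<double> &Tv = T[v];
    for (int r = 0; r < R_n; ++r) {
      double *Lp = &L[p][(size_t)r * S];
      double mx = 0.0;
      int o = (v < n_tip) ? obs(r, v) : NA_INTEGER;
      if (o != NA_INTEGER) {
        for (int x = 0; x < S; ++x) {
          buf[x] = Tv[x * S + o];
          if (buf[x] > mx) mx = buf[x];
        }
      } else {
        double *Lc = &L[v][(size_t)r * S];
        for (int x = 0; x < S; ++x) {
          double s = 0.0;
          for (int y = 0; y < S; ++y) s += Tv[x * S + y] * Lc[y];
          buf[x] = s;
          if (s > mx) mx = s;
        }
      }
      if (mx <= 0.0) mx = 1.0;           // impossible data; keep zeros
      for (int x = 0; x < S; ++x) Lp[x] *= buf[x] / mx;
      logscale[p][r] += logscale[v][r] + std::log(mx);
    }
    L[v].clear(); L[v].shrink_to_fit();
  }
  NumericVector out(R_n);
  int rt = root - 1;
  for (int r = 0; r < R_n; ++r) {
    double s = 0.0;
    for (int x = 0; x < S; ++x) s += prior[x] * L[rt][(size_t)r * S + x];
    out[r] = std::log(s) + logscale[rt][r];
  }
  return out;
}
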