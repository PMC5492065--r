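#include <Rcpp.h>
using namespace Rcpp;

// Forward-algorithm marginal log-likelihood over the 15-state space.
//
// obs:         n x T matrix of observation-category indices (1..15, 1 = not
//              seen); entries before an individual's first detection are
//              ignored.
// first_occ:   1-based occasion of first detection per individual.
// first_state: 1-based state index at first detection (the observed live
//              state; the likelihood conditions on it).
// grp:         n x (T-1) matrix, grp(k, t) = 1-based index of the
//              transition-matrix slice governing occasion t -> t+1.
// px:          15 x 15 x G array of column-stochastic transition matrices.
// po:          15 x 15 observation matrix (rows = categories).
//
// The forward vector is renormalized every step and the log of the scaling
// factors accumulated, so probabilities far below double precision remain
// representable; an impossible history returns -Inf.

// [[Rcpp::export]]
NumericVector forward_loglik_cpp(IntegerMatrix obs, IntegerVector first_occ,
                                 IntegerVector first_state, IntegerMatrix grp,
                                 NumericVector px, NumericMatrix po) {
  const int n = obs.nrow(), T = obs.ncol(), S = 15;
  if (grp.nrow() != n || grp.ncol() != T - 1)
    stop("grp must be n x (T-1)");
  if (px.size() % (S * S) != 0)
    stop("px must be a 15 x 15 x G array");
  const int G = px.size() / (S * S);
  NumericVector out(n);
  std::vector<double> alpha(S), anew(S);

  // PX is structurally sparse (at most ~6 nonzero fates per state);
  // precompute a compressed-column form of every slice
  std::vector<int> col_start(G * S + 1);
  std::vector<int> row_idx;
  std::vector<double> val;
  row_idx.reserve(G * S * 6);
  val.reserve(G * S * 6);
  {
    int pos = 0;
    for (int g = 0; g < G; ++g) {
      const double *P = &px[(std::size_t)g * S * S];
      for (int i = 0; i < S; ++i) {
        col_start[g * S + i] = pos;
        for (int j = 0; j < S; ++j) {
          const double v = P[j + S * i];
          if (v != 0.0) { row_idx.push_back(j); val.push_back(v); ++pos; }
        }
      }
    }
    col_start[G * S] = pos;
  }

  for (int k = 0; k < n; ++k) {
    std::fill(alpha.begin(), alpha.end(), 0.0);
    alpha[first_state[k] - 1] = 1.0;
    double ll = 0.0;
    bool impossible = false;
    // first_occ is 1-based, so it is also the 0-based index of the
    // occasion after first detection
    for (int t = first_occ[k]; t < T; ++t) {
      const int g = grp(k, t - 1) - 1;
      if (g < 0 || g >= G) stop("transition group index out of range");
      const int y = obs(k, t) - 1;
      if (y < 0 || y >= S) stop("observation category out of range");
      std::fill(anew.begin(), anew.end(), 0.0);
      // accumulate column-wise over the sparse kernel, skipping states
      // with no forward mass
      for (int i = 0; i < S; ++i) {
        const double a = alpha[i];
        if (a == 0.0) continue;
        const int c0 = col_start[g * S + i], c1 = col_start[g * S + i + 1];
        for (int c = c0; c < c1; ++c) anew[row_idx[c]] += val[c] * a;
      }
      double tot = 0.0;
      for (int j = 0; j < S; ++j) {
        anew[j] *= po(y, j);
        tot += anew[j];
      }
      if (!(tot > 0.0) || !R_finite(tot)) { impossible = true; break; }
      const double inv = 1.0 / tot;
      for (int j = 0; j < S; ++j) alpha[j] = anew[j] * inv;
      ll += std::log(tot);
    }
    out[k] = impossible ? R_NegInf : ll;
  }
  return out;
}
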