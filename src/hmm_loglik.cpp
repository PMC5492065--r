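#include <Rcpp.h>
using namespace Rcpp;

// Fused dataset log-likelihood for the sampler hot path: computes the
// logit/multinomial-logit links, assembles the sparse transition kernel
// per covariate group and the observation probabilities, and runs the
// scaled forward recursion — all in one call.
//
// Parameter slices arrive on the sampler's unconstrained scale:
//   b0s, b1s : survival intercept/slope mapped per stage (length 6;
//              b1s empty for the constant form)
//   a0       : growth intercepts (7: I1->I2, I1->I3, I2->I3, I2->I4,
//              I3->I4, I3->I5, I4->I5)
//   a1       : shared growth slopes per stage I1..I4 (empty if constant)
//   hatch_t, pup_t : logits of the informative-prior probabilities
//   pl_t (6), pd_t (5) : logits of detection probabilities
//   xs, xg   : standardized covariate values per group (length G)
//   grow_death : partition dying mass by psi (true) or keep in stage
// Data arguments are as in forward_loglik_cpp.

static inline double inv_logit(double x) {
  return x > 0 ? 1.0 / (1.0 + std::exp(-x)) : std::exp(x) / (1.0 + std::exp(x));
}

// [[Rcpp::export]]
double hmm_loglik_cpp(NumericVector b0s, NumericVector b1s,
                      NumericVector a0, NumericVector a1,
                      double hatch_t, double pup_t,
                      NumericVector pl_t, NumericVector pd_t,
                      NumericVector xs, NumericVector xg,
                      bool grow_death,
                      IntegerMatrix obs, IntegerVector first_occ,
                      IntegerVector first_state, IntegerMatrix grp) {
  const int S = 15, n = obs.nrow(), T = obs.ncol();
  const int G = xs.size();
  const bool has_b1 = b1s.size() > 0, has_a1 = a1.size() > 0;
  const double hatch = inv_logit(hatch_t), pup = inv_logit(pup_t);

  // detection per state (0-based: 0..6 live, 7..13 newly dead, 14 dead)
  double p_obs[15];
  for (int s = 0; s < 15; ++s) p_obs[s] = 0.0;
  for (int s = 0; s < 6; ++s) p_obs[s] = inv_logit(pl_t[s]);
  for (int s = 0; s < 5; ++s) p_obs[8 + s] = inv_logit(pd_t[s]);

  // sparse transition kernel per group: column-compressed over 15 states
  std::vector<int> col_start(G * S + 1);
  std::vector<int> row_idx; row_idx.reserve(G * S * 6);
  std::vector<double> val; val.reserve(G * S * 6);
  // growth-stage layout: I1..I3 have two destinations, I4 one
  const int g_stage[4] = {1, 2, 3, 4};
  const int g_a0[4] = {0, 2, 4, 6};
  int pos = 0;
  for (int g = 0; g < G; ++g) {
    double phi[7], psi[7][7];
    for (int i = 0; i < 7; ++i)
      for (int j = 0; j < 7; ++j) psi[j][i] = 0.0;
    for (int s = 0; s < 6; ++s) {
      double eta = b0s[s];
      if (has_b1) eta += b1s[s] * xs[g];
      phi[s] = inv_logit(eta);
    }
    phi[6] = 1.0;
    psi[0][0] = 1.0 - hatch;
    psi[1][0] = hatch;
    for (int q = 0; q < 4; ++q) {
      const int s = g_stage[q];
      const int nd = (s < 4) ? 2 : 1;
      double lw[2] = {a0[g_a0[q]], nd == 2 ? a0[g_a0[q] + 1] : 0.0};
      if (has_a1)
        for (int d = 0; d < nd; ++d) lw[d] += a1[q] * xg[g];
      double m = 0.0;
      for (int d = 0; d < nd; ++d) if (lw[d] > m) m = lw[d];
      const double e0 = std::exp(-m);
      double den = e0, e[2];
      for (int d = 0; d < nd; ++d) { e[d] = std::exp(lw[d] - m); den += e[d]; }
      psi[s][s] = e0 / den;
      for (int d = 0; d < nd; ++d) psi[s + 1 + d][s] = e[d] / den;
    }
    psi[5][5] = 1.0 - pup;
    psi[6][5] = pup;
    psi[6][6] = 1.0;
    // live columns: J block (phi * psi) and M block (dying mass)
    for (int i = 0; i < 7; ++i) {
      col_start[g * S + i] = pos;
      for (int j = 0; j < 7; ++j) {
        const double v = phi[i] * psi[j][i];
        if (v != 0.0) { row_idx.push_back(j); val.push_back(v); ++pos; }
      }
      if (grow_death) {
        for (int j = 0; j < 7; ++j) {
          const double v = (1.0 - phi[i]) * psi[j][i];
          if (v != 0.0) { row_idx.push_back(7 + j); val.push_back(v); ++pos; }
        }
      } else if (phi[i] < 1.0) {
        row_idx.push_back(7 + i); val.push_back(1.0 - phi[i]); ++pos;
      }
    }
    // newly dead -> absorbing; absorbing -> absorbing
    for (int i = 7; i < 15; ++i) {
      col_start[g * S + i] = pos;
      row_idx.push_back(14); val.push_back(1.0); ++pos;
    }
  }
  col_start[G * S] = pos;

  double total = 0.0;
  std::vector<double> alpha(S), anew(S);
  for (int k = 0; k < n; ++k) {
    std::fill(alpha.begin(), alpha.end(), 0.0);
    alpha[first_state[k] - 1] = 1.0;
    double ll = 0.0;
    bool impossible = false;
    for (int t = first_occ[k]; t < T; ++t) {
      const int g = grp(k, t - 1) - 1;
      const int y = obs(k, t) - 1; // category: 0 NS, 1..14 seen state y-1
      std::fill(anew.begin(), anew.end(), 0.0);
      for (int i = 0; i < S; ++i) {
        const double a = alpha[i];
        if (a == 0.0) continue;
        const int c0 = col_start[g * S + i], c1 = col_start[g * S + i + 1];
        for (int c = c0; c < c1; ++c) anew[row_idx[c]] += val[c] * a;
      }
      double tot = 0.0;
      if (y == 0) {
        for (int j = 0; j < S; ++j) {
          anew[j] *= (1.0 - p_obs[j]);
          tot += anew[j];
        }
      } else {
        tot = anew[y - 1] * p_obs[y - 1];
        if (tot > 0.0) {
          std::fill(anew.begin(), anew.end(), 0.0);
          anew[y - 1] = tot;
        }
      }
      if (!(tot > 0.0) || !R_finite(tot)) { impossible = true; break; }
      const double inv = 1.0 / tot;
      for (int j = 0; j < S; ++j) alpha[j] = anew[j] * inv;
      ll += std::log(tot);
    }
    if (impossible) return R_NegInf;
    total += ll;
  }
  return total;
}
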