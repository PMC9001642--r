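#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for source apportionment of one sink community.
//
// read_taxa: 0-based taxon index per sink read.
// m: training counts, (n_sources + 1) x n_taxa; the last row (unknown
//    environment) is all zero.
// alpha: per-environment Dirichlet smoothing of the taxon distribution.
// beta: symmetric prior on the mixing proportions.
// Returns an n_draws x (n_sources + 1) matrix of mixing-proportion draws.
// [[Rcpp::export]]
NumericMatrix gibbs_sink(IntegerVector read_taxa, NumericMatrix m,
                         NumericVector alpha, double beta,
                         int n_burn, int n_draws, int draw_interval) {
  const int n_reads = read_taxa.size();
  const int S = m.nrow();
  const int T = m.ncol();

  std::vector<double> m_row(S, 0.0);
  for (int s = 0; s < S; ++s)
    for (int t = 0; t < T; ++t) m_row[s] += m(s, t);

  // current assignments
  std::vector<int> z(n_reads);
  std::vector< std::vector<double> > nhat(S, std::vector<double>(T, 0.0));
  std::vector<double> n_env(S, 0.0);
  for (int r = 0; r < n_reads; ++r) {
    int s = (int)std::floor(unif_rand() * S);
    if (s == S) s = S - 1;
    z[r] = s;
    nhat[s][read_taxa[r]] += 1.0;
    n_env[s] += 1.0;
  }

  NumericMatrix draws(n_draws, S);
  std::vector<double> w(S);
  int sweep_total = n_burn + (n_draws - 1) * draw_interval + 1;
  int next_draw = n_burn;
  int k = 0;
  for (int sweep = 0; sweep < sweep_total; ++sweep) {
    for (int r = 0; r < n_reads; ++r) {
      const int t = read_taxa[r];
      const int old = z[r];
      nhat[old][t] -= 1.0;
      n_env[old] -= 1.0;
      double tot = 0.0;
      for (int s = 0; s < S; ++s) {
        double num = m(s, t) + nhat[s][t] + alpha[s];
        double den = m_row[s] + n_env[s] + alpha[s] * T;
        w[s] = num / den * (n_env[s] + beta);
        tot += w[s];
      }
      double u = unif_rand() * tot;
      int s_new = 0;
      double acc = w[0];
      while (u > acc && s_new < S - 1) acc += w[++s_new];
      z[r] = s_new;
      nhat[s_new][t] += 1.0;
      n_env[s_new] += 1.0;
    }
    if (sweep == next_draw && k < n_draws) {
      for (int s = 0; s < S; ++s) draws(k, s) = n_env[s] / n_reads;
      ++k;
      next_draw += draw_interval;
    }
  }
  return draws;
}
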