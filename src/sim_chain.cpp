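#include <Rcpp.h>
using namespace Rcpp;

// Discrete-time occupancy chain for one site: each OTU k flips
// absent -> present with probability m_k and present -> absent with
// probability e_k per yearly step; present OTUs are detected with
// probability rho at recorded observation years. Uses R's RNG stream so a
// set.seed() in the caller fixes the output exactly.
//
// lat_map / obs_map: for each simulated year (0-based step), the 1-based
// output row to write, or 0 to skip.
// [[Rcpp::export(name = ".sim_site_chain")]]
List sim_site_chain(NumericVector m_k, NumericVector e_k, double rho,
                    LogicalVector init_state,
                    IntegerVector lat_map, IntegerVector obs_map,
                    int n_lat_rows, int n_obs_rows) {
  const int S = m_k.size();
  const int n_years = lat_map.size();
  IntegerMatrix lat(n_lat_rows, S);
  IntegerMatrix obs(n_obs_rows, S);
  std::vector<char> state(S);
  for (int k = 0; k < S; ++k) state[k] = init_state[k] ? 1 : 0;

  for (int j = 0; j < n_years; ++j) {
    if (j > 0) {
      for (int k = 0; k < S; ++k) {
        const double u = unif_rand();
        state[k] = state[k] ? (u >= e_k[k]) : (u < m_k[k]);
      }
    }
    const int lr = lat_map[j];
    if (lr > 0)
      for (int k = 0; k < S; ++k) lat(lr - 1, k) = state[k];
    const int orow = obs_map[j];
    if (orow > 0)
      for (int k = 0; k < S; ++k)
        obs(orow - 1, k) = (state[k] && unif_rand() < rho) ? 1 : 0;
  }
  return List::create(_["lat"] = lat, _["obs"] = obs);
}
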