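#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Pairwise species-exchange kernel shared by the margin-preserving shuffle
// and the preference-improving refinement.
//
// A proposal picks two distinct sites i, j, then one species present at i
// and absent at j (uniformly among those) and one present at j and absent
// at i. Exchanging the two presences leaves every row and column sum
// unchanged. In `improve` mode the exchange is accepted iff it strictly
// increases the summed log-suitability of occupied cells; otherwise every
// valid exchange is accepted, which randomizes the matrix over realizations
// with the given margins (a trial-swap null-model walk).
//
// Uses R's RNG (unif_rand) so results are reproducible under set.seed().

static inline int sample_int(int n) {
  // uniform on 0..n-1
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

// [[Rcpp::export]]
List swap_kernel(IntegerMatrix presence, NumericMatrix logsuit,
                 bool improve, double max_proposals, int max_consec_rej) {
  const int ns = presence.nrow();   // species
  const int nc = presence.ncol();   // sites
  if (improve && (logsuit.nrow() != ns || logsuit.ncol() != nc))
    stop("log-suitability matrix dimensions must match presence matrix");
  if (nc < 2) {
    return List::create(_["presence"] = presence,
                        _["proposals"] = 0.0, _["accepted"] = 0.0);
  }

  IntegerMatrix pres = clone(presence);
  // per-site list of present species + positions for O(1) removal
  std::vector< std::vector<int> > at_site(nc);
  std::vector< std::vector<int> > pos(nc, std::vector<int>(ns, -1));
  for (int j = 0; j < nc; ++j)
    for (int s = 0; s < ns; ++s)
      if (pres(s, j) == 1) {
        pos[j][s] = (int)at_site[j].size();
        at_site[j].push_back(s);
      }

  RNGScope rng;
  double proposals = 0.0, accepted = 0.0;
  int consec_rej = 0;
  std::vector<int> cand_a, cand_b;
  cand_a.reserve(ns); cand_b.reserve(ns);

  while (proposals < max_proposals && consec_rej < max_consec_rej) {
    proposals += 1.0;
    int i = sample_int(nc);
    int j = sample_int(nc - 1);
    if (j >= i) ++j;

    cand_a.clear(); cand_b.clear();
    for (int s : at_site[i]) if (pres(s, j) == 0) cand_a.push_back(s);
    if (!cand_a.empty())
      for (int s : at_site[j]) if (pres(s, i) == 0) cand_b.push_back(s);
    if (cand_a.empty() || cand_b.empty()) { ++consec_rej; continue; }

    int a = cand_a[sample_int((int)cand_a.size())];
    int b = cand_b[sample_int((int)cand_b.size())];

    bool ok = true;
    if (improve) {
      double delta = logsuit(a, j) + logsuit(b, i)
                   - logsuit(a, i) - logsuit(b, j);
      ok = (delta > 0.0);
    }
    if (!ok) { ++consec_rej; continue; }

    // a moves i -> j, b moves j -> i
    pres(a, i) = 0; pres(b, j) = 0; pres(a, j) = 1; pres(b, i) = 1;
    // site i: replace a by b in the present-list
    int pa = pos[i][a];
    at_site[i][pa] = b; pos[i][b] = pa; pos[i][a] = -1;
    int pb = pos[j][b];
    at_site[j][pb] = a; pos[j][a] = pb; pos[j][b] = -1;

    accepted += 1.0;
    consec_rej = 0;
  }

  return List::create(_["presence"] = pres,
                      _["proposals"] = proposals,
                      _["accepted"] = accepted);
}
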