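#include <Rcpp.h>
using namespace Rcpp;

// Constrained datastream swap chain over a group-by-individual matrix.
//
// State is modified in place: M is the event x bat membership matrix (0/1),
// strat_event[[s]] / strat_bat[[s]] hold, for stratum s, the 1-based event and
// bat index of every observation in that stratum. A swap exchanges the bat
// identities of two observations drawn uniformly from one uniformly chosen
// eligible stratum; it is accepted iff the events differ, the bats differ,
// and neither bat already occupies the other's event. Uses R's RNG, so
// set.seed() in R makes the chain reproducible.
//
// [[Rcpp::export]]
List swap_engine(IntegerMatrix M, List strat_event, List strat_bat,
                 IntegerVector eligible, int n_accept, double max_attempts,
                 bool single_attempt) {
  int n_elig = eligible.size();
  if (n_elig == 0) stop("no stratum holds two or more observations; no swap is possible");
  double attempts = 0.0;
  int accepted = 0;
  int target = single_attempt ? 1 : n_accept;

  while (accepted < target) {
    if (single_attempt && attempts >= 1.0) break;
    if (attempts >= max_attempts)
      stop("no valid swap found after %.0f attempts: every stratum appears degenerate "
           "(observations confined to a single event or a single bat); the dataset is "
           "too small or too sparse for datastream permutation", attempts);
    attempts += 1.0;

    int s = eligible[(int)(unif_rand() * n_elig)] - 1;
    IntegerVector ev = strat_event[s];
    IntegerVector bt = strat_bat[s];
    int m = ev.size();
    int i = (int)(unif_rand() * m);
    int j = (int)(unif_rand() * (m - 1));
    if (j >= i) j += 1;

    int e1 = ev[i] - 1, e2 = ev[j] - 1;
    int b1 = bt[i] - 1, b2 = bt[j] - 1;
    if (e1 == e2 || b1 == b2) continue;          // same event or same bat: reject
    if (M(e1, b2) == 1 || M(e2, b1) == 1) continue;  // would duplicate a bat in an event

    M(e1, b1) = 0; M(e1, b2) = 1;
    M(e2, b2) = 0; M(e2, b1) = 1;
    bt[i] = b2 + 1;
    bt[j] = b1 + 1;
    accepted += 1;
  }

  return List::create(_["accepted"] = accepted, _["attempts"] = attempts);
}
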