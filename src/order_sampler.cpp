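#include <Rcpp.h>
using namespace Rcpp;

// Rejection sampler for semi-random dilemma presentation orders.
//
// A candidate order is a uniform permutation of the 2*K battery items; it is
// accepted iff (a) no run of more than `max_run` items shares a congruency
// status and (b) the two members of every congruent/incongruent pair are
// separated by at least `min_between` other items. The joint constraints are
// rare under uniform sampling (~1e-4 for the 10-pair battery), hence the
// compiled loop. R's RNG is used throughout so set.seed() governs the result.
//
// congruent: 0/1 per item; pair: 0-based pair index per item.
// Returns a 1-based permutation, or an empty vector if max_attempts is
// exhausted.
// [[Rcpp::export(name = ".order_rejection_sample")]]
IntegerVector order_rejection_sample(IntegerVector congruent,
                                     IntegerVector pair,
                                     int max_run,
                                     int min_between,
                                     int max_attempts) {
  int n = congruent.size();
  int n_pairs = n / 2;
  std::vector<int> perm(n), pos_a(n_pairs), pos_b(n_pairs), seen(n_pairs);

  for (int attempt = 0; attempt < max_attempts; ++attempt) {
    for (int i = 0; i < n; ++i) perm[i] = i;
    // Fisher-Yates with R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }

    bool ok = true;
    int run = 0, last = -1;
    std::fill(seen.begin(), seen.end(), 0);
    for (int k = 0; k < n && ok; ++k) {
      int item = perm[k];
      int c = congruent[item];
      run = (c == last) ? run + 1 : 1;
      last = c;
      if (run > max_run) ok = false;
      int p = pair[item];
      if (seen[p] == 0) {
        pos_a[p] = k;
        seen[p] = 1;
      } else {
        if (k - pos_a[p] - 1 < min_between) ok = false;
      }
    }
    if (ok) {
      IntegerVector out(n);
      for (int i = 0; i < n; ++i) out[i] = perm[i] + 1;
      return out;
    }
  }
  return IntegerVector(0);
}
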