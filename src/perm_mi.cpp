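#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Mutual information (bits) between integer-coded group labels and state
// labels over the samples whose state code is > 0 (0 encodes "undefined",
// which is excluded before all frequencies are computed). Zero-probability
// cells contribute nothing to the double sum.
static double mi_bits(const int* states, const int* groups, int n,
                      int n_groups, int n_states,
                      std::vector<int>& joint, std::vector<int>& gmarg,
                      std::vector<int>& smarg) {
  std::fill(joint.begin(), joint.end(), 0);
  std::fill(gmarg.begin(), gmarg.end(), 0);
  std::fill(smarg.begin(), smarg.end(), 0);
  int total = 0;
  for (int i = 0; i < n; ++i) {
    int s = states[i];
    if (s <= 0) continue;  // undefined: excluded from every frequency
    int g = groups[i];
    joint[(g - 1) * n_states + (s - 1)] += 1;
    gmarg[g - 1] += 1;
    smarg[s - 1] += 1;
    ++total;
  }
  if (total < 2) return 0.0;
  const double tot = (double)total;
  double mi = 0.0;
  for (int g = 0; g < n_groups; ++g) {
    if (gmarg[g] == 0) continue;
    const double pg = gmarg[g] / tot;
    for (int s = 0; s < n_states; ++s) {
      int c = joint[g * n_states + s];
      if (c == 0 || smarg[s] == 0) continue;
      const double pjs = c / tot;
      const double ps = smarg[s] / tot;
      mi += pjs * std::log2(pjs / (pg * ps));
    }
  }
  return mi < 0.0 ? 0.0 : mi;  // clamp -0.0 / rounding dust
}

// Observed MI plus a composition-preserving permutation null: the full
// profile vector (undefined entries included) is shuffled against the
// fixed group vector; every permuted MI re-applies the undefined
// exclusion. Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_perm_mi(IntegerVector profile, IntegerVector groups,
                 int n_states, int n_groups, int n_perm) {
  const int n = profile.size();
  if (groups.size() != n) stop("profile/groups length mismatch");
  std::vector<int> st(profile.begin(), profile.end());
  std::vector<int> gr(groups.begin(), groups.end());
  std::vector<int> joint(n_groups * n_states), gm(n_groups), sm(n_states);

  const double obs = mi_bits(st.data(), gr.data(), n, n_groups, n_states,
                             joint, gm, sm);
  const double thr = obs - 1e-12;  // count float-equal permutations as ties
  int count = 0;
  RNGScope scope;
  for (int p = 0; p < n_perm; ++p) {
    // Fisher-Yates shuffle of the profile labels
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(st[i], st[j]);
    }
    double m = mi_bits(st.data(), gr.data(), n, n_groups, n_states,
                       joint, gm, sm);
    if (m >= thr) ++count;
  }
  return List::create(_["mi"] = obs, _["n_ge"] = count,
                      _["n_perm"] = n_perm);
}

// Observed MI only (same exclusion rules), for vectorised scans.
// [[Rcpp::export]]
double cpp_mi(IntegerVector profile, IntegerVector groups, int n_states,
              int n_groups) {
  const int n = profile.size();
  if (groups.size() != n) stop("profile/groups length mismatch");
  std::vector<int> joint(n_groups * n_states), gm(n_groups), sm(n_states);
  return mi_bits(INTEGER(profile), INTEGER(groups), n, n_groups, n_states,
                 joint, gm, sm);
}
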