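#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Enrichment score for a hit-position subset of a ranked list, evaluated
// only at the running-sum extrema candidates (just before and at each hit;
// between hits the sum decays monotonically, and after the last hit it
// returns to exactly 0). sw = |score|^w in rank order; pos = sorted 1-based
// hit positions. Earliest extremum wins ties, matching the R walk.
// Also reports the 1-based ranked-list position of the chosen extremum
// (needed for the leading edge).
static void es_sorted_details(const NumericVector &sw,
                              const std::vector<int> &pos, double &es,
                              int &extremum) {
  const int n = sw.size();
  const int k = (int)pos.size();
  double nr = 0.0;
  for (int i = 0; i < k; ++i) nr += sw[pos[i] - 1];
  const double md = 1.0 / (double)(n - k);
  const bool flat = !(nr > 0.0);
  double h = 0.0, best = 0.0, best_abs = 0.0;
  int best_idx = pos[0];
  // the earliest extremum wins |rs| ties beyond 1e-12 (exact ties occur
  // with w = 0), matching the documented R walk policy
  for (int i = 0; i < k; ++i) {
    const double miss = (double)(pos[i] - (i + 1)) * md;
    const double before = h - miss;
    if (std::abs(before) > best_abs + 1e-12) {
      best_abs = std::abs(before);
      best = before;
      best_idx = pos[i] - 1;
    }
    h += flat ? (1.0 / (double)k) : sw[pos[i] - 1] / nr;
    const double at = h - miss;
    if (std::abs(at) > best_abs + 1e-12) {
      best_abs = std::abs(at);
      best = at;
      best_idx = pos[i];
    }
  }
  if (best > 1.0) best = 1.0;
  if (best < -1.0) best = -1.0;
  es = best;
  extremum = best_idx;
}

static std::vector<int> checked_sorted_positions(const NumericVector &sw,
                                                 const IntegerVector &p) {
  const int n = sw.size();
  std::vector<int> pos(p.begin(), p.end());
  std::sort(pos.begin(), pos.end());
  if (pos.empty() || pos.front() < 1 || pos.back() > n ||
      (int)pos.size() >= n) {
    stop("hit positions must be a non-empty strict subset of 1..N");
  }
  return pos;
}

static double es_sorted(const NumericVector &sw,
                        const std::vector<int> &pos) {
  double es;
  int extremum;
  es_sorted_details(sw, pos, es, extremum);
  return es;
}

// [[Rcpp::export]]
double gsea_es_positions(NumericVector sw, IntegerVector positions) {
  return es_sorted(sw, checked_sorted_positions(sw, positions));
}

// [[Rcpp::export]]
List gsea_es_extremum(NumericVector sw, IntegerVector positions) {
  std::vector<int> pos = checked_sorted_positions(sw, positions);
  double es;
  int extremum;
  es_sorted_details(sw, pos, es, extremum);
  return List::create(_["es"] = es, _["extremum"] = extremum);
}

// [[Rcpp::export]]
NumericVector gsea_null_es(NumericVector sw, int set_size, int n_perm) {
  const int n = sw.size();
  if (set_size < 1 || set_size >= n) {
    stop("set_size must lie in [1, N - 1]");
  }
  NumericVector out(n_perm);
  std::vector<int> pos(set_size);
  for (int p = 0; p < n_perm; ++p) {
    // uniformly random size-k subset via R's RNG (deterministic under
    // set.seed in the calling R session)
    IntegerVector draw = Rcpp::sample(n, set_size, false);
    std::copy(draw.begin(), draw.end(), pos.begin());
    std::sort(pos.begin(), pos.end());
    out[p] = es_sorted(sw, pos);
  }
  return out;
}
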