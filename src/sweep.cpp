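#include <Rcpp.h>
#include <deque>
#include <vector>
using namespace Rcpp;

// Sweep-line detection of candidate virtual-lock-mass / alignment groups.
//
// Peaks arrive through a binary min-heap keyed on (m/z, spectrum index) that
// always holds at most one unprocessed peak per spectrum.  The active
// sequence is a run of consecutive pooled peaks, one per spectrum, currently
// considered as a candidate group.  Candidates are emitted from a snapshot of
// the last state that satisfied the group definition; overlap removal happens
// on the R side.

namespace {

struct HeapEnt {
  double mz;
  int spec;  // 0-based spectrum index
  int g;     // 0-based global peak index
};

inline bool heap_lt(const HeapEnt &a, const HeapEnt &b) {
  // ties on m/z broken by spectrum index for determinism
  return a.mz < b.mz || (a.mz == b.mz && a.spec < b.spec);
}

class PeakHeap {
  std::vector<HeapEnt> h;

public:
  long pushes = 0, pops = 0;

  bool empty() const { return h.empty(); }
  const HeapEnt &top() const { return h.front(); }

  void push(const HeapEnt &e) {
    ++pushes;
    h.push_back(e);
    size_t i = h.size() - 1;
    while (i > 0) {
      size_t p = (i - 1) / 2;
      if (heap_lt(h[i], h[p])) {
        std::swap(h[i], h[p]);
        i = p;
      } else
        break;
    }
  }

  void pop() {
    ++pops;
    h[0] = h.back();
    h.pop_back();
    size_t i = 0, n = h.size();
    for (;;) {
      size_t l = 2 * i + 1, r = l + 1, s = i;
      if (l < n && heap_lt(h[l], h[s])) s = l;
      if (r < n && heap_lt(h[r], h[s])) s = r;
      if (s == i) break;
      std::swap(h[i], h[s]);
      i = s;
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".vlm_sweep")]]
List vlm_sweep(NumericVector mz, NumericVector intensity, IntegerVector spec,
               IntegerVector offsets, double w, bool require_full, double ta,
               double tb) {
  const int m = offsets.size() - 1;

  PeakHeap H;
  std::deque<int> L;            // active sequence: global peak indices
  std::vector<char> B(m, 0);    // spectrum membership flags
  double sum = 0.0;             // running sum of m/z in L
  double mu_l = 0.0, mu_l2 = 0.0;
  bool has_mul = false, has_mul2 = false;
  bool found = false, gap = false;
  std::vector<int> snap;        // last valid active sequence

  std::vector<double> cand_mean;
  std::vector<int> cand_members;  // flattened global indices
  std::vector<int> cand_sizes;

  auto keep = [&](int g) {
    return intensity[g] >= ta && intensity[g] <= tb;
  };

  // seed the heap with each spectrum's first peak passing the intensity gate
  for (int s = 0; s < m; ++s) {
    int g = offsets[s];
    while (g < offsets[s + 1] && !keep(g)) ++g;
    if (g < offsets[s + 1]) H.push({mz[g], s, g});
  }

  auto emit = [&](const std::vector<int> &members) {
    // fresh left-to-right mean so emitted values match a direct computation
    double s = 0.0;
    for (int g : members) s += mz[g];
    cand_mean.push_back(s / members.size());
    cand_sizes.push_back((int)members.size());
    for (int g : members) cand_members.push_back(g);
  };

  auto is_valid = [&]() -> bool {
    const int k = (int)L.size();
    if (k == 0) return false;
    if (require_full && k != m) return false;
    const double muA = sum / k, lo = muA * (1 - w), hi = muA * (1 + w);
    if (!H.empty() && H.top().mz >= lo && H.top().mz <= hi) return false;
    if (has_mul && mu_l >= lo && mu_l <= hi) return false;
    if (mz[L.front()] < lo || mz[L.back()] > hi) return false;
    return true;
  };

  // Would re-adding the last removed peak still satisfy the definition?
  // Used after a lower-bound advance: a state whose left extension is itself
  // a valid group is not maximal and must not become a candidate.
  auto left_ext_valid = [&]() -> bool {
    if (!has_mul || L.empty()) return false;
    const int k = (int)L.size();
    if (require_full && k + 1 != m) return false;
    const double s = sum + mu_l, mv = s / (k + 1);
    const double lo = mv * (1 - w), hi = mv * (1 + w);
    if (mu_l < lo || mz[L.back()] > hi) return false;
    if (!H.empty() && H.top().mz >= lo && H.top().mz <= hi) return false;
    if (has_mul2 && mu_l2 >= lo && mu_l2 <= hi) return false;
    return true;
  };

  auto try_insert = [&]() -> bool {
    const HeapEnt t = H.top();
    if (B[t.spec]) return false;
    const int k = (int)L.size();
    const double s2 = sum + t.mz;
    if (k > 0) {
      const double mu2 = s2 / (k + 1);
      if (mz[L.front()] < mu2 * (1 - w) || t.mz > mu2 * (1 + w)) return false;
    }
    L.push_back(t.g);
    B[t.spec] = 1;
    sum = s2;
    H.pop();
    int g = t.g + 1;
    while (g < offsets[t.spec + 1] && !keep(g)) ++g;
    if (g < offsets[t.spec + 1]) H.push({mz[g], t.spec, g});
    return true;
  };

  auto advance_lower_bound = [&]() {
    const int g = L.front();
    B[spec[g]] = 0;
    mu_l2 = mu_l;
    has_mul2 = has_mul;
    mu_l = mz[g];
    has_mul = true;
    L.pop_front();
    sum -= mz[g];
    if (L.empty()) sum = 0.0;
  };

  for (;;) {
    const bool ins = H.empty() ? false : try_insert();
    if (ins) {
      if (is_valid()) {
        // a pending snapshot separated from this state by an invalid
        // insertion is a maximal group in its own right
        if (found && gap) emit(snap);
        snap.assign(L.begin(), L.end());
        found = true;
        gap = false;
      } else if (found) {
        gap = true;
      }
    } else {
      if (found) {
        emit(snap);
        found = false;
        gap = false;
      }
      if (L.empty()) break;  // heap exhausted and sequence drained
      advance_lower_bound();
      if (is_valid() && !left_ext_valid()) {
        snap.assign(L.begin(), L.end());
        found = true;
        gap = false;
      }
    }
  }

  return List::create(
      _["mean"] = NumericVector(cand_mean.begin(), cand_mean.end()),
      _["members"] = IntegerVector(cand_members.begin(), cand_members.end()),
      _["sizes"] = IntegerVector(cand_sizes.begin(), cand_sizes.end()),
      _["pushes"] = (double)H.pushes, _["pops"] = (double)H.pops);
}
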