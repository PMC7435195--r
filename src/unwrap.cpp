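#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Quality-guided region-growing 2D phase unwrapper.
//
// Pixels are admitted into the unwrapped region in decreasing order of
// `quality`; each admitted pixel is made congruent (mod 2*pi) with its
// highest-quality already-unwrapped 4-neighbour.  The output therefore
// satisfies out == wrapped + 2*pi*k pixelwise with integer k, so
// rewrapping reproduces the input exactly (up to the floating
// representation of the added multiples of 2*pi).

namespace {

struct Entry {
  int idx;
  double q;
};

struct Lower {
  bool operator()(const Entry &a, const Entry &b) const { return a.q < b.q; }
};

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_quality_unwrap(NumericMatrix wrapped, NumericMatrix quality) {
  const int nr = wrapped.nrow(), nc = wrapped.ncol();
  const int n = nr * nc;
  if (quality.nrow() != nr || quality.ncol() != nc)
    stop("wrapped and quality must have identical dimensions");

  NumericMatrix out(nr, nc);
  std::vector<char> done(n, 0);
  std::priority_queue<Entry, std::vector<Entry>, Lower> pq;

  int seed = 0;
  double best = R_NegInf;
  for (int i = 0; i < n; ++i) {
    if (quality[i] > best) {
      best = quality[i];
      seed = i;
    }
  }
  out[seed] = wrapped[seed];
  done[seed] = 1;

  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  const double two_pi = 2.0 * M_PI;

  auto push_neighbours = [&](int idx) {
    const int r = idx % nr, c = idx / nr;
    for (int k = 0; k < 4; ++k) {
      const int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      const int j = cc * nr + rr;
      if (!done[j]) pq.push({j, quality[j]});
    }
  };
  push_neighbours(seed);

  while (!pq.empty()) {
    const Entry e = pq.top();
    pq.pop();
    if (done[e.idx]) continue;  // stale duplicate
    const int r = e.idx % nr, c = e.idx / nr;
    int ref = -1;
    double refq = R_NegInf;
    for (int k = 0; k < 4; ++k) {
      const int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      const int j = cc * nr + rr;
      if (done[j] && quality[j] >= refq) {
        refq = quality[j];
        ref = j;
      }
    }
    double d = wrapped[e.idx] - out[ref];
    d -= two_pi * std::nearbyint(d / two_pi);
    out[e.idx] = out[ref] + d;
    done[e.idx] = 1;
    push_neighbours(e.idx);
  }
  return out;
}

// Count phase residues: non-zero circulation of wrapped differences
// around each 2x2 plaquette.  Returns +1/-1 charges summed as absolute
// count.

// [[Rcpp::export]]
int cpp_count_residues(NumericMatrix wrapped) {
  const int nr = wrapped.nrow(), nc = wrapped.ncol();
  const double two_pi = 2.0 * M_PI;
  auto w = [&](double d) { return d - two_pi * std::nearbyint(d / two_pi); };
  int count = 0;
  for (int c = 0; c + 1 < nc; ++c) {
    for (int r = 0; r + 1 < nr; ++r) {
      const double s = w(wrapped(r, c + 1) - wrapped(r, c)) +
                       w(wrapped(r + 1, c + 1) - wrapped(r, c + 1)) +
                       w(wrapped(r + 1, c) - wrapped(r + 1, c + 1)) +
                       w(wrapped(r, c) - wrapped(r + 1, c));
      if (std::fabs(s) > 1e-6) ++count;
    }
  }
  return count;
}
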