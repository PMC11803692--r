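#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Quality-guided 2-D phase unwrapping by region growing.
//
// Pixel quality is the negative sum of squared wrapped phase differences to
// the 4-neighbours (flat regions are reliable, steep/noisy ones are not).
// Growth starts at the most reliable pixel and always unwraps the highest
// quality frontier pixel next relative to an already unwrapped neighbour, so
// errors in unreliable pixels cannot propagate into reliable regions.
// The seed keeps its wrapped value: output - input is a multiple of 2*pi
// everywhere and smooth fields are restored up to one global 2*pi offset.

static inline double wrap2pi(double x) {
  const double TWO_PI = 2.0 * M_PI;
  return x - TWO_PI * std::floor((x + M_PI) / TWO_PI);
}

struct Node {
  double quality;
  int idx;
  int ref;
  bool operator<(const Node& other) const { return quality < other.quality; }
};

// [[Rcpp::export(name = ".cpp_unwrap2d")]]
NumericMatrix cpp_unwrap2d(NumericMatrix phase) {
  int nr = phase.nrow(), nc = phase.ncol(), n = nr * nc;
  NumericMatrix out(nr, nc);
  std::vector<double> quality(n, 0.0);
  std::vector<char> done(n, 0);

  int best = 0;
  double bestq = -1e300;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int p = i + j * nr;
      double q = 0.0, v = phase[p];
      if (i > 0)      { double d = wrap2pi(v - phase[p - 1]);  q -= d * d; }
      if (i < nr - 1) { double d = wrap2pi(v - phase[p + 1]);  q -= d * d; }
      if (j > 0)      { double d = wrap2pi(v - phase[p - nr]); q -= d * d; }
      if (j < nc - 1) { double d = wrap2pi(v - phase[p + nr]); q -= d * d; }
      quality[p] = q;
      if (q > bestq) { bestq = q; best = p; }
    }
  }

  std::priority_queue<Node> pq;
  out[best] = phase[best];
  done[best] = 1;
  auto push_neighbours = [&](int p) {
    int i = p % nr, j = p / nr;
    int nb[4];
    int k = 0;
    if (i > 0) nb[k++] = p - 1;
    if (i < nr - 1) nb[k++] = p + 1;
    if (j > 0) nb[k++] = p - nr;
    if (j < nc - 1) nb[k++] = p + nr;
    for (int t = 0; t < k; ++t)
      if (!done[nb[t]]) pq.push(Node{quality[nb[t]], nb[t], p});
  };
  push_neighbours(best);

  while (!pq.empty()) {
    Node nd = pq.top();
    pq.pop();
    if (done[nd.idx]) continue;
    out[nd.idx] = out[nd.ref] + wrap2pi(phase[nd.idx] - out[nd.ref]);
    done[nd.idx] = 1;
    push_neighbours(nd.idx);
  }
  return out;
}
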