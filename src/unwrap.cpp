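// Quality-guided region-growing 3D phase unwrapping.
//
// Voxels are unwrapped in decreasing order of a quality map (typically the
// magnitude image): starting from the highest-quality voxel, neighbours are
// placed on a max-priority queue and each is unwrapped against the already
// unwrapped voxel that enqueued it by adding the integer multiple of 2*pi
// that minimises their difference. Ties in quality break on voxel index so
// the result is fully deterministic.

#include <Rcpp.h>
#include <queue>
#include <cmath>

using namespace Rcpp;

namespace {

struct Node {
  double q;      // quality of the voxel to unwrap
  int idx;       // linear voxel index
  double value;  // proposed unwrapped value
};

struct NodeCmp {
  bool operator()(const Node &a, const Node &b) const {
    if (a.q != b.q) return a.q < b.q;  // max-heap on quality
    return a.idx > b.idx;              // lower index wins on ties
  }
};

}  // namespace

// [[Rcpp::export]]
NumericVector unwrap_phase_cpp(NumericVector phase, NumericVector quality,
                               IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  const double two_pi = 2.0 * M_PI;
  if (phase.size() != n || quality.size() != n)
    stop("phase/quality size does not match dims");

  NumericVector out(n);
  std::vector<char> done(n, 0);

  int seed = 0;
  double best = quality[0];
  for (int i = 1; i < n; ++i) {
    if (quality[i] > best) { best = quality[i]; seed = i; }
  }

  std::priority_queue<Node, std::vector<Node>, NodeCmp> pq;
  pq.push(Node{quality[seed], seed, phase[seed]});

  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};

  while (!pq.empty()) {
    Node nd = pq.top();
    pq.pop();
    if (done[nd.idx]) continue;
    done[nd.idx] = 1;
    out[nd.idx] = nd.value;

    const int x = nd.idx % nx;
    const int y = (nd.idx / nx) % ny;
    const int z = nd.idx / (nx * ny);
    for (int d = 0; d < 6; ++d) {
      const int X = x + dx[d], Y = y + dy[d], Z = z + dz[d];
      if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
      const int j = X + nx * (Y + ny * Z);
      if (done[j]) continue;
      const double val =
          phase[j] + two_pi * std::round((nd.value - phase[j]) / two_pi);
      pq.push(Node{quality[j], j, val});
    }
  }
  return out;
}
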