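// Force-directed layout core: Fruchterman-Reingold style forces with a
// Barnes-Hut octree (theta = 0.8 by default) for the pairwise repulsion, a
// geometric cooling schedule capping per-iteration displacement, and a mean
// displacement stopping rule.  2D layouts run in the same code with the
// third coordinate pinned to zero.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct OctNode {
  double cx[3];        // cell centre
  double half;         // half side length
  double mass;
  double com[3];       // centre of mass
  int point;           // index of single point, -1 if internal/empty
  int children[8];
  bool leaf;
  OctNode() : half(0), mass(0), point(-1), leaf(true) {
    for (int i = 0; i < 3; ++i) { cx[i] = 0; com[i] = 0; }
    for (int i = 0; i < 8; ++i) children[i] = -1;
  }
};

class Octree {
public:
  std::vector<OctNode> nodes;
  const std::vector<double>& px;

  Octree(const std::vector<double>& pos, int n) : px(pos) {
    double lo[3] = {1e300, 1e300, 1e300}, hi[3] = {-1e300, -1e300, -1e300};
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        double v = pos[3 * i + d];
        if (v < lo[d]) lo[d] = v;
        if (v > hi[d]) hi[d] = v;
      }
    double half = 0;
    for (int d = 0; d < 3; ++d) half = std::max(half, (hi[d] - lo[d]) / 2);
    half = half * 1.0001 + 1e-9;
    OctNode root;
    for (int d = 0; d < 3; ++d) root.cx[d] = (lo[d] + hi[d]) / 2;
    root.half = half;
    nodes.push_back(root);
    for (int i = 0; i < n; ++i) insert(0, i, 0);
  }

  void insert(int node, int p, int depth) {
    OctNode& nd = nodes[node];
    if (nd.leaf && nd.point < 0) {           // empty leaf
      nd.point = p;
      accumulate(node, p);
      return;
    }
    if (nd.leaf) {                            // occupied leaf: split
      if (depth > 60) {                       // coincident points guard
        accumulate(node, p);
        return;
      }
      int old = nd.point;
      nd.leaf = false;
      nd.point = -1;
      push_down(node, old, depth);
    }
    accumulate(node, p);
    push_down(node, p, depth);
  }

  void push_down(int node, int p, int depth) {
    int oct = 0;
    double cx[3];
    for (int d = 0; d < 3; ++d) cx[d] = nodes[node].cx[d];
    double h = nodes[node].half / 2;
    double ncx[3];
    for (int d = 0; d < 3; ++d) {
      bool up = px[3 * p + d] >= cx[d];
      if (up) oct |= (1 << d);
      ncx[d] = cx[d] + (up ? h : -h);
    }
    int child = nodes[node].children[oct];
    if (child < 0) {
      OctNode nn;
      for (int d = 0; d < 3; ++d) nn.cx[d] = ncx[d];
      nn.half = h;
      nodes.push_back(nn);
      child = (int)nodes.size() - 1;
      nodes[node].children[oct] = child;
    }
    insert(child, p, depth + 1);
  }

  void accumulate(int node, int p) {
    OctNode& nd = nodes[node];
    double m = nd.mass + 1.0;
    for (int d = 0; d < 3; ++d)
      nd.com[d] = (nd.com[d] * nd.mass + px[3 * p + d]) / m;
    nd.mass = m;
  }

  // accumulate repulsive force k^2/d on point p
  void force(int node, int p, double theta, double k2, double* f) const {
    const OctNode& nd = nodes[node];
    if (nd.mass <= 0) return;
    double dx[3];
    double d2 = 0;
    for (int d = 0; d < 3; ++d) {
      dx[d] = px[3 * p + d] - nd.com[d];
      d2 += dx[d] * dx[d];
    }
    bool single = nd.leaf;
    double width = 2 * nd.half;
    if (single || width * width < theta * theta * d2) {
      if (d2 < 1e-12) {
        // coincident: deterministic tiny kick along axis by index parity
        double eps = 1e-4;
        double m = nd.mass - (single && nd.point == p ? 1.0 : 0.0);
        if (m <= 0) return;
        f[p % 3 == 0 ? 0 : (p % 3 == 1 ? 1 : 2)] += eps * m;
        return;
      }
      double m = nd.mass;
      if (single && nd.point == p) return;      // exclude self
      // FR repulsion magnitude k^2/d, applied along the unit separation
      double mag = k2 * m / d2;                 // = (k^2/d) / d, times dx below
      for (int d = 0; d < 3; ++d) f[d] += mag * dx[d];
      return;
    }
    for (int c = 0; c < 8; ++c)
      if (nd.children[c] >= 0) force(nd.children[c], p, theta, k2, f);
  }
};

} // namespace

// [[Rcpp::export(name = ".fr_layout_cpp")]]
List fr_layout_cpp(NumericMatrix init, IntegerVector from, IntegerVector to,
                   NumericVector weight, int dims, int max_iter, double tol,
                   double ideal = 1.0, double theta = 0.8,
                   double cooling = 0.95) {
  int n = init.nrow();
  int m = from.size();
  std::vector<double> pos(3 * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < dims; ++d) pos[3 * i + d] = init(i, d);

  double k = ideal;
  double k2 = k * k;
  double temp = 0.1 * std::sqrt((double)n) * k;   // initial step cap
  double min_temp = 1e-4 * k;
  std::vector<double> disp(3 * n);
  int it = 0;
  bool converged = false;

  for (it = 0; it < max_iter; ++it) {
    std::fill(disp.begin(), disp.end(), 0.0);
    Octree tree(pos, n);
    for (int i = 0; i < n; ++i) {
      double f[3] = {0, 0, 0};
      tree.force(0, i, theta, k2, f);
      for (int d = 0; d < dims; ++d) disp[3 * i + d] += f[d];
    }
    // attraction along edges: d^2/k per unit length, scaled by weight
    for (int e = 0; e < m; ++e) {
      int a = from[e], b = to[e];
      double dx[3], d2 = 0;
      for (int d = 0; d < 3; ++d) {
        dx[d] = pos[3 * a + d] - pos[3 * b + d];
        d2 += dx[d] * dx[d];
      }
      double dist = std::sqrt(d2);
      if (dist < 1e-12) continue;
      double mag = weight[e] * dist / k;          // F_a = d^2/k, direction unit
      for (int d = 0; d < dims; ++d) {
        double step = mag * dx[d] / dist;
        disp[3 * a + d] -= step;
        disp[3 * b + d] += step;
      }
    }
    // move, capped by temperature
    double total_move = 0;
    for (int i = 0; i < n; ++i) {
      double d2 = 0;
      for (int d = 0; d < dims; ++d) d2 += disp[3 * i + d] * disp[3 * i + d];
      double len = std::sqrt(d2);
      if (len < 1e-15) continue;
      double step = std::min(len, temp);
      for (int d = 0; d < dims; ++d)
        pos[3 * i + d] += disp[3 * i + d] / len * step;
      total_move += step;
    }
    double mean_move = n ? total_move / n : 0.0;
    if (temp > min_temp) temp *= cooling;
    if (mean_move < tol * k) { converged = true; ++it; break; }
  }

  NumericMatrix out(n, dims);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < dims; ++d) out(i, d) = pos[3 * i + d];
  return List::create(_["coords"] = out, _["iterations"] = it,
                      _["converged"] = converged);
}
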