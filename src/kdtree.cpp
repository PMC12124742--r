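#include <Rcpp.h>
#include <functional>
#include <set>
using namespace Rcpp;

// A 2-d kd-tree over cell centers with fixed-radius queries, used for
// pairwise overlap detection and the relaxation shover.  Periodic axes
// are handled by inserting ghost images of points lying within a margin
// of a periodic edge; candidate hits are mapped back to original
// indices and confirmed against the minimum-image distance, which is
// authoritative.  Coordinates here are physical (um).

namespace {

struct KD {
  std::vector<double> xs, ys;  // tree point coordinates (incl. ghosts)
  std::vector<int> id;         // original index of each tree point
  std::vector<int> ord;        // kd ordering (median-split layout)

  void add(double x, double y, int i) {
    xs.push_back(x); ys.push_back(y); id.push_back(i);
  }

  void build() {
    ord.resize(xs.size());
    for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
    rec(0, (int)ord.size(), 0);
  }

  void rec(int lo, int hi, int depth) {
    if (hi - lo <= 1) return;
    int mid = (lo + hi) / 2;
    if (depth % 2 == 0)
      std::nth_element(ord.begin() + lo, ord.begin() + mid, ord.begin() + hi,
                       [&](int a, int b) { return xs[a] < xs[b]; });
    else
      std::nth_element(ord.begin() + lo, ord.begin() + mid, ord.begin() + hi,
                       [&](int a, int b) { return ys[a] < ys[b]; });
    rec(lo, mid, depth + 1);
    rec(mid + 1, hi, depth + 1);
  }

  void query(double qx, double qy, double R, std::vector<int> &out) const {
    qrec(0, (int)ord.size(), 0, qx, qy, R, out);
  }

  void qrec(int lo, int hi, int depth, double qx, double qy, double R,
            std::vector<int> &out) const {
    if (hi <= lo) return;
    const int mid = (lo + hi) / 2;
    const int p = ord[mid];
    const double dx = xs[p] - qx, dy = ys[p] - qy;
    if (dx * dx + dy * dy <= R * R) out.push_back(p);
    const double dsplit = (depth % 2 == 0) ? dx : dy;
    if (dsplit >= -R) qrec(lo, mid, depth + 1, qx, qy, R, out);
    if (dsplit <= R) qrec(mid + 1, hi, depth + 1, qx, qy, R, out);
  }
};

// tree over the n points, ghost images within `margin` of periodic edges
KD make_tree(const NumericVector &x, const NumericVector &y,
             double Lx, double Ly, bool px, bool py, double margin) {
  KD kd;
  const int n = x.size();
  for (int i = 0; i < n; ++i) {
    for (int sx = -1; sx <= 1; ++sx) {
      if (sx != 0 && !px) continue;
      const double gx = x[i] + sx * Lx;
      // originals are always kept; only ghost images are bounds-filtered
      if (sx != 0 && (gx < -margin || gx > Lx + margin)) continue;
      for (int sy = -1; sy <= 1; ++sy) {
        if (sy != 0 && !py) continue;
        const double gy = y[i] + sy * Ly;
        if ((sx != 0 || sy != 0) && (gy < -margin || gy > Ly + margin))
          continue;
        kd.add(gx, gy, i);
      }
    }
  }
  kd.build();
  return kd;
}

inline double axdist(double a, double b, double L, bool per) {
  double d = a - b;
  if (per) d -= L * std::floor(d / L + 0.5);  // nearest periodic image
  return d;
}

inline double mi_dist(double x1, double y1, double x2, double y2,
                      double Lx, double Ly, bool px, bool py) {
  const double dx = axdist(x1, x2, Lx, px);
  const double dy = axdist(y1, y2, Ly, py);
  return std::sqrt(dx * dx + dy * dy);
}

inline double wrap(double v, double L) {
  double w = v - L * std::floor(v / L);
  return (w == L) ? 0.0 : w;
}

}  // namespace

// [[Rcpp::export]]
IntegerVector cpp_kd_query(NumericVector x, NumericVector y,
                           double qx, double qy, double R,
                           double Lx, double Ly, bool px, bool py) {
  KD kd = make_tree(x, y, Lx, Ly, px, py, R + 1e-9);
  std::vector<int> hits;
  kd.query(qx, qy, R, hits);
  std::set<int> uniq;
  for (int h : hits) {
    const int i = kd.id[h];
    if (mi_dist(x[i], y[i], qx, qy, Lx, Ly, px, py) <= R) uniq.insert(i);
  }
  IntegerVector out(uniq.size());
  int k = 0;
  for (int i : uniq) out[k++] = i + 1;  // 1-based
  return out;
}

// all unordered pairs (i < j) with center distance < r_i + r_j
// [[Rcpp::export]]
NumericMatrix cpp_kd_pairs(NumericVector x, NumericVector y, NumericVector r,
                           double Lx, double Ly, bool px, bool py) {
  const int n = x.size();
  if (n < 2) return NumericMatrix(0, 3);
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, (double)r[i]);
  KD kd = make_tree(x, y, Lx, Ly, px, py, 2.0 * rmax + 1e-9);
  std::set<std::pair<int, int> > seen;
  std::vector<double> pi, pj, pd;
  std::vector<int> hits;
  for (int i = 0; i < n; ++i) {
    hits.clear();
    kd.query(x[i], y[i], r[i] + rmax, hits);
    for (int h : hits) {
      const int j = kd.id[h];
      if (j <= i) continue;
      const double d = mi_dist(x[i], y[i], x[j], y[j], Lx, Ly, px, py);
      if (d < r[i] + r[j] && seen.insert(std::make_pair(i, j)).second) {
        pi.push_back(i + 1);
        pj.push_back(j + 1);
        pd.push_back(d);
      }
    }
  }
  NumericMatrix out((int)pi.size(), 3);
  for (size_t k = 0; k < pi.size(); ++k) {
    out(k, 0) = pi[k]; out(k, 1) = pj[k]; out(k, 2) = pd[k];
  }
  return out;
}

// Relaxation shover: sweeps in ascending id order; each overlapping pair
// is displaced symmetrically by depth/2 along the center line.  The tree
// is rebuilt at the start of every sweep; displacements use current
// positions.  Coincident centers separate along the focal cell's
// fallback angle (drawn from the caller's seeded RNG).  Terminates when
// the deepest overlap seen in a sweep is <= tol or after max_sweeps.
// [[Rcpp::export]]
List cpp_relax_shove(NumericVector x_in, NumericVector y_in, NumericVector r,
                     double Lx, double Ly, bool px, bool py,
                     bool solid_bottom, bool solid_top,
                     double tol, int max_sweeps, NumericVector angles) {
  NumericVector x = clone(x_in), y = clone(y_in);
  const int n = x.size();
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, (double)r[i]);
  int sweeps = 0;
  double max_depth = 0.0;
  int n_coincident = 0;
  std::vector<int> hits;
  for (int s = 0; s < max_sweeps; ++s) {
    ++sweeps;
    max_depth = 0.0;
    KD kd = make_tree(x, y, Lx, Ly, px, py, 2.0 * rmax + 1e-9);
    for (int i = 0; i < n; ++i) {
      hits.clear();
      kd.query(x[i], y[i], r[i] + rmax, hits);
      for (int h : hits) {
        const int j = kd.id[h];
        if (j == i) continue;
        const double dx = axdist(x[j], x[i], Lx, px);
        const double dy = axdist(y[j], y[i], Ly, py);
        const double d = std::sqrt(dx * dx + dy * dy);
        const double depth = r[i] + r[j] - d;
        if (depth <= tol) continue;
        if (depth > max_depth) max_depth = depth;
        double ux, uy;
        if (d < 1e-12) {
          ux = std::cos(angles[i]); uy = std::sin(angles[i]);
          ++n_coincident;
        } else {
          ux = dx / d; uy = dy / d;
        }
        x[i] -= 0.5 * depth * ux; y[i] -= 0.5 * depth * uy;
        x[j] += 0.5 * depth * ux; y[j] += 0.5 * depth * uy;
        for (int c : {i, j}) {
          if (px) x[c] = wrap(x[c], Lx);
          if (py) y[c] = wrap(y[c], Ly);
          if (solid_bottom && y[c] < r[c]) y[c] = r[c];
          if (solid_top && y[c] > Ly - r[c]) y[c] = Ly - r[c];
        }
      }
    }
    if (max_depth <= tol) break;
  }
  return List::create(_["x"] = x, _["y"] = y, _["sweeps"] = sweeps,
                      _["max_depth"] = max_depth,
                      _["n_coincident"] = n_coincident);
}
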