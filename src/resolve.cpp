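#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Core kernels of the grid-based overlap resolver.
//
// Occupancy grids are W x H matrices indexed [i + 1, j + 1] with i the
// 0-based x/column index and j the 0-based y/row index; unit (i, j)
// spans the half-open box [i, i+1) x [j, j+1) in continuous grid
// coordinates.  Cell centers and half-extents (rx = r/w, ry = r/h) are
// given in grid units.  Periodic axes wrap; on non-periodic axes mass
// falling outside the domain is truncated.
//
// Direction layers: 0 down, 1 right, 2 up, 3 left, then for the Moore
// variant 4 up-right, 5 up-left, 6 down-left, 7 down-right.

namespace {

static const int DI[8] = {0, 1, 0, -1, 1, -1, -1, 1};
static const int DJ[8] = {-1, 0, 1, 0, 1, 1, -1, -1};

// wrap tables: xm[i] = left neighbor column (-1 if off-grid), etc.
struct GridGeom {
  int W, H;
  bool px, py;
  std::vector<int> xm, xp, ym, yp;
  GridGeom(int W_, int H_, bool px_, bool py_)
      : W(W_), H(H_), px(px_), py(py_), xm(W_), xp(W_), ym(H_), yp(H_) {
    for (int i = 0; i < W; ++i) {
      xm[i] = (i > 0) ? i - 1 : (px ? W - 1 : -1);
      xp[i] = (i < W - 1) ? i + 1 : (px ? 0 : -1);
    }
    for (int j = 0; j < H; ++j) {
      ym[j] = (j > 0) ? j - 1 : (py ? H - 1 : -1);
      yp[j] = (j < H - 1) ? j + 1 : (py ? 0 : -1);
    }
  }
  // linear index of the neighbor of (i, j) in direction d; -1 off-grid
  inline long nbr(int i, int j, int d) const {
    const int ii = (DI[d] == 0) ? i : (DI[d] > 0 ? xp[i] : xm[i]);
    if (ii < 0) return -1;
    const int jj = (DJ[d] == 0) ? j : (DJ[d] > 0 ? yp[j] : ym[j]);
    if (jj < 0) return -1;
    return ii + (long)W * jj;
  }
};

// rasterize the cells' bounding squares, accumulating into omega
void rasterize_add(std::vector<double> &omega, const double *x,
                   const double *y, const double *rx, const double *ry,
                   int n, const GridGeom &g) {
  for (int k = 0; k < n; ++k) {
    const double xl = x[k] - rx[k], xr = x[k] + rx[k];
    const double yb = y[k] - ry[k], yt = y[k] + ry[k];
    const int i0 = (int)std::floor(xl), i1 = (int)std::ceil(xr) - 1;
    const int j0 = (int)std::floor(yb), j1 = (int)std::ceil(yt) - 1;
    for (int i = i0; i <= i1; ++i) {
      double ox = std::min((double)i + 1.0, xr) - std::max((double)i, xl);
      if (ox <= 0.0) continue;
      int ii = i;
      if (g.px) { ii = (i % g.W + g.W) % g.W; }
      else if (i < 0 || i >= g.W) continue;
      for (int j = j0; j <= j1; ++j) {
        double oy = std::min((double)j + 1.0, yt) - std::max((double)j, yb);
        if (oy <= 0.0) continue;
        int jj = j;
        if (g.py) { jj = (j % g.H + g.H) % g.H; }
        else if (j < 0 || j >= g.H) continue;
        omega[ii + (size_t)g.W * jj] += ox * oy;
      }
    }
  }
}

struct ResolveStats {
  int iterations = 0;
  double max_delta = 0.0;
  double residual = 0.0;
};

// iterative excess redistribution with motion accumulation:
//   omega' = omega - alpha * (E - wn * sum_N E),  E = max(0, omega - 1)
//   M[u][d] += alpha * wn * max(0, E_u - E_nbr)   (clamped by default)
// Updates are confined to the active set (units with positive excess
// plus their stencil neighbors; occupancy can change nowhere else) —
// an exact optimization.
ResolveStats resolve_iterate(std::vector<double> &omega,
                             std::vector<double> &M, const GridGeom &g,
                             double alpha, double tol, int max_iters,
                             int L, bool signed_motion) {
  const size_t WH = (size_t)g.W * g.H;
  const double wn = 1.0 / (double)L;
  std::vector<double> Ev(WH, 0.0);
  std::vector<int> exc, active, stamp(WH, -1);
  ResolveStats st;
  double max_excess = 0.0;

  for (size_t u = 0; u < WH; ++u) {
    const double e = omega[u] - 1.0;
    if (e > 0.0) {
      Ev[u] = e;
      exc.push_back((int)u);
      if (e > max_excess) max_excess = e;
    }
  }

  while (st.iterations < max_iters) {
    ++st.iterations;
    if (exc.empty()) { st.max_delta = 0.0; max_excess = 0.0; break; }

    active.clear();
    for (int u : exc) {
      if (stamp[u] != st.iterations) {
        stamp[u] = st.iterations;
        active.push_back(u);
      }
      const int i = u % g.W, j = u / g.W;
      for (int d = 0; d < L; ++d) {
        const long v = g.nbr(i, j, d);
        if (v >= 0 && stamp[v] != st.iterations) {
          stamp[v] = st.iterations;
          active.push_back((int)v);
        }
      }
    }

    st.max_delta = 0.0;
    if (L == 4) {
      // unrolled von Neumann update (the hot path)
      const double aw = alpha * wn;
      for (int u : active) {
        const int i = u % g.W, j = u / g.W;
        const double e = Ev[u];
        const int im = g.xm[i], ip = g.xp[i], jm = g.ym[j], jp = g.yp[j];
        const double ed = (jm >= 0) ? Ev[i + (size_t)g.W * jm] : 0.0;
        const double er = (ip >= 0) ? Ev[ip + (size_t)g.W * j] : 0.0;
        const double eu = (jp >= 0) ? Ev[i + (size_t)g.W * jp] : 0.0;
        const double el = (im >= 0) ? Ev[im + (size_t)g.W * j] : 0.0;
        double f;
        f = aw * (e - ed);
        if (f > 0.0 || (signed_motion && f != 0.0)) M[u] += f;
        f = aw * (e - er);
        if (f > 0.0 || (signed_motion && f != 0.0)) M[u + WH] += f;
        f = aw * (e - eu);
        if (f > 0.0 || (signed_motion && f != 0.0)) M[u + 2 * WH] += f;
        f = aw * (e - el);
        if (f > 0.0 || (signed_motion && f != 0.0)) M[u + 3 * WH] += f;
        const double delta = alpha * (e - wn * (ed + er + eu + el));
        omega[u] -= delta;
        const double ad = std::fabs(delta);
        if (ad > st.max_delta) st.max_delta = ad;
      }
    } else {
      for (int u : active) {
        const int i = u % g.W, j = u / g.W;
        const double e = Ev[u];
        double en = 0.0;
        for (int d = 0; d < L; ++d) {
          const long v = g.nbr(i, j, d);
          const double ekl = (v >= 0) ? Ev[v] : 0.0;
          en += ekl;
          double flow = alpha * wn * (e - ekl);
          if (!signed_motion && flow < 0.0) flow = 0.0;
          if (flow != 0.0) M[u + WH * d] += flow;
        }
        const double delta = alpha * (e - wn * en);
        omega[u] -= delta;
        const double ad = std::fabs(delta);
        if (ad > st.max_delta) st.max_delta = ad;
      }
    }

    exc.clear();
    max_excess = 0.0;
    for (int u : active) {
      double e = omega[u] - 1.0;
      if (e < 0.0) e = 0.0;
      Ev[u] = e;
      if (e > 0.0) {
        exc.push_back(u);
        if (e > max_excess) max_excess = e;
      }
    }
    if (st.max_delta < tol) break;
  }
  st.residual = max_excess;
  return st;
}

// Back-translation: per-unit movement vectors summed over each cell's
// covered units.  Units covered by N > 1 cells partition the covering
// cells into positive/negative movers per axis in proportion
// round(N * M+ / (M+ + M-)); positive movers are the cells furthest
// along that axis within the unit (ties by ascending id), each receiving
// an equal share.  Moore diagonal layers contribute 1/sqrt(2) of their
// magnitude to each adjacent cardinal component.
void back_translate(double *Vx, double *Vy, const double *x,
                    const double *y, const double *rx, const double *ry,
                    int n, const double *M, int L, const GridGeom &g) {
  const size_t WH = (size_t)g.W * g.H;
  const double eps = 1e-12;
  std::vector<int> cnt(WH, 0);

  auto for_each_unit = [&](int k, auto &&fn) {
    const double xl = x[k] - rx[k], xr = x[k] + rx[k];
    const double yb = y[k] - ry[k], yt = y[k] + ry[k];
    const int i0 = (int)std::floor(xl), i1 = (int)std::ceil(xr) - 1;
    const int j0 = (int)std::floor(yb), j1 = (int)std::ceil(yt) - 1;
    for (int i = i0; i <= i1; ++i) {
      double ox = std::min((double)i + 1.0, xr) - std::max((double)i, xl);
      if (ox <= eps) continue;
      int ii = i;
      if (g.px) { ii = (i % g.W + g.W) % g.W; }
      else if (i < 0 || i >= g.W) continue;
      for (int j = j0; j <= j1; ++j) {
        double oy = std::min((double)j + 1.0, yt) - std::max((double)j, yb);
        if (oy <= eps) continue;
        int jj = j;
        if (g.py) { jj = (j % g.H + g.H) % g.H; }
        else if (j < 0 || j >= g.H) continue;
        fn(ii, jj);
      }
    }
  };

  for (int k = 0; k < n; ++k)
    for_each_unit(k, [&](int i, int j) { cnt[i + (size_t)g.W * j]++; });

  std::vector<size_t> off(WH + 1, 0);
  for (size_t u = 0; u < WH; ++u) off[u + 1] = off[u] + cnt[u];
  std::vector<int> members(off[WH]);
  std::vector<size_t> pos(off.begin(), off.end() - 1);
  for (int k = 0; k < n; ++k)   // ascending k => ascending id within a unit
    for_each_unit(k, [&](int i, int j) {
      members[pos[i + (size_t)g.W * j]++] = k;
    });

  const double s2 = 1.0 / std::sqrt(2.0);
  std::vector<int> mem;
  for (size_t u = 0; u < WH; ++u) {
    const int N = cnt[u];
    if (N == 0) continue;
    double Md = M[u], Mr = M[u + WH], Mu = M[u + 2 * WH], Ml = M[u + 3 * WH];
    if (L == 8) {
      Mr += s2 * (M[u + 4 * WH] + M[u + 7 * WH]);
      Ml += s2 * (M[u + 5 * WH] + M[u + 6 * WH]);
      Mu += s2 * (M[u + 4 * WH] + M[u + 5 * WH]);
      Md += s2 * (M[u + 6 * WH] + M[u + 7 * WH]);
    }
    if (N == 1) {
      const int k = members[off[u]];
      Vx[k] += Mr - Ml;
      Vy[k] += Mu - Md;
    } else {
      mem.assign(members.begin() + off[u], members.begin() + off[u] + N);
      const double th = Mr + Ml;
      if (th > 0.0) {
        int nR = (int)std::lround((double)N * Mr / th);
        if (nR < 0) nR = 0;
        if (nR > N) nR = N;
        std::sort(mem.begin(), mem.end(), [&](int a, int b) {
          if (x[a] != x[b]) return x[a] > x[b];
          return a < b;
        });
        for (int t = 0; t < N; ++t) {
          const int k = mem[t];
          if (t < nR) Vx[k] += Mr / (double)nR;
          else Vx[k] -= Ml / (double)(N - nR);
        }
      }
      const double tv = Mu + Md;
      if (tv > 0.0) {
        int nU = (int)std::lround((double)N * Mu / tv);
        if (nU < 0) nU = 0;
        if (nU > N) nU = N;
        std::sort(mem.begin(), mem.end(), [&](int a, int b) {
          if (y[a] != y[b]) return y[a] > y[b];
          return a < b;
        });
        for (int t = 0; t < N; ++t) {
          const int k = mem[t];
          if (t < nU) Vy[k] += Mu / (double)nU;
          else Vy[k] -= Md / (double)(N - nU);
        }
      }
    }
  }
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_build_occupancy(NumericVector x, NumericVector y,
                                  NumericVector rx, NumericVector ry,
                                  int W, int H, bool px, bool py) {
  GridGeom g(W, H, px, py);
  std::vector<double> om((size_t)W * H, 0.0);
  rasterize_add(om, x.begin(), y.begin(), rx.begin(), ry.begin(),
                x.size(), g);
  NumericMatrix out(W, H);
  std::copy(om.begin(), om.end(), out.begin());
  return out;
}

// weighted rasterization: cell k deposits weight[k], distributed over
// its covered units in proportion to the fractional overlap (the share
// lost outside a non-periodic edge is truncated, as for occupancy)
// [[Rcpp::export]]
NumericMatrix cpp_rasterize_weighted(NumericVector x, NumericVector y,
                                     NumericVector rx, NumericVector ry,
                                     NumericVector weight, int W, int H,
                                     bool px, bool py) {
  GridGeom g(W, H, px, py);
  NumericMatrix out(W, H);
  const int n = x.size();
  for (int k = 0; k < n; ++k) {
    const double area = 4.0 * rx[k] * ry[k];
    if (area <= 0.0) continue;
    const double scale = weight[k] / area;
    const double xl = x[k] - rx[k], xr = x[k] + rx[k];
    const double yb = y[k] - ry[k], yt = y[k] + ry[k];
    const int i0 = (int)std::floor(xl), i1 = (int)std::ceil(xr) - 1;
    const int j0 = (int)std::floor(yb), j1 = (int)std::ceil(yt) - 1;
    for (int i = i0; i <= i1; ++i) {
      double ox = std::min((double)i + 1.0, xr) - std::max((double)i, xl);
      if (ox <= 0.0) continue;
      int ii = i;
      if (px) { ii = (i % W + W) % W; }
      else if (i < 0 || i >= W) continue;
      for (int j = j0; j <= j1; ++j) {
        double oy = std::min((double)j + 1.0, yt) - std::max((double)j, yb);
        if (oy <= 0.0) continue;
        int jj = j;
        if (py) { jj = (j % H + H) % H; }
        else if (j < 0 || j >= H) continue;
        out(ii, jj) += scale * ox * oy;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_resolve(NumericMatrix omega_in, double alpha, double tol,
                 int max_iters, bool moore, bool px, bool py,
                 bool signed_motion) {
  const int W = omega_in.nrow(), H = omega_in.ncol();
  const int L = moore ? 8 : 4;
  GridGeom g(W, H, px, py);
  std::vector<double> om(omega_in.begin(), omega_in.end());
  std::vector<double> M((size_t)W * H * L, 0.0);
  ResolveStats st = resolve_iterate(om, M, g, alpha, tol, max_iters, L,
                                    signed_motion);
  NumericMatrix omega(W, H);
  std::copy(om.begin(), om.end(), omega.begin());
  NumericVector Mout((R_xlen_t)M.size());
  std::copy(M.begin(), M.end(), Mout.begin());
  Mout.attr("dim") = IntegerVector::create(W, H, L);
  return List::create(_["omega"] = omega, _["motion"] = Mout,
                      _["iterations"] = st.iterations,
                      _["max_delta"] = st.max_delta,
                      _["residual_excess"] = st.residual);
}

// [[Rcpp::export]]
NumericMatrix cpp_cell_movements(NumericVector x, NumericVector y,
                                 NumericVector rx, NumericVector ry,
                                 NumericVector M, int W, int H, int L,
                                 bool px, bool py) {
  const int n = x.size();
  GridGeom g(W, H, px, py);
  NumericMatrix V(n, 2);
  std::vector<double> vx(n, 0.0), vy(n, 0.0);
  back_translate(vx.data(), vy.data(), x.begin(), y.begin(), rx.begin(),
                 ry.begin(), n, M.begin(), L, g);
  for (int k = 0; k < n; ++k) {
    V(k, 0) = vx[k];
    V(k, 1) = vy[k];
  }
  return V;
}

// Fused pipeline (forward translation -> excess redistribution -> back
// translation) used by the simulation hot path; equivalent to composing
// the three staged kernels but without materializing the occupancy
// matrix or motion tensor as R objects.
// [[Rcpp::export]]
List cpp_dora(NumericVector x, NumericVector y, NumericVector rx,
              NumericVector ry, int W, int H, bool px, bool py,
              double alpha, double tol, int max_iters, bool moore,
              bool signed_motion) {
  const int n = x.size();
  const int L = moore ? 8 : 4;
  GridGeom g(W, H, px, py);
  std::vector<double> om((size_t)W * H, 0.0);
  rasterize_add(om, x.begin(), y.begin(), rx.begin(), ry.begin(), n, g);
  std::vector<double> M((size_t)W * H * L, 0.0);
  ResolveStats st = resolve_iterate(om, M, g, alpha, tol, max_iters, L,
                                    signed_motion);
  NumericMatrix V(n, 2);
  if (st.iterations > 1 || st.residual > 0.0) {
    std::vector<double> vx(n, 0.0), vy(n, 0.0);
    back_translate(vx.data(), vy.data(), x.begin(), y.begin(), rx.begin(),
                   ry.begin(), n, M.data(), L, g);
    for (int k = 0; k < n; ++k) {
      V(k, 0) = vx[k];
      V(k, 1) = vy[k];
    }
  }
  return List::create(_["V"] = V, _["iterations"] = st.iterations,
                      _["max_delta"] = st.max_delta,
                      _["residual_excess"] = st.residual);
}
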