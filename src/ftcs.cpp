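#include <Rcpp.h>
using namespace Rcpp;

// Forward-Time Central-Space diffusion on a cell-centered nx x ny grid
// (S indexed [i = x, j = y], nrow = nx).  Boundary codes per edge:
// 0 periodic, 1 Neumann (zero flux, mirrored ghost), 2 Dirichlet
// (edge cells pinned to the bulk concentration).  A per-substep sink
// matrix is subtracted after the diffusion update; negative values are
// floored at zero and the total floored mass is reported as a deficit
// (concentration units, summed over units and substeps).

// [[Rcpp::export]]
List cpp_ftcs(NumericMatrix S_in, double D, double dt, double dx, int nsub,
              NumericMatrix sink, int bc_left, int bc_right,
              int bc_bottom, int bc_top, double bulk) {
  const int nx = S_in.nrow(), ny = S_in.ncol();
  NumericMatrix S = clone(S_in), T(nx, ny);
  const double c = D * dt / (dx * dx);
  const bool has_sink = sink.nrow() == nx && sink.ncol() == ny;
  double deficit = 0.0;

  auto pin = [&](NumericMatrix &A) {
    if (bc_left == 2)   for (int j = 0; j < ny; ++j) A(0, j) = bulk;
    if (bc_right == 2)  for (int j = 0; j < ny; ++j) A(nx - 1, j) = bulk;
    if (bc_bottom == 2) for (int i = 0; i < nx; ++i) A(i, 0) = bulk;
    if (bc_top == 2)    for (int i = 0; i < nx; ++i) A(i, ny - 1) = bulk;
  };
  pin(S);

  for (int s = 0; s < nsub; ++s) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const double sc = S(i, j);
        double sl, sr, sd, su;
        if (i > 0) sl = S(i - 1, j);
        else sl = (bc_left == 0) ? S(nx - 1, j) : sc;      // mirror if not periodic
        if (i < nx - 1) sr = S(i + 1, j);
        else sr = (bc_right == 0) ? S(0, j) : sc;
        if (j > 0) sd = S(i, j - 1);
        else sd = (bc_bottom == 0) ? S(i, ny - 1) : sc;
        if (j < ny - 1) su = S(i, j + 1);
        else su = (bc_top == 0) ? S(i, 0) : sc;
        double v = sc + c * (sl + sr + sd + su - 4.0 * sc);
        if (has_sink) v -= sink(i, j);
        if (v < 0.0) { deficit += -v; v = 0.0; }
        T(i, j) = v;
      }
    }
    pin(T);
    std::swap(S, T);
  }
  return List::create(_["S"] = S, _["deficit"] = deficit);
}
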