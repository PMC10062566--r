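#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Periodic cylinder substrate: collision acceleration via a 2D cell list.
// Each cylinder is registered in every cell overlapped by its bounding box;
// a step segment queries the cells overlapped by its own bounding box, which
// is guaranteed to cover any circle the segment can intersect.
namespace {

struct CellGrid {
  int nc;
  double cell, L;
  std::vector< std::vector<int> > cells;

  CellGrid(const NumericVector& cx, const NumericVector& cy,
           const NumericVector& r, double L_, double max_extent) : L(L_) {
    double target = max_extent;
    nc = (int) std::floor(L / std::max(target, 1e-12));
    if (nc < 1) nc = 1;
    if (nc > 64) nc = 64;
    cell = L / nc;
    cells.assign((size_t) nc * nc, std::vector<int>());
    for (int i = 0; i < cx.size(); ++i)
      register_box(cx[i] - r[i], cx[i] + r[i], cy[i] - r[i], cy[i] + r[i], i);
  }

  inline int wrap_idx(int k) const {
    k %= nc;
    return k < 0 ? k + nc : k;
  }

  void register_box(double x0, double x1, double y0, double y1, int id) {
    int ix0 = (int) std::floor(x0 / cell), ix1 = (int) std::floor(x1 / cell);
    int iy0 = (int) std::floor(y0 / cell), iy1 = (int) std::floor(y1 / cell);
    if (ix1 - ix0 >= nc) { ix0 = 0; ix1 = nc - 1; }
    if (iy1 - iy0 >= nc) { iy0 = 0; iy1 = nc - 1; }
    for (int ix = ix0; ix <= ix1; ++ix)
      for (int iy = iy0; iy <= iy1; ++iy) {
        std::vector<int>& v = cells[(size_t) wrap_idx(ix) * nc + wrap_idx(iy)];
        if (v.empty() || v.back() != id) v.push_back(id);
      }
  }

  // Collect candidate cylinder ids for a segment bounding box.
  void query(double x0, double x1, double y0, double y1,
             std::vector<int>& out, std::vector<char>& seen) const {
    out.clear();
    if (x0 > x1) std::swap(x0, x1);
    if (y0 > y1) std::swap(y0, y1);
    int ix0 = (int) std::floor(x0 / cell), ix1 = (int) std::floor(x1 / cell);
    int iy0 = (int) std::floor(y0 / cell), iy1 = (int) std::floor(y1 / cell);
    if (ix1 - ix0 >= nc) { ix0 = 0; ix1 = nc - 1; }
    if (iy1 - iy0 >= nc) { iy0 = 0; iy1 = nc - 1; }
    for (int ix = ix0; ix <= ix1; ++ix)
      for (int iy = iy0; iy <= iy1; ++iy) {
        const std::vector<int>& v =
          cells[(size_t) wrap_idx(ix) * nc + wrap_idx(iy)];
        for (size_t k = 0; k < v.size(); ++k)
          if (!seen[v[k]]) { seen[v[k]] = 1; out.push_back(v[k]); }
      }
    for (size_t k = 0; k < out.size(); ++k) seen[out[k]] = 0;
  }
};

inline double min_image(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

}  // namespace

// Spins take isotropic Gaussian steps; segments crossing a cylinder wall are
// specularly reflected (possibly several times per step). Positions are
// returned unwrapped; collision tests use the wrapped (periodic) frame.
// start: N x 3 matrix in [0, L)^3, all extracellular.
// Returns list(x, y, z) of (n_steps + 1) x N matrices plus the number of
// sub-steps truncated at the reflection cap.
// [[Rcpp::export]]
List cpp_walk_restricted(NumericMatrix start, int n_steps, double step_sd,
                         NumericVector cx, NumericVector cy,
                         NumericVector radii, double L, int max_reflect) {
  const int N = start.nrow();
  const int M = cx.size();
  const double eps_push = 1e-10;

  double maxr = 0.0;
  for (int i = 0; i < M; ++i) maxr = std::max(maxr, radii[i]);
  CellGrid grid(cx, cy, radii, L, maxr + 6.0 * step_sd);

  // Validate extracellular starts.
  for (int s = 0; s < N; ++s) {
    for (int i = 0; i < M; ++i) {
      double dx = min_image(start(s, 0) - cx[i], L);
      double dy = min_image(start(s, 1) - cy[i], L);
      if (dx * dx + dy * dy < radii[i] * radii[i] * (1.0 - 1e-12))
        stop("spin %d is initialised inside cylinder %d", s + 1, i + 1);
    }
  }

  NumericMatrix X(n_steps + 1, N), Y(n_steps + 1, N), Z(n_steps + 1, N);
  std::vector<int> cand;
  std::vector<char> seen((size_t) std::max(M, 1), 0);
  int n_clamped = 0;

  for (int s = 0; s < N; ++s) {
    double ux = start(s, 0), uy = start(s, 1), uz = start(s, 2);  // unwrapped
    double wx = ux, wy = uy;                                      // wrapped
    X(0, s) = ux; Y(0, s) = uy; Z(0, s) = uz;

    for (int t = 1; t <= n_steps; ++t) {
      double vx = norm_rand() * step_sd;
      double vy = norm_rand() * step_sd;
      double vz = norm_rand() * step_sd;
      uz += vz;

      if (M == 0) {
        ux += vx; uy += vy;
        wx = ux - L * std::floor(ux / L);
        wy = uy - L * std::floor(uy / L);
      } else {
        // Reflect the 2D segment (px, py) -> (px + vx, py + vy).
        double px = wx, py = wy;
        int nref = 0;
        while (true) {
          grid.query(px, px + vx, py, py + vy, cand, seen);
          double tmin = 2.0;
          int hit = -1;
          double a = vx * vx + vy * vy;
          if (a > 0.0) {
            for (size_t k = 0; k < cand.size(); ++k) {
              int i = cand[k];
              double ox = min_image(px - cx[i], L);
              double oy = min_image(py - cy[i], L);
              double b = 2.0 * (ox * vx + oy * vy);
              double c = ox * ox + oy * oy - radii[i] * radii[i];
              double disc = b * b - 4.0 * a * c;
              if (disc <= 0.0) continue;
              double th = (-b - std::sqrt(disc)) / (2.0 * a);
              if (th > 1e-12 && th <= 1.0 && th < tmin) { tmin = th; hit = i; }
            }
          }
          if (hit < 0) { px += vx; py += vy; break; }
          // Advance to the wall, reflect the remainder about the tangent.
          double hx = px + tmin * vx, hy = py + tmin * vy;
          double nx = min_image(hx - cx[hit], L);
          double ny = min_image(hy - cy[hit], L);
          double nn = std::sqrt(nx * nx + ny * ny);
          nx /= nn; ny /= nn;
          double rx = (1.0 - tmin) * vx, ry = (1.0 - tmin) * vy;
          double dot = rx * nx + ry * ny;
          rx -= 2.0 * dot * nx; ry -= 2.0 * dot * ny;
          px = hx + eps_push * nx; py = hy + eps_push * ny;
          vx = rx; vy = ry;
          if (++nref >= max_reflect) { ++n_clamped; break; }
        }
        ux += px - wx; uy += py - wy;
        wx = px - L * std::floor(px / L);
        wy = py - L * std::floor(py / L);
      }
      X(t, s) = ux; Y(t, s) = uy; Z(t, s) = uz;
    }
  }
  return List::create(_["x"] = X, _["y"] = Y, _["z"] = Z,
                      _["n_clamped"] = n_clamped);
}
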