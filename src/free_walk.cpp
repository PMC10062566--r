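#include <Rcpp.h>
using namespace Rcpp;

// Free Brownian walk: independent Gaussian increments per axis with
// per-axis step SDs. Positions are filled time-major ((n_steps + 1) x N);
// the RNG is consumed per spin, per step, in axis order x, y, z.
// [[Rcpp::export]]
List cpp_walk_free(NumericMatrix start, int n_steps,
                   double sdx, double sdy, double sdz) {
  const int N = start.nrow();
  NumericMatrix X(n_steps + 1, N), Y(n_steps + 1, N), Z(n_steps + 1, N);
  for (int s = 0; s < N; ++s) {
    double x = start(s, 0), y = start(s, 1), z = start(s, 2);
    X(0, s) = x; Y(0, s) = y; Z(0, s) = z;
    for (int t = 1; t <= n_steps; ++t) {
      x += norm_rand() * sdx;
      y += norm_rand() * sdy;
      z += norm_rand() * sdz;
      X(t, s) = x; Y(t, s) = y; Z(t, s) = z;
    }
  }
  return List::create(_["x"] = X, _["y"] = Y, _["z"] = Z);
}
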