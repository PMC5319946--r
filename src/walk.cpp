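#include <Rcpp.h>
using namespace Rcpp;

// Correlated random walk confined to an annulus [r_min, r_max], with an
// optional heading bias toward (bias_gain > 0) or away from (bias_gain < 0)
// the arena centre.  Uses R's RNG so set.seed() governs determinism.
// Returns an (n_steps + 1) x 2 matrix of positions.
// [[Rcpp::export]]
NumericMatrix crw_walk_cpp(int n_steps, double x0, double y0, double heading0,
                           NumericVector step_len, double turn_sd,
                           double bias_gain, double r_min, double r_max) {
  NumericMatrix pos(n_steps + 1, 2);
  double x = x0, y = y0, h = heading0;
  pos(0, 0) = x;
  pos(0, 1) = y;
  double g = std::abs(bias_gain);
  if (g > 1.0) g = 1.0;
  for (int i = 0; i < n_steps; i++) {
    h += R::rnorm(0.0, turn_sd);
    if (bias_gain != 0.0 && (x != 0.0 || y != 0.0)) {
      double tgt = (bias_gain > 0.0) ? std::atan2(-y, -x) : std::atan2(y, x);
      double d = tgt - h;
      while (d > M_PI) d -= 2.0 * M_PI;
      while (d < -M_PI) d += 2.0 * M_PI;
      h += g * d;
    }
    double L = step_len[i];
    double nx = x + L * std::cos(h), ny = y + L * std::sin(h);
    double r = std::sqrt(nx * nx + ny * ny);
    if (r > r_max && r > 1e-12) {          // reflect radially off the wall
      double rr = 2.0 * r_max - r;
      if (rr < r_min) rr = r_min;
      nx *= rr / r;
      ny *= rr / r;
    }
    r = std::sqrt(nx * nx + ny * ny);
    if (r < r_min) {                        // reflect off the inner boundary
      double rr = (r > 1e-12) ? 2.0 * r_min - r : r_min;
      if (rr > r_max) rr = r_max;
      if (r > 1e-12) {
        nx *= rr / r;
        ny *= rr / r;
      } else {
        nx = rr;
        ny = 0.0;
      }
    }
    if (nx != x || ny != y) h = std::atan2(ny - y, nx - x);
    x = nx;
    y = ny;
    pos(i + 1, 0) = x;
    pos(i + 1, 1) = y;
  }
  return pos;
}
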