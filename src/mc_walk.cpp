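#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Random walk of non-interacting spins in the cross-section of an
// impermeable cylinder (disc of radius R), accumulating the phase imparted
// by a gradient applied along the x axis of the cross-section.  The axial
// coordinate is free and does not couple to the perpendicular gradient, so
// it is not simulated.  Reflection at the wall is radial (equivalent to
// specular reflection for steps much smaller than R, which the caller
// enforces).  Uses R's RNG, so results are reproducible under set.seed().
//
// gvals: effective gradient (T/m) sampled at the midpoint of each time
// step; dt: step (s); returns mean of cos(phi) and its standard error.
// [[Rcpp::export]]
List mc_walk_cylinder(double R, double D, NumericVector gvals, double dt,
                      int n_walkers, double gamma) {
  const int nt = gvals.size();
  const double step = std::sqrt(2.0 * D * dt);
  double sum = 0.0, sumsq = 0.0;
  for (int w = 0; w < n_walkers; ++w) {
    // uniform start in the disc
    double r0 = R * std::sqrt(unif_rand());
    double th = 2.0 * M_PI * unif_rand();
    double x = r0 * std::cos(th), y = r0 * std::sin(th);
    double phi = 0.0;
    for (int i = 0; i < nt; ++i) {
      x += step * norm_rand();
      y += step * norm_rand();
      double rr = std::sqrt(x * x + y * y);
      if (rr > R) {
        double sc = (2.0 * R - rr) / rr;
        if (sc < 0.0) sc = 0.0; // pathological overshoot: clamp to centre
        x *= sc; y *= sc;
      }
      if (gvals[i] != 0.0) phi += gamma * gvals[i] * x * dt;
    }
    double c = std::cos(phi);
    sum += c; sumsq += c * c;
  }
  const double mean = sum / n_walkers;
  const double var = (sumsq - n_walkers * mean * mean) / (n_walkers - 1.0);
  return List::create(_["signal"] = mean,
                      _["se"] = std::sqrt(var / n_walkers));
}
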