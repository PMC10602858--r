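#include <Rcpp.h>
using namespace Rcpp;

// Overdamped Langevin (Euler-Maruyama) propagation of a 1-D coordinate on a
// tabulated force field plus a harmonic bias. The landscape force is given
// on a uniform grid and interpolated linearly; R's RNG supplies the noise so
// runs are reproducible via set.seed() on the R side.
//
// x <- x + (D/kT) * (f_landscape(x) - k (x - c)) * dt + sqrt(2 D dt) * N(0,1)
//
// Returns every stride-th position and the final position (the production
// stage of the umbrella protocol resumes from the equilibration endpoint).
// [[Rcpp::export(name = ".langevin_kernel")]]
List langevin_kernel(double x0, int n_samples, int stride, double dt,
                     double D, double kT, double bias_center, double bias_k,
                     NumericVector fgrid, double xlo, double dx,
                     double lo_guard, double hi_guard) {
  NumericVector out(n_samples);
  const double pref = D / kT * dt;
  const double noise = std::sqrt(2.0 * D * dt);
  const int ng = fgrid.size();
  double x = x0;
  RNGScope scope;
  const long total = (long)n_samples * (long)stride;
  int isamp = 0;
  for (long step = 1; step <= total; ++step) {
    double u = (x - xlo) / dx;
    double f;
    if (u <= 0.0) {
      f = fgrid[0];
    } else if (u >= ng - 1.0) {
      f = fgrid[ng - 1];
    } else {
      int i = (int)u;
      double w = u - i;
      f = fgrid[i] * (1.0 - w) + fgrid[i + 1] * w;
    }
    f -= bias_k * (x - bias_center);
    x += pref * f + noise * norm_rand();
    if (x < lo_guard || x > hi_guard) {
      stop("trajectory diverged at step %ld (x = %.3f A); "
           "reduce dt or check the bias constants", step, x);
    }
    if (step % stride == 0) out[isamp++] = x;
  }
  return List::create(_["samples"] = out, _["xfinal"] = x);
}
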