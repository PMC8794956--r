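#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration of dx = -(a x^3 - b x + c(t)) dt + sqrt(2 D dt) dW
// over a piecewise-constant tilt series c(t). Tilt is supplied per step to keep
// the concentration schedule logic in R. Uses R's RNG so set.seed() governs it.

// [[Rcpp::export]]
List ni_simulate_path(double a, double b, double D, double dt,
                      NumericVector tilt_times, NumericVector tilt_values,
                      double total_s, double x0, int thin) {
  const long n_steps = (long)std::floor(total_s / dt);
  const double sd_step = std::sqrt(2.0 * D * dt);
  const long n_out = n_steps / thin + 1;
  NumericVector out_t(n_out), out_x(n_out);
  IntegerVector out_s(n_out);

  double x = x0;
  int state = (x > 0) ? 1 : 0;
  int seg = 0;
  const int n_seg = tilt_times.size();

  out_t[0] = 0.0; out_x[0] = x; out_s[0] = state;
  long k = 1;
  for (long i = 0; i < n_steps; ++i) {
    const double t = i * dt;
    while (seg + 1 < n_seg && t >= tilt_times[seg + 1]) ++seg;
    const double c = tilt_values[seg];
    const double drift = -(a * x * x * x - b * x + c);
    x += drift * dt + sd_step * norm_rand();
    if (!std::isfinite(x) || std::fabs(x) > 1e6)
      stop("trajectory diverged: dt too large for the stated potential");
    if (x > 0.0) state = 1; else if (x < 0.0) state = 0; /* x == 0: keep */
    if ((i + 1) % thin == 0) {
      out_t[k] = (i + 1) * dt;
      out_x[k] = x;
      out_s[k] = state;
      ++k;
    }
  }
  return List::create(_["time_s"] = out_t, _["x"] = out_x, _["state"] = out_s);
}

// First-passage times from x_start to x_target (same sign convention as the
// potential): used to check simulated escape rates against the Kramers form.

// [[Rcpp::export]]
NumericVector ni_first_passage(double a, double b, double D, double dt,
                               double x_start, double x_target, int n_escapes,
                               double t_max) {
  const double sd_step = std::sqrt(2.0 * D * dt);
  NumericVector times(n_escapes);
  for (int e = 0; e < n_escapes; ++e) {
    double x = x_start, t = 0.0;
    while (true) {
      const double drift = -(a * x * x * x - b * x);
      x += drift * dt + sd_step * norm_rand();
      t += dt;
      if ((x_target > x_start && x >= x_target) ||
          (x_target < x_start && x <= x_target)) break;
      if (t > t_max) stop("escape did not occur within t_max");
      if (!std::isfinite(x)) stop("trajectory diverged: dt too large");
    }
    times[e] = t;
  }
  return times;
}
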