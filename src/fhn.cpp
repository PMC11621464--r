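#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration of the FitzHugh-Nagumo system
//   dv = (v - v^3/3 - w + drive) * dt + noise_sd * dW
//   dw = eps * (v + a - b*w) * dt
// in model time units (dt = dt_model). Draws come from R's RNG so the caller
// controls the seed with set.seed(). Returns the activation variable v at
// every integration step (thinning happens in R).
// [[Rcpp::export(name = ".fhn_integrate")]]
NumericVector fhn_integrate(int n_steps, double dt, double eps, double a,
                            double b, double drive, double noise_sd,
                            double v0, double w0) {
  NumericVector v_out(n_steps);
  double v = v0, w = w0;
  double sqdt = std::sqrt(dt);
  bool noisy = noise_sd > 0.0;
  for (int i = 0; i < n_steps; ++i) {
    double dv = (v - v * v * v / 3.0 - w + drive) * dt;
    if (noisy) dv += noise_sd * sqdt * R::norm_rand();
    double dw = eps * (v + a - b * w) * dt;
    v += dv;
    w += dw;
    if (!std::isfinite(v) || !std::isfinite(w))
      stop("FitzHugh-Nagumo integration diverged at step %d; reduce dt_s or the parameter magnitudes", i + 1);
    v_out[i] = v;
  }
  return v_out;
}
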