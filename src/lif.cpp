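#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Leaky integrate-and-fire spike generation for a population sharing one
// drive time course, scaled per afferent by a receptive-field weight.
// Threshold noise: after each spike the effective threshold is redrawn as
// theta + sd * z with z ~ N(0,1) from a per-afferent mersenne-twister
// stream, so spike trains are reproducible given the seed vector and
// independent of R's global RNG state.
//
// [[Rcpp::export]]
List lif_population(NumericVector drive, NumericVector weights,
                    double dt, double tau, double threshold,
                    double threshold_noise_sd, double refractory,
                    IntegerVector seeds) {
  const int n_aff = weights.size();
  const int n_t = drive.size();
  if (seeds.size() != n_aff) stop("one seed per afferent required");
  List out(n_aff);
  const int refr_steps = (int)std::ceil(refractory / dt);

  for (int a = 0; a < n_aff; ++a) {
    std::mt19937 rng((uint32_t)seeds[a]);
    std::normal_distribution<double> gauss(0.0, 1.0);
    const double w = weights[a];
    std::vector<double> spikes;
    double v = 0.0;
    double theta = threshold + threshold_noise_sd * gauss(rng);
    if (theta < 1e-6) theta = 1e-6;
    int refr_until = -1;
    for (int t = 0; t < n_t; ++t) {
      if (t <= refr_until) continue;  // voltage clamped at reset
      v += dt * (w * drive[t] - v) / tau;
      if (v >= theta) {
        spikes.push_back(t * dt);
        v = 0.0;
        theta = threshold + threshold_noise_sd * gauss(rng);
        if (theta < 1e-6) theta = 1e-6;
        refr_until = t + refr_steps;
      }
    }
    out[a] = NumericVector(spikes.begin(), spikes.end());
  }
  return out;
}
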