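#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Forward-Euler integration of the firing-rate network
//   tau dr_i/dt = -r_i + phi( sum_j J_ij r_j + I_i(t) )
// with phi(h) = rmax/2 (1 + erf((h - theta)/(sqrt(2) sigma))).
//
// J is a dgCMatrix (CSC). External input is piecewise constant in time:
// input_base is an N x K matrix of per-neuron currents, phase_end_step[k]
// is the last step (1-based) integrated with column k. Optional zero-mean
// Ornstein-Uhlenbeck noise (stationary sd noise_sd, correlation time
// noise_tau) is added independently per neuron, using the exact
// discretisation so stationary moments hold at any dt. Uses R's RNG.
//
// Returns an N x (nsteps+1) matrix of rates including the initial state.
// [[Rcpp::export]]
NumericMatrix rate_euler_cpp(S4 J, NumericVector r0, NumericMatrix input_base,
                             IntegerVector phase_end_step,
                             double theta, double sigma, double rmax,
                             double tau, double dt, int nsteps,
                             double noise_sd, double noise_tau) {
  IntegerVector Jp = J.slot("p"), Ji = J.slot("i");
  NumericVector Jx = J.slot("x");
  IntegerVector dims = J.slot("Dim");
  const int N = dims[0];
  if (dims[1] != N) stop("connectivity matrix must be square");
  if (r0.size() != N) stop("initial state length does not match network size");
  if (input_base.nrow() != N) stop("input matrix rows must match network size");
  if (input_base.ncol() != phase_end_step.size())
    stop("one phase_end_step entry is required per input column");

  NumericMatrix rates(N, nsteps + 1);
  std::vector<double> r(r0.begin(), r0.end());
  std::vector<double> h(N);
  std::vector<double> noise;
  const bool use_noise = noise_sd > 0.0;
  double ou_decay = 0.0, ou_innov = 0.0;
  if (use_noise) {
    ou_decay = std::exp(-dt / noise_tau);
    ou_innov = noise_sd * std::sqrt(1.0 - ou_decay * ou_decay);
    noise.resize(N);
    for (int i = 0; i < N; ++i) noise[i] = noise_sd * norm_rand();
  }

  for (int i = 0; i < N; ++i) rates(i, 0) = r[i];

  const double inv_tau = dt / tau;
  const double gain = 1.0 / (sigma * M_SQRT2);
  int phase = 0;
  const int K = phase_end_step.size();

  for (int step = 1; step <= nsteps; ++step) {
    while (phase < K - 1 && step > phase_end_step[phase]) ++phase;

    std::fill(h.begin(), h.end(), 0.0);
    for (int j = 0; j < N; ++j) {
      const double rj = r[j];
      if (rj == 0.0) continue;
      const int kend = Jp[j + 1];
      for (int k = Jp[j]; k < kend; ++k) h[Ji[k]] += Jx[k] * rj;
    }

    const double *inp_col = &input_base(0, phase);
    bool bad = false;
    for (int i = 0; i < N; ++i) {
      double inp = h[i] + inp_col[i];
      if (use_noise) inp += noise[i];
      const double phi = rmax * 0.5 * std::erfc(-(inp - theta) * gain);
      r[i] += inv_tau * (phi - r[i]);
      if (!std::isfinite(r[i])) bad = true;
      rates(i, step) = r[i];
    }
    if (bad) stop("non-finite firing rate at step %d", step);

    if (use_noise)
      for (int i = 0; i < N; ++i)
        noise[i] = noise[i] * ou_decay + ou_innov * norm_rand();

    if (step % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return rates;
}
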