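#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Clock-driven simulation of a leaky integrate-and-fire network with
// exponential synapses and a uniform conduction delay.
//
// Membrane dynamics (population alpha of neuron i):
//   tau_m dV/dt = Theta(V - V_floor) (-V + V_rest + h_E + h_I + I_ext(t))
//                 + sigma sqrt(tau_m) W(t)
// The voltage-floor gate is realised by clamping V at V_floor from below.
// Spikes: V >= V_thresh -> emit, reset to V_reset, hold for tau_rp.
//
// Synapses: presynaptic spike of neuron j (population beta) arriving after
// delay D increments the exponentially filtered current h^beta_i by W_ij for
// every postsynaptic i; h^beta decays with time constant tau_s[beta].
//
// W is a dgCMatrix with W_ij in row i, column j (presynaptic j).
// pop: 0-based population index per neuron (0 = E, 1 = I); per-population
// parameter vectors have length 2. External input is piecewise constant,
// as in rate_euler_cpp. rec_idx: 1-based neuron indices whose voltage is
// recorded every step.
// [[Rcpp::export]]
List lif_euler_cpp(S4 W, IntegerVector pop,
                   NumericMatrix input_base, IntegerVector phase_end_step,
                   NumericVector tau_m, NumericVector v_rest,
                   NumericVector v_thresh, NumericVector v_reset,
                   NumericVector v_floor, NumericVector tau_rp,
                   NumericVector tau_s, NumericVector sigma_noise,
                   double delay, double dt, int nsteps,
                   NumericVector v0, IntegerVector rec_idx) {
  IntegerVector Wp = W.slot("p"), Wi = W.slot("i");
  NumericVector Wx = W.slot("x");
  IntegerVector dims = W.slot("Dim");
  const int N = dims[0];
  if (dims[1] != N) stop("weight matrix must be square");
  if (pop.size() != N || v0.size() != N) stop("pop/v0 length mismatch");
  if (input_base.nrow() != N) stop("input matrix rows must match N");
  if (input_base.ncol() != phase_end_step.size())
    stop("one phase_end_step entry is required per input column");

  const int npop = 2;
  std::vector<double> decay_s(npop), dt_over_tm(npop), noise_amp(npop);
  std::vector<int> rp_steps(npop);
  for (int a = 0; a < npop; ++a) {
    decay_s[a] = std::exp(-dt / tau_s[a]);
    dt_over_tm[a] = dt / tau_m[a];
    noise_amp[a] = sigma_noise[a] * std::sqrt(dt / tau_m[a]);
    rp_steps[a] = (int)std::lround(tau_rp[a] / dt);
  }

  std::vector<double> V(v0.begin(), v0.end());
  std::vector<double> hE(N, 0.0), hI(N, 0.0);
  std::vector<int> refr(N, 0);

  const int dsteps = std::max(1, (int)std::lround(delay / dt));
  std::vector<std::vector<int>> ring(dsteps);

  std::vector<int> sp_neuron;
  std::vector<double> sp_time;
  sp_neuron.reserve(1 << 16);
  sp_time.reserve(1 << 16);

  const int nrec = rec_idx.size();
  NumericMatrix vtrace(nrec, nsteps + 1);
  for (int k = 0; k < nrec; ++k) vtrace(k, 0) = V[rec_idx[k] - 1];

  int phase = 0;
  const int K = phase_end_step.size();

  for (int step = 1; step <= nsteps; ++step) {
    while (phase < K - 1 && step > phase_end_step[phase]) ++phase;

    // deliver spikes emitted dsteps ago
    std::vector<int> &due = ring[step % dsteps];
    for (size_t q = 0; q < due.size(); ++q) {
      const int j = due[q];
      std::vector<double> &h = (pop[j] == 0) ? hE : hI;
      const int kend = Wp[j + 1];
      for (int k = Wp[j]; k < kend; ++k) h[Wi[k]] += Wx[k];
    }
    due.clear();

    const double *inp_col = &input_base(0, phase);
    for (int i = 0; i < N; ++i) {
      const int a = pop[i];
      if (refr[i] > 0) { --refr[i]; V[i] = v_reset[a]; continue; }
      double dV = dt_over_tm[a] * (-V[i] + v_rest[a] + hE[i] + hI[i] + inp_col[i]);
      if (noise_amp[a] > 0.0) dV += noise_amp[a] * norm_rand();
      double v = V[i] + dV;
      if (v < v_floor[a]) v = v_floor[a];
      if (v >= v_thresh[a]) {
        sp_neuron.push_back(i + 1);
        sp_time.push_back(step * dt);
        ring[(step) % dsteps].push_back(i); // delivered at step + dsteps
        v = v_reset[a];
        refr[i] = rp_steps[a];
      }
      if (!std::isfinite(v)) stop("non-finite membrane potential at step %d", step);
      V[i] = v;
    }

    for (int i = 0; i < N; ++i) { hE[i] *= decay_s[0]; hI[i] *= decay_s[1]; }
    for (int k = 0; k < nrec; ++k) vtrace(k, step) = V[rec_idx[k] - 1];
    if (step % 128 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["neuron"] = wrap(sp_neuron),
                      _["time"] = wrap(sp_time),
                      _["vtrace"] = vtrace);
}
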