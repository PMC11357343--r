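# seqspeed

Recurrent network models that store a *sequence* of activity patterns in
Hebbian synaptic weights and replay it at a speed controlled by external
input. The scientific question the package addresses: how can a circuit
retrieve the same motor or cognitive sequence at different tempos without
rewiring? The mechanism studied here is *heterogeneity in the temporal
symmetry of synaptic plasticity* — neurons whose plasticity is temporally
symmetric stabilise the current pattern (brakes), neurons with temporally
asymmetric plasticity push toward the next pattern (accelerators), and
external inputs that bias one group against the other set the replay
speed. The package is aimed at computational neuroscientists who want to
simulate, measure and analyse these networks at desk scale.

## The model

Firing rates follow

```
tau dr_i/dt = -r_i + phi( sum_j J_ij r_j + I_i^ext(t) ),
phi(h) = r_max/2 (1 + erf((h - theta) / (sqrt(2) sigma)))
```

with connectivity built from `P` random Gaussian patterns `xi^mu` over a
Bernoulli(`c`) structural mask,

```
J_ij = A c_ij/(N c) ( z_i sum_mu f(xi_i^mu) g(xi_j^mu)
                    + (1 - z_i) sum_mu f(xi_i^{mu+1}) g(xi_j^mu) )
```

where `z_i` in [0,1] is neuron `i`'s degree of temporal symmetry and
`f`, `g` are bilinear or thresholded plasticity functions. Retrieval is
measured through pattern correlations `m_mu(t)`; the speed estimator is
the inverse mean spacing of consecutive correlation peaks in units of
`1/tau`. The package implements, on top of this core: the mean-field
theory (gain functions, the speed-symmetry law `v = 1 - z`, the
feasibility condition `max_x[G_a + G_s] >= 1`), input-plane phase
diagrams, a preparatory/execution protocol that switches between
persistent and sequential activity, a perturbation-based reward rule that
*learns* the external inputs achieving a target speed, and a leaky
integrate-and-fire E/I implementation of the same storage scheme.

## Worked example

Build the desk-scale two-population network (N = 4000 neurons, connection
probability 0.05, 16 stored patterns, tau = 10 ms) and retrieve the
sequence with both external inputs at zero:

```r
library(seqspeed)
fx <- standard_fixture(kind = "two_pop", seed = 1)
run_retrieval(fx, I_a = 0, I_s = 0)
#> retrieval_summary: status = retrieved, speed = 0.421 (1/tau), quality = 0.508
```

Speed `0.421` means consecutive pattern correlations peak about
`tau/0.42 ≈ 24 ms` apart — close to the mean-field value 0.5 for a
half-symmetric network (one pattern per `2 tau`); quality `0.508` is the
peak correlation of the final pattern (success threshold 0.05). Silencing
the symmetric population doubles the speed; inhibiting the asymmetric one
slows retrieval several-fold before it fails:

```r
run_retrieval(fx, I_a = 0, I_s = -1)$v    # brakes off  -> 0.924
run_retrieval(fx, I_a = -0.7, I_s = 0, T = 1200)$v  # accelerators inhibited -> 0.228
```

The reward-driven rule finds such inputs by itself from a speed target:

```r
res <- learn_inputs(learner_config(v_target = 0.8, seed = 101), fx, dt = 1)
res$speed; res$inputs
#> 0.751
#> -0.035 -0.722
```

Scaled-down reproductions of the headline experiments (speed vs symmetry,
input-plane phase diagrams, persistent-to-sequential transitions,
learning trajectories, spiking fast/slow retrieval) are available through
`reproduce("fig1c")` ... `reproduce("fig7")` and the CLI:

```sh
Rscript inst/cli/seqspeed.R reproduce --figure fig1c --out results/
```

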