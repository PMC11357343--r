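---
title: "Models and methods: speed-controllable sequence retrieval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: speed-controllable sequence retrieval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`seqspeed` studies recurrent networks that store a *sequence* of activity
patterns in their synaptic weights and can replay it at a controllable
speed. The firing-rate network is

$$\tau \frac{dr_i}{dt} = -r_i + \phi\Big(\sum_j J_{ij} r_j + I^{ext}_i(t)\Big),
\qquad
\phi(h) = \frac{r_{max}}{2}\Big(1 + \mathrm{erf}\big(\tfrac{h-\theta}{\sqrt{2}\sigma}\big)\Big),$$

with `tau` the rate time constant (ms), `theta` the half-activation input
and `sigma` the inverse gain. Rates are fractions of the maximum, so
`r_max = 1`; all currents are dimensionless and measured relative to the
firing threshold, which is why the biologically sensible operating region
has *negative* external inputs (mean rates far below saturation).

A sequence of `P` i.i.d. standard Gaussian patterns $\xi^\mu$ over `N`
neurons is imprinted by a Hebbian rule with a per-neuron *degree of
temporal symmetry* $z_i \in [0,1]$:

$$J_{ij} = \frac{A c_{ij}}{N c}\Big( z_i \sum_{\mu=1}^{P} f(\xi_i^\mu)g(\xi_j^\mu)
 + (1-z_i) \sum_{\mu=1}^{P-1} f(\xi_i^{\mu+1})g(\xi_j^\mu) \Big),$$

where $c_{ij}$ is an i.i.d. Bernoulli($c$) structural mask. The first
(autoassociative) term stabilises each pattern; the second (sequential)
term pushes the state from pattern $\mu$ to $\mu+1$. Neurons with $z_i=1$
act as *brakes*, neurons with $z_i=0$ as *accelerators*, and external
inputs that favour one group or the other set the replay speed. Three
symmetry layouts are built in: homogeneous ($z_i = z$), bimodal
($z_i \in \{0,1\}$, the two-population network), and a continuum
($z_i \sim U(0,1)$) with per-neuron mixed inputs
$I_i = z_i I_s + (1-z_i) I_a$.

The plasticity functions are either bilinear ($f(x)=g(x)=x$) or
thresholded, $f(x) = q_f - 1 + \Theta(x - x_f)$ and likewise for $g$,
which binarises the patterns (active fraction $1-\Phi(x_g)$). We fix
$\Theta(0)=1$; the choice only matters on a measure-zero set but must be
pinned for reproducibility. For the thresholded presynaptic function the
offset $q_g = \Phi(x_g)$ makes $g$ zero-mean over the pattern
distribution, keeping the mean connection strength at zero
(`solve_qg_zero_mean()`). The nonlinear reference configuration prints an
explicit $q_g = 0.8$ alongside the zero-mean prescription ($\approx 0.933$
at $x_g = 1.5$); both are supported, constructors take either an explicit
`q_g` or `zero_mean_qg = TRUE`, and the desk-scale nonlinear fixture uses
the zero-mean value, which is the variant whose retrieval dynamics we
could validate at reduced scale.

### Two-population normalisation

The block (two-population) form of the connectivity normalises each row by
the presynaptic block size, $1/(N_{a}c)$ or $1/(N_{s}c)$. The mean-field
overlap equations for the same network, however, contain no factor of the
coupling $A$: for them to describe the simulated network, the drive must
be $(q_a + q_s)\,G$ exactly, which happens for the *whole-network*
normalisation $A/(Nc)$ at $A=2$ (each half then contributes its overlap
with weight $A/2 = 1$). With the per-block normalisation the recurrent
drive is doubled, and we verified that a strongly negative symmetric input
then fails to silence the symmetric population — the hallmark Fig.-style
speed asymmetries disappear. `build_connectivity_two_pop()` therefore
implements the block form as printed (and the test suite pins it to
exactly twice the bimodal whole-network build for equal halves), while all
fixtures and experiments use the bimodal whole-network build, which is how
the two-population network is introduced in the first place (a bimodal
draw of $z_i$).

## Measuring retrieval

Retrieval is quantified by the Pearson-type correlation
$m_\mu(t) = \frac{1}{N}\sum_i r_i(t)\xi_i^\mu / \sigma_r(t)$ (population
standard deviation, patterns used as stored). Retrieval *quality* is the
peak correlation of the final pattern, with success threshold
$\theta_P = 0.05$. Retrieval *speed* is

$$v = \tau \Big/ \overline{\Delta t}, \qquad
\overline{\Delta t} = \frac{1}{P-1}\sum_{l=2}^{P}
\big(\mathrm{argmax}_t\, m_l - \mathrm{argmax}_t\, m_{l-1}\big),$$

after a single pass that drops differences exceeding the mean plus two
standard deviations of the raw differences; if nothing survives, the run
is *not retrieved*. $v = 1$ means one pattern per $\tau$; peaks $2\tau$
apart give $v = 0.5$ exactly.

Two practical refinements were forced by what desk-scale simulations
actually do:

* **First-peak truncation.** Runs longer than the retrieval episode do not
  simply decay: the bilinear network re-enters late patterns cyclically
  with overlap amplitudes within a fraction of a percent of the true
  transient peaks, so an argmax over the whole run lands on a revisit.
  Peak detection is restricted to the window ending at the final
  pattern's first prominent peak (first time $m_P$ reaches 95% of its
  maximum, plus $2\tau$), applied only when $m_P$ reaches $\theta_P$.
  On unimodal traces this changes nothing, so the estimator's exactness
  cases are unaffected.
* **Order gating.** Mixed (multi-pattern) end states can push $m_P$ above
  $\theta_P$ while many patterns peak coincidentally or out of order. A
  run is only classified `retrieved` when at least 80% of the consecutive
  peak-time differences are positive. The 80% allowance tolerates a
  single adjacent swap from pattern-level noise at `N = 4000` while
  rejecting the coincident-peak states we observed (which show 4-6
  inversions out of 15).

`classify_dynamics()` additionally labels `persistent` (a single pattern's
correlation plateaus — within 10% of its end value and above $\theta_P$ —
over the final 200 ms with nothing peaking before) and
`partial_then_persistent` (at least one but fewer than `P` patterns peaked
before such a plateau). The window and plateau tolerance are operational
choices; the reference figures mark these regimes but give no formula.

## Mean-field theory

The overlap $q_l = E[r\,\xi^l]$ obeys, per pattern,
$\tau \dot q_l = -q_l + q^z_l\, G\big((q^z_l)^2 + R_l^2\big)$ with
$q^z_l = (1-z)q_{l-1} + z q_l$ and the gain

$$G(x) = \int Dv\, \phi'(v\sqrt{x} + I)
 = \frac{1}{\sqrt{2\pi(\sigma^2+x)}}
   \exp\Big(-\frac{(I-\theta)^2}{2(\sigma^2+x)}\Big)$$

(the closed form holds for the error-function transfer with `r_max = 1`;
we implement the analytically derived $(I-\theta)^2$ exponent — the
printed $(\theta+I)^2$ variant, available behind a flag, coincides at
$\theta = 0$, which is where all input-plane analyses live). The
crosstalk amplitudes $R_l$ contributed by non-retrieved patterns are
*supplied parameters* (default 0, the low-load limit); their derivation is
outside this package's scope. When the gain is near one, the homogeneous
dynamics reduce to $\frac{\tau}{1-z}\dot q_l = -q_l + q_{l-1}$: the
speed-symmetry law $v = 1-z$. With constant two-channel gains the
combined overlap obeys an effective time constant $\tau/(1-G_s)$ and
transfer ratio $G_a/(1-G_s)$; retrieval of a long sequence requires
$\max_x [G_a(x) + G_s(x)] \ge 1$ (`retrieval_feasible()`, scalar
optimisation over the bracket covering both per-channel maxima).

The same theory explains a desk-scale subtlety: at zero external input the
small-overlap gain $\phi'(0) = 1/(\sqrt{2\pi}\sigma) \approx 4$ is
strongly supercritical, so the symmetric feedback $z\,\phi'(I)$ makes
states sticky and stalls high-`z` retrieval. Clean pulse propagation needs
$z\,\phi'(I) < 1$, i.e. $|I| \gtrsim 0.15$ at $z = 0.75$, $\sigma = 0.1$.
The speed-symmetry experiments therefore run at $I = -0.2$ — inside the
negative-input operating region the model assumes anyway.

## Desk-scale study conditions

The reference simulations use $N = 8\times10^4$, $c = 0.005$. All
experiments here run at the desk scale `N = 4000`, `c = 0.05`, `P = 16`,
`tau = 10` ms, `A = 2`, `theta = 0`, `sigma = 0.1` (`standard_fixture()`),
integrating with forward Euler at `dt = 0.5` ms (`dt = 1` ms — still
$\tau/10$ — for the many-trial learning loops), horizon 600-1200 ms per
run. Step-halving changes measured speeds by under 1%, so the scheme is
converged for these quantities. At this scale single runs are noticeably
stochastic across pattern/mask seeds: roughly half the $z = 0.75$
homogeneous realisations stall mid-sequence, and the slow-retrieval edge
of the two-population input plane sits near $I_a \approx -0.75$ rather
than $-1$ (the hand-off there relies on the sparse tail of high-drive
accelerator neurons, which thins as $N$ shrinks; we verified the stall is
dt-independent and survives at `N = 8000` and under input noise).
Summaries over a small pre-registered seed panel (1-5), restricted to
runs classified `retrieved`, are therefore the unit of comparison for the
speed-symmetry law, and the four-fold-slowdown check scans
$I_a \in [-1, -0.6]$ at $I_s = 0$ for the slowest successfully retrieved
speed. What passing these desk-scale checks shows is that the *mechanism*
(brake/accelerator control of speed by external input) operates
quantitatively as the theory predicts; it does not reproduce the
reference's exact failure boundaries, which are size-dependent.

The synthetic-data generator (`generate_patterns()` plus the structural
masks) emulates exactly what the model assumes: i.i.d. Gaussian patterns
and i.i.d. Bernoulli connectivity. Real neural data would add correlated
patterns, degree structure and plasticity heterogeneity beyond the $z_i$
mixing, none of which these tests probe.

## Input protocols

Piecewise-constant two-channel schedules with optional pattern cues and
Ornstein-Uhlenbeck input noise (exact discretisation; stationary sd and
correlation time are exact at any `dt`). The preparatory/execution
protocol holds a single pattern persistently and then releases the
sequence: a 10 ms cue of the first pattern to the symmetric population, a
200 ms preparatory period with the asymmetric population strongly
inhibited ($I_a = -1.6$, $I_s = -0.2$ at the desk-scale nonlinear
configuration $A = 20$, $\sigma = 0.05$, $\theta = 0.07$), then execution
inputs ($I_a = 0$, $I_s = -0.1$) that launch retrieval. For binarising
rules the network is initialised to the stored member state
(`member-clamp`): the transfer of the raw Gaussian pattern activates ~half
the network, which is far from the low-activity attractors such rules
store, and desk-scale runs started there collapse.

## Reward-driven input learning

`learn_inputs()` implements the perturbation rule: each trial perturbs
both inputs by $\lambda\,U(-1,1)$ (independent draws, $\lambda = 0.1$),
simulates one retrieval, and keeps the perturbation only if the trial
succeeded (final-pattern correlation $\ge \theta_m = 0.05$ and measurable
speed) and improved $|v - v_{target}|$ over the reference trial.
"Improvement over previous trials" admits two readings, and the choice
turned out to matter at desk scale. Comparing against the *best*
successful trial so far (`compare = "best"`) is strictly greedy; because
the measured-speed landscape is deterministic and locally ragged — with
a near-flat plateau ($v \approx 0.46$–$0.51$) for
$I_s \in [-0.4, 0]$, a finite-size bias of the estimator — the greedy
walk stalls permanently at shallow local optima for a fraction of
network realisations. The default therefore compares against the *most
recent* successful trial, accepted or not (`compare = "previous"`): a
perturbation only has to beat the last attempt, so the walk tolerates
lateral moves and diffuses off plateaus. The first successful trial is
always accepted; failed retrievals never count as improvements; stopping
tolerance 0.05 in speed units, at most 200 trials per run. From
$(-0.2, -0.2)$ the learner then reaches both reference targets (0.8 via
the fast corner $I_s \to -0.8$; 0.3 via the slow edge
$I_a \approx -0.6$) in roughly 9 of 10 perturbation streams; since the
search is stochastic, the reproduction script allows a small number of
restarts with fresh streams and reports the first converged run.

## Spiking implementation

The same storage scheme runs in a leaky integrate-and-fire network of
excitatory neurons (equal asymmetric and symmetric subpopulations, E-to-E
weights from the thresholded rule passed through the rectifier
$\omega(x) = \max(x, 0)$, both block sums over $\mu \le P-1$ as printed in
the reference formulation) plus an unstructured inhibitory population.
Membrane dynamics include a voltage floor (realised as clamping from
below), delayed exponential synapses, threshold-reset with 2 ms
refractoriness, and white-noise drive. Many auxiliary constants of the
reference spiking model live in an appendix that is not reproduced here;
everything not printed is a documented package choice, calibrated once so
the desk-scale fixture (`N_E = 2000`, `N_I = 500`, `P = 8`, in-degree
~400 within E) retrieves: threshold 20 mV above rest, $\tau_m$ 20/10 ms
(E/I), $\tau_s$ 6/3 ms, delay 1 ms, potentiated E-E weights ~2.8 mV,
E-to-I 2 mV, inhibitory weights $-1.5$ mV, background drive 19 mV (E) and
12 mV (I), noise 1 mV. The stated constants $A_{EE} = 0.25$,
$J_{IE}/K_{IE}$ and the input scalings $\lambda_{VE}, \lambda_{VI}$ are
carried in `spiking_params()` for provenance. Under the stated input
configurations (fast: $I_a = 0.75$, $I_s = -0.75$ mV; slow: $I_a = -1.5$,
$I_s = 0.5$ mV; zero external input to inhibitory neurons) the same
connectivity replays the sequence with a slow/fast duration ratio of
1.1-1.3 across noise seeds at this scale; the reference's ~2x factor is
treated as qualitative, as its exact auxiliary parameters are not
available.

## Numerical choices

* Forward Euler (`dt <= tau/10` enforced); spiking Euler-Maruyama at
  `dt <= 0.1` ms; spike effects delivered on the grid after the delay.
* Self-connections are zeroed (the spiking formulation sums $j \ne i$;
  negligible at the stated sparsity but pinned for tests).
* Structural masks are drawn column-wise as i.i.d. Bernoulli draws from
  one seeded stream; identical seeds give bitwise-identical networks.
* Peak detection takes the first grid index at ties.
* The gain's scalar maximisation brackets $[0,\,2\max((I_a-\theta)^2,
  (I_s-\theta)^2) + 10\sigma^2]$ and checks the endpoints, since the
  per-channel maximum sits at $x^* = (I-\theta)^2 - \sigma^2$.
* Overlaps where the population rate variance is numerically zero
  (below $10^{-8}$) are `NA`, never silently zero.

## Limitations

Single stored sequence only (the rule generalises, but capacity questions
are out of scope); crosstalk amplitudes $R_l$ are supplied, not derived;
no synaptic adaptation or depression; desk-scale failure boundaries are
finite-size-shifted as described above; the spiking model's published
constants are incomplete, so its quantitative speed factor is a package
calibration, not a reproduction.
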