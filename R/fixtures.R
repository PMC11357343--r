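# Desk-scale network fixtures bundling patterns, connectivity, transfer and
# integration parameters, so sweeps and learning loops can re-simulate the
# same stored sequence under varying external inputs.

#' Standard desk-scale retrieval fixture
#'
#' Builds a reduced-scale network with the reference parameter set
#' (`tau = 10` ms, `A = 2`, `theta = 0`, `sigma = 0.1`, `P = 16`) at
#' `N = 4000`, `c = 0.05`. Shrinking `N` while raising `c` keeps the mean
#' in-degree `N c` large, which is what governs the connectivity noise per
#' neuron and hence retrieval fidelity.
#'
#' @param N,c_prob Network size and connection probability.
#' @param P Sequence length.
#' @param tau Time constant (ms).
#' @param A Connection strength.
#' @param theta,sigma Transfer parameters.
#' @param rule A [plasticity_rule()].
#' @param kind `"two_pop"` (block asymmetric/symmetric build),
#'   `"homogeneous"` (shared `z`), or `"uniform"` (continuum of `z`).
#' @param z Degree of temporal symmetry for the homogeneous kind.
#' @param dt,T Default integration step and horizon (ms).
#' @param seed Root seed; patterns, mask and symmetry draws use offset
#'   streams derived from it.
#' @return An object of class `retrieval_fixture`: list with `patterns`,
#'   `net`, `tf`, `tau`, `dt`, `T`, `init` and the build arguments.
#' @export
standard_fixture <- function(N = 4000, c_prob = 0.05, P = 16, tau = 10,
                             A = 2, theta = 0, sigma = 0.1,
                             rule = plasticity_rule("bilinear"),
                             kind = c("two_pop", "homogeneous", "uniform"),
                             z = 0.5, dt = 0.5, T = 800, seed = 1L) {
  kind <- match.arg(kind)
  patterns <- generate_patterns(P, N, seed)
  net <- switch(kind,
    # deterministic equal split: first half asymmetric (z=0), second half
    # symmetric (z=1), whole-network 1/(Nc) normalisation (the bimodal
    # special case of the general rule, which is what the A-free
    # two-population mean-field equations describe at A=2)
    two_pop = build_connectivity(
      patterns,
      assign_symmetry(N, values = rep(c(0, 1), each = N / 2)),
      rule, A, c_prob, seed = seed + 1L),
    homogeneous = build_connectivity(
      patterns, assign_symmetry(N, "homogeneous", z = z), rule, A, c_prob,
      seed = seed + 1L),
    uniform = build_connectivity(
      patterns, assign_symmetry(N, "uniform", seed = seed + 2L), rule, A,
      c_prob, seed = seed + 1L))
  tf <- transfer_function(theta, sigma)
  structure(list(patterns = patterns, net = net, tf = tf, tau = tau,
                 dt = dt, T = T, init = initial_state(patterns, tf),
                 kind = kind, seed = seed),
            class = "retrieval_fixture")
}

#' @export
print.retrieval_fixture <- function(x, ...) {
  cat(sprintf("retrieval_fixture (%s): N = %d, P = %d, A = %g, c = %g\n",
              x$kind, x$net$N, x$net$P, x$net$A, x$net$c_prob))
  invisible(x)
}

#' Run one retrieval simulation on a fixture
#'
#' Integrates the fixture's network from the rate-clamped first pattern
#' under constant external inputs and summarises retrieval.
#'
#' @param fixture A [standard_fixture()].
#' @param I_a,I_s Constant external inputs.
#' @param T,dt Override the fixture's horizon/step (ms).
#' @param noise Optional list(`sd`, `tau_corr`) of OU input noise.
#' @param seed Optional seed for the noise stream.
#' @param keep_trajectory Also return the full rate trajectory.
#' @return A `retrieval_summary`; with `keep_trajectory = TRUE`, a list
#'   `(summary, trajectory, overlaps)`.
#' @export
run_retrieval <- function(fixture, I_a, I_s, T = fixture$T,
                          dt = fixture$dt, noise = NULL, seed = NULL,
                          keep_trajectory = FALSE) {
  stopifnot(inherits(fixture, "retrieval_fixture"))
  prot <- constant_protocol(I_a, I_s, T, noise = noise)
  traj <- integrate_rates(fixture$net, fixture$init, prot, fixture$tf,
                          fixture$patterns, tau = fixture$tau,
                          dt = dt, T = T, seed = seed)
  s <- retrieval_summary(traj, fixture$patterns)
  if (!keep_trajectory) return(s)
  list(summary = s,
       trajectory = traj,
       overlaps = pattern_correlations(traj, fixture$patterns))
}
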