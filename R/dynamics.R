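#' Sigmoidal neuronal transfer function
#'
#' \deqn{\phi(h) = \frac{r_{max}}{2}\left(1 +
#'   \mathrm{erf}\left(\frac{h - \theta}{\sqrt{2}\sigma}\right)\right)}
#' `theta` is the input at which the neuron fires at half its maximal rate
#' and `sigma` is inversely proportional to the gain. Rates are expressed as
#' fractions of the maximal rate, so `r_max = 1` by default.
#'
#' @param theta Half-activation input.
#' @param sigma Inverse-gain scale (must be positive).
#' @param r_max Maximal firing rate.
#' @return An object of class `transfer_function`.
#' @export
transfer_function <- function(theta = 0, sigma = 0.1, r_max = 1) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  if (!is.finite(r_max) || r_max <= 0) stop("r_max must be positive")
  structure(list(theta = theta, sigma = sigma, r_max = r_max),
            class = "transfer_function")
}

#' Evaluate the transfer function
#'
#' @param h Numeric vector of input currents.
#' @param tf A [transfer_function()].
#' @return Firing rates in `(0, r_max)`.
#' @examples
#' tf <- transfer_function(theta = 0, sigma = 0.1)
#' transfer(0, tf)  # half-maximal rate
#' @export
transfer <- function(h, tf) {
  stopifnot(inherits(tf, "transfer_function"))
  tf$r_max * stats::pnorm((h - tf$theta) / tf$sigma)
}

#' Ornstein-Uhlenbeck input noise trace
#'
#' Generates stationary Ornstein-Uhlenbeck processes with the given mean,
#' stationary standard deviation and correlation time, independently per
#' neuron, using the exact update
#' \deqn{x(t + dt) = m + (x(t) - m) e^{-dt/\tau_c} +
#'   sd\sqrt{1 - e^{-2 dt/\tau_c}}\,\eta}
#' so the stationary moments are exact at any step size. The initial value
#' is drawn from the stationary distribution.
#'
#' @param mean Process mean (scalar or length-`n` vector).
#' @param sd Stationary standard deviation (`>= 0`).
#' @param tau_corr Correlation time constant (ms, `> 0`).
#' @param dt Time step (ms).
#' @param T Duration (ms); the trace has `round(T/dt) + 1` samples.
#' @param seed Optional integer seed.
#' @param n Number of independent traces.
#' @return A numeric matrix (`n x` samples); a vector when `n = 1`.
#' @export
ou_noise <- function(mean, sd, tau_corr, dt, T, seed = NULL, n = 1L) {
  if (sd < 0) stop("sd must be non-negative")
  if (tau_corr <= 0) stop("tau_corr must be positive")
  if (!is.null(seed)) set.seed(seed)
  nt <- as.integer(round(T / dt)) + 1L
  m <- rep_len(mean, n)
  if (sd == 0) {
    out <- matrix(rep(m, nt), nrow = n)
  } else {
    decay <- exp(-dt / tau_corr)
    innov <- sd * sqrt(1 - decay^2)
    out <- matrix(0, n, nt)
    out[, 1L] <- m + sd * stats::rnorm(n)
    for (t in seq_len(nt - 1L))
      out[, t + 1L] <- m + (out[, t] - m) * decay + innov * stats::rnorm(n)
  }
  if (n == 1L) drop(out) else out
}

#' External-input protocol
#'
#' A piecewise-constant schedule of external inputs to the asymmetric and
#' symmetric input channels, an optional pattern cue, and optional
#' Ornstein-Uhlenbeck input noise. The per-neuron input mixes the two
#' channels through each neuron's degree of temporal symmetry,
#' \eqn{I_i = z_i I_s + (1 - z_i) I_a}, which reduces to per-population
#' inputs when `z` is binary.
#'
#' @param phases `data.frame` with columns `t_start`, `t_end`, `I_a`, `I_s`
#'   (ms; dimensionless currents relative to threshold). Intervals must be
#'   non-overlapping, contiguous and start at 0.
#' @param cue Optional list with elements `pattern` (index), `amplitude`,
#'   `t_start`, `t_end`, and `scope` (`"all"`, `"asymmetric"`, or
#'   `"symmetric"`); adds `amplitude * xi^pattern` to the input of neurons in
#'   scope during the window.
#' @param noise Optional list with `sd` and `tau_corr` (ms): zero-mean OU
#'   noise added to every neuron's input.
#' @return An object of class `input_protocol`.
#' @seealso [make_prep_exec_protocol()], [constant_protocol()]
#' @export
input_protocol <- function(phases, cue = NULL, noise = NULL) {
  req <- c("t_start", "t_end", "I_a", "I_s")
  if (!is.data.frame(phases) || !all(req %in% names(phases)))
    stop("phases must be a data.frame with columns t_start, t_end, I_a, I_s")
  phases <- phases[order(phases$t_start), , drop = FALSE]
  if (phases$t_start[1L] != 0)
    stop("the first phase must start at t = 0")
  if (any(phases$t_end <= phases$t_start))
    stop("each phase must have t_end > t_start")
  if (nrow(phases) > 1L &&
      any(abs(phases$t_start[-1L] - phases$t_end[-nrow(phases)]) > 1e-9))
    stop("phases must be contiguous and non-overlapping")
  if (!is.null(cue)) {
    cue <- utils::modifyList(
      list(pattern = 1L, amplitude = 1, t_start = 0, scope = "all"), cue)
    if (is.null(cue$t_end)) stop("cue requires t_end")
    if (!cue$scope %in% c("all", "asymmetric", "symmetric"))
      stop("cue scope must be 'all', 'asymmetric' or 'symmetric'")
  }
  if (!is.null(noise)) {
    if (is.null(noise$sd) || is.null(noise$tau_corr))
      stop("noise requires sd and tau_corr")
    if (noise$sd < 0 || noise$tau_corr <= 0)
      stop("noise needs sd >= 0 and tau_corr > 0")
  }
  structure(list(phases = phases, cue = cue, noise = noise),
            class = "input_protocol")
}

#' Constant-input protocol
#'
#' @param I_a,I_s Inputs to the asymmetric and symmetric channels.
#' @param T Duration (ms).
#' @param ... Passed on to [input_protocol()] (e.g. `cue`, `noise`).
#' @return An `input_protocol` with a single phase.
#' @export
constant_protocol <- function(I_a, I_s, T, ...) {
  input_protocol(data.frame(t_start = 0, t_end = T, I_a = I_a, I_s = I_s), ...)
}

#' Preparatory/execution input protocol
#'
#' Builds the protocol that first holds the network in a persistent
#' (preparatory) state and then releases the sequence (execution): a brief
#' cue with the first pattern is presented to the symmetric population,
#' preparatory-period inputs are applied for `prep_duration`, and execution
#' inputs thereafter.
#'
#' @param prep_duration Preparatory period (ms).
#' @param cue_duration Cue window at the start of the preparatory period
#'   (ms, at most `prep_duration`).
#' @param cue_amplitude Amplitude multiplying the cue pattern.
#' @param prep_inputs Length-2 numeric `(I_a, I_s)` during preparation.
#' @param exec_inputs Length-2 numeric `(I_a, I_s)` during execution.
#' @param T Total duration (ms).
#' @param cue_pattern Pattern index presented as cue.
#' @param cue_scope Population receiving the cue.
#' @param ... Passed on to [input_protocol()] (e.g. `noise`).
#' @return An `input_protocol` with the three-phase structure.
#' @export
make_prep_exec_protocol <- function(prep_duration = 200, cue_duration = 10,
                                    cue_amplitude = 1,
                                    prep_inputs, exec_inputs, T,
                                    cue_pattern = 1L,
                                    cue_scope = "symmetric", ...) {
  if (cue_duration > prep_duration)
    stop("cue_duration must not exceed prep_duration")
  if (T <= prep_duration)
    stop("T must exceed prep_duration")
  phases <- data.frame(
    t_start = c(0, prep_duration),
    t_end = c(prep_duration, T),
    I_a = c(prep_inputs[1L], exec_inputs[1L]),
    I_s = c(prep_inputs[2L], exec_inputs[2L]))
  input_protocol(phases,
                 cue = list(pattern = cue_pattern, amplitude = cue_amplitude,
                            t_start = 0, t_end = cue_duration,
                            scope = cue_scope), ...)
}

#' Initial network state
#'
#' `"rate-clamp"` sets the initial rates to the transfer of the first
#' pattern, \eqn{r_i(0) = \phi(\xi_i^1)}; `"member-clamp"` (for
#' binarising plasticity rules) activates exactly the neurons whose first
#' pattern entry crosses the rule's postsynaptic threshold,
#' \eqn{r_i(0) = r_{max}\Theta(\xi_i^1 - x_f)}, which is the stored
#' low-activity network state for such rules; `"cue-pulse"` starts the
#' network quiescent (`r(0) = 0`), with the pattern expected to be
#' delivered through a protocol cue instead.
#'
#' @param patterns A [generate_patterns()] object.
#' @param tf A [transfer_function()].
#' @param mode `"rate-clamp"`, `"member-clamp"` or `"cue-pulse"`.
#' @param rule A threshold [plasticity_rule()] (member-clamp only).
#' @return Numeric rate vector of length `N`.
#' @export
initial_state <- function(patterns, tf,
                          mode = c("rate-clamp", "member-clamp", "cue-pulse"),
                          rule = NULL) {
  mode <- match.arg(mode)
  switch(mode,
         `rate-clamp` = transfer(patterns$xi[1L, ], tf),
         `member-clamp` = {
           if (is.null(rule) || rule$kind != "threshold")
             stop("member-clamp requires a threshold plasticity rule")
           tf$r_max * as.numeric(patterns$xi[1L, ] >= rule$x_f)
         },
         `cue-pulse` = rep(0, patterns$N))
}

# Compile a protocol into the piecewise-constant per-neuron input matrix and
# the step index at which each column stops applying.
.compile_protocol <- function(protocol, z, patterns, dt, nsteps) {
  ph <- protocol$phases
  T_total <- nsteps * dt
  if (max(ph$t_end) < T_total - 1e-9)
    stop("protocol phases end before the simulation horizon")
  brk <- c(ph$t_start, ph$t_end)
  if (!is.null(protocol$cue))
    brk <- c(brk, protocol$cue$t_start, protocol$cue$t_end)
  brk <- sort(unique(pmin(pmax(brk, 0), T_total)))
  brk <- brk[brk < T_total]
  seg_start <- brk
  seg_end <- c(brk[-1L], T_total)
  N <- length(z)
  K <- length(seg_start)
  inp <- matrix(0, N, K)
  for (k in seq_len(K)) {
    mid <- (seg_start[k] + seg_end[k]) / 2
    row <- which(ph$t_start <= mid & ph$t_end > mid)[1L]
    if (is.na(row)) stop("protocol phases do not cover t = ", mid, " ms")
    inp[, k] <- (1 - z) * ph$I_a[row] + z * ph$I_s[row]
    cue <- protocol$cue
    if (!is.null(cue) && cue$t_start <= mid && cue$t_end > mid) {
      add <- cue$amplitude * patterns$xi[cue$pattern, ]
      if (cue$scope == "asymmetric") add[z > 0.5] <- 0
      if (cue$scope == "symmetric") add[z <= 0.5] <- 0
      inp[, k] <- inp[, k] + add
    }
  }
  phase_end <- as.integer(round(seg_end / dt))
  phase_end[K] <- nsteps
  list(input = inp, phase_end = phase_end)
}

#' Integrate the firing-rate dynamics
#'
#' Forward-Euler integration of
#' \deqn{\tau \frac{dr_i}{dt} = -r_i +
#'   \phi\left(\sum_j J_{ij} r_j + I^{ext}_i(t)\right)}
#' on a uniform time grid. The step size must satisfy `dt <= tau / 10`.
#' Non-finite rates abort with the first offending step.
#'
#' @param net A `connectivity_matrix` (its `z` drives the input mixing).
#' @param init Initial rate vector (see [initial_state()]).
#' @param protocol An [input_protocol()].
#' @param tf A [transfer_function()].
#' @param patterns The stored [generate_patterns()] sequence (needed when
#'   the protocol has a cue; also attached to the result for metrics).
#' @param tau Rate time constant (ms).
#' @param dt Step size (ms).
#' @param T Duration (ms).
#' @param seed Optional seed controlling the noise stream.
#' @return An object of class `rate_trajectory`: list with `times` (ms),
#'   `rates` (`N x` length(times) matrix), `dt`, `tau`, `tf`, `protocol`,
#'   `seed`, and the network's `z`/`labels`.
#' @export
integrate_rates <- function(net, init, protocol, tf, patterns = NULL,
                            tau = 10, dt = 0.5, T, seed = NULL) {
  stopifnot(inherits(protocol, "input_protocol"),
            inherits(tf, "transfer_function"))
  J <- if (inherits(net, "connectivity_matrix")) net$J else net
  J <- methods::as(J, "CsparseMatrix")
  z <- if (inherits(net, "connectivity_matrix")) net$z else
    rep(0.5, nrow(J))
  if (dt > tau / 10 + 1e-12)
    stop("configuration error: dt must satisfy dt <= tau / 10")
  if (!is.null(protocol$cue) && is.null(patterns))
    stop("a protocol with a cue requires the stored patterns")
  nsteps <- as.integer(round(T / dt))
  comp <- .compile_protocol(protocol, z, patterns, dt, nsteps)
  noise_sd <- 0; noise_tau <- 1
  if (!is.null(protocol$noise)) {
    noise_sd <- protocol$noise$sd
    noise_tau <- protocol$noise$tau_corr
  }
  if (!is.null(seed)) set.seed(seed)
  rates <- rate_euler_cpp(J, as.numeric(init), comp$input, comp$phase_end,
                          tf$theta, tf$sigma, tf$r_max,
                          tau, dt, nsteps, noise_sd, noise_tau)
  structure(list(times = seq(0, by = dt, length.out = nsteps + 1L),
                 rates = rates, dt = dt, tau = tau, tf = tf,
                 protocol = protocol, seed = seed, z = z,
                 labels = if (inherits(net, "connectivity_matrix"))
                   net$labels else NULL),
            class = "rate_trajectory")
}

#' @export
print.rate_trajectory <- function(x, ...) {
  cat(sprintf(
    "rate_trajectory: N = %d neurons, %d steps of %g ms (T = %g ms, tau = %g ms)\n",
    nrow(x$rates), length(x$times) - 1L, x$dt, max(x$times), x$tau))
  invisible(x)
}
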