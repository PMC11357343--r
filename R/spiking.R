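# Leaky integrate-and-fire implementation of the same storage scheme:
# excitatory neurons split into asymmetric and symmetric subpopulations with
# rectified Hebbian E-to-E connectivity built from thresholded (binary)
# patterns, plus unstructured E-I, I-E and I-I wiring for stabilisation.

#' Parameters of the spiking network
#'
#' Per-population (E, I) leaky integrate-and-fire parameters and the wiring
#' constants. Several auxiliary constants of the reference implementation
#' (the rectifier, membrane constants, in-degrees, delays, noise) are not
#' published; the defaults below are this package's own documented choices,
#' tuned so the desk-scale fixture retrieves: membrane time constants 20/10
#' ms (E/I), threshold 20 mV above rest, reset and voltage floor at rest,
#' 2 ms refractoriness, 3 ms exponential synapses, 1 ms delay. `A_EE`,
#' `J_IE_over_K` and the input scalings `lambda_VE`, `lambda_VI` are carried
#' as stated.
#'
#' @param N_a,N_s Sizes of the asymmetric and symmetric excitatory
#'   subpopulations (must be equal).
#' @param N_I Number of inhibitory neurons.
#' @param c_EE Structural connection probability within E.
#' @param c_I Connection probability of the E-I, I-E and I-I blocks.
#' @param A_EE Learning strength of the E-to-E Hebbian term.
#' @param g_EE Overall scale (mV) converting the rectified Hebbian sum into
#'   synaptic weights.
#' @param J_IE,J_EI,J_II Unstructured per-synapse weights (mV): E-to-I
#'   (positive), I-to-E and I-to-I (negative).
#' @param tau_m,v_rest,v_thresh,v_reset,v_floor,tau_rp,tau_s,sigma_noise
#'   Length-2 numeric vectors `(E, I)`: membrane time constant (ms), resting
#'   potential (mV), spike threshold (mV), reset (mV), voltage floor (mV),
#'   refractory period (ms), synaptic time constant (ms), white-noise
#'   amplitude (mV).
#' @param delay Synaptic delay (ms).
#' @param I_bg_E,I_bg_I Constant background drive (mV) to E and I neurons.
#' @param lambda_VE,lambda_VI Input-scaling constants of the reference
#'   parameter set; carried in the object for provenance (the background
#'   drives above are the operative knobs here).
#' @return An object of class `spiking_params`.
#' @export
spiking_params <- function(N_a = 1000, N_s = 1000, N_I = 500,
                           c_EE = 0.2, c_I = 0.2,
                           A_EE = 0.25, g_EE = 3500,
                           J_IE = 2, J_EI = -1.5, J_II = -1.5,
                           tau_m = c(20, 10), v_rest = c(0, 0),
                           v_thresh = c(20, 20), v_reset = c(0, 0),
                           v_floor = c(0, 0), tau_rp = c(2, 2),
                           tau_s = c(6, 3), sigma_noise = c(1, 1),
                           delay = 1, I_bg_E = 19, I_bg_I = 12,
                           lambda_VE = 5.123, lambda_VI = 3.012) {
  if (N_a != N_s) stop("asymmetric and symmetric populations must be equal")
  stopifnot(all(tau_m > 0), all(tau_s > 0), all(tau_rp > 0))
  structure(as.list(environment()), class = "spiking_params")
}

#' Build the spiking-network connectivity
#'
#' E-to-E weights follow the two-population Hebbian rule applied to
#' thresholded (binary) patterns, passed through the rectified synaptic
#' transfer \eqn{\omega(x) = \max(x, 0)} so no E-to-E weight is negative:
#' \deqn{J^{aX}_{ij} = c^{aX}_{ij}\,
#'   \omega\!\left(g_{EE}\frac{A_{EE}}{N_a c}\sum_{\mu=1}^{P-1}
#'   f(\xi_i^{a,\mu+1})\,g(\xi_j^{X,\mu})\right)}
#' and likewise for symmetric rows with \eqn{f(\xi_i^{s,\mu})} (the
#' autoassociative pairing; both sums run to `P - 1` as in the reference
#' formulation). The E-I, I-E and I-I blocks are sparse random graphs with
#' fixed weights. Excitatory rows are non-negative and inhibitory rows
#' non-positive (Dale's law).
#'
#' @param patterns Patterns over the `N_a + N_s` excitatory neurons
#'   (first `N_a` asymmetric).
#' @param rule A threshold [plasticity_rule()] binarising the patterns.
#' @param params A [spiking_params()].
#' @param seed Integer seed for the structural masks.
#' @return An object of class `spiking_connectivity`: list with `W`
#'   (`(N_E + N_I) x (N_E + N_I)` sparse weight matrix, E neurons first),
#'   `pop` (0 = E, 1 = I), `labels` for E neurons, and the build
#'   parameters.
#' @export
build_spiking_connectivity <- function(patterns, rule, params, seed) {
  stopifnot(inherits(patterns, "pattern_sequence"),
            inherits(rule, "plasticity_rule"),
            inherits(params, "spiking_params"))
  N_a <- params$N_a; N_s <- params$N_s; N_I <- params$N_I
  N_E <- N_a + N_s
  if (patterns$N != N_E) stop("patterns must cover the excitatory neurons")
  P <- patterns$P
  if (P < 2) stop("need at least two patterns")
  Fm <- matrix(eval_f(patterns$xi, rule), P, N_E)
  G <- matrix(eval_g(patterns$xi, rule), P, N_E)
  # postsynaptic factor per row: sequential (mu+1) for asymmetric rows,
  # same-pattern for symmetric rows; both sums run over mu = 1..P-1
  U <- matrix(0, P - 1L, N_E)
  for (mu in seq_len(P - 1L)) {
    U[mu, seq_len(N_a)] <- Fm[mu + 1L, seq_len(N_a)]
    U[mu, N_a + seq_len(N_s)] <- Fm[mu, N_a + seq_len(N_s)]
  }
  set.seed(seed)
  # E-to-E structured block
  m <- .sample_mask(N_E, params$c_EE, seed)
  keep <- m$i != m$j
  ii <- m$i[keep]; jj <- m$j[keep]
  scale_row <- c(rep(params$A_EE / (N_a * params$c_EE), N_a),
                 rep(params$A_EE / (N_s * params$c_EE), N_s))
  vals <- numeric(length(ii))
  chunk <- 250000L; start <- 1L
  Gsub <- G[seq_len(P - 1L), , drop = FALSE]
  while (start <= length(ii)) {
    end <- min(start + chunk - 1L, length(ii))
    idx <- start:end
    vals[idx] <- colSums(U[, ii[idx], drop = FALSE] *
                           Gsub[, jj[idx], drop = FALSE])
    start <- end + 1L
  }
  vals <- pmax(params$g_EE * scale_row[ii] * vals, 0)  # rectifier omega
  # unstructured blocks
  rand_block <- function(npost, npre, prob, w, post0, pre0) {
    nnz_col <- stats::rbinom(npre, npost, prob)
    jj <- rep.int(seq_len(npre), nnz_col)
    ii <- unlist(lapply(seq_len(npre), function(j) {
      k <- nnz_col[j]
      if (k > 0L) sample.int(npost, k) else integer(0)
    }), use.names = FALSE)
    list(i = ii + post0, j = jj + pre0, x = rep(w, length(ii)))
  }
  b_IE <- rand_block(N_I, N_E, params$c_I, params$J_IE, N_E, 0L)
  b_EI <- rand_block(N_E, N_I, params$c_I, params$J_EI, 0L, N_E)
  b_II <- rand_block(N_I, N_I, params$c_I, params$J_II, N_E, N_E)
  Ntot <- N_E + N_I
  W <- Matrix::sparseMatrix(
    i = c(ii, b_IE$i, b_EI$i, b_II$i),
    j = c(jj, b_IE$j, b_EI$j, b_II$j),
    x = c(vals, b_IE$x, b_EI$x, b_II$x),
    dims = c(Ntot, Ntot))
  structure(list(W = W, pop = c(rep(0L, N_E), rep(1L, N_I)),
                 labels = c(rep("asymmetric", N_a), rep("symmetric", N_s)),
                 N_a = N_a, N_s = N_s, N_I = N_I, P = P,
                 params = params, rule = rule, seed = seed),
            class = "spiking_connectivity")
}

#' Simulate the leaky integrate-and-fire network
#'
#' Euler-Maruyama integration (`dt <= 0.1` ms) of the membrane equations
#' with voltage-floor gating, delayed exponential synapses,
#' threshold-reset-refractory spiking, and per-population white-noise
#' input. Excitatory neurons receive the background drive plus a
#' subpopulation bias (`I_a` for asymmetric, `I_s` for symmetric neurons,
#' in mV); inhibitory neurons receive `I_bg_I`. A brief cue depolarises the
#' neurons active in the first pattern.
#'
#' @param conn A [build_spiking_connectivity()] object.
#' @param I_a,I_s External input biases (mV) to the two E subpopulations.
#'   The reference retrieval configurations are slow: `I_a = -1.5`,
#'   `I_s = 0.5`; fast: `I_a = 0.75`, `I_s = -0.75`.
#' @param patterns The stored patterns (for the cue).
#' @param cue List with `amplitude` (mV), `duration` (ms) and `pattern`;
#'   applied from `t = 0` to neurons whose thresholded pattern entry is
#'   active.
#' @param T Duration (ms).
#' @param dt Step (ms, at most 0.1).
#' @param seed Integer seed.
#' @param record Indices of neurons whose voltage is recorded.
#' @return An object of class `spike_data`: list with `neuron`, `time`
#'   (spike times, ms), `pop`, `labels`, `vtrace`, `times`, `T`, `dt` and
#'   sizes.
#' @export
simulate_lif <- function(conn, I_a, I_s, patterns,
                         cue = list(amplitude = 10, duration = 20,
                                    pattern = 1L),
                         T = 400, dt = 0.1, seed = 1L,
                         record = c(1L, 2L, 3L)) {
  stopifnot(inherits(conn, "spiking_connectivity"))
  if (dt > 0.1 + 1e-12) stop("dt must be at most 0.1 ms")
  p <- conn$params
  N_E <- conn$N_a + conn$N_s
  Ntot <- N_E + conn$N_I
  nsteps <- as.integer(round(T / dt))
  base <- c(rep(p$I_bg_E + I_a, conn$N_a), rep(p$I_bg_E + I_s, conn$N_s),
            rep(p$I_bg_I, conn$N_I))
  cue_vec <- base
  cue_steps <- 0L
  if (!is.null(cue) && cue$amplitude != 0 && cue$duration > 0) {
    act <- which(eval_f(patterns$xi[cue$pattern, ], conn$rule) > 0)
    cue_vec[act] <- cue_vec[act] + cue$amplitude
    cue_steps <- as.integer(round(cue$duration / dt))
  }
  if (cue_steps > 0L && cue_steps < nsteps) {
    input <- cbind(cue_vec, base)
    phase_end <- c(cue_steps, nsteps)
  } else {
    input <- cbind(base)
    phase_end <- nsteps
  }
  set.seed(seed)
  v0 <- stats::runif(Ntot, 0, p$v_thresh[1] * 0.5)
  out <- lif_euler_cpp(conn$W, conn$pop, input, as.integer(phase_end),
                       p$tau_m, p$v_rest, p$v_thresh, p$v_reset,
                       p$v_floor, p$tau_rp, p$tau_s, p$sigma_noise,
                       p$delay, dt, nsteps, v0, as.integer(record))
  structure(list(neuron = out$neuron, time = out$time, pop = conn$pop,
                 labels = conn$labels, vtrace = out$vtrace,
                 times = seq(0, by = dt, length.out = nsteps + 1L),
                 record = record, T = T, dt = dt,
                 N_E = N_E, N_I = conn$N_I,
                 N_a = conn$N_a, N_s = conn$N_s),
            class = "spike_data")
}

#' @export
print.spike_data <- function(x, ...) {
  cat(sprintf("spike_data: %d spikes from %d neurons over %g ms\n",
              length(x$time), x$N_E + x$N_I, x$T))
  invisible(x)
}

# Gaussian-kernel smoothed firing rates on a 1 ms grid (Hz), per neuron.
.smoothed_rates <- function(spikes, neurons, kernel_width, grid_dt = 1) {
  tgrid <- seq(0, spikes$T, by = grid_dt)
  nt <- length(tgrid)
  counts <- matrix(0, length(neurons), nt)
  idx <- match(spikes$neuron, neurons)
  sel <- !is.na(idx)
  if (any(sel)) {
    bins <- pmin(pmax(floor(spikes$time[sel] / grid_dt) + 1L, 1L), nt)
    for (k in which(sel))
      counts[idx[k], bins[k]] <- counts[idx[k], bins[k]] + 1
  }
  half <- ceiling(3 * kernel_width / grid_dt)
  kern <- stats::dnorm(seq(-half, half) * grid_dt, sd = kernel_width)
  kern <- kern / sum(kern) / (grid_dt / 1000)  # counts/bin -> Hz
  sm <- t(apply(counts, 1L, function(x)
    stats::filter(x, kern, sides = 2L, circular = FALSE)))
  sm[is.na(sm)] <- 0
  list(rates = sm, times = tgrid)
}

#' Pattern correlations from spike trains
#'
#' Smooths each excitatory neuron's spike train with a Gaussian kernel to
#' obtain instantaneous rates, then computes the same normalised pattern
#' correlations as [pattern_correlations()].
#'
#' @param spikes A [simulate_lif()] result.
#' @param patterns The stored patterns over the excitatory neurons.
#' @param kernel_width Gaussian kernel width (ms, `> 0`).
#' @param scope `"all"` (all E), `"asymmetric"`, or `"symmetric"`.
#' @return An `overlap_trajectory` (time grid of 1 ms).
#' @export
spiking_overlaps <- function(spikes, patterns, kernel_width = 10,
                             scope = c("all", "asymmetric", "symmetric")) {
  scope <- match.arg(scope)
  if (kernel_width <= 0) stop("kernel_width must be positive")
  neurons <- switch(scope,
                    all = seq_len(spikes$N_E),
                    asymmetric = seq_len(spikes$N_a),
                    symmetric = spikes$N_a + seq_len(spikes$N_s))
  sm <- .smoothed_rates(spikes, neurons, kernel_width)
  traj <- list(rates = sm$rates, times = sm$times, tau = NA_real_,
               labels = NULL)
  pat <- list(xi = patterns$xi[, neurons, drop = FALSE],
              P = patterns$P, N = length(neurons))
  out <- pattern_correlations(traj, pat, "all")
  out$scope <- scope
  out
}

#' Order neurons by the latency of their peak firing rate
#'
#' Returns the permutation of the requested neurons sorted by the time of
#' their peak kernel-smoothed rate (ties keep index order); neurons that
#' never spike are appended last.
#'
#' @param spikes A [simulate_lif()] result.
#' @param neurons Neuron indices to order (default: all excitatory).
#' @param kernel_width Gaussian kernel width (ms).
#' @return Integer vector: `neurons` reordered.
#' @export
sorted_raster <- function(spikes, neurons = seq_len(spikes$N_E),
                          kernel_width = 10) {
  sm <- .smoothed_rates(spikes, neurons, kernel_width)
  silent <- rowSums(sm$rates) == 0
  peak_t <- sm$times[max.col(sm$rates, ties.method = "first")]
  ord <- order(silent, peak_t)
  neurons[ord]
}
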