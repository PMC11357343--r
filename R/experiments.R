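# Configuration-driven experiment runner and scaled-down reproductions of
# the reference figure experiments.

.required_config <- list(
  network = c("N", "c", "P", "A", "rule", "z_dist"),
  dynamics = c("tau", "dt", "T", "theta", "sigma", "r_max"),
  protocol = c("I_a", "I_s"),
  metrics = c("theta_P"),
  seeds = c("root"))

#' Validate an experiment configuration
#'
#' An experiment configuration is a nested list with blocks `network`
#' (`N`, `c`, `P`, `A`, `rule` = `"bilinear"`/`"threshold"`, `z_dist` =
#' `"two_pop"`/`"homogeneous"`/`"uniform"`, optional `z`, `x_f`, `x_g`,
#' `q_f`, `q_g`, `zero_mean_qg`), `dynamics` (`tau`, `dt`, `T`, `theta`,
#' `sigma`, `r_max`; ms units), `protocol` (`I_a`, `I_s`, optional `noise`
#' = list(sd, tau_corr), optional `prep` block for the
#' preparatory/execution schedule), `metrics` (`theta_P`, optional
#' `window`), and `seeds` (`root`). Unknown keys and missing required
#' fields are reported with their paths.
#'
#' @param config Nested list as above.
#' @return The validated config, invisibly.
#' @export
validate_config <- function(config) {
  if (!is.list(config)) stop("config must be a list")
  extra <- setdiff(names(config), names(.required_config))
  if (length(extra))
    stop("unknown config block(s): ", paste(extra, collapse = ", "))
  optional <- list(network = c("z", "x_f", "x_g", "q_f", "q_g",
                               "zero_mean_qg"),
                   dynamics = character(0),
                   protocol = c("noise", "prep"),
                   metrics = c("window"),
                   seeds = character(0))
  for (blk in names(.required_config)) {
    if (is.null(config[[blk]]))
      stop("missing config block: ", blk)
    have <- names(config[[blk]])
    miss <- setdiff(.required_config[[blk]], have)
    if (length(miss))
      stop("missing config field(s): ",
           paste(paste0(blk, ".", miss), collapse = ", "))
    unk <- setdiff(have, c(.required_config[[blk]], optional[[blk]]))
    if (length(unk))
      stop("unknown config field(s): ",
           paste(paste0(blk, ".", unk), collapse = ", "))
  }
  invisible(config)
}

#' Run one configured experiment
#'
#' Executes build, simulate and metrics for a validated configuration and
#' optionally writes the results (summary JSON, overlap CSV) to a
#' directory. All seeds are echoed in the summary.
#'
#' @param config See [validate_config()].
#' @param out_dir Optional output directory.
#' @return List with `summary` (list), `overlaps` (`overlap_trajectory`),
#'   `trajectory` (`rate_trajectory`) and the resolved `config`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  validate_config(config)
  nw <- config$network; dy <- config$dynamics; pr <- config$protocol
  rule <- if (identical(nw$rule, "threshold"))
    plasticity_rule("threshold", x_f = nw$x_f, x_g = nw$x_g,
                    q_f = nw$q_f, q_g = nw$q_g,
                    zero_mean_qg = isTRUE(nw$zero_mean_qg))
  else plasticity_rule("bilinear")
  seed <- config$seeds$root
  fx <- standard_fixture(N = nw$N, c_prob = nw$c, P = nw$P, tau = dy$tau,
                         A = nw$A, theta = dy$theta, sigma = dy$sigma,
                         rule = rule, kind = nw$z_dist,
                         z = if (!is.null(nw$z)) nw$z else 0.5,
                         dt = dy$dt, T = dy$T, seed = seed)
  noise <- pr$noise
  if (!is.null(pr$prep)) {
    prot <- make_prep_exec_protocol(
      prep_duration = pr$prep$prep_duration,
      cue_duration = pr$prep$cue_duration,
      cue_amplitude = pr$prep$cue_amplitude,
      prep_inputs = c(pr$prep$prep_I_a, pr$prep$prep_I_s),
      exec_inputs = c(pr$I_a, pr$I_s), T = dy$T, noise = noise)
    init <- initial_state(fx$patterns, fx$tf, "cue-pulse")
  } else {
    prot <- constant_protocol(pr$I_a, pr$I_s, dy$T, noise = noise)
    init <- fx$init
  }
  traj <- integrate_rates(fx$net, init, prot, fx$tf, fx$patterns,
                          tau = dy$tau, dt = dy$dt, T = dy$T,
                          seed = seed + 10L)
  ov <- pattern_correlations(traj, fx$patterns)
  sm <- retrieval_summary(traj, fx$patterns, theta_P = config$metrics$theta_P)
  summary <- list(speed = sm$v, quality = sm$quality, status = sm$status,
                  peak_times = sm$peak_times,
                  seeds = list(root = seed, noise = seed + 10L),
                  config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    utils::write.csv(overlaps_to_df(ov),
                     file.path(out_dir, "overlaps.csv"), row.names = FALSE)
  }
  list(summary = summary, overlaps = ov, trajectory = traj, config = config)
}

#' Overlap trajectory as a long data frame
#'
#' @param ov An `overlap_trajectory`.
#' @return `data.frame` with columns `time`, `pattern`, `m`.
#' @export
overlaps_to_df <- function(ov) {
  data.frame(time = rep(ov$times, each = nrow(ov$m)),
             pattern = rep(seq_len(nrow(ov$m)), ncol(ov$m)),
             m = as.vector(ov$m))
}

#' Reproduce a reference experiment at reduced scale
#'
#' Runs the desk-scale version of one of the headline experiments and
#' returns its data:
#' * `"fig1c"`: homogeneous-network speed versus degree of temporal
#'   symmetry `z`, against the mean-field line `1 - z`.
#' * `"fig2"`: two-population phase diagram of speed and quality over a
#'   grid of external inputs, with the mean-field feasibility boundary.
#' * `"fig3"`: nonlinear-rule phase diagram with persistent and
#'   partial-then-persistent regimes flagged.
#' * `"fig4"`: preparatory/execution protocol correlations.
#' * `"fig5"`: continuum-symmetry network speeds over mixed inputs.
#' * `"fig6"`: reward-learning trajectories toward target speeds.
#' * `"fig7"`: spiking-network fast and slow retrieval.
#'
#' @param id Figure experiment id.
#' @param seed Root seed.
#' @param scale Scale factor applied to the reference network size
#'   (`N = 80000 * scale`).
#' @param ... Overrides passed to the underlying experiment functions.
#' @return A list of data frames / objects, per experiment.
#' @export
reproduce <- function(id = c("fig1c", "fig2", "fig3", "fig4", "fig5",
                             "fig6", "fig7"),
                      seed = 1L, scale = 1 / 20, ...) {
  id <- match.arg(id)
  switch(id,
         fig1c = reproduce_speed_symmetry(seed = seed, scale = scale, ...),
         fig2 = reproduce_phase_diagram(seed = seed, scale = scale, ...),
         fig3 = reproduce_nonlinear_phase(seed = seed, scale = scale, ...),
         fig4 = reproduce_prep_exec(seed = seed, scale = scale, ...),
         fig5 = reproduce_continuum(seed = seed, scale = scale, ...),
         fig6 = reproduce_reward_learning(seed = seed, scale = scale, ...),
         fig7 = reproduce_spiking(seed = seed, ...))
}

#' Speed versus degree of temporal symmetry (desk scale)
#'
#' Simulates homogeneous bilinear networks at several `z` and compares the
#' measured retrieval speed with the mean-field prediction `1 - z`. Runs
#' use a mildly negative external input (see the package vignette: clean
#' pulse propagation requires the small-overlap symmetric feedback
#' `z * phi'(I)` to be subcritical, which fails at `I = 0` for large `z`).
#'
#' @param z_values Degrees of temporal symmetry to simulate.
#' @param seeds Seed panel; the per-`z` summary is the median over
#'   successfully retrieved runs.
#' @param I External input applied to every neuron.
#' @param scale Network scale factor (`N = 80000 * scale`).
#' @param c_prob Connection probability.
#' @param seed Unused when `seeds` is given explicitly.
#' @return List with `runs` (per-run data frame) and `summary` (per-`z`
#'   median speed and the `1 - z` prediction).
#' @export
reproduce_speed_symmetry <- function(z_values = c(0, 0.25, 0.5, 0.75),
                                     seeds = 1:5, I = -0.2,
                                     scale = 1 / 20, c_prob = 0.05,
                                     seed = NULL) {
  N <- as.integer(round(80000 * scale))
  runs <- list()
  for (sd_ in seeds) for (z in z_values) {
    fx <- standard_fixture(N = N, c_prob = c_prob, kind = "homogeneous",
                           z = z, seed = sd_)
    s <- run_retrieval(fx, I, I)
    runs[[length(runs) + 1L]] <-
      data.frame(seed = sd_, z = z, speed = s$v, quality = s$quality,
                 status = s$status)
  }
  runs <- do.call(rbind, runs)
  summary <- do.call(rbind, lapply(split(runs, runs$z), function(d) {
    ok <- d$status == "retrieved" & !is.na(d$speed)
    data.frame(z = d$z[1L],
               speed = if (any(ok)) stats::median(d$speed[ok]) else NA_real_,
               n_retrieved = sum(ok),
               mft = mft_speed_homogeneous(d$z[1L]))
  }))
  rownames(summary) <- NULL
  list(runs = runs, summary = summary)
}

#' Two-population input-plane phase diagram (desk scale)
#'
#' @param grid_n Cells per input axis over `[-1, 0]`.
#' @param seed Root seed of the fixture.
#' @param scale Network scale factor.
#' @param T Per-cell horizon (ms).
#' @return List with `diagram` (a `phase_diagram`) and `boundary`
#'   (`data.frame` of the mean-field feasibility classification per cell).
#' @export
reproduce_phase_diagram <- function(grid_n = 9, seed = 1L, scale = 1 / 20,
                                    T = 900) {
  N <- as.integer(round(80000 * scale))
  fx <- standard_fixture(N = N, kind = "two_pop", seed = seed, T = T)
  gI <- seq(-1, 0, length.out = grid_n)
  pd <- sweep_phase_diagram(fx$net, fx$patterns, gI, gI, fx$tf,
                            tau = fx$tau, dt = fx$dt, T = T)
  fe <- expand.grid(I_a = gI, I_s = gI, KEEP.OUT.ATTRS = FALSE)
  fe$feasible <- vapply(seq_len(nrow(fe)), function(k)
    retrieval_feasible(fx$tf$theta, fx$tf$sigma,
                       fe$I_a[k], fe$I_s[k])$feasible, logical(1))
  list(diagram = pd, boundary = fe)
}

#' Nonlinear-rule phase diagram with regime labels (desk scale)
#'
#' Uses the thresholded plasticity rule and the stronger coupling of the
#' nonlinear reference configuration (`A = 20`, `sigma = 0.05`).
#'
#' @inheritParams reproduce_phase_diagram
#' @param I_a_grid,I_s_grid Input grids.
#' @export
reproduce_nonlinear_phase <- function(I_a_grid = seq(-2.5, 0, length.out = 6),
                                      I_s_grid = seq(-1.5, 0, length.out = 4),
                                      seed = 1L, scale = 1 / 20, T = 900) {
  N <- as.integer(round(80000 * scale))
  fx <- nonlinear_fixture(N = N, seed = seed, T = T)
  pd <- sweep_phase_diagram(fx$net, fx$patterns, I_a_grid, I_s_grid, fx$tf,
                            tau = fx$tau, dt = fx$dt, T = T)
  pd
}

#' Preparatory/execution transition experiment (desk scale)
#'
#' Runs the nonlinear-rule network under the cue + preparatory +
#' execution input schedule: a 10 ms cue with the first pattern to the
#' symmetric population, a 200 ms preparatory period with the asymmetric
#' population inhibited (persistent activity holds the first pattern),
#' then an execution period that releases the sequence.
#'
#' @param prep_inputs,exec_inputs Length-2 `(I_a, I_s)` for the two phases.
#' @param cue_amplitude Cue strength.
#' @param seed Root seed.
#' @param scale Network scale factor.
#' @param T Total duration (ms).
#' @return List with `overlaps` (whole network), `overlaps_sym`,
#'   `overlaps_asym`, `summary`, and the protocol.
#' @export
reproduce_prep_exec <- function(prep_inputs = c(-1.6, -0.2),
                                exec_inputs = c(0, -0.1),
                                cue_amplitude = 2, seed = 1L,
                                scale = 1 / 20, T = 900) {
  N <- as.integer(round(80000 * scale))
  fx <- nonlinear_fixture(N = N, seed = seed, T = T, theta = 0.07)
  prot <- make_prep_exec_protocol(prep_duration = 200, cue_duration = 10,
                                  cue_amplitude = cue_amplitude,
                                  prep_inputs = prep_inputs,
                                  exec_inputs = exec_inputs, T = T)
  init <- initial_state(fx$patterns, fx$tf, "cue-pulse")
  traj <- integrate_rates(fx$net, init, prot, fx$tf, fx$patterns,
                          tau = fx$tau, dt = fx$dt, T = T)
  list(overlaps = pattern_correlations(traj, fx$patterns),
       overlaps_sym = pattern_correlations(traj, fx$patterns, "symmetric"),
       overlaps_asym = pattern_correlations(traj, fx$patterns, "asymmetric"),
       summary = retrieval_summary(traj, fx$patterns),
       protocol = prot, trajectory = traj)
}

#' Continuum-symmetry retrieval (desk scale)
#'
#' Network with `z_i ~ U(0, 1)` and per-neuron mixed inputs
#' `I_i = z_i I_s + (1 - z_i) I_a`, using the thresholded rule at `A = 10`.
#'
#' @param input_pairs List of `(I_a, I_s)` pairs to simulate.
#' @param seed Root seed.
#' @param scale Network scale factor.
#' @param T Horizon (ms).
#' @return `data.frame` of speeds per input pair.
#' @export
reproduce_continuum <- function(input_pairs = list(c(-0.1, 0.1),
                                                   c(-0.6, 0.3),
                                                   c(-1.1, 0.5)),
                                seed = 1L, scale = 1 / 20, T = 1200) {
  N <- as.integer(round(80000 * scale))
  fx <- nonlinear_fixture(N = N, seed = seed, T = T, A = 10,
                          kind = "uniform")
  out <- lapply(input_pairs, function(p) {
    s <- run_retrieval(fx, p[1L], p[2L], T = T)
    data.frame(I_a = p[1L], I_s = p[2L], speed = s$v,
               quality = s$quality, status = s$status)
  })
  do.call(rbind, out)
}

#' Reward-learning input trajectories (desk scale)
#'
#' Runs the perturbation learner toward the two reference target speeds on
#' the two-population fixture.
#'
#' @param v_targets Target speeds.
#' @param seed Seed for both fixture and learner stream.
#' @param scale Network scale factor.
#' @param max_trials Trial budget per target.
#' @return List of [learn_inputs()] results, one per target.
#' @export
reproduce_reward_learning <- function(v_targets = c(0.8, 0.3), seed = 1L,
                                      scale = 1 / 20, max_trials = 200L) {
  N <- as.integer(round(80000 * scale))
  fx <- standard_fixture(N = N, kind = "two_pop", seed = 1L, T = 700)
  lapply(v_targets, function(vt) {
    cfg <- learner_config(v_target = vt, seed = seed,
                          max_trials = max_trials)
    learn_inputs(cfg, fx, dt = 1)
  })
}

#' Spiking-network fast and slow retrieval (desk scale)
#'
#' Simulates the LIF network under the fast (`I_a = 0.75, I_s = -0.75`)
#' and slow (`I_a = -1.5, I_s = 0.5`) external input configurations on the
#' same connectivity.
#'
#' @param seed Root seed.
#' @param T Duration (ms).
#' @param params A [spiking_params()].
#' @return List with per-configuration `spikes`, `overlaps` and the span
#'   of overlap peak latencies.
#' @export
reproduce_spiking <- function(seed = 1L, T = 500, params = spiking_params()) {
  fx <- spiking_fixture(params = params, seed = seed)
  run_cfg <- function(I_a, I_s) {
    sp <- simulate_lif(fx$conn, I_a, I_s, fx$patterns, T = T,
                       seed = seed + 7L)
    ov <- spiking_overlaps(sp, fx$patterns)
    pk <- .overlap_peaks(ov, burn_in = 0)
    list(spikes = sp, overlaps = ov, peak_times = pk$t,
         span = diff(range(pk$t, na.rm = TRUE)))
  }
  list(fast = run_cfg(0.75, -0.75), slow = run_cfg(-1.5, 0.5))
}

#' Nonlinear-rule fixture
#'
#' Desk-scale fixture with the thresholded plasticity rule of the
#' nonlinear reference configuration: thresholds `x_f = x_g = 1.5`, offset
#' `q_f = 0.8`, and zero-mean presynaptic offset `q_g` (kept at the
#' explicit reference value 0.8 via `q_g =` if wanted).
#'
#' @param N,c_prob,P,tau Network geometry.
#' @param A Coupling (the nonlinear reference value is 20).
#' @param theta,sigma Transfer parameters (reference: 0 resp. 0.05).
#' @param q_g Presynaptic offset; `NULL` solves the zero-mean value.
#' @param kind Symmetry layout.
#' @param dt,T,seed As in [standard_fixture()].
#' @return A `retrieval_fixture`.
#' @export
nonlinear_fixture <- function(N = 4000, c_prob = 0.05, P = 16, tau = 10,
                              A = 20, theta = 0, sigma = 0.05,
                              q_g = NULL, kind = "two_pop",
                              dt = 0.5, T = 900, seed = 1L) {
  rule <- if (is.null(q_g))
    plasticity_rule("threshold", x_f = 1.5, x_g = 1.5, q_f = 0.8,
                    zero_mean_qg = TRUE)
  else
    plasticity_rule("threshold", x_f = 1.5, x_g = 1.5, q_f = 0.8, q_g = q_g)
  fx <- standard_fixture(N = N, c_prob = c_prob, P = P, tau = tau, A = A,
                         theta = theta, sigma = sigma, rule = rule,
                         kind = kind, dt = dt, T = T, seed = seed)
  # binarising rule: start from the stored low-activity member state
  fx$init <- initial_state(fx$patterns, fx$tf, "member-clamp", rule)
  fx
}

#' Spiking fixture: binary patterns plus connectivity
#'
#' @param params A [spiking_params()].
#' @param P Sequence length.
#' @param seed Root seed.
#' @return List with `patterns`, `rule`, `conn`.
#' @export
spiking_fixture <- function(params = spiking_params(), P = 8, seed = 1L) {
  N_E <- params$N_a + params$N_s
  patterns <- generate_patterns(P, N_E, seed)
  rule <- plasticity_rule("threshold", x_f = 1.5, x_g = 1.5,
                          q_f = 0.8, q_g = 0.8)
  conn <- build_spiking_connectivity(patterns, rule, params, seed + 1L)
  list(patterns = patterns, rule = rule, conn = conn)
}
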