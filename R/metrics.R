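# Retrieval metrics: pattern correlations, the peak-spacing speed estimator,
# quality thresholding, dynamical-regime classification, and input-plane
# sweeps.

#' Correlation of network activity with each stored pattern
#'
#' For every time point the overlap of the instantaneous rates with each
#' stored pattern, normalised by the population standard deviation of the
#' rates:
#' \deqn{m_\mu(t) = \frac{1}{N}\sum_i r_i(t)\,\xi_i^\mu \,/\, \sigma_r(t)}
#' Patterns are used as stored (already zero-mean, unit-variance by
#' construction), and \eqn{\sigma_r} uses the population (1/N)
#' normalisation. Where the rate variance is zero the correlation is
#' undefined and returned as `NA` rather than silently zero.
#'
#' @param traj A [integrate_rates()] trajectory, or any list with `rates`
#'   (`N x T`), `times`, and optionally `labels`.
#' @param patterns The stored [generate_patterns()] sequence.
#' @param scope `"all"`, `"asymmetric"`, or `"symmetric"`: neurons (and
#'   pattern entries) over which the correlation is computed.
#' @return An object of class `overlap_trajectory`: list with `m` (`P x T`
#'   matrix, `NA` where undefined), `times`, `tau`, `scope`.
#' @export
pattern_correlations <- function(traj, patterns,
                                 scope = c("all", "asymmetric", "symmetric")) {
  scope <- match.arg(scope)
  rates <- traj$rates
  idx <- seq_len(nrow(rates))
  if (scope != "all") {
    if (is.null(traj$labels) || all(is.na(traj$labels)))
      stop("trajectory carries no population labels for scope '", scope, "'")
    idx <- which(traj$labels == scope)
    if (length(idx) == 0L) stop("empty population scope '", scope, "'")
  }
  r <- rates[idx, , drop = FALSE]
  xi <- patterns$xi[, idx, drop = FALSE]
  n <- length(idx)
  mu_r <- colMeans(r)
  sd_r <- sqrt(pmax(colMeans(r * r) - mu_r^2, 0))
  m <- (xi %*% r) / n
  m <- sweep(m, 2L, sd_r, "/")
  # rate variance at (or numerically indistinguishable from) zero leaves
  # the correlation undefined
  m[, sd_r < 1e-8] <- NA_real_
  structure(list(m = as.matrix(m), times = traj$times,
                 tau = if (!is.null(traj$tau)) traj$tau else NA_real_,
                 scope = scope),
            class = "overlap_trajectory")
}

#' Construct an overlap trajectory from a plain matrix
#'
#' Convenience constructor used for synthetic overlap traces (e.g. the
#' worked examples of the speed estimator).
#'
#' @param m `P x T` matrix of overlaps.
#' @param times Time grid (ms).
#' @param tau Rate time constant (ms).
#' @param scope Population scope label.
#' @return An `overlap_trajectory`.
#' @export
overlap_trajectory <- function(m, times, tau, scope = "all") {
  stopifnot(is.matrix(m), ncol(m) == length(times))
  structure(list(m = m, times = times, tau = tau, scope = scope),
            class = "overlap_trajectory")
}

#' @export
print.overlap_trajectory <- function(x, ...) {
  cat(sprintf("overlap_trajectory: P = %d patterns, %d time points, scope = %s\n",
              nrow(x$m), ncol(x$m), x$scope))
  invisible(x)
}

# Peak times of each pattern's overlap: argmax on the discrete grid within
# [burn_in, t_stop], first index wins ties.
.overlap_peaks <- function(overlaps, burn_in, t_stop = Inf) {
  keep <- overlaps$times >= burn_in & overlaps$times <= t_stop
  if (!any(keep)) stop("burn-in removes the whole trajectory")
  times <- overlaps$times[keep]
  m <- overlaps$m[, keep, drop = FALSE]
  P <- nrow(m)
  peak_t <- rep(NA_real_, P)
  peak_v <- rep(NA_real_, P)
  for (l in seq_len(P)) {
    row <- m[l, ]
    if (all(is.na(row))) next
    k <- which.max(row)  # first maximum wins ties; NAs never win
    peak_t[l] <- times[k]
    peak_v[l] <- row[k]
  }
  list(t = peak_t, v = peak_v)
}

#' Retrieval speed from overlap peak spacing
#'
#' Estimates the retrieval speed, in units of the inverse time constant, as
#' \deqn{v = \tau \Big/ \overline{\Delta t}, \qquad
#'   \overline{\Delta t} = \frac{1}{P-1}\sum_{l=2}^{P}
#'   \mathrm{argmax}_t m_l(t) - \mathrm{argmax}_t m_{l-1}(t)}
#' after a single-pass exclusion of consecutive peak-time differences
#' exceeding the mean plus two standard deviations of the raw differences
#' (poorly defined peaks, e.g. under persistent activity, produce outlying
#' differences). If no difference survives the exclusion the sequence is
#' considered not retrieved and `v` is `NA`.
#'
#' When a run extends well past the retrieval episode, the network can
#' revisit late patterns with overlap amplitudes nearly identical to the
#' true transient peaks, corrupting a whole-run argmax. Peak detection is
#' therefore restricted to the window ending at the final pattern's first
#' prominent peak: the first time `m_P` reaches 95% of its maximum, plus a
#' `2 * tau` margin. The truncation applies only when the final pattern's
#' maximum reaches `trunc_threshold`; set `trunc_threshold = Inf` to
#' disable it.
#'
#' @param overlaps An [pattern_correlations()] trajectory (`P >= 2`).
#' @param tau Time constant (ms); defaults to the trajectory's.
#' @param burn_in Initial interval (ms) excluded from peak detection.
#' @param trunc_threshold Minimal final-pattern overlap for the
#'   first-peak truncation to apply.
#' @return A list with `v` (speed in `1/tau` units, `NA` when not
#'   retrieved), `retrieved`, `peak_times`, `diffs`, `kept` (logical mask of
#'   surviving differences), `n_excluded`, `t_stop`, and `ordered_frac`
#'   (fraction of raw peak-time differences that are positive, i.e. how
#'   consistently the patterns peaked in sequence order).
#' @examples
#' tm <- seq(0, 400, by = 0.5)
#' m <- t(sapply(1:16, function(l) exp(-(tm - 20 * l)^2 / 50)))
#' ov <- overlap_trajectory(m, tm, tau = 10)
#' retrieval_speed(ov)$v  # peaks 2*tau apart -> 0.5
#' @export
retrieval_speed <- function(overlaps, tau = overlaps$tau,
                            burn_in = 0, trunc_threshold = 0.05) {
  stopifnot(inherits(overlaps, "overlap_trajectory"))
  P <- nrow(overlaps$m)
  if (P < 2) stop("speed needs at least two patterns")
  t_stop <- Inf
  final <- overlaps$m[P, ]
  if (!all(is.na(final))) {
    fmax <- max(final, na.rm = TRUE)
    if (is.finite(fmax) && fmax >= trunc_threshold) {
      k <- which(!is.na(final) & final >= 0.95 * fmax)[1L]
      t_stop <- overlaps$times[k] + 2 * tau
    }
  }
  pk <- .overlap_peaks(overlaps, burn_in, t_stop)
  if (all(is.na(pk$t)))
    return(list(v = NA_real_, retrieved = FALSE, peak_times = pk$t,
                diffs = numeric(0), kept = logical(0), n_excluded = 0L,
                t_stop = t_stop, ordered_frac = NA_real_))
  d <- diff(pk$t)
  d <- d[!is.na(d)]
  if (length(d) == 0L)
    return(list(v = NA_real_, retrieved = FALSE, peak_times = pk$t,
                diffs = d, kept = logical(0), n_excluded = 0L,
                t_stop = t_stop, ordered_frac = NA_real_))
  thr <- mean(d) + 2 * stats::sd(d)
  kept <- if (is.na(thr)) rep(TRUE, length(d)) else d <= thr
  if (!any(kept) || mean(d[kept]) <= 0)
    return(list(v = NA_real_, retrieved = FALSE, peak_times = pk$t,
                diffs = d, kept = kept, n_excluded = sum(!kept),
                t_stop = t_stop, ordered_frac = mean(d > 0)))
  list(v = tau / mean(d[kept]), retrieved = TRUE, peak_times = pk$t,
       diffs = d, kept = kept, n_excluded = sum(!kept), t_stop = t_stop,
       ordered_frac = mean(d > 0))
}

#' Retrieval quality of the final pattern
#'
#' Quality is the maximal correlation of the final stored pattern over the
#' run; retrieval is successful when it reaches the threshold
#' `theta_P = 0.05`.
#'
#' @param overlaps An `overlap_trajectory` containing the final pattern.
#' @param theta_P Success threshold.
#' @return List with `quality` (peak final-pattern correlation) and
#'   `success`.
#' @export
retrieval_quality <- function(overlaps, theta_P = 0.05) {
  stopifnot(inherits(overlaps, "overlap_trajectory"))
  row <- overlaps$m[nrow(overlaps$m), ]
  if (all(is.na(row)))
    return(list(quality = NA_real_, success = FALSE))
  q <- max(row, na.rm = TRUE)
  list(quality = q, success = is.finite(q) && q >= theta_P)
}

#' Classify the dynamical regime of a run
#'
#' Distinguishes four regimes from the overlap traces:
#' * `"persistent"`: a single pattern's correlation plateaus (stays at or
#'   above `theta_P` and within `plateau_tol` of its final value) over the
#'   last `window` ms, with no other pattern having peaked before.
#' * `"partial_then_persistent"`: at least one but fewer than `P` patterns
#'   peaked before such a plateau (sequential activity that stalls into
#'   persistent activity).
#' * `"retrieved"` / `"not_retrieved"`: no plateau; per
#'   [retrieval_quality()] of the final pattern.
#'
#' @param overlaps An `overlap_trajectory`.
#' @param window Plateau assessment window (ms).
#' @param theta_P Activity threshold.
#' @param plateau_tol Relative tolerance for "within x of its end value".
#' @param burn_in Peak-detection burn-in (ms).
#' @return A single status string.
#' @export
classify_dynamics <- function(overlaps, window = 200, theta_P = 0.05,
                              plateau_tol = 0.1,
                              burn_in = 2 * overlaps$tau) {
  stopifnot(inherits(overlaps, "overlap_trajectory"))
  times <- overlaps$times
  T_end <- max(times)
  if (T_end - min(times) <= window)
    stop("run shorter than the plateau window")
  win <- times > T_end - window
  m <- overlaps$m
  P <- nrow(m)
  end_vals <- m[, ncol(m)]
  plateau <- rep(FALSE, P)
  for (l in seq_len(P)) {
    seg <- m[l, win]
    if (any(is.na(seg)) || is.na(end_vals[l])) next
    plateau[l] <- all(seg >= theta_P) &&
      all(abs(seg - end_vals[l]) <= plateau_tol * abs(end_vals[l]))
  }
  pk <- .overlap_peaks(overlaps, burn_in)
  active <- which(!is.na(pk$v) & pk$v >= theta_P)
  if (any(plateau)) {
    lp <- which(plateau)[which.max(end_vals[plateau])]
    before <- setdiff(active[pk$t[active] <= T_end - window], lp)
    if (length(active) >= P && lp == P) {
      # full sequence peaked and the last pattern holds
      return("retrieved")
    }
    if (length(before) == 0L) return("persistent")
    if (length(union(before, lp)) < P) return("partial_then_persistent")
  }
  if (retrieval_quality(overlaps, theta_P)$success) "retrieved"
  else "not_retrieved"
}

#' Summarise one retrieval run
#'
#' Bundles speed, quality and regime classification for a simulated
#' trajectory.
#'
#' @param traj A [integrate_rates()] trajectory.
#' @param patterns The stored pattern sequence.
#' @param theta_P Quality threshold.
#' @param scope Population scope for the correlations.
#' @param window,plateau_tol Passed to [classify_dynamics()]; the regime is
#'   classified only when the run is longer than `window`.
#' @return An object of class `retrieval_summary`: list with `v`, `quality`,
#'   `status`, `peak_times`, `n_excluded`.
#' @export
retrieval_summary <- function(traj, patterns, theta_P = 0.05, scope = "all",
                              window = 200, plateau_tol = 0.1) {
  ov <- pattern_correlations(traj, patterns, scope)
  sp <- retrieval_speed(ov)
  qu <- retrieval_quality(ov, theta_P)
  status <- if (max(ov$times) - min(ov$times) > window)
    classify_dynamics(ov, window, theta_P, plateau_tol)
  else if (qu$success) "retrieved" else "not_retrieved"
  if (status == "retrieved" && !sp$retrieved) status <- "not_retrieved"
  if (status == "retrieved" && !qu$success) status <- "not_retrieved"
  # sequential retrieval requires the peaks (mostly) in sequence order;
  # mixed states can lift the final-pattern correlation above threshold
  # while many patterns peak coincidentally or out of order
  if (status == "retrieved" &&
      (!length(sp$ordered_frac) || is.na(sp$ordered_frac) ||
       sp$ordered_frac < 0.8)) status <- "not_retrieved"
  structure(list(v = sp$v, quality = qu$quality, status = status,
                 peak_times = sp$peak_times, n_excluded = sp$n_excluded,
                 ordered_frac = sp$ordered_frac),
            class = "retrieval_summary")
}

#' @export
print.retrieval_summary <- function(x, ...) {
  cat(sprintf("retrieval_summary: status = %s, speed = %s (1/tau), quality = %s\n",
              x$status,
              ifelse(is.na(x$v), "NA", sprintf("%.3f", x$v)),
              ifelse(is.na(x$quality), "NA", sprintf("%.3f", x$quality))))
  invisible(x)
}

#' Sweep retrieval metrics over a grid of external inputs
#'
#' Runs one retrieval simulation per `(I_a, I_s)` cell on a shared
#' connectivity and summarises each run. Per-cell failures are recorded as
#' status `"error"` rather than aborting the sweep.
#'
#' @param net A `connectivity_matrix`.
#' @param patterns The stored pattern sequence.
#' @param I_a_grid,I_s_grid Strictly monotone input grids.
#' @param tf A [transfer_function()].
#' @param tau,dt,T Integration parameters (ms).
#' @param init Initial state; defaults to the rate-clamped first pattern.
#' @param theta_P Quality threshold.
#' @param noise Optional noise spec passed to each cell's protocol.
#' @param progress Print one line per grid row.
#' @return An object of class `phase_diagram`: `data.frame` in long format
#'   with columns `I_a`, `I_s`, `speed`, `quality`, `status`.
#' @export
sweep_phase_diagram <- function(net, patterns, I_a_grid, I_s_grid, tf,
                                tau = 10, dt = 0.5, T,
                                init = initial_state(patterns, tf),
                                theta_P = 0.05, noise = NULL,
                                progress = FALSE) {
  if (any(diff(I_a_grid) <= 0) || any(diff(I_s_grid) <= 0))
    stop("input grids must be strictly increasing")
  cells <- expand.grid(I_a = I_a_grid, I_s = I_s_grid,
                       KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    Ia <- cells$I_a[k]; Is <- cells$I_s[k]
    res <- tryCatch({
      prot <- constant_protocol(Ia, Is, T, noise = noise)
      traj <- integrate_rates(net, init, prot, tf, patterns,
                              tau = tau, dt = dt, T = T)
      s <- retrieval_summary(traj, patterns, theta_P)
      data.frame(I_a = Ia, I_s = Is, speed = s$v, quality = s$quality,
                 status = s$status)
    }, error = function(e)
      data.frame(I_a = Ia, I_s = Is, speed = NA_real_, quality = NA_real_,
                 status = "error"))
    out[[k]] <- res
    if (progress && k %% length(I_a_grid) == 0L)
      message(sprintf("sweep: %d / %d cells", k, nrow(cells)))
  }
  res <- do.call(rbind, out)
  class(res) <- c("phase_diagram", class(res))
  res
}
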