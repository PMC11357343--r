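# Mean-field theory of sequence retrieval: gain functions, the
# speed-symmetry law, overlap dynamics and the retrieval-feasibility
# condition.
#
# The central object is the gain
#   G(x) = int Dv phi'(v sqrt(x) + I)
# i.e. the Gaussian-averaged slope of the transfer function when the input
# has mean I and variance x. It controls how much of one pattern's overlap
# is transferred to the next in the overlap dynamics.

#' Gain function by numerical quadrature
#'
#' Evaluates \eqn{G(x) = \frac{1}{\sqrt{x}}\int Dv\, \phi(v\sqrt{x} + I)\,v}
#' which, integrating by parts over the Gaussian measure, equals
#' \eqn{\int Dv\, \phi'(v\sqrt{x} + I)}; the latter form is integrated
#' numerically and remains well defined at `x = 0`, where the gain reduces
#' to \eqn{\phi'(I)}.
#'
#' @param x Input variance (`>= 0`).
#' @param theta,sigma Transfer-function parameters (`sigma > 0`).
#' @param I External input.
#' @param r_max Maximal rate of the transfer function.
#' @return The gain (scalar; vectorised over `x`).
#' @export
gain_integral <- function(x, theta, sigma, I, r_max = 1) {
  if (any(x < 0)) stop("x must be non-negative")
  if (sigma <= 0) stop("sigma must be positive")
  phi_prime <- function(h)
    r_max / (sqrt(2 * pi) * sigma) * exp(-(h - theta)^2 / (2 * sigma^2))
  vapply(x, function(xx) {
    if (xx == 0) return(phi_prime(I))
    stats::integrate(function(v) stats::dnorm(v) * phi_prime(v * sqrt(xx) + I),
                     lower = -Inf, upper = Inf,
                     rel.tol = 1e-10, abs.tol = 1e-12)$value
  }, numeric(1))
}

#' Gain function in closed form
#'
#' For the error-function transfer with `r_max = 1` the gain has the closed
#' form
#' \deqn{G(x) = \frac{1}{\sqrt{2\pi(\sigma^2 + x)}}
#'   \exp\left(-\frac{(I - \theta)^2}{2(\sigma^2 + x)}\right)}
#' The exponent uses the analytically derived `(I - theta)^2`;
#' `printed_sign = TRUE` switches to the `(theta + I)^2` variant (the two
#' coincide at `theta = 0`, the setting of all input-plane analyses here).
#'
#' @inheritParams gain_integral
#' @param printed_sign Use `(theta + I)^2` in the exponent.
#' @return The gain (vectorised over `x`).
#' @export
gain_closed_form <- function(x, theta, sigma, I, r_max = 1,
                             printed_sign = FALSE) {
  if (any(x < 0)) stop("x must be non-negative")
  if (sigma <= 0) stop("sigma must be positive")
  num <- if (printed_sign) (theta + I)^2 else (I - theta)^2
  r_max / sqrt(2 * pi * (sigma^2 + x)) * exp(-num / (2 * (sigma^2 + x)))
}

#' Mean-field retrieval speed of the homogeneous network
#'
#' In the homogeneous network with degree of temporal symmetry `z`, the
#' overlap dynamics reduce (for gain near one during successful retrieval)
#' to \eqn{\frac{\tau}{1 - z}\dot q_l = -q_l + q_{l-1}}: each pattern is
#' visited every \eqn{\tau / (1 - z)}, so the retrieval speed is `1 - z` in
#' units of `1/tau`.
#'
#' @param z Degree of temporal symmetry in `[0, 1]` (vectorised).
#' @return Speed `1 - z`.
#' @export
mft_speed_homogeneous <- function(z) {
  if (any(!is.finite(z)) || any(z < 0 | z > 1))
    stop("z must lie in [0, 1]")
  1 - z
}

#' Retrieval feasibility condition
#'
#' Retrieval of an asymptotically long sequence requires the summed gains of
#' the asymmetric and symmetric channels to reach one at some input
#' variance:
#' \deqn{\max_x\left[G_a(x; \theta, \sigma, I_a) +
#'   G_s(x; \theta, \sigma, I_s)\right] \ge 1}
#' The maximum over `x >= 0` is located by scalar optimisation over a
#' bracket covering both per-channel maxima, with the endpoints checked.
#'
#' @param theta,sigma Transfer parameters.
#' @param I_a,I_s External inputs to the two channels.
#' @param r_max Maximal rate.
#' @return List with `feasible` (logical), `max_gain_sum`, `x_max`.
#' @export
retrieval_feasible <- function(theta, sigma, I_a, I_s, r_max = 1) {
  if (sigma <= 0) stop("sigma must be positive")
  gsum <- function(x)
    gain_closed_form(x, theta, sigma, I_a, r_max) +
    gain_closed_form(x, theta, sigma, I_s, r_max)
  # each channel's gain peaks at x* = (I - theta)^2 - sigma^2 (or 0)
  upper <- max((I_a - theta)^2, (I_s - theta)^2, sigma^2) * 2 + 10 * sigma^2
  opt <- stats::optimize(gsum, interval = c(0, upper), maximum = TRUE,
                         tol = 1e-10)
  cand_x <- c(0, opt$maximum, upper)
  cand_g <- vapply(cand_x, gsum, numeric(1))
  k <- which.max(cand_g)
  list(feasible = cand_g[k] >= 1, max_gain_sum = cand_g[k], x_max = cand_x[k])
}

#' Mean-field configuration
#'
#' Parameters of the mean-field overlap dynamics. With `z` supplied the
#' single-population homogeneous dynamics are integrated; otherwise the
#' two-population (asymmetric/symmetric) dynamics with inputs `I_a`, `I_s`.
#' Crosstalk noise amplitudes from non-retrieved patterns enter only through
#' the supplied `R_a`, `R_s` (or `R` for the homogeneous case); the default
#' 0 is the low-load limit.
#'
#' @param theta,sigma Transfer parameters.
#' @param I_a,I_s External inputs (two-population case).
#' @param I External input (homogeneous case).
#' @param z Homogeneous degree of temporal symmetry, or `NULL` for the
#'   two-population model.
#' @param P Number of patterns.
#' @param tau Time constant (ms).
#' @param R_a,R_s,R Crosstalk noise amplitudes (`>= 0`).
#' @param q_init Initial overlap of the first pattern; defaults to the
#'   overlap of the rate-clamped state \eqn{\phi(\xi^1)} with its pattern,
#'   \eqn{E[\phi(\xi)\xi] = G(1)}.
#' @param r_max Maximal rate.
#' @return An object of class `mft_config`.
#' @export
mft_config <- function(theta = 0, sigma = 0.1, I_a = 0, I_s = 0, I = 0,
                       z = NULL, P = 16, tau = 10,
                       R_a = 0, R_s = 0, R = 0, q_init = NULL, r_max = 1) {
  if (sigma <= 0) stop("sigma must be positive")
  if (any(c(R_a, R_s, R) < 0)) stop("crosstalk amplitudes must be >= 0")
  if (!is.null(z) && (z < 0 || z > 1)) stop("z must lie in [0, 1]")
  if (is.null(q_init))
    q_init <- gain_closed_form(1, theta, sigma, 0, r_max)
  structure(list(theta = theta, sigma = sigma, I_a = I_a, I_s = I_s, I = I,
                 z = z, P = as.integer(P), tau = tau,
                 R_a = R_a, R_s = R_s, R = R, q_init = q_init,
                 r_max = r_max),
            class = "mft_config")
}

#' Integrate the mean-field overlap dynamics
#'
#' Two-population form (per pattern `l`, gains re-evaluated each step):
#' \deqn{\tau \dot q^a_l = -q^a_l + (q^a_{l-1} + q^s_{l-1})\,
#'   G_a\big((q^a_{l-1} + q^s_{l-1})^2 + R_a^2\big)}
#' \deqn{\tau \dot q^s_l = -q^s_l + (q^a_l + q^s_l)\,
#'   G_s\big((q^a_l + q^s_l)^2 + R_s^2\big)}
#' Homogeneous form (config with `z`):
#' \deqn{\tau \dot q_l = -q_l + q^z_l\, G\big((q^z_l)^2 + R^2\big), \quad
#'   q^z_l = (1 - z) q_{l-1} + z q_l}
#' The first pattern starts at `q_init`, all others at zero.
#'
#' @param config An [mft_config()].
#' @param T Duration (ms).
#' @param dt Step size (ms).
#' @return An object of class `overlap_state`: list with `times`, `q`
#'   (`P x T` combined overlaps), and for the two-population case `q_a`,
#'   `q_s`.
#' @export
mft_overlap_dynamics <- function(config, T, dt = 0.5) {
  stopifnot(inherits(config, "mft_config"))
  P <- config$P; tau <- config$tau
  nsteps <- as.integer(round(T / dt))
  times <- seq(0, by = dt, length.out = nsteps + 1L)
  th <- config$theta; sg <- config$sigma; rm <- config$r_max
  if (!is.null(config$z)) {
    z <- config$z
    q <- matrix(0, P, nsteps + 1L)
    q[1L, 1L] <- config$q_init
    cur <- q[, 1L]
    for (s in seq_len(nsteps)) {
      prev <- c(0, cur[-P])
      qz <- (1 - z) * prev + z * cur
      G <- gain_closed_form(qz^2 + config$R^2, th, sg, config$I, rm)
      cur <- cur + dt / tau * (-cur + qz * G)
      q[, s + 1L] <- cur
    }
    return(structure(list(times = times, q = q, q_a = NULL, q_s = NULL,
                          config = config),
                     class = "overlap_state"))
  }
  qa <- matrix(0, P, nsteps + 1L)
  qs <- matrix(0, P, nsteps + 1L)
  qa[1L, 1L] <- config$q_init / 2
  qs[1L, 1L] <- config$q_init / 2
  ca <- qa[, 1L]; cs <- qs[, 1L]
  for (s in seq_len(nsteps)) {
    tot <- ca + cs
    prev <- c(0, tot[-P])
    Ga <- gain_closed_form(prev^2 + config$R_a^2, th, sg, config$I_a, rm)
    Gs <- gain_closed_form(tot^2 + config$R_s^2, th, sg, config$I_s, rm)
    ca_new <- ca + dt / tau * (-ca + prev * Ga)
    cs_new <- cs + dt / tau * (-cs + tot * Gs)
    ca <- ca_new; cs <- cs_new
    qa[, s + 1L] <- ca
    qs[, s + 1L] <- cs
  }
  structure(list(times = times, q = qa + qs, q_a = qa, q_s = qs,
                 config = config),
            class = "overlap_state")
}

#' Constant-gain reduction of the overlap dynamics
#'
#' With constant gains the combined overlap dynamics reduce to
#' \deqn{\frac{\tau}{1 - G_s}\dot q_l = -q_l + \frac{G_a}{1 - G_s} q_{l-1}}
#' i.e. an effective time constant \eqn{\tau/(1 - G_s)} and an overlap
#' transfer ratio \eqn{G_a/(1 - G_s)}; the sequence is retrieved only when
#' the ratio exceeds one, otherwise overlap peaks decay along the sequence.
#' `G_s >= 1` is flagged as a diverging effective time constant.
#'
#' @param G_a,G_s Constant gains of the two channels.
#' @param tau Time constant (ms).
#' @return List with `tau_eff`, `transfer_ratio`, `diverges`,
#'   `retrievable`.
#' @export
mft_constant_gain <- function(G_a, G_s, tau = 10) {
  diverges <- G_s >= 1
  list(tau_eff = if (diverges) Inf else tau / (1 - G_s),
       transfer_ratio = if (diverges) Inf else G_a / (1 - G_s),
       diverges = diverges,
       retrievable = !diverges && G_a / (1 - G_s) > 1)
}

#' Mean-field retrieval speed from overlap peak spacing
#'
#' Applies the same peak-spacing estimator used for simulations to a
#' mean-field [mft_overlap_dynamics()] solution.
#'
#' @param state An `overlap_state`.
#' @return As [retrieval_speed()].
#' @export
mft_speed <- function(state) {
  stopifnot(inherits(state, "overlap_state"))
  ov <- overlap_trajectory(state$q, state$times, state$config$tau)
  retrieval_speed(ov)
}
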