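#' Generate a sequence of random Gaussian patterns
#'
#' Draws the `P` stored patterns \eqn{\xi^\mu} (each a vector over `N`
#' neurons) as i.i.d. standard normal entries. The sequence defines the
#' successive network states imprinted in the recurrent connectivity by the
#' Hebbian rule.
#'
#' @param P Number of patterns in the sequence (at least 2).
#' @param N Number of neurons (at least 1).
#' @param seed Integer seed; the same seed reproduces identical patterns.
#' @return An object of class `pattern_sequence`: a list with elements `xi`
#'   (`P x N` matrix, pattern index in rows), `P`, `N`, `seed`.
#' @examples
#' pats <- generate_patterns(P = 4, N = 100, seed = 1)
#' dim(pats$xi)
#' @export
generate_patterns <- function(P, N, seed) {
  if (!is.numeric(P) || length(P) != 1L || P < 2)
    stop("P must be a single count >= 2")
  if (!is.numeric(N) || length(N) != 1L || N < 1)
    stop("N must be a single count >= 1")
  P <- as.integer(P); N <- as.integer(N)
  set.seed(seed)
  xi <- matrix(stats::rnorm(P * N), nrow = P, ncol = N)
  structure(list(xi = xi, P = P, N = N, seed = seed),
            class = "pattern_sequence")
}

#' @export
print.pattern_sequence <- function(x, ...) {
  cat(sprintf("pattern_sequence: P = %d patterns over N = %d neurons (seed %s)\n",
              x$P, x$N, format(x$seed)))
  invisible(x)
}

#' Define a synaptic plasticity rule
#'
#' The Hebbian rule factorises into a postsynaptic function `f` and a
#' presynaptic function `g` applied to the stored pattern entries. Two kinds
#' are supported: the bilinear rule, `f(x) = g(x) = x`, and the threshold
#' (binarising) rule
#' \deqn{f(x) = q_f - 1 + \Theta(x - x_f), \quad
#'       g(x) = q_g - 1 + \Theta(x - x_g)}
#' with the step convention \eqn{\Theta(0) = 1} (thresholds inclusive).
#'
#' For the threshold rule, choosing `q_g` equal to the standard-normal CDF at
#' `x_g` (see [solve_qg_zero_mean()]) makes `g` zero-mean over the Gaussian
#' pattern distribution, which keeps the mean connection strength at zero;
#' set `zero_mean_qg = TRUE` to apply that choice automatically.
#'
#' @param kind `"bilinear"` or `"threshold"`.
#' @param x_f,x_g Thresholds of `f` and `g` (threshold kind only).
#' @param q_f,q_g Offsets of `f` and `g` (threshold kind only).
#' @param zero_mean_qg If `TRUE`, ignore `q_g` and solve for the zero-mean
#'   offset.
#' @return An object of class `plasticity_rule`.
#' @examples
#' plasticity_rule("bilinear")
#' plasticity_rule("threshold", x_f = 1.5, x_g = 1.5, q_f = 0.8, q_g = 0.8)
#' @export
plasticity_rule <- function(kind = c("bilinear", "threshold"),
                            x_f = NA_real_, x_g = NA_real_,
                            q_f = NA_real_, q_g = NA_real_,
                            zero_mean_qg = FALSE) {
  kind <- match.arg(kind)
  if (kind == "threshold") {
    if (!is.finite(x_f) || !is.finite(x_g))
      stop("threshold rule requires finite x_f and x_g")
    if (zero_mean_qg) q_g <- solve_qg_zero_mean(x_g)
    if (!is.finite(q_f) || !is.finite(q_g))
      stop("threshold rule requires q_f and q_g (or zero_mean_qg = TRUE)")
  }
  structure(list(kind = kind, x_f = x_f, x_g = x_g, q_f = q_f, q_g = q_g),
            class = "plasticity_rule")
}

#' @export
print.plasticity_rule <- function(x, ...) {
  if (x$kind == "bilinear") {
    cat("plasticity_rule: bilinear (f(x) = g(x) = x)\n")
  } else {
    cat(sprintf(
      "plasticity_rule: threshold (x_f = %g, q_f = %g; x_g = %g, q_g = %g)\n",
      x$x_f, x$q_f, x$x_g, x$q_g))
  }
  invisible(x)
}

#' Evaluate the postsynaptic plasticity function f
#'
#' @param x Numeric vector of pattern entries.
#' @param rule A [plasticity_rule()].
#' @return `f(x)`, same length as `x`.
#' @export
eval_f <- function(x, rule) {
  stopifnot(inherits(rule, "plasticity_rule"))
  if (rule$kind == "bilinear") return(x)
  rule$q_f - 1 + as.numeric(x >= rule$x_f)
}

#' Evaluate the presynaptic plasticity function g
#'
#' @inheritParams eval_f
#' @return `g(x)`, same length as `x`.
#' @export
eval_g <- function(x, rule) {
  stopifnot(inherits(rule, "plasticity_rule"))
  if (rule$kind == "bilinear") return(x)
  rule$q_g - 1 + as.numeric(x >= rule$x_g)
}

#' Zero-mean offset for the presynaptic threshold function
#'
#' Returns the offset \eqn{q_g} such that the thresholded presynaptic
#' function \eqn{g(x) = q_g - 1 + \Theta(x - x_g)} has zero mean under the
#' standard-normal pattern distribution, i.e. \eqn{q_g = \Phi(x_g)}. A
#' zero-mean `g` keeps the mean recurrent connection strength at zero.
#'
#' @param x_g Finite threshold.
#' @return The offset `q_g` in `[0, 1]`.
#' @examples
#' solve_qg_zero_mean(0)    # 0.5 by symmetry
#' solve_qg_zero_mean(1.5)  # ~0.933
#' @export
solve_qg_zero_mean <- function(x_g) {
  if (!is.numeric(x_g) || length(x_g) != 1L || !is.finite(x_g))
    stop("x_g must be a single finite number")
  stats::pnorm(x_g)
}

#' Assign per-neuron degrees of temporal symmetry
#'
#' Each neuron carries a degree of temporal symmetry \eqn{z_i \in [0, 1]}
#' mixing the autoassociative (same-pattern, `z = 1`) and sequential
#' (next-pattern, `z = 0`) components of its plasticity rule.
#' Three distributions are supported:
#' * `"homogeneous"`: all neurons share the value `z`.
#' * `"bimodal"`: `z_i` is Bernoulli, `P(z_i = 1) = p`, splitting the
#'   network into symmetric and asymmetric subpopulations.
#' * `"uniform"`: `z_i ~ U(0, 1)`, a continuum of rules.
#'
#' @param N Number of neurons.
#' @param kind Distribution kind.
#' @param z Shared value for the homogeneous kind (in `[0, 1]`).
#' @param p Probability of `z_i = 1` for the bimodal kind.
#' @param seed Integer seed for the random kinds.
#' @param values Optional explicit numeric vector of length `N` in `[0, 1]`;
#'   overrides `kind` (recorded as `"explicit"`).
#' @return An object of class `symmetry_profile`: list with `z` (length-`N`
#'   vector), `kind`, `p`, `seed`.
#' @examples
#' prof <- assign_symmetry(1000, "bimodal", p = 0.5, seed = 2)
#' mean(prof$z == 1)
#' @export
assign_symmetry <- function(N, kind = c("homogeneous", "bimodal", "uniform"),
                            z = 0.5, p = 0.5, seed = NULL, values = NULL) {
  if (!is.numeric(N) || length(N) != 1L || N < 1)
    stop("N must be a single count >= 1")
  N <- as.integer(N)
  if (!is.null(values)) {
    if (length(values) != N || any(!is.finite(values)) ||
        any(values < 0 | values > 1))
      stop("values must be length N with entries in [0, 1]")
    return(structure(list(z = as.numeric(values), kind = "explicit",
                          p = NA_real_, seed = seed),
                     class = "symmetry_profile"))
  }
  kind <- match.arg(kind)
  zvec <- switch(kind,
    homogeneous = {
      if (!is.finite(z) || z < 0 || z > 1) stop("z must lie in [0, 1]")
      rep(as.numeric(z), N)
    },
    bimodal = {
      if (!is.finite(p) || p < 0 || p > 1) stop("p must lie in [0, 1]")
      if (!is.null(seed)) set.seed(seed)
      as.numeric(stats::runif(N) < p)
    },
    uniform = {
      if (!is.null(seed)) set.seed(seed)
      stats::runif(N)
    })
  structure(list(z = zvec, kind = kind,
                 p = if (kind == "bimodal") p else NA_real_, seed = seed),
            class = "symmetry_profile")
}

#' @export
print.symmetry_profile <- function(x, ...) {
  cat(sprintf("symmetry_profile: N = %d, kind = %s, mean z = %.3f\n",
              length(x$z), x$kind, mean(x$z)))
  invisible(x)
}
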