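# Independent reference implementations used as oracles. These deliberately
# avoid the package's vectorised/sparse code paths: dense triple loops and
# plain-R integrators.

# Dense triple-loop evaluation of the generalised Hebbian rule on a given
# structural mask (0/1 matrix):
#   J_ij = A mask_ij / (N c) [ z_i sum_mu f(xi_i^mu) g(xi_j^mu)
#                            + (1-z_i) sum_{mu<P} f(xi_i^{mu+1}) g(xi_j^mu) ]
dense_hebbian_oracle <- function(xi, z, f, g, A, c_prob, mask,
                                 row_scale = NULL, zero_diag = TRUE) {
  P <- nrow(xi); N <- ncol(xi)
  J <- matrix(0, N, N)
  for (i in seq_len(N)) {
    sc <- if (is.null(row_scale)) A / (N * c_prob) else row_scale[i]
    for (j in seq_len(N)) {
      if (mask[i, j] == 0) next
      if (zero_diag && i == j) next
      acc <- 0
      for (mu in seq_len(P))
        acc <- acc + z[i] * f(xi[mu, i]) * g(xi[mu, j])
      for (mu in seq_len(P - 1L))
        acc <- acc + (1 - z[i]) * f(xi[mu + 1L, i]) * g(xi[mu, j])
      J[i, j] <- sc * acc
    }
  }
  J
}

# Plain-R forward-Euler integration of the rate equations with constant
# per-neuron input (dense J).
euler_rates_oracle <- function(J, r0, input, theta, sigma, rmax, tau, dt,
                               nsteps) {
  N <- length(r0)
  rates <- matrix(0, N, nsteps + 1L)
  r <- r0
  rates[, 1L] <- r
  for (s in seq_len(nsteps)) {
    h <- as.vector(J %*% r) + input
    phi <- rmax * pnorm((h - theta) / sigma)
    r <- r + dt / tau * (phi - r)
    rates[, s + 1L] <- r
  }
  rates
}

# Monte-Carlo estimate of the gain G(x) = (1/sqrt(x)) E[ phi(v sqrt(x) + I) v ]
# for standard-normal v, with its standard error.
gain_mc_oracle <- function(x, theta, sigma, I, n = 1e6, seed = 1) {
  set.seed(seed)
  v <- rnorm(n)
  vals <- pnorm((v * sqrt(x) + I - theta) / sigma) * v / sqrt(x)
  c(est = mean(vals), se = sd(vals) / sqrt(n))
}

# Small helper: synthetic unimodal overlap traces with prescribed peak times.
synthetic_overlaps <- function(peak_times, times, width = 5) {
  m <- t(vapply(peak_times,
                function(p) exp(-(times - p)^2 / (2 * width^2)),
                numeric(length(times))))
  m
}

# Shared desk-scale fixture cache so acceptance blocks reuse heavy builds.
.fixture_cache <- new.env(parent = emptyenv())
cached_fixture <- function(key, builder) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}
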