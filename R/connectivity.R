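# Sparse Hebbian connectivity built from a stored pattern sequence.
#
# The general rule, for postsynaptic neuron i and presynaptic neuron j:
#   J_ij = A c_ij / (N c) * ( z_i  sum_{mu=1}^{P}   f(xi_i^mu)   g(xi_j^mu)
#                         + (1-z_i) sum_{mu=1}^{P-1} f(xi_i^{mu+1}) g(xi_j^mu) )
# with c_ij an i.i.d. Bernoulli(c) structural mask. The degree of temporal
# symmetry z_i depends only on the postsynaptic neuron. Collapsing the two
# sums gives J_ij propto sum_mu U[mu, i] G[mu, j] with
#   U[mu, i] = z_i f(xi_i^mu) + (1 - z_i) f(xi_i^{mu+1})   (mu < P)
#   U[P, i]  = z_i f(xi_i^P)
# so values at mask entries are computed by streaming over triplet chunks,
# never forming a dense N x N intermediate.

# Column-wise i.i.d. Bernoulli(c) mask as triplets (deterministic per seed).
.sample_mask <- function(N, c_prob, seed) {
  set.seed(seed)
  rows <- vector("list", N)
  counts <- stats::rbinom(N, N, c_prob)
  for (j in seq_len(N)) {
    k <- counts[j]
    rows[[j]] <- if (k > 0L) sort.int(sample.int(N, k)) else integer(0)
  }
  list(i = unlist(rows, use.names = FALSE), j = rep.int(seq_len(N), counts))
}

# Shared core: values at mask entries from U, G and a per-row scale.
.build_sparse_hebbian <- function(U, G, row_scale, N, c_prob, seed,
                                  zero_diag = TRUE) {
  m <- .sample_mask(N, c_prob, seed)
  ii <- m$i; jj <- m$j
  if (zero_diag) {
    keep <- ii != jj
    ii <- ii[keep]; jj <- jj[keep]
  }
  nnz <- length(ii)
  vals <- numeric(nnz)
  chunk <- 250000L
  start <- 1L
  while (start <= nnz) {
    end <- min(start + chunk - 1L, nnz)
    idx <- start:end
    vals[idx] <- colSums(U[, ii[idx], drop = FALSE] * G[, jj[idx], drop = FALSE])
    start <- end + 1L
  }
  vals <- vals * row_scale[ii]
  list(J = Matrix::sparseMatrix(i = ii, j = jj, x = vals, dims = c(N, N)),
       mask = Matrix::sparseMatrix(i = m$i, j = m$j, x = TRUE,
                                   dims = c(N, N)))
}

.postsyn_mix <- function(Fm, z) {
  P <- nrow(Fm)
  U <- matrix(0, P, ncol(Fm))
  for (mu in seq_len(P - 1L))
    U[mu, ] <- z * Fm[mu, ] + (1 - z) * Fm[mu + 1L, ]
  U[P, ] <- z * Fm[P, ]
  U
}

#' Build the recurrent connectivity matrix
#'
#' Imprints the pattern sequence into a sparse recurrent weight matrix using
#' the generalised Hebbian rule that mixes an autoassociative (same-pattern)
#' and a sequential (next-pattern) component per postsynaptic neuron,
#' weighted by its degree of temporal symmetry `z_i`. Weights are normalised
#' by `A / (N c)` and carried only on an i.i.d. Bernoulli(`c`) structural
#' mask. Self-connections are zeroed.
#'
#' @param patterns A [generate_patterns()] object.
#' @param profile A [assign_symmetry()] profile with matching `N`.
#' @param rule A [plasticity_rule()].
#' @param A Overall connection strength.
#' @param c_prob Connection probability in `(0, 1]`.
#' @param seed Integer seed for the structural mask.
#' @return An object of class `connectivity_matrix`: list with `J`
#'   (`Matrix::dgCMatrix`), `mask` (pattern of structural connections), `z`,
#'   `labels` (`"asymmetric"`/`"symmetric"` where `z` is binary, else `NA`),
#'   and the build parameters.
#' @examples
#' pats <- generate_patterns(P = 3, N = 50, seed = 1)
#' prof <- assign_symmetry(50, "homogeneous", z = 0.5)
#' net <- build_connectivity(pats, prof, plasticity_rule("bilinear"),
#'                           A = 2, c_prob = 1, seed = 2)
#' @export
build_connectivity <- function(patterns, profile, rule, A, c_prob, seed) {
  stopifnot(inherits(patterns, "pattern_sequence"),
            inherits(profile, "symmetry_profile"),
            inherits(rule, "plasticity_rule"))
  if (length(profile$z) != patterns$N)
    stop("patterns and symmetry profile disagree on N")
  if (!is.finite(c_prob) || c_prob <= 0 || c_prob > 1)
    stop("c_prob must lie in (0, 1]")
  N <- patterns$N; P <- patterns$P
  Fm <- matrix(eval_f(patterns$xi, rule), P, N)
  G <- matrix(eval_g(patterns$xi, rule), P, N)
  U <- .postsyn_mix(Fm, profile$z)
  built <- .build_sparse_hebbian(U, G, rep(A / (N * c_prob), N),
                                 N, c_prob, seed)
  z <- profile$z
  labels <- if (all(z %in% c(0, 1)))
    ifelse(z == 1, "symmetric", "asymmetric") else rep(NA_character_, N)
  structure(list(J = built$J, mask = built$mask, N = N, P = P, A = A,
                 c_prob = c_prob, z = z, labels = labels,
                 normalization = "whole-network", rule = rule,
                 mask_seed = seed),
            class = "connectivity_matrix")
}

#' Build two-population (asymmetric/symmetric) connectivity
#'
#' Block form of the Hebbian connectivity in which neurons `1..N_a`
#' (asymmetric rows) carry only the sequential term, normalised by
#' `1 / (N_a c)`, and neurons `N_a+1..N` (symmetric rows) carry only the
#' autoassociative term, normalised by `1 / (N_s c)`:
#' \deqn{J^{aX}_{ij} = \frac{A c_{ij}}{N_a c} \sum_{\mu=1}^{P-1}
#'   f(\xi_i^{a,\mu+1}) g(\xi_j^{X,\mu}), \qquad
#'   J^{sX}_{ij} = \frac{A c_{ij}}{N_s c} \sum_{\mu=1}^{P}
#'   f(\xi_i^{s,\mu}) g(\xi_j^{X,\mu})}
#'
#' @inheritParams build_connectivity
#' @param N_a,N_s Sizes of the asymmetric and symmetric populations
#'   (`N_a + N_s` must equal the patterns' `N`; equal sizes by default).
#' @return A `connectivity_matrix` with `normalization = "per-population"`.
#' @export
build_connectivity_two_pop <- function(patterns, rule, A, c_prob,
                                       N_a = patterns$N / 2,
                                       N_s = patterns$N - N_a, seed) {
  stopifnot(inherits(patterns, "pattern_sequence"),
            inherits(rule, "plasticity_rule"))
  N <- patterns$N; P <- patterns$P
  if (N_a < 1 || N_s < 1) stop("both populations must be non-empty")
  if (N_a + N_s != N) stop("N_a + N_s must equal the patterns' N")
  if (!is.finite(c_prob) || c_prob <= 0 || c_prob > 1)
    stop("c_prob must lie in (0, 1]")
  z <- c(rep(0, N_a), rep(1, N_s))
  Fm <- matrix(eval_f(patterns$xi, rule), P, N)
  G <- matrix(eval_g(patterns$xi, rule), P, N)
  U <- .postsyn_mix(Fm, z)
  row_scale <- c(rep(A / (N_a * c_prob), N_a), rep(A / (N_s * c_prob), N_s))
  built <- .build_sparse_hebbian(U, G, row_scale, N, c_prob, seed)
  structure(list(J = built$J, mask = built$mask, N = N, P = P, A = A,
                 c_prob = c_prob, z = z,
                 labels = c(rep("asymmetric", N_a), rep("symmetric", N_s)),
                 N_a = N_a, N_s = N_s,
                 normalization = "per-population", rule = rule,
                 mask_seed = seed),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf(
    "connectivity_matrix: N = %d, P = %d, A = %g, c = %g (%s normalisation)\n",
    x$N, x$P, x$A, x$c_prob, x$normalization))
  cat(sprintf("  nonzero structural entries: %d (density %.4f)\n",
              Matrix::nnzero(x$mask), Matrix::nnzero(x$mask) / x$N^2))
  invisible(x)
}

#' Indices of neurons in a named population scope
#'
#' @param net A `connectivity_matrix` (or any object with `labels`/`z`).
#' @param scope `"all"`, `"asymmetric"`, or `"symmetric"`.
#' @return Integer vector of neuron indices.
#' @export
population_indices <- function(net, scope = c("all", "asymmetric", "symmetric")) {
  scope <- match.arg(scope)
  if (scope == "all") return(seq_len(net$N))
  idx <- which(net$labels == scope)
  if (length(idx) == 0L)
    stop("no neurons labelled '", scope, "' in this network")
  idx
}
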