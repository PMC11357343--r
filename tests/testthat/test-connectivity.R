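# Sparse Hebbian connectivity against dense brute-force oracles.

test_that("sparse build equals the dense triple-loop oracle", {
  for (rule_kind in c("bilinear", "threshold")) {
    rule <- if (rule_kind == "bilinear") plasticity_rule("bilinear")
    else plasticity_rule("threshold", x_f = 0.5, x_g = 0.8,
                         q_f = 0.7, q_g = 0.6)
    pats <- generate_patterns(P = 3, N = 20, seed = 11)
    prof <- assign_symmetry(20, "uniform", seed = 12)
    net <- build_connectivity(pats, prof, rule, A = 2, c_prob = 1, seed = 13)
    oracle <- dense_hebbian_oracle(
      pats$xi, prof$z,
      function(x) eval_f(x, rule), function(x) eval_g(x, rule),
      A = 2, c_prob = 1, mask = as.matrix(net$mask) * 1)
    expect_equal(as.matrix(net$J), oracle, ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
})

test_that("sparse build matches the oracle on a random mask", {
  pats <- generate_patterns(P = 5, N = 40, seed = 21)
  prof <- assign_symmetry(40, "bimodal", p = 0.5, seed = 22)
  net <- build_connectivity(pats, prof, plasticity_rule("bilinear"),
                            A = 1.5, c_prob = 0.4, seed = 23)
  oracle <- dense_hebbian_oracle(
    pats$xi, prof$z, identity, identity,
    A = 1.5, c_prob = 0.4, mask = as.matrix(net$mask) * 1)
  expect_equal(as.matrix(net$J), oracle, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("pure z limits keep only one Hebbian term", {
  pats <- generate_patterns(P = 3, N = 15, seed = 31)
  rule <- plasticity_rule("bilinear")
  # z = 0 everywhere: only the sequential term; J r-clamped to pattern mu
  # projects onto f(xi^{mu+1})
  net0 <- build_connectivity(pats, assign_symmetry(15, "homogeneous", z = 0),
                             rule, A = 1, c_prob = 1, seed = 32)
  seq_only <- dense_hebbian_oracle(pats$xi, rep(0, 15), identity, identity,
                                   A = 1, c_prob = 1,
                                   mask = matrix(1, 15, 15))
  expect_equal(as.matrix(net0$J), seq_only, ignore_attr = TRUE)
  # z = 1 everywhere: only the autoassociative term
  net1 <- build_connectivity(pats, assign_symmetry(15, "homogeneous", z = 1),
                             rule, A = 1, c_prob = 1, seed = 32)
  auto_only <- dense_hebbian_oracle(pats$xi, rep(1, 15), identity, identity,
                                    A = 1, c_prob = 1,
                                    mask = matrix(1, 15, 15))
  expect_equal(as.matrix(net1$J), auto_only, ignore_attr = TRUE)
  expect_false(identical(as.matrix(net0$J), as.matrix(net1$J)))
})

test_that("two-population block build is the bimodal rule up to normalisation", {
  pats <- generate_patterns(P = 3, N = 20, seed = 41)
  rule <- plasticity_rule("bilinear")
  two <- build_connectivity_two_pop(pats, rule, A = 2, c_prob = 0.5,
                                    N_a = 10, N_s = 10, seed = 42)
  bim <- build_connectivity(pats,
                            assign_symmetry(20, values = rep(c(0, 1), each = 10)),
                            rule, A = 2, c_prob = 0.5, seed = 42)
  # identical mask (same seed); per-population rows normalise by N/2
  # instead of N, hence exactly twice the whole-network build
  expect_equal(as.matrix(two$J), 2 * as.matrix(bim$J), ignore_attr = TRUE)
  expect_error(build_connectivity_two_pop(pats, rule, 2, 0.5,
                                          N_a = 0, N_s = 20, seed = 1),
               "non-empty")
  expect_error(build_connectivity_two_pop(pats, rule, 2, 0.5,
                                          N_a = 5, N_s = 10, seed = 1),
               "must equal")
})

test_that("asymmetric rows project mu -> mu+1 and symmetric rows mu -> mu", {
  pats <- generate_patterns(P = 3, N = 120, seed = 51)
  rule <- plasticity_rule("bilinear")
  net <- build_connectivity_two_pop(pats, rule, A = 1, c_prob = 1, seed = 52)
  J <- as.matrix(net$J)
  # feed pattern mu as presynaptic rates: asymmetric rows respond along
  # f(xi^{mu+1}) (sequential), symmetric rows along f(xi^{mu}) (same)
  mu <- 2
  drive <- J %*% pats$xi[mu, ]
  asym <- 1:60; sym <- 61:120
  expect_gt(cor(drive[asym], pats$xi[mu + 1, asym]), 0.8)
  expect_gt(cor(drive[sym], pats$xi[mu, sym]), 0.8)
  expect_lt(abs(cor(drive[asym], pats$xi[mu, asym])), 0.4)
})

test_that("mask density, mask consistency, diagonal and determinism hold", {
  N <- 2000
  pats <- generate_patterns(P = 4, N = N, seed = 61)
  prof <- assign_symmetry(N, "homogeneous", z = 0.5)
  net <- build_connectivity(pats, prof, plasticity_rule("bilinear"),
                            A = 2, c_prob = 0.05, seed = 62)
  dens <- Matrix::nnzero(net$mask) / N^2
  se <- sqrt(0.05 * 0.95 / N^2)
  expect_lt(abs(dens - 0.05), 5 * se)
  # weights only where the mask allows
  bad <- Matrix::sparseMatrix(
    i = net$J@i + 1L,
    j = rep(seq_len(N), diff(net$J@p)),
    x = TRUE, dims = c(N, N)) & !net$mask
  expect_equal(sum(bad), 0)
  expect_equal(Matrix::diag(net$J), rep(0, N))
  # zero mean of bilinear weights over pattern draws
  mean_w <- mean(net$J@x)
  se_w <- sd(net$J@x) / sqrt(length(net$J@x))
  expect_lt(abs(mean_w), 5 * se_w)
  net2 <- build_connectivity(pats, prof, plasticity_rule("bilinear"),
                             A = 2, c_prob = 0.05, seed = 62)
  expect_identical(as.matrix(net$J), as.matrix(net2$J))
})
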