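# Transfer function, input protocols, OU noise and the Euler integrator.

test_that("transfer function has the error-function shape", {
  tf <- transfer_function(theta = 0.3, sigma = 0.2, r_max = 5)
  expect_equal(transfer(0.3, tf), 2.5)
  expect_equal(transfer(1e3, tf), 5)
  expect_equal(transfer(-1e3, tf), 0)
  tf2 <- transfer_function(theta = 0, sigma = 0.1, r_max = 1)
  expect_equal(transfer(0.1, tf2), 0.8413, tolerance = 1e-4)
  expect_true(all(diff(transfer(seq(-0.3, 0.3, by = 0.01), tf2)) > 0))
  expect_error(transfer_function(sigma = 0), "sigma")
})

test_that("OU noise has exact stationary moments and correlation time", {
  x <- ou_noise(mean = -0.2, sd = 0.3, tau_corr = 4, dt = 0.5, T = 4e4,
                seed = 5)
  expect_lt(abs(mean(x) + 0.2), 0.02)
  expect_lt(abs(sd(x) - 0.3) / 0.3, 0.05)
  # lag-4ms autocorrelation ~ exp(-1)
  lag <- 8  # 4 ms at dt = 0.5
  ac <- cor(x[-(1:lag)], x[seq_len(length(x) - lag)])
  expect_lt(abs(ac - exp(-1)), 0.05)
  expect_identical(ou_noise(1, 0, 4, 0.5, 10), rep(1, 21))
  expect_identical(ou_noise(0, 0.3, 4, 0.5, 10, seed = 9),
                   ou_noise(0, 0.3, 4, 0.5, 10, seed = 9))
})

test_that("protocol validation rejects malformed schedules", {
  expect_error(input_protocol(data.frame(t_start = 10, t_end = 20,
                                         I_a = 0, I_s = 0)),
               "start at t = 0")
  expect_error(input_protocol(data.frame(t_start = c(0, 30),
                                         t_end = c(20, 50),
                                         I_a = 0, I_s = 0)),
               "contiguous")
  expect_error(input_protocol(data.frame(t_start = 0, t_end = 0,
                                         I_a = 0, I_s = 0)),
               "t_end > t_start")
  expect_error(constant_protocol(0, 0, 100, noise = list(sd = 0.1)),
               "noise requires")
  expect_error(make_prep_exec_protocol(cue_duration = 300,
                                       prep_inputs = c(0, 0),
                                       exec_inputs = c(0, 0), T = 500),
               "cue_duration")
  p <- make_prep_exec_protocol(prep_duration = 200, cue_duration = 10,
                               cue_amplitude = 2, prep_inputs = c(-2, 0),
                               exec_inputs = c(0, -0.5), T = 600)
  expect_equal(nrow(p$phases), 2L)
  expect_equal(p$cue$t_end, 10)
  expect_equal(p$phases$I_a, c(-2, 0))
})

test_that("uncoupled network relaxes to the transfer fixed point", {
  N <- 30
  J <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(N, N))
  tf <- transfer_function(theta = 0, sigma = 0.1)
  pats <- generate_patterns(2, N, seed = 1)
  traj <- integrate_rates(J, rep(0, N), constant_protocol(0.25, 0.25, 210),
                          tf, pats, tau = 10, dt = 0.5, T = 210)
  fp <- transfer(0.25, tf)
  expect_lt(max(abs(traj$rates[, ncol(traj$rates)] - fp)), 1e-6)
  # e-fold relaxation time ~ tau: after one tau the gap shrinks to ~1/e
  gap0 <- fp - traj$rates[1, 1]
  gap_tau <- fp - traj$rates[1, which.min(abs(traj$times - 10))]
  expect_lt(abs(gap_tau / gap0 - exp(-1)), 0.05)
})

test_that("integrator agrees with a plain-R Euler oracle", {
  N <- 50
  pats <- generate_patterns(3, N, seed = 2)
  prof <- assign_symmetry(N, "homogeneous", z = 0.5)
  net <- build_connectivity(pats, prof, plasticity_rule("bilinear"),
                            A = 1, c_prob = 1, seed = 3)
  tf <- transfer_function()
  r0 <- initial_state(pats, tf)
  traj <- integrate_rates(net, r0, constant_protocol(-0.1, -0.1, 50), tf,
                          pats, tau = 10, dt = 1, T = 50)
  oracle <- euler_rates_oracle(as.matrix(net$J), r0, rep(-0.1, N),
                               0, 0.1, 1, 10, 1, 50)
  expect_equal(traj$rates, oracle, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("rates stay bounded and dt is validated", {
  fx <- standard_fixture(N = 400, c_prob = 0.5, P = 4, seed = 4, T = 100)
  traj <- integrate_rates(fx$net, fx$init, constant_protocol(0, 0, 100),
                          fx$tf, fx$patterns, tau = 10, dt = 0.5, T = 100)
  expect_true(all(traj$rates >= 0 & traj$rates <= fx$tf$r_max))
  expect_error(integrate_rates(fx$net, fx$init,
                               constant_protocol(0, 0, 100), fx$tf,
                               fx$patterns, tau = 10, dt = 2, T = 100),
               "dt must satisfy")
})

test_that("step-size refinement is converged", {
  # (a) pointwise on a configuration that settles to a fixed point; a
  # travelling retrieval pulse is compared through its measured speed in
  # (b), since tiny time shifts make pointwise comparison meaningless
  fx <- standard_fixture(N = 800, c_prob = 0.25, P = 8, seed = 5, T = 200)
  t1 <- integrate_rates(fx$net, fx$init, constant_protocol(-1.5, -1.5, 200),
                        fx$tf, fx$patterns, tau = 10, dt = 1, T = 200)
  t2 <- integrate_rates(fx$net, fx$init, constant_protocol(-1.5, -1.5, 200),
                        fx$tf, fx$patterns, tau = 10, dt = 0.5, T = 200)
  expect_lt(max(abs(t1$rates[, ncol(t1$rates)] - t2$rates[, ncol(t2$rates)])),
            0.01 * fx$tf$r_max)
  # (b) the measured retrieval speed is insensitive to halving dt
  fx2 <- cached_fixture("hom_z05_s1", function()
    standard_fixture(kind = "homogeneous", z = 0.5, seed = 1))
  v1 <- run_retrieval(fx2, -0.2, -0.2, dt = 1)$v
  v2 <- run_retrieval(fx2, -0.2, -0.2, dt = 0.5)$v
  expect_lt(abs(v1 - v2) / v2, 0.05)
})

test_that("noisy runs are seed-deterministic and distinct across seeds", {
  fx <- standard_fixture(N = 400, c_prob = 0.5, P = 4, seed = 6, T = 80)
  noise <- list(sd = 0.3, tau_corr = 4)
  t1 <- integrate_rates(fx$net, fx$init,
                        constant_protocol(0, 0, 80, noise = noise),
                        fx$tf, fx$patterns, tau = 10, dt = 0.5, T = 80,
                        seed = 99)
  t2 <- integrate_rates(fx$net, fx$init,
                        constant_protocol(0, 0, 80, noise = noise),
                        fx$tf, fx$patterns, tau = 10, dt = 0.5, T = 80,
                        seed = 99)
  t3 <- integrate_rates(fx$net, fx$init,
                        constant_protocol(0, 0, 80, noise = noise),
                        fx$tf, fx$patterns, tau = 10, dt = 0.5, T = 80,
                        seed = 100)
  expect_identical(t1$rates, t2$rates)
  expect_false(identical(t1$rates, t3$rates))
})

test_that("initial states follow the requested mode", {
  pats <- generate_patterns(3, 100, seed = 7)
  tf <- transfer_function(theta = 0, sigma = 0.1)
  rc <- initial_state(pats, tf, "rate-clamp")
  expect_equal(rc, transfer(pats$xi[1, ], tf))
  expect_true(all(rc[pats$xi[1, ] > 0.5] > 0.99))
  expect_equal(initial_state(pats, tf, "cue-pulse"), rep(0, 100))
  thr <- plasticity_rule("threshold", x_f = 1.5, x_g = 1.5,
                         q_f = 0.8, q_g = 0.8)
  mc <- initial_state(pats, tf, "member-clamp", rule = thr)
  expect_setequal(unique(mc), c(0, 1))
  expect_equal(which(mc == 1), which(pats$xi[1, ] >= 1.5))
  expect_error(initial_state(pats, tf, "member-clamp"), "threshold")
})
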