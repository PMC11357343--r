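# Pattern correlations, the speed estimator, quality and regime
# classification.

test_that("correlation of a linear transform of a pattern approaches 1", {
  N <- 1e4
  pats <- generate_patterns(3, N, seed = 1)
  rates <- cbind(0.7 * pats$xi[2, ] + 0.3)  # a * xi^2 + b, a > 0
  traj <- list(rates = rates, times = 0, tau = 10)
  ov <- pattern_correlations(traj, pats)
  expect_gt(ov$m[2, 1], 0.95)
  # uncorrelated patterns stay near zero
  expect_lt(abs(ov$m[1, 1]), 5 / sqrt(N))
  expect_lt(abs(ov$m[3, 1]), 5 / sqrt(N))
})

test_that("zero rate variance flags the correlation as undefined", {
  pats <- generate_patterns(2, 50, seed = 2)
  traj <- list(rates = matrix(0.4, 50, 3), times = c(0, 1, 2), tau = 10)
  ov <- pattern_correlations(traj, pats)
  expect_true(all(is.na(ov$m)))
  expect_equal(retrieval_quality(ov)$success, FALSE)
})

test_that("population-scoped correlations agree with manual subsetting", {
  fx <- standard_fixture(N = 200, c_prob = 0.5, P = 3, seed = 3, T = 30)
  traj <- integrate_rates(fx$net, fx$init, constant_protocol(0, 0, 30),
                          fx$tf, fx$patterns, tau = 10, dt = 0.5, T = 30)
  ov_all <- pattern_correlations(traj, fx$patterns, "all")
  ov_sym <- pattern_correlations(traj, fx$patterns, "symmetric")
  idx <- which(traj$labels == "symmetric")
  sub <- list(rates = traj$rates[idx, ], times = traj$times, tau = 10)
  subpat <- list(xi = fx$patterns$xi[, idx], P = 3, N = length(idx))
  ov_manual <- pattern_correlations(sub, subpat, "all")
  expect_equal(ov_sym$m, ov_manual$m)
  expect_false(isTRUE(all.equal(ov_sym$m, ov_all$m)))
})

test_that("speed estimator is exact on synthetic peak trains", {
  tm <- seq(0, 500, by = 0.5)
  # peaks spaced exactly tau apart -> v = 1
  m1 <- synthetic_overlaps(20 + 10 * (0:15), tm)
  expect_equal(retrieval_speed(overlap_trajectory(m1, tm, tau = 10))$v, 1.0)
  # peaks spaced 2 tau apart -> v = 0.5
  m2 <- synthetic_overlaps(20 * (1:16), tm)
  sp2 <- retrieval_speed(overlap_trajectory(m2, tm, tau = 10))
  expect_identical(sp2$v, 0.5)
  expect_equal(sp2$n_excluded, 0L)
  expect_equal(sp2$ordered_frac, 1)
})

test_that("outlier peak-time differences are excluded by the 2-sd rule", {
  tm <- seq(0, 1200, by = 0.5)
  # 15 differences of 2 tau plus one of 50 tau
  peaks <- c(20 * (1:16), 20 * 16 + 500)
  m <- synthetic_overlaps(peaks, tm)
  sp <- retrieval_speed(overlap_trajectory(m, tm, tau = 10))
  # hand application of the rule: d = (20 x 15, 500); mean 50, sd 120.2;
  # threshold 290.4 excludes only the 500
  expect_equal(sp$n_excluded, 1L)
  expect_equal(sp$v, 0.5)
})

test_that("degenerate overlap traces are reported as not retrieved", {
  tm <- seq(0, 100, by = 0.5)
  ov <- overlap_trajectory(matrix(NA_real_, 4, length(tm)), tm, tau = 10)
  sp <- retrieval_speed(ov)
  expect_true(is.na(sp$v))
  expect_false(sp$retrieved)
  expect_error(retrieval_speed(
    overlap_trajectory(matrix(0, 1, length(tm)), tm, 10)), "two patterns")
})

test_that("retrieval quality thresholds the final-pattern peak", {
  tm <- seq(0, 100, by = 1)
  good <- overlap_trajectory(synthetic_overlaps(c(20, 60), tm), tm, 10)
  expect_true(retrieval_quality(good)$success)
  expect_gt(retrieval_quality(good)$quality, 0.9)
  flat <- overlap_trajectory(matrix(0.01, 2, length(tm)), tm, 10)
  expect_false(retrieval_quality(flat)$success)
  expect_equal(retrieval_quality(flat)$quality, 0.01)
})

test_that("regime classification distinguishes the hand-built cases", {
  tm <- seq(0, 600, by = 1)
  P <- 5
  # retrieved: five clean ordered peaks, then decay
  m_ret <- synthetic_overlaps(c(50, 100, 150, 200, 250), tm, width = 15)
  expect_equal(classify_dynamics(overlap_trajectory(m_ret, tm, 10)),
               "retrieved")
  # persistent: pattern 1 plateaus from the start, others silent
  m_per <- matrix(0, P, length(tm))
  m_per[1, ] <- 0.6
  m_per[1, tm < 50] <- 0.6 * tm[tm < 50] / 50
  expect_equal(classify_dynamics(overlap_trajectory(m_per, tm, 10)),
               "persistent")
  # partial then persistent: patterns 1-3 peak, pattern 3 then plateaus
  m_pp <- matrix(0, P, length(tm))
  m_pp[1, ] <- exp(-(tm - 50)^2 / 450)
  m_pp[2, ] <- exp(-(tm - 120)^2 / 450)
  m_pp[3, ] <- 0.5 / (1 + exp(-(tm - 180) / 15))
  expect_equal(classify_dynamics(overlap_trajectory(m_pp, tm, 10)),
               "partial_then_persistent")
  # nothing above threshold
  m_no <- matrix(0.01, P, length(tm))
  expect_equal(classify_dynamics(overlap_trajectory(m_no, tm, 10)),
               "not_retrieved")
})

test_that("a single-cell sweep equals a direct simulation", {
  fx <- standard_fixture(N = 400, c_prob = 0.5, P = 4, seed = 5, T = 120)
  pd <- sweep_phase_diagram(fx$net, fx$patterns, I_a_grid = -0.2,
                            I_s_grid = -0.2, fx$tf, tau = 10, dt = 0.5,
                            T = 120)
  expect_equal(nrow(pd), 1L)
  direct <- run_retrieval(fx, -0.2, -0.2, T = 120)
  expect_equal(pd$speed, direct$v)
  expect_equal(pd$status, direct$status)
  expect_error(sweep_phase_diagram(fx$net, fx$patterns, c(0, -1), -0.2,
                                   fx$tf, T = 120),
               "strictly increasing")
})
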