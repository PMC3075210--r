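test_that("switch-path sampler enforces the refractory floor exactly", {
  p <- switch_params(mean_on = 4, refractory = 3, mean_excess_off = 3.5)
  for (seed in 1:20) {
    path <- sample_switch_path(p, 60, seed = seed)
    iv <- txcycle:::path_intervals(path)
    off <- iv[!iv$censored & iv$state == "off", ]
    if (nrow(off)) expect_true(all(off$end - off$start >= 3))
  }
})

test_that("off-duration moments match the refractory-plus-exponential law", {
  p <- switch_params(mean_on = 4, refractory = 3, mean_excess_off = 3.5)
  off <- sample_durations(p, 10000, state = "off", seed = 1)
  # mean 6.5 h, SD 3.5 h
  expect_equal(mean(off), 6.5, tolerance = 0.02)
  expect_equal(sd(off), 3.5, tolerance = 0.05)
  on <- sample_durations(p, 10000, state = "on", seed = 2)
  expect_equal(mean(on), 4.0, tolerance = 0.03)
})

test_that("zero-refractory off-times are exponential (KS vs known CDF)", {
  p <- switch_params(mean_on = 4, refractory = 0, mean_excess_off = 3.5)
  off <- sample_durations(p, 10000, state = "off", seed = 3)
  ks <- suppressWarnings(stats::ks.test(off, "pexp", rate = 1 / 3.5))
  expect_gt(ks$p.value, 0.05)
})

test_that("path sampler is deterministic under a fixed seed", {
  p <- calibrated_switch_params()
  a <- sample_switch_path(p, 30, seed = 42)
  b <- sample_switch_path(p, 30, seed = 42)
  expect_identical(a, b)
  pop1 <- simulate_population(3, "paper-calibrated", seed = 7)
  pop2 <- simulate_population(3, "paper-calibrated", seed = 7)
  expect_identical(pop1, pop2)
})

test_that("invalid switch parameters are rejected", {
  expect_error(switch_params(-1, 3, 3.5), "mean_on")
  expect_error(switch_params(4, -1, 3.5), "refractory")
  expect_error(switch_params(4, 3, 3.5, rate_on = 1, rate_off = 2),
               "rate_on")
  expect_error(sample_switch_path(calibrated_switch_params(), -5), "duration")
})

test_that("noiseless decaying reporter follows the homogeneous closed form", {
  kin <- kinetic_params(alpha = 1, delta_m = 0.8, delta_p = 0.3)
  path <- switch_path(numeric(0), "off", rate_on = 10, rate_off = 0,
                      duration = 20)
  grid <- seq(0, 20, by = 0.5)
  tr <- simulate_reporter(path, kin, sampling_grid = grid, m0 = 5, p0 = 7)
  m_t <- 5 * exp(-0.8 * grid)
  p_t <- (7 - 5 / (0.3 - 0.8)) * exp(-0.3 * grid) +
    5 / (0.3 - 0.8) * exp(-0.8 * grid)
  expect_equal(tr$values, p_t, tolerance = 1e-10)
})

test_that("constant transcription converges to the analytic steady state", {
  kin <- kinetic_params(alpha = 2, delta_m = 0.6, delta_p = 0.4)
  path <- switch_path(numeric(0), "on", rate_on = 5, rate_off = 0,
                      duration = 100)
  tr <- simulate_reporter(path, kin, sampling_grid = seq(0, 100, by = 10),
                          m0 = 0, p0 = 0)
  expect_equal(tr$values[11], 2 * 5 / (0.6 * 0.4), tolerance = 1e-6)
})

test_that("closed-form propagation matches the RK4 oracle on random paths", {
  set.seed(99)
  for (rep in 1:20) {
    kin <- kinetic_params(alpha = runif(1, 0.5, 2),
                          delta_m = runif(1, 0.3, 1.5),
                          delta_p = runif(1, 0.1, 0.8))
    params <- switch_params(mean_on = runif(1, 2, 6), refractory = 3,
                            mean_excess_off = runif(1, 2, 5),
                            rate_on = runif(1, 5, 20))
    path <- sample_switch_path(params, 20, seed = rep)
    grid <- seq(0.5, 19.5, by = 1)
    m0 <- runif(1, 0, 10); p0 <- runif(1, 0, 50)
    got <- noiseless_reporter(path, kin, grid, m0 = m0, p0 = p0)$values
    want <- rk4_reporter(path, kin, grid, m0, p0)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("single on-pulse protein matches fine-step integration", {
  kin <- default_kinetics("luc")
  path <- switch_path(c(8, 12), "off", rate_on = 10, rate_off = 0,
                      duration = 30)
  grid <- seq(0, 30, by = 1)
  got <- noiseless_reporter(path, kin, grid, m0 = 0, p0 = 0)$values
  want <- rk4_reporter(path, kin, grid, 0, 0)
  expect_equal(got[-1], want[-1], tolerance = 1e-6)
})

test_that("equal degradation rates use the degenerate t*exp closed form", {
  kin <- kinetic_params(alpha = 1, delta_m = 0.5, delta_p = 0.5)
  path <- switch_path(c(5, 9), "off", rate_on = 8, rate_off = 0,
                      duration = 25)
  grid <- seq(1, 24, by = 1)
  got <- noiseless_reporter(path, kin, grid, m0 = 2, p0 = 3)$values
  want <- rk4_reporter(path, kin, grid, 2, 3)
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("shared-path noiseless dual cell gives identical traces", {
  kin <- default_kinetics("luc")
  out <- simulate_dual_cell(calibrated_switch_params(), kin_luc = kin,
                            kin_gfp = kin, coupling = "shared",
                            duration = 30, dt = 1, stagger = 0,
                            seed = 5)
  expect_identical(out$luc$values, out$gfp$values)
  expect_identical(out$path_luc, out$path_gfp)
})

test_that("independent dual paths are uncorrelated at the population level", {
  grid <- seq(0, 30, by = 0.5)
  rhos <- vapply(1:50, function(i) {
    out <- simulate_dual_cell(calibrated_switch_params(),
                              coupling = "independent", duration = 30,
                              seed = 1000 + i)
    suppressWarnings(cor(path_rate(out$path_luc, grid),
                         path_rate(out$path_gfp, grid),
                         method = "spearman"))
  }, numeric(1))
  expect_lt(abs(median(rhos, na.rm = TRUE)), 0.15)
})

test_that("decay experiments follow their closed forms", {
  kin <- kinetic_params(alpha = 1, delta_m = 0.9, delta_p = 0.35)
  grid <- seq(0, 10, by = 0.5)
  chx <- simulate_decay_experiment("translation-block", kin, m0 = 3,
                                   p0 = 50, grid = grid)
  expect_equal(log(chx$values), log(50) - 0.35 * grid, tolerance = 1e-10)
  actd <- simulate_decay_experiment("transcription-block", kin, m0 = 10,
                                    p0 = 40, grid = grid)
  path <- switch_path(numeric(0), "off", rate_on = 1, rate_off = 0,
                      duration = 11)
  want <- rk4_reporter(path, kin, grid, 10, 40)
  expect_equal(actd$values[-1], want[-1], tolerance = 1e-6)
  # protein rises to a single maximum then decays monotonically
  dp <- diff(actd$values)
  peak <- which.max(actd$values)
  expect_true(all(dp[seq_len(peak - 1)] > 0))
  expect_true(all(dp[peak:length(dp)] < 0))
})

test_that("unknown scenario names are rejected", {
  expect_error(simulate_population(3, "no-such-scenario"), "unknown scenario")
})
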