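kin <- default_kinetics("luc")

test_that("near-interpolating spline reproduces a cubic polynomial", {
  t <- seq(0, 20, length.out = 30)
  y <- 2 + 0.5 * t - 0.08 * t^2 + 0.002 * t^3
  tr <- cell_trace("c", "luc", t, y)
  # spar = -1 drives the penalty to (near) zero: interpolation regime
  sp <- fit_protein_spline(tr, smoothing = -1)
  expect_equal(sp$fitted(t), y, tolerance = 1e-8)
})

test_that("GCV spline recovers a noisy sine below the noise level", {
  set.seed(1)
  t <- seq(0, 29, by = 1)
  truth <- 50 + 20 * sin(2 * pi * t / 12)
  y <- truth + rnorm(length(t), 0, 0.05 * 50)
  sp <- fit_protein_spline(cell_trace("c", "luc", t, y))
  rmse <- sqrt(mean((sp$fitted(t) - truth)^2))
  expect_lt(rmse, 0.05 * 50)
})

test_that("a constant trace has zero derivative everywhere", {
  t <- seq(0, 20, by = 1)
  sp <- fit_protein_spline(cell_trace("c", "luc", t, rep(40, length(t))))
  expect_equal(sp$derivative(seq(1, 19, 0.25)), rep(0, 73),
               tolerance = 1e-8)
  mr <- reconstruct_mrna(sp, delta_p = 0.35)
  expect_equal(mr$alpha_m, rep(0.35 * 40, length(mr$grid)),
               tolerance = 1e-6)
})

test_that("spline input validation catches short and duplicated traces", {
  expect_error(cell_trace("c", "luc", 1:5, 1:5), "at least 8")
  tr <- cell_trace("c", "luc", 1:10, rnorm(10))
  tr$times[2] <- tr$times[1]  # corrupt after construction
  expect_error(fit_protein_spline(tr), "increasing|duplicate")
  sp <- fit_protein_spline(cell_trace("c", "luc", 1:10, rnorm(10)))
  expect_error(sp$fitted(11), "support")
})

test_that("delta_p = 0 reduces the mRNA step to the pure derivative", {
  t <- seq(0, 20, by = 0.5)
  y <- 10 + 3 * t
  sp <- fit_protein_spline(cell_trace("c", "luc", t, y), smoothing = 1e-8)
  mr <- reconstruct_mrna(sp, delta_p = 0)
  expect_equal(mr$alpha_m, rep(3, length(mr$grid)), tolerance = 1e-4)
})

test_that("Euler inversion is exact for constant mRNA and delta_m limits", {
  grid <- seq(0, 10, by = 0.1)
  mr <- list(grid = grid, alpha_m = rep(7, length(grid)))
  pr <- reconstruct_transcription(mr, delta_m = 0.65)
  expect_equal(pr$tau, rep(0.65 * 7, length(pr$tau)))
  # delta_m = 0: tau equals the discrete derivative
  mr2 <- list(grid = grid, alpha_m = 2 * grid)
  pr2 <- reconstruct_transcription(mr2, delta_m = 0)
  expect_equal(pr2$tau, rep(2, length(pr2$tau)), tolerance = 1e-9)
  expect_error(reconstruct_transcription(
    list(grid = c(0, 1, 3), alpha_m = 1:3), 0.5), "uniform")
})

test_that("output grid step equals the configured fine step", {
  path <- sample_switch_path(calibrated_switch_params(), 30, seed = 2)
  tr <- simulate_reporter(path, kin, sampling_grid = seq(0, 30, 1))
  prof <- reconstruct_cell(tr, kin)
  expect_equal(prof$grid_step, 0.1)
  expect_equal(unique(round(diff(prof$grid), 10)), 0.1)
})

test_that("noiseless round trip recovers the transcription pulse", {
  path <- switch_path(c(8, 16), "off", rate_on = 10, rate_off = 0,
                      duration = 30)
  tr <- simulate_reporter(path, kin, sampling_grid = seq(0, 30, 0.5),
                          m0 = 0, p0 = 0)
  prof <- reconstruct_cell(tr, kin, smoothing = 1e-4)
  interior <- prof$grid > 9.5 & prof$grid < 15
  expect_equal(median(prof$tau[interior]), 10, tolerance = 0.1)
  outside <- (prof$grid > 2 & prof$grid < 7) |
    (prof$grid > 20 & prof$grid < 28)
  expect_lt(max(abs(prof$tau[outside])), 2)
  # relative L2 error away from boundaries
  sel <- !prof$low_confidence
  truth <- path_rate(path, prof$grid[sel])
  l2 <- sqrt(sum((prof$tau[sel] - truth)^2) / sum(truth^2))
  expect_lt(l2, 0.35)
})

test_that("reconstruction is a linear operator", {
  t <- seq(0, 30, by = 0.5)
  set.seed(4)
  y1 <- 50 + 10 * sin(2 * pi * t / 11) + rnorm(length(t))
  y2 <- 40 + 8 * cos(2 * pi * t / 9) + rnorm(length(t))
  a <- 2; b <- -0.5
  # fix the smoothing so all three fits use the same linear smoother
  rec <- function(y) {
    sp <- fit_protein_spline(cell_trace("c", "luc", t, y), smoothing = 0.5)
    mr <- reconstruct_mrna(sp, 0.35)
    reconstruct_transcription(mr, 0.65)$tau
  }
  expect_equal(rec(a * y1 + b * y2), a * rec(y1) + b * rec(y2),
               tolerance = 1e-6)
})

test_that("dual shared-path reporters reconstruct to matching profiles", {
  out <- simulate_dual_cell(calibrated_switch_params(),
                            coupling = "shared", duration = 30, dt = 0.5,
                            stagger = 0, seed = 9)
  p_luc <- reconstruct_cell(out$luc, default_kinetics("luc"))
  p_gfp <- reconstruct_cell(out$gfp, default_kinetics("gfp"))
  common <- seq(2, 27, by = 0.25)
  rho <- cor(profile_at(p_luc, common), profile_at(p_gfp, common),
             method = "spearman")
  expect_gt(rho, 0.95)
})

test_that("steady-state protein reconstructs to the analytic constant", {
  # pure-noise trace around a constant: tau should fluctuate around
  # delta_m * delta_p * P / alpha
  set.seed(11)
  t <- seq(0, 30, by = 0.5)
  pbar <- 60
  y <- pbar + rnorm(length(t), 0, 1)
  prof <- reconstruct_cell(cell_trace("c", "luc", t, y), kin)
  expect_equal(median(prof$tau), kin$delta_m * kin$delta_p * pbar,
               tolerance = 0.1)
})
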