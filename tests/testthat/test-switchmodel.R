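kin <- default_kinetics("luc")
quick_cfg <- function(seed, iterations = 6000, burn_in = 2000)
  switch_model_config(iterations = iterations, burn_in = burn_in,
                      thin = 5, seed = seed)

test_that("a clean single on-pulse is recovered with tight posteriors", {
  path <- switch_path(c(10, 14), "off", rate_on = 10, rate_off = 0,
                      duration = 30)
  tr <- simulate_reporter(path, kin, noise_params(0.4, 0.05),
                          seq(0, 30, 1), seed = 5, m0 = 0, p0 = 0)
  post <- suppressWarnings(run_switch_mcmc(tr, kin, quick_cfg(6)))
  d <- extract_durations(post)
  expect_equal(length(d$switch_times), 2)
  expect_equal(d$initial_state, "off")
  expect_equal(d$switch_times, c(10, 14), tolerance = 0.05)
  mc <- txcycle:::modal_config(post)
  mat <- do.call(rbind, post$switch_times[mc$idx])
  expect_true(all(apply(mat, 2, sd) < 0.25))
})

test_that("a steady-state trace concentrates on zero switches", {
  path <- switch_path(numeric(0), "on", rate_on = 10, rate_off = 0,
                      duration = 30)
  tr <- simulate_reporter(path, kin, noise_params(0.4, 0.02),
                          seq(0, 30, 1), seed = 7)
  post <- suppressWarnings(run_switch_mcmc(tr, kin, quick_cfg(8,
                                                              4000, 1000)))
  expect_equal(as.integer(names(which.max(table(post$samples$k)))), 0)
})

test_that("every retained sample keeps ordered times and b_on > b_off", {
  path <- sample_switch_path(calibrated_switch_params(), 30, seed = 1)
  tr <- simulate_reporter(path, kin, noise_params(0.4, 0.05),
                          seq(0, 30, 1), seed = 2)
  post <- suppressWarnings(run_switch_mcmc(tr, kin, quick_cfg(3, 4000,
                                                              1000)))
  expect_true(all(post$samples$b_on > post$samples$b_off))
  ok <- vapply(post$switch_times, function(s)
    !length(s) || all(diff(s) > 0), logical(1))
  expect_true(all(ok))
  expect_true(all(vapply(post$switch_times, length, 0L) ==
                    post$samples$k))
})

test_that("identical seeds give identical chains", {
  path <- sample_switch_path(calibrated_switch_params(), 30, seed = 4)
  tr <- simulate_reporter(path, kin, noise_params(0.4, 0.05),
                          seq(0, 30, 1), seed = 5)
  p1 <- suppressWarnings(run_switch_mcmc(tr, kin, quick_cfg(9, 2000, 500)))
  p2 <- suppressWarnings(run_switch_mcmc(tr, kin, quick_cfg(9, 2000, 500)))
  expect_identical(p1$samples, p2$samples)
  expect_identical(p1$switch_times, p2$switch_times)
})

test_that("posterior intervals cover true switch times on calibrated cells", {
  covered <- 0; total <- 0
  for (i in 1:6) {
    path <- sample_switch_path(calibrated_switch_params(), 30,
                               seed = 40 + i)
    if (length(path$switch_times) < 1) next
    tr <- simulate_reporter(path, kin, noise_params(0.4, 0.05),
                            seq(0, 30, 1), seed = 60 + i)
    post <- suppressWarnings(run_switch_mcmc(tr, kin, quick_cfg(80 + i)))
    pooled <- sort(unlist(post$switch_times))
    if (!length(pooled)) next
    for (st in path$switch_times) {
      total <- total + 1
      # covered if any posterior switch-time mass falls within 1 h
      if (min(abs(pooled - st)) < 1) covered <- covered + 1
    }
  }
  expect_gt(covered / total, 0.8)
})

test_that("duration extraction does interval arithmetic correctly", {
  # construct a posterior by hand: switches {2,6,13,17}, starting off
  samples <- data.frame(k = rep(4L, 20), z0 = 0L, b_off = 0, b_on = 10,
                        sigma = 1, m0 = 0, p0 = 0)
  post <- structure(list(samples = samples,
                         switch_times = replicate(20, c(2, 6, 13, 17),
                                                  simplify = FALSE),
                         t_end = 21, kin = kin, cell_id = "c",
                         cfg = switch_model_config(100, 10, 1),
                         warning_flags = character(0)),
                    class = "switch_posterior")
  d <- extract_durations(post)
  expect_equal(d$on_durations, c(4, 4))      # 2-6 and 13-17 on
  expect_equal(d$off_durations, 7)           # 6-13 off
  expect_equal(d$periods, 11)                # onsets at 2 and 13
  # shortening the record to 18 h censors the 13-17 interval via the
  # boundary guard (switch at 17 within 1 h of the record end)
  post$t_end <- 18
  d2 <- extract_durations(post)
  expect_equal(d2$on_durations, 4)
})

test_that("empty and sub-two-switch posteriors give empty duration sets", {
  samples <- data.frame(k = 1L, z0 = 1L, b_off = 0, b_on = 5, sigma = 1,
                        m0 = 0, p0 = 0)
  post <- structure(list(samples = samples, switch_times = list(10),
                         t_end = 21, kin = kin, cell_id = "c",
                         cfg = switch_model_config(100, 10, 1),
                         warning_flags = character(0)),
                    class = "switch_posterior")
  d <- extract_durations(post)
  expect_length(d$on_durations, 0)
  expect_length(d$off_durations, 0)
  expect_length(d$periods, 0)
})

test_that("weak-switch removal deletes an injected blip and nothing else", {
  base <- c(5, 9, 15, 20)
  blip <- sort(c(base, 11, 11.08))
  samples <- data.frame(k = rep(6L, 40), z0 = 1L, b_off = 0, b_on = 10,
                        sigma = 1, m0 = 0, p0 = 0)
  post <- structure(list(samples = samples,
                         switch_times = replicate(40, blip,
                                                  simplify = FALSE),
                         t_end = 30, kin = kin, cell_id = "c",
                         cfg = switch_model_config(100, 10, 1),
                         warning_flags = character(0)),
                    class = "switch_posterior")
  # excursion of a 0.08 h blip at delta_m = 0.65: ~5% of the level
  # difference, well under the 20% threshold
  clean <- remove_weak_switches(post, threshold = 0.2, min_inclusion = 0)
  expect_true(all(clean$samples$k == 4))
  expect_equal(clean$switch_times[[1]], base)
  # threshold 0 with inclusion disabled is the identity
  ident <- remove_weak_switches(post, threshold = 0, min_inclusion = 0)
  expect_identical(ident$switch_times, post$switch_times)
})

test_that("inclusion rule strips excursions unsupported by the posterior", {
  base <- c(5, 9, 15, 20)
  samples <- data.frame(k = c(rep(4L, 30), rep(6L, 10)), z0 = 1L,
                        b_off = 0, b_on = 10, sigma = 1, m0 = 0, p0 = 0)
  stimes <- c(replicate(30, base, simplify = FALSE),
              replicate(10, sort(c(base, 11, 12.5)), simplify = FALSE))
  post <- structure(list(samples = samples, switch_times = stimes,
                         t_end = 30, kin = kin, cell_id = "c",
                         cfg = switch_model_config(100, 10, 1),
                         warning_flags = character(0)),
                    class = "switch_posterior")
  clean <- remove_weak_switches(post, threshold = 0, min_inclusion = 0.5)
  expect_true(all(clean$samples$k == 4))
})

test_that("duration association detects coupling and its absence", {
  mk_ds <- function(st, id) {
    structure(list(on_durations = NULL, off_durations = NULL,
                   periods = NULL, switch_times = st,
                   initial_state = "off", cell_id = id),
              class = "duration_set")
  }
  # perfectly coupled: off = 2 * preceding on (all values untied)
  sets <- lapply(1:6, function(i) {
    ons <- 1 + (1:3) * 0.37 + i * 0.013
    st <- numeric(0); t <- 1
    for (o in ons) { st <- c(st, t, t + o); t <- t + o + 2 * o }
    mk_ds(st, paste0("c", i))
  })
  res <- duration_association(sets, "on-then-off", n_perm = 200, seed = 1)
  expect_equal(res$rho, 1)
  # anti-coupled
  sets2 <- lapply(1:6, function(i) {
    ons <- 1 + (1:3) * 0.37 + i * 0.013
    st <- numeric(0); t <- 1
    for (o in ons) { st <- c(st, t, t + o); t <- t + o + (6 - o) }
    mk_ds(st, paste0("c", i))
  })
  res2 <- duration_association(sets2, "on-then-off", n_perm = 200,
                               seed = 2)
  expect_equal(res2$rho, -1)
  # independent generator durations
  set.seed(3)
  sets3 <- lapply(1:12, function(i) {
    st <- numeric(0); t <- 0.5
    for (j in 1:3) {
      on <- rexp(1, 1 / 4); off <- 3 + rexp(1, 1 / 3.5)
      st <- c(st, t, t + on); t <- t + on + off
    }
    mk_ds(st, paste0("c", i))
  })
  res3 <- duration_association(sets3, "on-then-off", n_perm = 400,
                               seed = 4)
  expect_lt(abs(res3$rho), 0.4)
  expect_gt(res3$p_value, 0.01)
})
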