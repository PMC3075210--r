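#' Sample a binary switch path with refractory off-times
#'
#' Draws alternating on/off intervals: on-durations are exponential with mean
#' `mean_on`; off-durations are the refractory floor plus an exponential
#' excess with mean `mean_excess_off`. The initial state is drawn from the
#' stationary occupancy of the renewal process, i.e. on with probability
#' `mean_on / (mean_on + refractory + mean_excess_off)`.
#'
#' @param params A [switch_params()] object.
#' @param duration Record length in hours (> 0).
#' @param seed Optional integer seed; fixed seed gives identical paths.
#' @param initial_state `"stationary"` (default) draws the starting state
#'   from the stationary occupancy; `"on"` or `"off"` force it, emulating a
#'   stimulus that synchronises activation at t = 0.
#' @return A [switch_path()].
#' @examples
#' p <- sample_switch_path(calibrated_switch_params(), 30, seed = 1)
#' @export
sample_switch_path <- function(params, duration, seed = NULL,
                               initial_state = c("stationary", "on",
                                                 "off")) {
  stopifnot(inherits(params, "switch_params"))
  initial_state <- match.arg(initial_state)
  if (!is.numeric(duration) || duration <= 0)
    stop("`duration` must be > 0", call. = FALSE)
  with_local_seed(seed, function() {
    p_on <- params$mean_on /
      (params$mean_on + params$refractory + params$mean_excess_off)
    state <- if (initial_state == "stationary") {
      if (runif(1) < p_on) "on" else "off"
    } else initial_state
    t_cur <- 0
    times <- numeric(0)
    s <- state
    repeat {
      dur <- if (s == "on") rexp(1, 1 / params$mean_on)
             else params$refractory + rexp(1, 1 / params$mean_excess_off)
      t_cur <- t_cur + dur
      if (t_cur >= duration) break
      times <- c(times, t_cur)
      s <- if (s == "on") "off" else "on"
    }
    switch_path(times, state, rate_on = params$rate_on,
                rate_off = params$rate_off, duration = duration)
  })
}

#' Draw raw on- or off-durations from switch parameters
#'
#' Convenience sampler for duration-level analyses (exponential fits, memory
#' function, cyclicity simulation) that bypasses path construction.
#'
#' @param params A [switch_params()].
#' @param n Number of durations.
#' @param state `"on"` or `"off"`.
#' @param seed Optional seed.
#' @return Numeric vector of durations (hours).
#' @export
sample_durations <- function(params, n, state = c("off", "on"), seed = NULL) {
  state <- match.arg(state)
  stopifnot(inherits(params, "switch_params"))
  with_local_seed(seed, function() {
    if (state == "on") rexp(n, 1 / params$mean_on)
    else params$refractory + rexp(n, 1 / params$mean_excess_off)
  })
}

#' The calibrated operating point of the switch process
#'
#' Default parameter set used as ground truth in recovery experiments:
#' mean on-duration 4.0 h, refractory floor 3.0 h, mean excess off 3.5 h
#' (so the mean off-duration is 6.5 h and the mean on-to-on cycle 10.5 h),
#' with zero basal transcription in the off state.
#'
#' @param rate_on On-state transcription level (default 10 units/h).
#' @return A [switch_params()] object.
#' @export
calibrated_switch_params <- function(rate_on = 10) {
  switch_params(mean_on = 4.0, refractory = 3.0, mean_excess_off = 3.5,
                rate_on = rate_on, rate_off = 0)
}

#' Default reporter kinetics
#'
#' Plausible kinetic constants for a destabilised luciferase and a d2EGFP
#' reporter: sub-hour to few-hour mRNA and protein half-lives, and a 0.5 h
#' maturation lag for the fluorescent reporter relative to luciferase.
#'
#' @param reporter `"luc"` or `"gfp"`.
#' @return A [kinetic_params()] object.
#' @export
default_kinetics <- function(reporter = c("luc", "gfp")) {
  reporter <- match.arg(reporter)
  if (reporter == "luc")
    kinetic_params(alpha = 1, delta_m = 0.65, delta_p = 0.35,
                   maturation_delay = 0)
  else
    kinetic_params(alpha = 1, delta_m = 0.90, delta_p = 0.30,
                   maturation_delay = 0.5)
}

# deterministic protein path at `times` for a switch path + kinetics;
# initial condition defaults to the steady state of the time-averaged rate.
protein_path <- function(path, kin, times, m0 = NULL, p0 = NULL) {
  tau_bar <- mean_path_rate(path)
  if (is.null(m0)) m0 <- tau_bar / kin$delta_m
  if (is.null(p0)) p0 <- kin$alpha * tau_bar / (kin$delta_m * kin$delta_p)
  protein_path_cpp(path$switch_times, as.integer(path$initial_state == "on"),
                   path$rate_off, path$rate_on, kin$alpha, kin$delta_m,
                   kin$delta_p, m0, p0, times, path$duration)
}

mean_path_rate <- function(path) {
  iv <- path_intervals(path)
  w <- iv$end - iv$start
  sum(w * ifelse(iv$state == "on", path$rate_on, path$rate_off)) / sum(w)
}

#' Simulate an observed reporter trace from a switch path
#'
#' Integrates the linear mRNA/protein system exactly (piecewise closed form
#' on each constant-rate segment), applies the maturation delay as a constant
#' shift of the observation time axis, samples protein at the grid times, and
#' adds heteroscedastic measurement noise
#' `observed = P * (1 + eps_m) + eps_a`.
#'
#' @param path A [switch_path()].
#' @param kin A [kinetic_params()].
#' @param noise A [noise_params()]; default is noiseless.
#' @param sampling_grid Observation times (hours), within the path duration.
#' @param seed Optional seed (noise only).
#' @param cell_id,reporter,treatment Labels for the returned trace.
#' @param m0,p0 Optional initial mRNA/protein values; default is the steady
#'   state of the time-averaged transcription rate.
#' @return A [cell_trace()].
#' @export
simulate_reporter <- function(path, kin, noise = noise_params(),
                              sampling_grid, seed = NULL,
                              cell_id = "cell1", reporter = "luc",
                              treatment = "unstimulated",
                              m0 = NULL, p0 = NULL) {
  stopifnot(inherits(path, "switch_path"), inherits(kin, "kinetic_params"))
  sampling_grid <- as.numeric(sampling_grid)
  if (min(sampling_grid) < 0 || max(sampling_grid) > path$duration)
    stop("`sampling_grid` must lie within [0, duration]", call. = FALSE)
  eval_times <- pmax(sampling_grid - kin$maturation_delay, 0)
  p <- protein_path(path, kin, eval_times, m0 = m0, p0 = p0)
  obs <- with_local_seed(seed, function() {
    n <- length(p)
    p * (1 + rnorm(n, 0, noise$cv_multiplicative)) +
      rnorm(n, 0, noise$sd_additive)
  })
  cell_trace(cell_id, reporter, sampling_grid, obs, treatment)
}

#' Simulate a dual-reporter cell
#'
#' Two reporters driven either by independent switch paths (unstimulated
#' scenario) or by a single shared path (stimulated-synchronisation
#' scenario). The second reporter's sampling grid is offset by `stagger`
#' hours, reflecting alternating acquisition of the two channels.
#'
#' @param params A [switch_params()] or a list of two (first reporter,
#'   second reporter) for independent coupling.
#' @param kin_luc,kin_gfp [kinetic_params()] for the two reporters.
#' @param coupling `"independent"` or `"shared"`.
#' @param duration Record length (hours).
#' @param dt Sampling interval (hours).
#' @param stagger Grid offset of the second reporter (hours, < `dt`).
#' @param noise A [noise_params()].
#' @param seed Optional seed.
#' @param cell_id Cell label.
#' @param initial_state Passed to [sample_switch_path()]; `"on"` emulates
#'   stimulated activation at t = 0.
#' @return List with `luc`, `gfp` ([cell_trace()]s) and the ground-truth
#'   paths `path_luc`, `path_gfp`.
#' @export
simulate_dual_cell <- function(params, kin_luc = default_kinetics("luc"),
                               kin_gfp = default_kinetics("gfp"),
                               coupling = c("independent", "shared"),
                               duration = 30, dt = 1, stagger = 0.5,
                               noise = noise_params(), seed = NULL,
                               cell_id = "cell1",
                               initial_state = "stationary") {
  coupling <- match.arg(coupling)
  if (stagger >= dt)
    stop("`stagger` must be smaller than the sampling interval", call. = FALSE)
  if (inherits(params, "switch_params")) params <- list(params, params)
  with_local_seed(seed, function() {
    path1 <- sample_switch_path(params[[1]], duration,
                                initial_state = initial_state)
    path2 <- if (coupling == "shared") path1
             else sample_switch_path(params[[2]], duration,
                                     initial_state = initial_state)
    grid1 <- seq(0, duration, by = dt)
    grid2 <- grid1[-length(grid1)] + stagger
    if (stagger == 0) grid2 <- grid1
    # stimulated cells were quiescent before t = 0: start at the off-state
    # steady level instead of the stationary mean
    init <- function(kin) {
      if (initial_state == "on")
        list(m0 = params[[1]]$rate_off / kin$delta_m,
             p0 = kin$alpha * params[[1]]$rate_off /
               (kin$delta_m * kin$delta_p))
      else list(m0 = NULL, p0 = NULL)
    }
    i1 <- init(kin_luc); i2 <- init(kin_gfp)
    luc <- simulate_reporter(path1, kin_luc, noise, grid1,
                             cell_id = cell_id, reporter = "luc",
                             m0 = i1$m0, p0 = i1$p0)
    gfp <- simulate_reporter(path2, kin_gfp, noise, grid2,
                             cell_id = cell_id, reporter = "gfp",
                             m0 = i2$m0, p0 = i2$p0)
    list(luc = luc, gfp = gfp, path_luc = path1, path_gfp = path2)
  })
}

#' Registered simulation scenarios
#'
#' Scenario presets are stored as YAML in the package (`inst/extdata/`
#' `scenarios.yaml`) and define the switch parameters, coupling, record
#' length, sampling interval, stagger and noise level of a simulated
#' population.
#'
#' @return Named list of scenario definitions.
#' @export
scenario_presets <- function() {
  path <- system.file("extdata", "scenarios.yaml", package = "txcycle")
  yaml::read_yaml(path)
}

scenario_to_objects <- function(sc) {
  sp <- switch_params(mean_on = sc$mean_on, refractory = sc$refractory,
                      mean_excess_off = sc$mean_excess_off,
                      rate_on = sc$rate_on %||% 10,
                      rate_off = sc$rate_off %||% 0)
  noise <- noise_params(sd_additive = sc$sd_additive %||% 0,
                        cv_multiplicative = sc$cv_multiplicative %||% 0)
  list(params = sp, noise = noise,
       coupling = sc$coupling %||% "independent",
       duration = sc$duration %||% 30, dt = sc$dt %||% 1,
       stagger = sc$stagger %||% 0.5,
       initial_state = {
         # YAML 1.1 reads a bare on/off as logical
         is <- sc$initial_state %||% "stationary"
         if (isTRUE(is)) "on" else if (isFALSE(is)) "off" else is
       })
}

#' Simulate a population of dual-reporter cells
#'
#' Batch wrapper around [simulate_dual_cell()] using a named scenario
#' preset; stores the ground-truth switch paths for recovery tests.
#' The additive-noise SD stated in a scenario is interpreted as a fraction
#' of the expected mean protein signal, so noise scales sensibly with the
#' transcription level.
#'
#' @param n_cells Number of cells.
#' @param scenario Scenario name (see [scenario_presets()]).
#' @param seed Integer seed; the population is reproducible bit-for-bit.
#' @return List of per-cell lists as returned by [simulate_dual_cell()],
#'   with attribute `"scenario"`.
#' @export
simulate_population <- function(n_cells, scenario = "paper-calibrated",
                                seed = NULL) {
  presets <- scenario_presets()
  if (!scenario %in% names(presets))
    stop(sprintf("unknown scenario '%s'; available: %s", scenario,
                 paste(names(presets), collapse = ", ")), call. = FALSE)
  sc <- scenario_to_objects(presets[[scenario]])
  # additive noise scales with the stationary-mean signal of the slower
  # reporter so that it stays a fixed fraction of a typical trace value
  kin <- default_kinetics("luc")
  p_on <- sc$params$mean_on /
    (sc$params$mean_on + sc$params$refractory + sc$params$mean_excess_off)
  tau_bar <- p_on * sc$params$rate_on + (1 - p_on) * sc$params$rate_off
  mean_signal <- kin$alpha * tau_bar / (kin$delta_m * kin$delta_p)
  noise <- noise_params(sd_additive = sc$noise$sd_additive * mean_signal,
                        cv_multiplicative = sc$noise$cv_multiplicative)
  with_local_seed(seed, function() {
    cells <- lapply(seq_len(n_cells), function(i) {
      simulate_dual_cell(sc$params, coupling = sc$coupling,
                         duration = sc$duration, dt = sc$dt,
                         stagger = sc$stagger, noise = noise,
                         cell_id = sprintf("cell%03d", i),
                         initial_state = sc$initial_state)
    })
    attr(cells, "scenario") <- scenario
    attr(cells, "params") <- sc$params
    cells
  })
}

#' Simulate an inhibitor decay experiment
#'
#' Translation block (cycloheximide-type) sets `alpha = 0` at t = 0, so the
#' protein decays as a single exponential `P0 * exp(-delta_p * t)`.
#' Transcription block (actinomycin D-type) sets `tau = 0` at t = 0, so the
#' mRNA decays at `delta_m` and the protein follows the double-exponential
#' (or degenerate `t * exp(-delta * t)`) solution.
#'
#' @param kind `"translation-block"` or `"transcription-block"`.
#' @param kin A [kinetic_params()].
#' @param m0,p0 Initial mRNA and protein levels (>= 0).
#' @param grid Observation times (hours).
#' @param noise A [noise_params()].
#' @param seed Optional seed.
#' @param cell_id,reporter Labels.
#' @return A [cell_trace()] with treatment `"decay-CHX"` or `"decay-ActD"`.
#' @export
simulate_decay_experiment <- function(kind = c("translation-block",
                                               "transcription-block"),
                                      kin, m0, p0, grid,
                                      noise = noise_params(), seed = NULL,
                                      cell_id = "decay1", reporter = "luc") {
  kind <- match.arg(kind)
  stopifnot(inherits(kin, "kinetic_params"))
  if (m0 < 0 || p0 < 0) stop("m0 and p0 must be >= 0", call. = FALSE)
  grid <- as.numeric(grid)
  p <- if (kind == "translation-block") {
    p0 * exp(-kin$delta_p * grid)
  } else {
    # tau = 0 path: reuse the closed-form propagator with zero rates
    protein_path_cpp(numeric(0), 0L, 0, 1, kin$alpha, kin$delta_m,
                     kin$delta_p, m0, p0, grid, max(grid) + 1)
  }
  obs <- with_local_seed(seed, function() {
    n <- length(p)
    p * (1 + rnorm(n, 0, noise$cv_multiplicative)) +
      rnorm(n, 0, noise$sd_additive)
  })
  cell_trace(cell_id, reporter, grid, obs,
             treatment = if (kind == "translation-block") "decay-CHX"
                         else "decay-ActD")
}
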