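#' Fit an exponential distribution with the same mean as the data
#'
#' The moment estimator `rate = 1/mean` (which coincides with the maximum
#' likelihood estimator for the exponential family) plus the fitted density
#' evaluated on a grid, for overlaying on duration histograms.
#'
#' @param durations Positive durations (hours), at least 10.
#' @param grid Optional evaluation grid; default spans the data.
#' @return List with `rate` (per hour), `mean`, `density` (data.frame
#'   `x`, `density`).
#' @export
fit_exponential_same_mean <- function(durations, grid = NULL) {
  if (length(durations) < 10)
    stop("need at least 10 durations", call. = FALSE)
  if (any(durations <= 0))
    stop("durations must all be > 0", call. = FALSE)
  m <- mean(durations)
  if (is.null(grid)) grid <- seq(0, max(durations), length.out = 200)
  list(rate = 1 / m, mean = m,
       density = data.frame(x = grid, density = exp(-grid / m) / m))
}

#' One-sample exponentiality test with parametric-bootstrap calibration
#'
#' Kolmogorov-Smirnov test of the exponential null with the rate estimated
#' from the data. Estimating the rate invalidates the standard KS critical
#' values, so the null distribution of the statistic is recalibrated by
#' parametric bootstrap (Lilliefors-type).
#'
#' @param durations Positive durations.
#' @param n_boot Bootstrap replicates (default 500).
#' @param seed Optional seed.
#' @return List with `statistic` (KS distance), `p_value`, `rate`.
#' @export
ks_exponential_test <- function(durations, n_boot = 500, seed = NULL) {
  n <- length(durations)
  ks_stat <- function(x) {
    r <- 1 / mean(x)
    xs <- sort(x)
    u <- 1 - exp(-r * xs)
    i <- seq_len(length(xs))
    max(pmax(i / length(xs) - u, u - (i - 1) / length(xs)))
  }
  d_obs <- ks_stat(durations)
  rate <- 1 / mean(durations)
  p <- with_local_seed(seed, function() {
    d_null <- replicate(n_boot, ks_stat(rexp(n, rate)))
    (1 + sum(d_null >= d_obs)) / (n_boot + 1)
  })
  list(statistic = d_obs, p_value = p, rate = rate)
}

#' Memory function of a duration distribution
#'
#' The conditional survival `P(D > s + t | D > s)`: the probability of
#' waiting at least `t` further hours in the off state given `s` hours
#' already waited. For an exponential (memoryless) distribution this is
#' independent of `s`; a refractory floor makes it decrease in `s` within
#' the refractory window. The exponential reference `exp(-t / mean)` is
#' attached for comparison.
#'
#' @param durations Positive durations (hours).
#' @param s_grid Conditioning times `s` (hours); default `seq(0, 6, 0.5)`.
#' @param t_max Largest `t` (hours, in 0.5 h increments from 0).
#' @param min_survivors Values of `s` with fewer surviving durations are
#'   dropped (default 20).
#' @return Object of class `memory_curve`: list with `s_grid`, `t_values`,
#'   `prob` (matrix s x t), `exponential_reference` (vector over t),
#'   `n_survivors`.
#' @export
memory_function <- function(durations, s_grid = seq(0, 6, by = 0.5),
                            t_max = 6, min_survivors = 20) {
  if (any(durations <= 0)) stop("durations must be > 0", call. = FALSE)
  t_values <- seq(0, t_max, by = 0.5)
  n_surv <- vapply(s_grid, function(s) sum(durations > s), integer(1))
  keep <- n_surv >= min_survivors
  s_grid <- s_grid[keep]; n_surv <- n_surv[keep]
  prob <- matrix(NA_real_, length(s_grid), length(t_values),
                 dimnames = list(sprintf("s=%g", s_grid),
                                 sprintf("t=%g", t_values)))
  for (i in seq_along(s_grid)) {
    s <- s_grid[i]
    surv <- durations[durations > s]
    prob[i, ] <- vapply(t_values, function(t) mean(surv > s + t), numeric(1))
  }
  m <- mean(durations)
  structure(list(s_grid = s_grid, t_values = t_values, prob = prob,
                 exponential_reference = exp(-t_values / m),
                 n_survivors = n_surv, mean = m),
            class = "memory_curve")
}

#' Shift durations by the refractory floor
#'
#' `direction = "remove"` subtracts the refractory period, yielding the
#' excess off-times (all inputs must be >= the refractory value);
#' `direction = "enforce"` adds it back. The two directions are exact
#' inverses.
#'
#' @param durations Durations (hours).
#' @param refractory Refractory floor (hours, default 3).
#' @param direction `"remove"` or `"enforce"`.
#' @return Shifted durations.
#' @export
shift_by_refractory <- function(durations, refractory = 3,
                                direction = c("remove", "enforce")) {
  direction <- match.arg(direction)
  if (direction == "remove") {
    bad <- which(durations < refractory)
    if (length(bad))
      stop("cannot remove the refractory period: durations below ",
           refractory, " h at positions ",
           paste(head(bad, 10), collapse = ", "), call. = FALSE)
    durations - refractory
  } else {
    durations + refractory
  }
}

#' Mode of a duration histogram on 0.5-hour bins
#'
#' Histogram with `bin_width` bins starting at 0 (`[0, 0.5), [0.5, 1), ...`
#' by default); returns the left edge of the maximal bin, the value a
#' histogram labelled on the half-hour grid reads off as the most likely
#' duration. Used to locate the most likely off-duration of a pooled
#' population distribution.
#'
#' @param durations Durations (hours).
#' @param bin_width Bin width (default 0.5).
#' @return Left edge (hours) of the maximal bin.
#' @export
duration_histogram_mode <- function(durations, bin_width = 0.5) {
  left <- floor(durations / bin_width) * bin_width
  tab <- table(left)
  as.numeric(names(tab)[which.max(tab)])
}

#' Cyclicity of transcription cycles via first-ACF-peak variance
#'
#' Simulates a population of cells whose binary transcription paths have
#' on- and off-durations drawn from the supplied samplers, generates the
#' corresponding mRNA time series (`dM/dt = tau - delta_m * M`, closed-form
#' piecewise integration), runs the autocorrelation first-peak period
#' estimator per cell, and returns the variance of the first-peak times
#' across cells with a detected peak: low variance means regular cycling.
#'
#' @param on_sampler,off_sampler Functions `n -> durations` (hours); see
#'   [make_duration_sampler()].
#' @param n_cells Number of simulated cells (default 1000).
#' @param kin A [kinetic_params()] (only `delta_m` is used).
#' @param record_length Record length per cell (hours, default 50).
#' @param dt mRNA sampling interval (hours, default 0.5).
#' @param seed Optional seed.
#' @param scenario Label stored on the result.
#' @return Object of class `cyclicity_result`: list with `n_cells`,
#'   `first_peak_times`, `variance`, `fraction_detected`, `scenario`.
#' @export
cyclicity_simulation <- function(on_sampler, off_sampler, n_cells = 1000,
                                 kin = default_kinetics("luc"),
                                 record_length = 50, dt = 0.5, seed = NULL,
                                 scenario = "custom") {
  grid <- seq(0, record_length, by = dt)
  peaks <- with_local_seed(seed, function() {
    vapply(seq_len(n_cells), function(i) {
      # alternate on/off durations, starting in the on state
      times <- numeric(0)
      t_cur <- 0; on <- TRUE
      repeat {
        d <- if (on) on_sampler(1) else off_sampler(1)
        t_cur <- t_cur + d
        if (t_cur >= record_length) break
        times <- c(times, t_cur)
        on <- !on
      }
      m <- mrna_path_cpp(times, 1L, 0, 1, kin$delta_m, 0, grid,
                         record_length)
      # simulated series carry no measurement noise, so the white-noise
      # guard is disabled: the first-maximum location is the period signal
      first_peak(sample_acf(m, dt), reject_in_band = FALSE)
    }, numeric(1))
  })
  det <- peaks[!is.na(peaks)]
  if (length(det) < n_cells / 2)
    warning("fewer than half of the simulated cells yield an ACF peak",
            call. = FALSE)
  structure(list(n_cells = n_cells, first_peak_times = peaks,
                 variance = if (length(det) > 1) var(det) else NA_real_,
                 fraction_detected = length(det) / n_cells,
                 scenario = scenario),
            class = "cyclicity_result")
}

#' Duration samplers for the cyclicity simulation
#'
#' Builds a sampler function `n -> durations` either parametrically
#' (exponential, optionally shifted by a refractory floor) or by empirical
#' resampling of observed durations.
#'
#' @param type `"exponential"`, `"refractory-exponential"` or
#'   `"empirical"`.
#' @param mean Mean of the exponential (or of the excess beyond the
#'   refractory floor).
#' @param refractory Refractory floor for `"refractory-exponential"`.
#' @param durations Observed durations for `"empirical"`.
#' @return A function of `n`.
#' @export
make_duration_sampler <- function(type = c("exponential",
                                           "refractory-exponential",
                                           "empirical"),
                                  mean = NULL, refractory = 3,
                                  durations = NULL) {
  type <- match.arg(type)
  switch(type,
    "exponential" = {
      stopifnot(!is.null(mean))
      function(n) rexp(n, 1 / mean)
    },
    "refractory-exponential" = {
      stopifnot(!is.null(mean))
      function(n) refractory + rexp(n, 1 / mean)
    },
    "empirical" = {
      stopifnot(!is.null(durations), length(durations) > 0)
      function(n) sample(durations, n, replace = TRUE)
    })
}

#' @export
print.memory_curve <- function(x, ...) {
  cat(sprintf("<memory_curve> %d s values, t up to %g h (mean duration %.3g h)\n",
              length(x$s_grid), max(x$t_values), x$mean))
  invisible(x)
}

#' @export
print.cyclicity_result <- function(x, ...) {
  cat(sprintf("<cyclicity_result> %s: first-peak variance %.3g h^2 (%d cells, %.0f%% detected)\n",
              x$scenario, x$variance, x$n_cells, 100 * x$fraction_detected))
  invisible(x)
}
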