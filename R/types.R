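#' Switch-process parameters
#'
#' Parameters of the binary transcription switch: exponentially distributed
#' on-times, and off-times composed of a hard refractory floor plus an
#' exponential excess. Setting `refractory = 0` recovers the classical
#' memoryless telegraph process.
#'
#' @param mean_on Mean of the exponential on-duration (hours).
#' @param refractory Hard minimum off-duration (hours, >= 0).
#' @param mean_excess_off Mean of the exponential excess off-duration beyond
#'   the refractory floor (hours).
#' @param rate_on Transcription rate in the on state (transcript units/hour).
#' @param rate_off Basal transcription rate in the off state (>= 0, <
#'   `rate_on`).
#' @return An object of class `switch_params`.
#' @examples
#' switch_params(mean_on = 4, refractory = 3, mean_excess_off = 3.5)
#' @export
switch_params <- function(mean_on, refractory, mean_excess_off,
                          rate_on = 10, rate_off = 0) {
  if (!is.numeric(mean_on) || mean_on <= 0)
    stop("`mean_on` must be > 0", call. = FALSE)
  if (!is.numeric(refractory) || refractory < 0)
    stop("`refractory` must be >= 0", call. = FALSE)
  if (!is.numeric(mean_excess_off) || mean_excess_off <= 0)
    stop("`mean_excess_off` must be > 0", call. = FALSE)
  if (!(rate_on > rate_off) || rate_off < 0)
    stop("need rate_on > rate_off >= 0", call. = FALSE)
  structure(list(mean_on = mean_on, refractory = refractory,
                 mean_excess_off = mean_excess_off,
                 rate_on = rate_on, rate_off = rate_off),
            class = "switch_params")
}

#' Reporter kinetic parameters
#'
#' First-order kinetic constants of a reporter: translation rate `alpha`
#' (protein units per transcript unit per hour), mRNA and protein degradation
#' rates (per hour) and a constant signal-maturation lag (hours). Since the
#' translation rate is not identifiable from protein data alone, the analysis
#' pipeline works in units of `alpha * M` and fixes `alpha = 1` by default.
#'
#' @param alpha Translation/synthesis rate (> 0).
#' @param delta_m mRNA degradation rate, per hour (> 0).
#' @param delta_p Protein degradation rate, per hour (> 0).
#' @param maturation_delay Constant lag between synthesis and detectable
#'   signal (hours, >= 0).
#' @return An object of class `kinetic_params`.
#' @examples
#' kin_luc <- kinetic_params(delta_m = 0.65, delta_p = 0.35)
#' @export
kinetic_params <- function(alpha = 1, delta_m, delta_p,
                           maturation_delay = 0) {
  if (alpha <= 0 || delta_m <= 0 || delta_p <= 0)
    stop("alpha, delta_m and delta_p must all be > 0", call. = FALSE)
  if (maturation_delay < 0)
    stop("`maturation_delay` must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, delta_m = delta_m, delta_p = delta_p,
                 maturation_delay = maturation_delay),
            class = "kinetic_params")
}

#' Measurement-noise parameters
#'
#' Heteroscedastic observation noise applied to simulated protein signal:
#' `observed = P * (1 + eps_m) + eps_a` with multiplicative coefficient of
#' variation `cv_multiplicative` and additive standard deviation
#' `sd_additive` (intensity units).
#'
#' @param sd_additive Additive noise SD (>= 0).
#' @param cv_multiplicative Multiplicative noise CV (>= 0).
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(sd_additive = 0, cv_multiplicative = 0) {
  if (sd_additive < 0 || cv_multiplicative < 0)
    stop("noise parameters must be >= 0", call. = FALSE)
  structure(list(sd_additive = sd_additive,
                 cv_multiplicative = cv_multiplicative),
            class = "noise_params")
}

#' Piecewise-binary transcription path
#'
#' A realisation of the binary switch process: strictly increasing switch
#' times within `[0, duration]`, the state before the first switch, and the
#' two transcription levels. The state alternates at every switch.
#'
#' @param switch_times Strictly increasing switch times (hours).
#' @param initial_state `"on"` or `"off"`.
#' @param rate_on,rate_off Transcription levels (transcript units/hour).
#' @param duration Record length (hours).
#' @return An object of class `switch_path`.
#' @export
switch_path <- function(switch_times, initial_state, rate_on, rate_off,
                        duration) {
  switch_times <- as.numeric(switch_times)
  if (length(switch_times) && any(diff(switch_times) <= 0))
    stop("`switch_times` must be strictly increasing", call. = FALSE)
  if (length(switch_times) &&
      (min(switch_times) <= 0 || max(switch_times) >= duration))
    stop("`switch_times` must lie strictly inside (0, duration)",
         call. = FALSE)
  initial_state <- match.arg(initial_state, c("on", "off"))
  if (duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  structure(list(switch_times = switch_times, initial_state = initial_state,
                 rate_on = rate_on, rate_off = rate_off, duration = duration),
            class = "switch_path")
}

#' Evaluate a switch path as a step function
#'
#' @param path A [switch_path()].
#' @param times Times (hours) at which to evaluate the transcription rate.
#' @return Numeric vector of transcription rates at `times`.
#' @export
path_rate <- function(path, times) {
  stopifnot(inherits(path, "switch_path"))
  k <- findInterval(times, path$switch_times)
  on_first <- path$initial_state == "on"
  on <- (k %% 2 == 0) == on_first
  ifelse(on, path$rate_on, path$rate_off)
}

# interval decomposition of a path: data.frame(start, end, state, censored)
path_intervals <- function(path) {
  bounds <- c(0, path$switch_times, path$duration)
  n <- length(bounds) - 1L
  states <- rep(c(path$initial_state,
                  setdiff(c("on", "off"), path$initial_state)),
                length.out = n)
  data.frame(start = bounds[-length(bounds)], end = bounds[-1],
             state = states,
             censored = seq_len(n) %in% c(1L, n))
}

#' Observed single-cell reporter trace
#'
#' @param cell_id Cell label.
#' @param reporter Reporter label (e.g. `"luc"`, `"gfp"`).
#' @param times Strictly increasing observation times (hours).
#' @param values Intensities (arbitrary units), finite.
#' @param treatment Treatment label; default `"unstimulated"`.
#' @return An object of class `cell_trace`.
#' @export
cell_trace <- function(cell_id, reporter, times, values,
                       treatment = "unstimulated") {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("`times` and `values` must have equal length", call. = FALSE)
  if (length(times) < 8)
    stop("a trace needs at least 8 observations", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (any(!is.finite(values)))
    stop("`values` must be finite", call. = FALSE)
  structure(list(cell_id = as.character(cell_id),
                 reporter = as.character(reporter),
                 times = times, values = values,
                 treatment = as.character(treatment)),
            class = "cell_trace")
}

#' @export
print.cell_trace <- function(x, ...) {
  cat(sprintf("<cell_trace> cell %s, reporter %s, %d points over [%g, %g] h (%s)\n",
              x$cell_id, x$reporter, length(x$times), min(x$times),
              max(x$times), x$treatment))
  invisible(x)
}

#' @export
print.switch_path <- function(x, ...) {
  cat(sprintf("<switch_path> %d switches over %g h, starts %s\n",
              length(x$switch_times), x$duration, x$initial_state))
  invisible(x)
}

#' @export
print.switch_params <- function(x, ...) {
  cat(sprintf(
    "<switch_params> on ~ Exp(mean %.3g h); off ~ %.3g h + Exp(mean %.3g h); levels %.3g/%.3g\n",
    x$mean_on, x$refractory, x$mean_excess_off, x$rate_off, x$rate_on))
  invisible(x)
}
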