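#' Fit a smoothing spline to a protein trace
#'
#' Approximates the observed protein path by a penalised cubic smoothing
#' spline. The smoothing penalty is chosen by generalised cross-validation
#' when `smoothing = "auto"`; a numeric value is passed through as the
#' `spar` argument of [stats::smooth.spline()].
#'
#' @param trace A [cell_trace()] with at least 8 observations and no
#'   duplicate times.
#' @param smoothing `"auto"` (GCV) or a numeric `spar` in (-1.5, 1.5].
#' @return An object of class `spline_fit` with elements `fit` (the
#'   smooth.spline object), `t_min`, `t_max`, and evaluators `fitted(t)` /
#'   `derivative(t)`.
#' @export
fit_protein_spline <- function(trace, smoothing = "auto") {
  stopifnot(inherits(trace, "cell_trace"))
  if (length(trace$times) < 8)
    stop("need at least 8 observations for spline fitting", call. = FALSE)
  if (anyDuplicated(trace$times))
    stop("duplicate observation times", call. = FALSE)
  fit <- if (identical(smoothing, "auto")) {
    smooth.spline(trace$times, trace$values, cv = FALSE,
                  all.knots = TRUE, keep.data = FALSE)
  } else {
    smooth.spline(trace$times, trace$values, spar = as.numeric(smoothing),
                  all.knots = TRUE, keep.data = FALSE)
  }
  t_min <- min(trace$times); t_max <- max(trace$times)
  check_range <- function(t) {
    if (min(t) < t_min - 1e-9 || max(t) > t_max + 1e-9)
      stop("evaluation outside the spline support", call. = FALSE)
  }
  structure(list(
    fit = fit, t_min = t_min, t_max = t_max,
    cell_id = trace$cell_id, reporter = trace$reporter,
    fitted = function(t) { check_range(t); predict(fit, t)$y },
    derivative = function(t) { check_range(t); predict(fit, t, deriv = 1)$y }),
    class = "spline_fit")
}

#' Reconstruct the (scaled) mRNA profile from a fitted protein spline
#'
#' Applies the inversion identity `alpha * M(t) = dP/dt + delta_p * P(t)` on
#' a uniform fine grid inside the spline support.
#'
#' @param spline A `spline_fit` from [fit_protein_spline()].
#' @param delta_p Protein degradation rate (per hour, >= 0; 0 returns the
#'   pure derivative).
#' @param grid_step Fine grid step in hours (default 0.1).
#' @return A list with `grid` and `alpha_m` (the reconstructed
#'   `alpha * M(t)` values).
#' @export
reconstruct_mrna <- function(spline, delta_p, grid_step = 0.1) {
  stopifnot(inherits(spline, "spline_fit"))
  if (delta_p < 0) stop("`delta_p` must be >= 0", call. = FALSE)
  grid <- seq(spline$t_min, spline$t_max, by = grid_step)
  alpha_m <- spline$derivative(grid) + delta_p * spline$fitted(grid)
  list(grid = grid, alpha_m = alpha_m)
}

#' Reconstruct the transcription profile from an mRNA profile
#'
#' Forward Euler inversion of `dM/dt = tau - delta_m * M` on a uniform grid:
#' `tau(t_i) = (M(t_{i+1}) - M(t_i)) / dt + delta_m * M(t_i)`. The last
#' grid point is dropped (no forward difference available).
#'
#' @param mrna List with `grid` (uniform) and `alpha_m`, as returned by
#'   [reconstruct_mrna()].
#' @param delta_m mRNA degradation rate (per hour, >= 0).
#' @param cell_id,reporter Labels carried onto the profile.
#' @param clip_negative Clip reconstructed rates at 0 (default FALSE; raw
#'   values preserve ranks for correlation analysis).
#' @return An object of class `transcription_profile` with `grid`, `tau`,
#'   `alpha_m`, `cell_id`, `reporter`.
#' @export
reconstruct_transcription <- function(mrna, delta_m, cell_id = "cell1",
                                      reporter = "luc",
                                      clip_negative = FALSE) {
  grid <- mrna$grid
  dsteps <- diff(grid)
  if (max(abs(dsteps - dsteps[1])) > 1e-8)
    stop("`grid` must be uniform", call. = FALSE)
  dt <- dsteps[1]
  m <- mrna$alpha_m
  n <- length(m)
  tau <- diff(m) / dt + delta_m * m[-n]
  if (clip_negative) tau <- pmax(tau, 0)
  structure(list(grid = grid[-n], tau = tau, alpha_m = m[-n],
                 cell_id = cell_id, reporter = reporter,
                 grid_step = dt),
            class = "transcription_profile")
}

#' Full protein-to-transcription reconstruction for one cell
#'
#' Composition of [fit_protein_spline()], [reconstruct_mrna()] and
#' [reconstruct_transcription()], with the reporter's maturation delay
#' removed as a constant shift of the time axis. The first and last
#' `boundary` hours of the reconstruction are flagged as low confidence
#' (spline edge effects) via the `low_confidence` logical vector.
#'
#' @param trace A [cell_trace()].
#' @param kin A [kinetic_params()].
#' @param grid_step Fine grid step in hours (default 0.1).
#' @param smoothing Passed to [fit_protein_spline()].
#' @param clip_negative Clip negative rates (default FALSE).
#' @param boundary Width of the low-confidence boundary in hours (default 1).
#' @return A `transcription_profile` with extra fields `low_confidence` and
#'   `spline`.
#' @export
reconstruct_cell <- function(trace, kin, grid_step = 0.1,
                             smoothing = "auto", clip_negative = FALSE,
                             boundary = 1) {
  stopifnot(inherits(kin, "kinetic_params"))
  sp <- fit_protein_spline(trace, smoothing)
  mr <- reconstruct_mrna(sp, kin$delta_p, grid_step)
  prof <- reconstruct_transcription(mr, kin$delta_m,
                                    cell_id = trace$cell_id,
                                    reporter = trace$reporter,
                                    clip_negative = clip_negative)
  # undo the constant maturation shift: signal observed at t was made at
  # t - d, so the reconstructed profile is moved back by d
  prof$grid <- prof$grid - kin$maturation_delay
  prof$low_confidence <- prof$grid < (sp$t_min - kin$maturation_delay +
                                        boundary) |
    prof$grid > (sp$t_max - kin$maturation_delay - boundary)
  prof$spline <- sp
  prof
}

#' @export
print.transcription_profile <- function(x, ...) {
  cat(sprintf("<transcription_profile> cell %s (%s), %d points, step %g h\n",
              x$cell_id, x$reporter, length(x$grid), x$grid_step))
  invisible(x)
}

#' Evaluate a transcription profile on times (linear interpolation)
#'
#' @param profile A `transcription_profile`.
#' @param times Target times within the profile's grid range.
#' @return Numeric vector of interpolated rates.
#' @export
profile_at <- function(profile, times) {
  approx(profile$grid, profile$tau, xout = times, rule = 1)$y
}
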