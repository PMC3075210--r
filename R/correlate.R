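#' Windowed rank correlation between two transcription profiles
#'
#' Computes the Spearman (or Kendall) rank correlation `C(T)` between two
#' reconstructed transcription profiles over growing windows
#' `[origin, origin + T]`. The second profile is linearly interpolated onto
#' the first profile's grid, which also absorbs the sampling stagger between
#' reporters.
#'
#' @param tau1,tau2 `transcription_profile` objects.
#' @param origin Window start in hours (stimulus time, or 2 h into the
#'   record for unstimulated data).
#' @param t_grid Window lengths T in hours (default `seq(1.5, 8, 0.5)`).
#' @param method `"spearman"` (default) or `"kendall"`.
#' @return Object of class `correlation_curve`: data.frame with `T_h` and
#'   `c_of_T` (`NA` where the window is not covered), plus attributes
#'   `origin` and `cell_id`.
#' @export
window_correlation <- function(tau1, tau2, origin = 2,
                               t_grid = seq(1.5, 8, by = 0.5),
                               method = c("spearman", "kendall")) {
  method <- match.arg(method)
  g <- tau1$grid
  y1 <- tau1$tau
  y2 <- approx(tau2$grid, tau2$tau, xout = g, rule = 1)$y
  cvals <- vapply(t_grid, function(T) {
    win <- g >= origin & g <= origin + T
    sel <- win & !is.na(y2)
    # a window is usable only when both profiles essentially cover it
    if (sum(win) < 3 || sum(sel) < 0.9 * sum(win)) return(NA_real_)
    suppressWarnings(cor(y1[sel], y2[sel], method = method))
  }, numeric(1))
  structure(data.frame(T_h = t_grid, c_of_T = cvals),
            origin = origin, cell_id = tau1$cell_id,
            class = c("correlation_curve", "data.frame"))
}

#' Bootstrap population summary of correlation curves
#'
#' Per-window-length quantiles of `C(T)` across cells, with a percentile
#' bootstrap confidence interval for the median obtained by resampling cells
#' with replacement.
#'
#' @param curves List of `correlation_curve` objects on a common T grid.
#' @param n_boot Number of bootstrap resamples (default 4000).
#' @param seed Optional seed for the bootstrap.
#' @param conf Confidence level for the median CI (default 0.95).
#' @return Object of class `population_correlation_summary`: data.frame
#'   with per-T quantiles (`q025`, `q25`, `q50`, `q75`, `q975`),
#'   `median_ci_low`, `median_ci_high`, `significant` (CI excludes 0) and
#'   `n_cells`.
#' @export
population_summary <- function(curves, n_boot = 4000, seed = NULL,
                               conf = 0.95) {
  if (length(curves) < 10)
    stop("population summary needs at least 10 cells", call. = FALSE)
  t_grid <- curves[[1]]$T_h
  mat <- vapply(curves, function(cv) {
    stopifnot(isTRUE(all.equal(cv$T_h, t_grid)))
    cv$c_of_T
  }, numeric(length(t_grid)))         # T x cells
  mat <- matrix(mat, nrow = length(t_grid))
  qs <- t(apply(mat, 1, quantile,
                probs = c(0.025, 0.25, 0.5, 0.75, 0.975), na.rm = TRUE))
  n_cells <- ncol(mat)
  alpha <- (1 - conf) / 2
  ci <- with_local_seed(seed, function() {
    boot_med <- matrix(NA_real_, n_boot, length(t_grid))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n_cells, n_cells, replace = TRUE)
      boot_med[b, ] <- apply(mat[, idx, drop = FALSE], 1, median,
                             na.rm = TRUE)
    }
    apply(boot_med, 2, quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
  })
  out <- data.frame(T_h = t_grid,
                    q025 = qs[, 1], q25 = qs[, 2], q50 = qs[, 3],
                    q75 = qs[, 4], q975 = qs[, 5],
                    median_ci_low = ci[1, ], median_ci_high = ci[2, ])
  out$significant <- out$median_ci_low > 0 | out$median_ci_high < 0
  attr(out, "n_cells") <- n_cells
  class(out) <- c("population_correlation_summary", "data.frame")
  out
}

#' Between-cell correlation of one reporter across cells
#'
#' Windowed rank correlation for all unordered pairs of cells within each
#' experiment, summarised with the same bootstrap machinery as the
#' within-cell analysis (each pair is the resampling unit).
#'
#' @param profiles List of `transcription_profile`s for one reporter.
#' @param experiment Optional factor assigning profiles to experiments;
#'   pairs are formed within experiments only. Default: one experiment.
#' @param origin,t_grid,method As in [window_correlation()].
#' @param n_boot,seed As in [population_summary()].
#' @return A `population_correlation_summary` over cell pairs.
#' @export
between_cell_correlation <- function(profiles, experiment = NULL,
                                     origin = 2,
                                     t_grid = seq(1.5, 8, by = 0.5),
                                     method = "spearman",
                                     n_boot = 4000, seed = NULL) {
  if (is.null(experiment)) experiment <- rep("e1", length(profiles))
  curves <- list()
  for (ex in unique(experiment)) {
    idx <- which(experiment == ex)
    if (length(idx) < 2) {
      warning(sprintf("experiment '%s' has a single cell; skipped", ex),
              call. = FALSE)
      next
    }
    prs <- utils::combn(idx, 2)
    for (j in seq_len(ncol(prs))) {
      curves[[length(curves) + 1]] <-
        window_correlation(profiles[[prs[1, j]]], profiles[[prs[2, j]]],
                           origin, t_grid, method)
    }
  }
  population_summary(curves, n_boot = n_boot, seed = seed)
}

#' Correlation scan over candidate maturation-delay shifts
#'
#' Recomputes `C(T)` after shifting one profile's time axis back by each
#' candidate difference `d` in maturation time, to check that the
#' correlation conclusions are insensitive to the (unknown) between-reporter
#' maturation offset.
#'
#' @param tau_gfp,tau_luc `transcription_profile`s.
#' @param shifts Candidate maturation differences in hours
#'   (default `c(0, 0.5, 1)`).
#' @param origin,t_grid,method As in [window_correlation()].
#' @return Named list of `correlation_curve`s, one per shift.
#' @export
maturation_shift_scan <- function(tau_gfp, tau_luc,
                                  shifts = c(0, 0.5, 1), origin = 2,
                                  t_grid = seq(1.5, 8, by = 0.5),
                                  method = "spearman") {
  out <- lapply(shifts, function(d) {
    shifted <- tau_gfp
    shifted$grid <- shifted$grid - d
    window_correlation(tau_luc, shifted, origin, t_grid, method)
  })
  names(out) <- sprintf("d=%g", shifts)
  out
}

#' Filter out low-amplitude cells before correlation analysis
#'
#' Cells whose reconstructed transcription range is below a fraction of the
#' population median range carry little rank information and are discarded.
#'
#' @param profiles List of `transcription_profile`s.
#' @param threshold Fraction of the population median range (default 0.2).
#' @return Logical vector: TRUE for cells to keep.
#' @export
filter_low_amplitude <- function(profiles, threshold = 0.2) {
  rng <- vapply(profiles, function(p) diff(range(p$tau)), numeric(1))
  rng >= threshold * median(rng)
}
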