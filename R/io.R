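#' Read cell traces from a tidy CSV file
#'
#' Expects the header `cell_id,reporter,time_h,intensity,treatment`. Rows
#' with missing intensity cause their whole cell/reporter series to be
#' skipped with a warning; unsorted times are rejected with the offending
#' line reported.
#'
#' @param path CSV file path.
#' @return List of [cell_trace()] objects.
#' @export
read_traces <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("cell_id", "reporter", "time_h", "intensity", "treatment")
  if (!identical(names(df)[seq_along(required)], required))
    stop("malformed header: expected '", paste(required, collapse = ","),
         "'", call. = FALSE)
  out <- list()
  for (key in unique(paste(df$cell_id, df$reporter, sep = "\r"))) {
    parts <- strsplit(key, "\r")[[1]]
    sub <- df[df$cell_id == parts[1] & df$reporter == parts[2], ]
    if (anyNA(sub$intensity)) {
      warning(sprintf("cell %s/%s has missing intensities; skipped",
                      parts[1], parts[2]), call. = FALSE)
      next
    }
    if (any(diff(sub$time_h) <= 0)) {
      bad <- which(diff(sub$time_h) <= 0)[1]
      stop(sprintf(
        "times not strictly increasing for cell %s/%s (near data row %d)",
        parts[1], parts[2], bad + 1), call. = FALSE)
    }
    out[[length(out) + 1]] <-
      cell_trace(parts[1], parts[2], sub$time_h, sub$intensity,
                 sub$treatment[1])
  }
  out
}

#' Write cell traces to a tidy CSV file
#'
#' @param traces List of [cell_trace()] objects (or a single one).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "cell_trace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, function(tr)
    data.frame(cell_id = tr$cell_id, reporter = tr$reporter,
               time_h = tr$times, intensity = tr$values,
               treatment = tr$treatment)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write ground-truth switch paths as a sidecar CSV
#'
#' Header: `cell_id,reporter,switch_times_h,initial_state,rate_on,rate_off`
#' with switch times packed as a `;`-separated list.
#'
#' @param paths Named list: per cell, a list of `switch_path`s keyed by
#'   reporter.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_paths <- function(paths, path) {
  rows <- list()
  for (cell in names(paths)) {
    for (rep_name in names(paths[[cell]])) {
      sp <- paths[[cell]][[rep_name]]
      rows[[length(rows) + 1]] <- data.frame(
        cell_id = cell, reporter = rep_name,
        switch_times_h = paste(signif(sp$switch_times, 10), collapse = ";"),
        initial_state = sp$initial_state,
        rate_on = sp$rate_on, rate_off = sp$rate_off)
    }
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write transcription profiles to CSV
#'
#' Columns: `cell_id,reporter,time_h,tau,alphaM`.
#'
#' @param profiles List of `transcription_profile`s.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  df <- do.call(rbind, lapply(profiles, function(p)
    data.frame(cell_id = p$cell_id, reporter = p$reporter,
               time_h = p$grid, tau = p$tau, alphaM = p$alpha_m)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-cell durations to CSV
#'
#' Tidy long format: `cell_id,kind,duration_h` with kind one of
#' `on`, `off`, `period`.
#'
#' @param duration_sets List of `duration_set`s.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_durations <- function(duration_sets, path) {
  df <- do.call(rbind, lapply(duration_sets, function(d) {
    rbind(
      if (length(d$on_durations))
        data.frame(cell_id = d$cell_id, kind = "on",
                   duration_h = d$on_durations),
      if (length(d$off_durations))
        data.frame(cell_id = d$cell_id, kind = "off",
                   duration_h = d$off_durations),
      if (length(d$periods))
        data.frame(cell_id = d$cell_id, kind = "period",
                   duration_h = d$periods))
  }))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
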