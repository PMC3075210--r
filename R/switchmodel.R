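#' Configuration for the binary switch-model MCMC
#'
#' Controls for the reversible-jump sampler over the number of switches,
#' their times, the two transcription levels and the observation-noise SD.
#'
#' @param iterations Total sweeps (default 50000).
#' @param burn_in Discarded sweeps (default 10000).
#' @param thin Keep every `thin`-th sweep (default 10).
#' @param max_switches Upper cap on the number of switches (default 20).
#' @param prior_mean_switches Mean of the truncated Poisson prior on the
#'   number of switches (default 4).
#' @param weak_switch_threshold Fraction of the posterior-median level
#'   difference below which a transcription excursion counts as a weak
#'   switch (default 0.2).
#' @param shift_scale SD of the switch-time random-walk proposal (hours).
#' @param level_scale_frac Level proposal SD as a fraction of the data-driven
#'   level scale.
#' @param sigma_scale SD of the log-random-walk proposal for the noise SD.
#' @param seed Integer seed; fixed seed gives identical chains.
#' @return A list of class `switch_model_config`.
#' @export
switch_model_config <- function(iterations = 50000, burn_in = 10000,
                                thin = 10, max_switches = 20,
                                prior_mean_switches = 4,
                                weak_switch_threshold = 0.2,
                                shift_scale = 0.5,
                                level_scale_frac = 0.1,
                                sigma_scale = 0.3, seed = NULL) {
  if (!(iterations > burn_in) || burn_in < 0)
    stop("need iterations > burn_in >= 0", call. = FALSE)
  if (max_switches < 1) stop("max_switches must be >= 1", call. = FALSE)
  structure(list(iterations = iterations, burn_in = burn_in, thin = thin,
                 max_switches = max_switches,
                 prior_mean_switches = prior_mean_switches,
                 weak_switch_threshold = weak_switch_threshold,
                 shift_scale = shift_scale,
                 level_scale_frac = level_scale_frac,
                 sigma_scale = sigma_scale, seed = seed),
            class = "switch_model_config")
}

# log prior of a switch configuration (excluding levels/noise)
lp_switch <- function(k, lambda, t_end) {
  dpois(k, lambda, log = TRUE) + lfactorial(k) - k * log(t_end)
}

#' Reversible-jump MCMC for the binary transcription switch model
#'
#' Fits a piecewise-binary transcription model to an observed protein trace.
#' The likelihood is Gaussian observation noise around the deterministic
#' protein path implied by the switch configuration and the known reporter
#' kinetics (closed-form piecewise ODE solution). The sampler moves between
#' configurations with different numbers of switches using pair birth/death
#' moves (insert or delete a transient state excursion), edge moves that add
#' or remove a switch at either end of the record (flipping the initial
#' state where needed), switch-time shifts, an initial-state flip, and
#' random-walk updates of the two levels, the noise SD and the initial
#' mRNA/protein values.
#'
#' Priors: number of switches `k` ~ Poisson(`prior_mean_switches`) truncated
#' at `max_switches`; switch times ~ uniform order statistics on the record;
#' basal level and level difference ~ half-normal with a scale set from the
#' trace range; noise SD ~ half-Cauchy; initial state ~ Bernoulli(1/2).
#'
#' @param trace A [cell_trace()] with at least 10 observations.
#' @param kin A [kinetic_params()] with known `delta_m`, `delta_p`.
#' @param cfg A [switch_model_config()].
#' @return Object of class `switch_posterior`: list with `samples`
#'   (data.frame of `k`, `z0`, `b_off`, `b_on`, `sigma`, `m0`, `p0`),
#'   `switch_times` (list of per-sample time vectors), `acceptance`,
#'   `t_end`, `kin`, `trace`, `warning_flags`.
#' @export
run_switch_mcmc <- function(trace, kin, cfg = switch_model_config()) {
  stopifnot(inherits(trace, "cell_trace"), inherits(kin, "kinetic_params"))
  if (length(trace$times) < 10)
    stop("switch-model inference needs at least 10 observations",
         call. = FALSE)
  tt <- trace$times - trace$times[1]
  y <- trace$values
  t_end <- max(tt)
  lambda <- cfg$prior_mean_switches
  kmax <- cfg$max_switches

  # data-driven scales (weakly informative)
  tau_scale <- max(abs(y)) * kin$delta_m * kin$delta_p / kin$alpha
  scale_b <- 2 * tau_scale
  scale_m <- 2 * max(abs(y)) * kin$delta_p / kin$alpha
  scale_p <- 2 * max(abs(y))
  scale_sig <- max(sd(y) / 2, 1e-6)
  prop_level <- cfg$level_scale_frac * scale_b
  prop_m0 <- 0.1 * scale_m
  prop_p0 <- 0.1 * scale_p

  lp_levels <- function(b_off, d_b)
    dnorm(b_off, 0, scale_b, log = TRUE) + dnorm(d_b, 0, scale_b, log = TRUE)
  lp_sigma <- function(s) dcauchy(s, 0, scale_sig, log = TRUE)
  lp_init <- function(m0, p0)
    dnorm(m0, 0, scale_m, log = TRUE) + dnorm(p0, 0, scale_p, log = TRUE)

  ll_fun <- function(s, z0, b_off, d_b, sigma, m0, p0)
    switch_loglik_cpp(y, tt, s, z0, b_off, b_off + d_b, kin$alpha,
                      kin$delta_m, kin$delta_p, m0, p0, sigma, t_end)

  # move-type probabilities
  p_birth <- 0.15; p_death <- 0.15
  p_edge <- 0.075  # each of the four edge moves

  with_local_seed(cfg$seed, function() {
    # initial state
    z0 <- as.integer(y[1] > median(y))
    s <- numeric(0)
    q <- quantile(y, c(0.1, 0.9))
    b_off <- max(0.05 * tau_scale, 1e-3)
    d_b <- max(tau_scale * 0.5, 1e-3)
    sigma <- max(0.2 * sd(y), 1e-6)
    m0 <- max(y[1] * kin$delta_p / kin$alpha, 1e-3)
    p0 <- max(y[1], 1e-3)
    ll <- ll_fun(s, z0, b_off, d_b, sigma, m0, p0)

    n_keep <- floor((cfg$iterations - cfg$burn_in) / cfg$thin)
    samp <- matrix(NA_real_, n_keep, 7,
                   dimnames = list(NULL, c("k", "z0", "b_off", "b_on",
                                           "sigma", "m0", "p0")))
    stimes <- vector("list", n_keep)
    acc <- c(rj = 0, shift = 0, flip = 0, level = 0, sigma = 0, init = 0)
    prop <- acc
    ikeep <- 0L

    for (it in seq_len(cfg$iterations)) {
      # --- reversible-jump moves (3 attempts per sweep) ---
      for (rep_rj in 1:3) {
        u <- runif(1)
        k <- length(s)
        if (u < p_birth) {                       # pair birth
          prop["rj"] <- prop["rj"] + 1
          if (k + 2 <= kmax) {
            pts <- sort(runif(2, 0, t_end))
            iv1 <- findInterval(pts[1], s)
            iv2 <- findInterval(pts[2], s)
            if (iv1 == iv2) {
              s_new <- sort(c(s, pts))
              ll_new <- ll_fun(s_new, z0, b_off, d_b, sigma, m0, p0)
              lacc <- (ll_new - ll) +
                (lp_switch(k + 2, lambda, t_end) -
                   lp_switch(k, lambda, t_end)) +
                log(p_death / (k + 1)) - log(p_birth * 2 / t_end^2)
              if (log(runif(1)) < lacc) {
                s <- s_new; ll <- ll_new; acc["rj"] <- acc["rj"] + 1
              }
            }
          }
        } else if (u < p_birth + p_death) {      # pair death
          prop["rj"] <- prop["rj"] + 1
          if (k >= 2) {
            i <- sample.int(k - 1, 1)
            s_new <- s[-c(i, i + 1)]
            ll_new <- ll_fun(s_new, z0, b_off, d_b, sigma, m0, p0)
            lacc <- (ll_new - ll) +
              (lp_switch(k - 2, lambda, t_end) -
                 lp_switch(k, lambda, t_end)) +
              log(p_birth * 2 / t_end^2) - log(p_death / (k - 1))
            if (log(runif(1)) < lacc) {
              s <- s_new; ll <- ll_new; acc["rj"] <- acc["rj"] + 1
            }
          }
        } else if (u < p_birth + p_death + 4 * p_edge) {  # edge moves
          prop["rj"] <- prop["rj"] + 1
          mv <- floor((u - p_birth - p_death) / p_edge)   # 0..3
          if (mv == 0 && k + 1 <= kmax) {        # add-front (flip z0)
            smin <- if (k > 0) s[1] else t_end
            snew <- runif(1, 0, smin)
            s_new <- c(snew, s); z_new <- 1L - z0
            ll_new <- ll_fun(s_new, z_new, b_off, d_b, sigma, m0, p0)
            lacc <- (ll_new - ll) +
              (lp_switch(k + 1, lambda, t_end) - lp_switch(k, lambda, t_end)) +
              log(p_edge) - log(p_edge / smin)
            if (log(runif(1)) < lacc) {
              s <- s_new; z0 <- z_new; ll <- ll_new; acc["rj"] <- acc["rj"] + 1
            }
          } else if (mv == 1 && k >= 1) {        # del-front (flip z0)
            s_new <- s[-1]; z_new <- 1L - z0
            smin_after <- if (k >= 2) s[2] else t_end
            ll_new <- ll_fun(s_new, z_new, b_off, d_b, sigma, m0, p0)
            lacc <- (ll_new - ll) +
              (lp_switch(k - 1, lambda, t_end) - lp_switch(k, lambda, t_end)) +
              log(p_edge / smin_after) - log(p_edge)
            if (log(runif(1)) < lacc) {
              s <- s_new; z0 <- z_new; ll <- ll_new; acc["rj"] <- acc["rj"] + 1
            }
          } else if (mv == 2 && k + 1 <= kmax) { # add-end
            smax <- if (k > 0) s[k] else 0
            snew <- runif(1, smax, t_end)
            s_new <- c(s, snew)
            ll_new <- ll_fun(s_new, z0, b_off, d_b, sigma, m0, p0)
            lacc <- (ll_new - ll) +
              (lp_switch(k + 1, lambda, t_end) - lp_switch(k, lambda, t_end)) +
              log(p_edge) - log(p_edge / (t_end - smax))
            if (log(runif(1)) < lacc) {
              s <- s_new; ll <- ll_new; acc["rj"] <- acc["rj"] + 1
            }
          } else if (mv == 3 && k >= 1) {        # del-end
            s_new <- s[-k]
            smax_after <- if (k >= 2) s[k - 1] else 0
            ll_new <- ll_fun(s_new, z0, b_off, d_b, sigma, m0, p0)
            lacc <- (ll_new - ll) +
              (lp_switch(k - 1, lambda, t_end) - lp_switch(k, lambda, t_end)) +
              log(p_edge / (t_end - smax_after)) - log(p_edge)
            if (log(runif(1)) < lacc) {
              s <- s_new; ll <- ll_new; acc["rj"] <- acc["rj"] + 1
            }
          }
        }
      }

      # --- switch-time shifts ---
      k <- length(s)
      if (k > 0) for (rep_sh in 1:2) {
        prop["shift"] <- prop["shift"] + 1
        i <- sample.int(k, 1)
        snew <- s[i] + rnorm(1, 0, cfg$shift_scale)
        lo <- if (i > 1) s[i - 1] else 0
        hi <- if (i < k) s[i + 1] else t_end
        if (snew > lo && snew < hi) {
          s_new <- s; s_new[i] <- snew
          ll_new <- ll_fun(s_new, z0, b_off, d_b, sigma, m0, p0)
          if (log(runif(1)) < ll_new - ll) {
            s <- s_new; ll <- ll_new; acc["shift"] <- acc["shift"] + 1
          }
        }
      }

      # --- initial-state flip ---
      prop["flip"] <- prop["flip"] + 1
      ll_new <- ll_fun(s, 1L - z0, b_off, d_b, sigma, m0, p0)
      if (log(runif(1)) < ll_new - ll) {
        z0 <- 1L - z0; ll <- ll_new; acc["flip"] <- acc["flip"] + 1
      }

      # --- level updates (reflected random walks) ---
      prop["level"] <- prop["level"] + 1
      b_new <- abs(b_off + rnorm(1, 0, prop_level))
      d_new <- abs(d_b + rnorm(1, 0, prop_level))
      ll_new <- ll_fun(s, z0, b_new, d_new, sigma, m0, p0)
      lacc <- (ll_new - ll) + lp_levels(b_new, d_new) - lp_levels(b_off, d_b)
      if (log(runif(1)) < lacc) {
        b_off <- b_new; d_b <- d_new; ll <- ll_new
        acc["level"] <- acc["level"] + 1
      }

      # --- noise SD (log random walk) ---
      prop["sigma"] <- prop["sigma"] + 1
      sig_new <- sigma * exp(rnorm(1, 0, cfg$sigma_scale))
      ll_new <- ll_fun(s, z0, b_off, d_b, sig_new, m0, p0)
      lacc <- (ll_new - ll) + lp_sigma(sig_new) - lp_sigma(sigma) +
        log(sig_new) - log(sigma)
      if (log(runif(1)) < lacc) {
        sigma <- sig_new; ll <- ll_new; acc["sigma"] <- acc["sigma"] + 1
      }

      # --- initial conditions ---
      prop["init"] <- prop["init"] + 1
      m_new <- abs(m0 + rnorm(1, 0, prop_m0))
      p_new <- abs(p0 + rnorm(1, 0, prop_p0))
      ll_new <- ll_fun(s, z0, b_off, d_b, sigma, m_new, p_new)
      lacc <- (ll_new - ll) + lp_init(m_new, p_new) - lp_init(m0, p0)
      if (log(runif(1)) < lacc) {
        m0 <- m_new; p0 <- p_new; ll <- ll_new; acc["init"] <- acc["init"] + 1
      }

      # --- store ---
      if (it > cfg$burn_in && (it - cfg$burn_in) %% cfg$thin == 0) {
        ikeep <- ikeep + 1L
        samp[ikeep, ] <- c(length(s), z0, b_off, b_off + d_b, sigma, m0, p0)
        stimes[[ikeep]] <- s
      }
    }

    samples <- as.data.frame(samp[seq_len(ikeep), , drop = FALSE])
    flags <- character(0)
    rates <- acc / pmax(prop, 1)
    # the flip move is excluded: once the data pin the state sequence its
    # acceptance is legitimately near zero
    if (mean(rates[c("rj", "shift", "level", "sigma", "init")]) < 0.01)
      flags <- c(flags, "low-acceptance")
    kmode <- as.integer(names(which.max(table(samples$k))))
    if (kmode == kmax) flags <- c(flags, "k-at-max")
    if (length(flags))
      warning("switch MCMC convergence heuristics flagged: ",
              paste(flags, collapse = ", "), call. = FALSE)
    structure(list(samples = samples, switch_times = stimes[seq_len(ikeep)],
                   acceptance = rates, t_end = t_end,
                   t_offset = trace$times[1], kin = kin,
                   cell_id = trace$cell_id, cfg = cfg,
                   warning_flags = flags),
              class = "switch_posterior")
  })
}

#' @export
print.switch_posterior <- function(x, ...) {
  kmode <- as.integer(names(which.max(table(x$samples$k))))
  cat(sprintf(
    "<switch_posterior> cell %s: %d retained samples, modal k = %d%s\n",
    x$cell_id, nrow(x$samples), kmode,
    if (length(x$warning_flags))
      paste0(" [", paste(x$warning_flags, collapse = ","), "]") else ""))
  invisible(x)
}

# modal (k, z0) combination of a posterior
modal_config <- function(post) {
  key <- paste(post$samples$k, post$samples$z0)
  mk <- names(which.max(table(key)))
  parts <- as.integer(strsplit(mk, " ")[[1]])
  list(k = parts[1], z0 = parts[2],
       idx = which(key == mk))
}

#' Remove weak switches from a posterior
#'
#' Two cleaning rules, applied to every retained sample:
#' \enumerate{
#' \item \emph{Excursion rule}: an interior interval of length `d` bounded
#'   by two switches perturbs the observed protein trajectory by roughly
#'   `|b_on - b_off| * (1 - exp(-delta_m * d)) * (1 - exp(-delta_p * d))`
#'   relative to a sustained level change (the excursion is attenuated
#'   twice, once per kinetic stage); the pair is deleted when this
#'   observable excursion falls below `threshold *` the posterior-median
#'   level difference.
#' \item \emph{Inclusion rule}: the posterior state-occupancy probability
#'   `p_on(t)` is computed across all samples; an interior interval whose
#'   state is supported by less than `min_inclusion` of the posterior mass
#'   at its midpoint is a transient excursion of the sampler, and its
#'   bounding switch pair is deleted.
#' }
#' Deleting a pair re-merges the flanking same-state intervals.
#'
#' @param post A `switch_posterior`.
#' @param threshold Fraction of the posterior-median level difference
#'   (default from the fitting config; 0 disables the excursion rule).
#' @param min_inclusion Minimum posterior inclusion probability (default
#'   0.5; 0 disables the inclusion rule).
#' @return A `switch_posterior` with cleaned samples.
#' @export
remove_weak_switches <- function(post, threshold = NULL,
                                 min_inclusion = 0.5) {
  stopifnot(inherits(post, "switch_posterior"))
  if (is.null(threshold)) threshold <- post$cfg$weak_switch_threshold
  if (threshold <= 0 && min_inclusion <= 0) return(post)
  amp_med <- median(post$samples$b_on - post$samples$b_off)
  dm <- post$kin$delta_m
  dp <- post$kin$delta_p
  n_samp <- nrow(post$samples)
  # posterior on-occupancy across samples on a fine grid
  grid <- seq(0, post$t_end, by = 0.05)
  occ_on <- if (min_inclusion > 0) {
    on_mat <- vapply(seq_len(n_samp), function(i) {
      j <- findInterval(grid, post$switch_times[[i]])
      (j %% 2 == 0) == (post$samples$z0[i] == 1)
    }, logical(length(grid)))
    rowMeans(on_mat)
  } else NULL
  for (i in seq_len(n_samp)) {
    s <- post$switch_times[[i]]
    amp <- post$samples$b_on[i] - post$samples$b_off[i]
    z0 <- post$samples$z0[i]
    repeat {
      k <- length(s)
      if (k < 2) break
      durs <- diff(s)                         # interior intervals j=1..k-1
      weak <- rep(FALSE, k - 1)
      if (threshold > 0)
        weak <- weak | (amp * (1 - exp(-dm * durs)) *
                          (1 - exp(-dp * durs)) < threshold * amp_med)
      if (min_inclusion > 0) {
        mids <- (s[-k] + s[-1]) / 2
        on_state <- (seq_len(k - 1) %% 2 == 0) == (z0 == 1)
        p_mid <- occ_on[pmin(length(grid),
                             pmax(1, round(mids / 0.05) + 1))]
        incl <- ifelse(on_state, p_mid, 1 - p_mid)
        weak <- weak | (incl < min_inclusion)
      }
      if (!any(weak)) break
      j <- which(weak)[which.min(durs[weak])]
      s <- s[-c(j, j + 1)]
    }
    if (length(s) != length(post$switch_times[[i]])) {
      post$switch_times[[i]] <- s
      post$samples$k[i] <- length(s)
    }
  }
  post
}

#' Extract on/off durations and cycle periods from a switch posterior
#'
#' Conditional on the modal (number of switches, initial state)
#' configuration, the point estimate of each switch time is its marginal
#' posterior mean (or the maximum a posteriori sample). Durations of the
#' censored boundary intervals (cut by the start or end of the record) are
#' excluded; the on-to-on cycle period is the difference between successive
#' onsets of the on state.
#'
#' In addition to the first and last intervals, any interval bounded by a
#' switch lying within `boundary_guard` hours of the start or end of the
#' record is treated as censored: such a switch is constrained by at most
#' one observation and its timing is unreliable.
#'
#' @param post A `switch_posterior`.
#' @param estimator `"posterior-mean"` (default) or `"MAP"`.
#' @param boundary_guard Width (hours) of the unreliable zone at each end
#'   of the record (default 1).
#' @return Object of class `duration_set`: list with `on_durations`,
#'   `off_durations`, `periods` (hours), `switch_times`, `initial_state`,
#'   `cell_id`.
#' @export
extract_durations <- function(post, estimator = c("posterior-mean", "MAP"),
                              boundary_guard = 1) {
  stopifnot(inherits(post, "switch_posterior"))
  estimator <- match.arg(estimator)
  mc <- modal_config(post)
  empty <- structure(list(on_durations = numeric(0),
                          off_durations = numeric(0),
                          periods = numeric(0),
                          switch_times = numeric(0),
                          initial_state = if (mc$z0 == 1) "on" else "off",
                          cell_id = post$cell_id),
                     class = "duration_set")
  if (mc$k < 2) return(empty)
  mat <- do.call(rbind, post$switch_times[mc$idx])
  st <- if (estimator == "posterior-mean") colMeans(mat) else {
    # sample with the largest k-conditional posterior density is not stored;
    # use the member closest to the componentwise median as the MAP proxy
    med <- apply(mat, 2, median)
    mat[which.min(rowSums((mat - rep(med, each = nrow(mat)))^2)), ]
  }
  path <- switch_path(st, if (mc$z0 == 1) "on" else "off",
                      rate_on = 1, rate_off = 0, duration = post$t_end)
  iv <- path_intervals(path)
  guarded <- function(x) x <= boundary_guard | x >= post$t_end - boundary_guard
  iv$censored <- iv$censored | guarded(iv$start) | guarded(iv$end)
  complete <- iv[!iv$censored, , drop = FALSE]
  dur <- complete$end - complete$start
  onsets <- iv$start[iv$state == "on" & iv$start > 0 &
                       !guarded(iv$start)]
  structure(list(on_durations = dur[complete$state == "on"],
                 off_durations = dur[complete$state == "off"],
                 periods = if (length(onsets) >= 2) diff(onsets)
                           else numeric(0),
                 switch_times = st,
                 initial_state = if (mc$z0 == 1) "on" else "off",
                 cell_id = post$cell_id),
            class = "duration_set")
}

#' @export
print.duration_set <- function(x, ...) {
  cat(sprintf(
    "<duration_set> cell %s: %d on, %d off, %d periods\n", x$cell_id,
    length(x$on_durations), length(x$off_durations), length(x$periods)))
  invisible(x)
}

#' Pooled posterior off-durations across samples
#'
#' Pools the complete (uncensored) off-durations implied by every retained
#' posterior sample, for population histogram analyses.
#'
#' @param post A `switch_posterior`.
#' @param boundary_guard As in [extract_durations()]: intervals bounded by
#'   a switch within this distance of the record edge are dropped.
#' @return Numeric vector of off-durations (hours).
#' @export
posterior_off_durations <- function(post, boundary_guard = 1) {
  lo <- boundary_guard; hi <- post$t_end - boundary_guard
  out <- lapply(seq_len(nrow(post$samples)), function(i) {
    s <- post$switch_times[[i]]
    if (length(s) < 2) return(numeric(0))
    z0 <- post$samples$z0[i]
    # interior interval j spans (s[j], s[j+1]); its state is off when
    # (j even) == (z0 == 1) in 1-based indexing after the first interval
    durs <- diff(s)
    ok <- s[-length(s)] >= lo & s[-1] <= hi
    states_on <- (seq_along(durs) %% 2 == 0) == (z0 == 1)
    durs[!states_on & ok]
  })
  unlist(out)
}

#' Association between on-durations and adjacent off-durations
#'
#' Pairs each on-duration with the subsequent (or preceding) off-duration
#' within a cell, pools the pairs across cells, and tests for rank
#' association by Spearman correlation with a permutation p-value.
#'
#' @param duration_sets List of `duration_set` objects (one per cell).
#' @param direction `"on-then-off"` (on vs subsequent off) or
#'   `"off-then-on"`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional seed.
#' @return List with `pairs` (data.frame `x`, `y`, `cell_id`), `rho`,
#'   `p_value`, `n`.
#' @export
duration_association <- function(duration_sets,
                                 direction = c("on-then-off",
                                               "off-then-on"),
                                 n_perm = 1000, seed = NULL) {
  direction <- match.arg(direction)
  pairs <- do.call(rbind, lapply(duration_sets, function(d) {
    iv <- adjacent_pairs(d, direction)
    if (is.null(iv) || nrow(iv) == 0) return(NULL)
    iv$cell_id <- d$cell_id
    iv
  }))
  if (is.null(pairs) || nrow(pairs) < 10)
    stop("need at least 10 duration pairs", call. = FALSE)
  rho <- suppressWarnings(cor(pairs$x, pairs$y, method = "spearman"))
  p <- with_local_seed(seed, function() {
    perm <- replicate(n_perm, suppressWarnings(
      cor(pairs$x, sample(pairs$y), method = "spearman")))
    (1 + sum(abs(perm) >= abs(rho))) / (n_perm + 1)
  })
  list(pairs = pairs, rho = rho, p_value = p, n = nrow(pairs))
}

# reconstruct the interval sequence of a duration_set's point path and
# return adjacent (on, off) or (off, on) complete pairs
adjacent_pairs <- function(d, direction) {
  st <- d$switch_times
  if (length(st) < 2) return(NULL)
  n_int <- length(st) + 1
  states <- rep(c(d$initial_state,
                  setdiff(c("on", "off"), d$initial_state)),
                length.out = n_int)
  bounds <- c(0, st, Inf)
  durs <- diff(bounds)
  complete <- seq_len(n_int) > 1 & seq_len(n_int) < n_int
  first_state <- if (direction == "on-then-off") "on" else "off"
  out <- NULL
  for (i in seq_len(n_int - 1)) {
    if (states[i] == first_state && complete[i] && complete[i + 1]) {
      out <- rbind(out, data.frame(x = durs[i], y = durs[i + 1]))
    }
  }
  out
}
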