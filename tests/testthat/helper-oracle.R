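# Independent brute-force integrator for the reporter ODE system.
# RK4 with a fine fixed step, restarted at every switch time so the
# discontinuities in tau(t) fall on step boundaries. Entirely separate from
# the closed-form propagator used by the package.
rk4_reporter <- function(path, kin, times, m0, p0, h = 0.001) {
  rhs <- function(t, y, tau) {
    c(tau - kin$delta_m * y[1], kin$alpha * y[1] - kin$delta_p * y[2])
  }
  bounds <- c(0, path$switch_times, path$duration)
  states <- rep(c(path$initial_state,
                  setdiff(c("on", "off"), path$initial_state)),
                length.out = length(bounds) - 1)
  y <- c(m0, p0)
  out <- numeric(length(times))
  t_cur <- 0
  for (seg in seq_along(states)) {
    t1 <- bounds[seg + 1]
    tau <- if (states[seg] == "on") path$rate_on else path$rate_off
    while (t_cur < t1 - 1e-12) {
      step <- min(h, t1 - t_cur)
      # record any requested times inside this step by dense-ish handling:
      # we simply land exactly on requested times
      nxt <- times[times > t_cur + 1e-12 & times <= t_cur + step + 1e-12]
      if (length(nxt)) step <- min(step, min(nxt) - t_cur)
      k1 <- rhs(t_cur, y, tau)
      k2 <- rhs(t_cur + step / 2, y + step / 2 * k1, tau)
      k3 <- rhs(t_cur + step / 2, y + step / 2 * k2, tau)
      k4 <- rhs(t_cur + step, y + step * k3, tau)
      y <- y + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t_cur <- t_cur + step
      hit <- which(abs(times - t_cur) < 1e-9)
      if (length(hit)) out[hit] <- y[2]
    }
  }
  if (any(abs(times) < 1e-12)) out[abs(times) < 1e-12] <- p0
  out
}

# deterministic protein values without noise, via the package path
noiseless_reporter <- function(path, kin, grid, m0 = NULL, p0 = NULL) {
  simulate_reporter(path, kin, noise_params(), grid, m0 = m0, p0 = p0)
}
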