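# Independent oracles and small utilities shared across the suite.

# Kept parameter set of the study system (one-decimal rounded estimates).
kept_params <- function(N = 4L, ...) behavioural_params(N = as.integer(N), ...)

# Renewal-theory moments of a single intermittent walker started stopped:
# two-state Markov velocity process with activation rate mu_A and stop rate
# mu_I, speed v. Mean is exact; the variance comes from quadrature of the
# velocity autocovariance (independent of any PDE or simulator code).
walker_moments_oracle <- function(t, v, mu_A, mu_I, n_grid = 2000) {
  lam <- mu_A + mu_I
  p <- mu_A / lam
  p_u <- function(u) p * (1 - exp(-lam * u))     # P(moving at u | stopped at 0)
  mean_x <- v * p * (t - (1 - exp(-lam * t)) / lam)
  u <- seq(0, t, length.out = n_grid)
  du <- u[2] - u[1]
  # E[x^2] = 2 v^2 int_0^t int_0^s P(m at u) P(m at s | m at u) du ds
  inner <- vapply(seq_along(u), function(i) {
    s <- u[i]
    if (i == 1L) return(0)
    uu <- u[1:i]
    sum(p_u(uu) * (p + (1 - p) * exp(-lam * (s - uu)))) * du
  }, numeric(1))
  ex2 <- 2 * v^2 * sum(inner) * du
  list(mean = mean_x, var = ex2 - mean_x^2)
}

# Total-variation distance between two samples/densities on common bins.
hist_density <- function(z, breaks) {
  lo <- breaks[1] + 1e-9
  hi <- breaks[length(breaks)] - 1e-9
  graphics::hist(pmin(pmax(z, lo), hi), breaks = breaks,
                 plot = FALSE)$density
}

tv_distance <- function(d1, d2, bin_width) 0.5 * sum(abs(d1 - d2)) * bin_width

# Normalized density of a kinetic snapshot interpolated at bin midpoints,
# relative to its own center of mass.
profile_density_at <- function(sol, mids) {
  eta <- sol$A[nrow(sol$A), ] + sol$I[nrow(sol$I), ]
  cm <- sum(eta * sol$x) / sum(eta)
  d <- approx(sol$x - cm, eta / (sum(eta) * sol$dx), xout = mids,
              rule = 2)$y
  d / (sum(d) * (mids[2] - mids[1]))
}

sech2 <- function(z) 1 / cosh(z)^2

# shift a discretized profile right by k cells (zero inflow)
shiftprof <- function(v, k) c(rep(0, k), v[seq_len(length(v) - k)])

# Exponential sojourn durations of walker 1 extracted from a finely
# sampled trajectory (durations in seconds, split by mode).
sojourns_from_traj <- function(traj, walker = 1L) {
  m <- traj$modes[, walker]
  dt <- traj$times[2] - traj$times[1]
  r <- rle(as.vector(m))
  # drop the censored first and last sojourns
  keep <- seq_along(r$lengths)[-c(1, length(r$lengths))]
  list(stopped = r$lengths[keep][r$values[keep] == 0] * dt,
       moving = r$lengths[keep][r$values[keep] == 1] * dt)
}
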