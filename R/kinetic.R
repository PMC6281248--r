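#' Discretized density field of moving and stopped walkers
#'
#' Holds the pair of densities `A(x)` (moving, sheep per m) and `I(x)`
#' (stopped) on a uniform grid. Total mass `integral(A + I) dx` is the
#' group size `N` and is conserved by the solver.
#'
#' @param x uniform grid of abscissae (m).
#' @param A,I non-negative densities per node (sheep m^-1).
#' @param t current time (s).
#' @return An object of class `density_field`.
#' @export
density_field <- function(x, A, I, t = 0) {
  stopifnot(length(x) == length(A), length(x) == length(I))
  dx <- diff(x)
  if (any(abs(dx - dx[1]) > 1e-9 * dx[1])) stop("grid must be uniform")
  if (any(A < 0) || any(I < 0)) stop("densities must be non-negative")
  structure(list(x = x, dx = dx[1], A = A, I = I, t = t,
                 N = sum(A + I) * dx[1]),
            class = "density_field")
}

#' @export
print.density_field <- function(x, ...) {
  cat(sprintf("density_field: %d nodes, dx = %g m, mass = %.6g, t = %g s\n",
              length(x$x), x$dx, x$N, x$t))
  invisible(x)
}

#' Gaussian initial density field
#'
#' Convenience constructor: total mass `N` split between the moving and
#' stopped pools in proportion `moving_fraction0`, spread as a Gaussian
#' bump of standard deviation `sd` centred at `center`.
#'
#' @param N total mass (group size).
#' @param x grid of abscissae (m).
#' @param center,sd bump location and width (m).
#' @param moving_fraction0 initial fraction of mass in the moving pool.
#' @return A [density_field()].
#' @export
gaussian_field <- function(N, x, center = 0, sd = 2, moving_fraction0 = 0) {
  dx <- x[2] - x[1]
  shape <- exp(-(x - center)^2 / (2 * sd^2))
  shape <- shape / (sum(shape) * dx) * N
  density_field(x, A = shape * moving_fraction0,
                I = shape * (1 - moving_fraction0))
}

kinetic_param_vec <- function(params) {
  list(mu_A = params$mu_A, mu_I = spontaneous_stop_rate(params),
       alpha_A = params$alpha_A, beta_A = params$beta_A,
       gamma_A = params$gamma_A, alpha_I = params$alpha_I,
       beta_I = params$beta_I, gamma_I = params$gamma_I,
       v = params$v, N = params$N)
}

#' Nonlocal activation and inactivation rate profiles
#'
#' The density counterpart of the individual switching rates: at abscissa
#' `x`, activation is stimulated by all moving mass ahead,
#' \deqn{K_A(x) = \mu_A + \alpha_A S_A(x)^{\beta_A} (N - S_A(x))^{-\gamma_A},
#'   \quad S_A(x) = \int_x^\infty A\,du,}
#' and inactivation by all stopped mass behind (mirror with
#' \eqn{\int_{-\infty}^x I\,du}). Integrals are right/left cumulative sums
#' on the grid including half of the focal cell; the inhibitory base
#' `N - S` is clamped below at 1, matching the microscopic convention that
#' the focal individual always counts in its own inhibitory pool (and
#' keeping the expression finite when all mass is stimulating).
#'
#' @param field a [density_field()].
#' @param params a [behavioural_params()] object.
#' @return List with numeric vectors `K_A` and `K_I` (s^-1).
#' @export
nonlocal_rates <- function(field, params) {
  if (any(field$A < 0) || any(field$I < 0))
    stop("negative densities in field")
  p <- kinetic_param_vec(params)
  .nonlocal_rates_cpp(field$A, field$I, field$dx, field$N,
                      p$mu_A, p$mu_I, p$alpha_A, p$beta_A, p$gamma_A,
                      p$alpha_I, p$beta_I, p$gamma_I)
}

#' One explicit time step of the kinetic equations
#'
#' First-order conservative upwind transport of the moving density `A` at
#' speed `v` towards positive `x` (zero flux through both ends), followed
#' by the reaction exchange `+K_A I - K_I A` applied to `A` and its
#' negative to `I`; total mass is conserved to round-off. Requires the
#' advection stability condition `v dt <= dx`.
#'
#' @param field a [density_field()].
#' @param params a [behavioural_params()] object.
#' @param dt time step (s).
#' @return The advanced [density_field()].
#' @export
kinetic_step <- function(field, params, dt) {
  p <- kinetic_param_vec(params)
  out <- .kinetic_run_cpp(field$A, field$I, field$dx, dt, 1L, 1L,
                          p$v, field$N, p$mu_A, p$mu_I,
                          p$alpha_A, p$beta_A, p$gamma_A,
                          p$alpha_I, p$beta_I, p$gamma_I)
  density_field(field$x, out$A[2, ], out$I[2, ], t = field$t + dt)
}

#' Solve the kinetic density equations
#'
#' Iterates [kinetic_step()] with the compiled core, recording snapshots
#' every `record_every` seconds, and asserts throughout that (i) total
#' mass stays within `1e-8 * N` of its initial value and (ii) the mass in
#' the outermost 5% of the domain stays below `tail_tol * N` (so the
#' static domain is effectively unbounded for the run).
#'
#' @param field initial [density_field()].
#' @param params a [behavioural_params()] object.
#' @param t_end final time (s).
#' @param dt time step (s); the stated scheme uses 1e-2 s.
#' @param record_every snapshot spacing (s); must be a multiple of `dt`.
#' @param tail_tol boundary tail-mass tolerance (fraction of `N`).
#' @return An object of class `kinetic_solution`: `times`, matrices `A`
#'   and `I` (snapshots x nodes), grid `x`, `params`.
#' @export
kinetic_solve <- function(field, params, t_end, dt = 1e-2,
                          record_every = 10, tail_tol = 1e-6) {
  stopifnot(t_end > 0, dt > 0)
  if (params$v * dt > field$dx * (1 + 1e-12))
    stop("stability condition v*dt <= dx violated")
  n_steps <- as.integer(round(t_end / dt))
  rec_steps <- max(1L, as.integer(round(record_every / dt)))
  p <- kinetic_param_vec(params)
  out <- .kinetic_run_cpp(field$A, field$I, field$dx, dt, n_steps,
                          rec_steps, p$v, field$N, p$mu_A, p$mu_I,
                          p$alpha_A, p$beta_A, p$gamma_A,
                          p$alpha_I, p$beta_I, p$gamma_I)
  dx <- field$dx
  mass <- rowSums(out$A + out$I) * dx
  if (any(abs(mass - field$N) > 1e-8 * field$N))
    stop("mass conservation violated: max deviation ",
         max(abs(mass - field$N)))
  edge <- max(2L, as.integer(round(2 / dx)))  # outermost 2 m on each side
  tot <- out$A + out$I
  tail_mass <- (rowSums(tot[, seq_len(edge), drop = FALSE]) +
                  rowSums(tot[, ncol(tot) - seq_len(edge) + 1L,
                              drop = FALSE])) * dx
  if (any(tail_mass > tail_tol * field$N))
    stop("tail mass exceeded tolerance: domain too small for this run")
  structure(list(times = out$times, A = out$A, I = out$I, x = field$x,
                 dx = dx, N = field$N, params = params),
            class = "kinetic_solution")
}

#' @export
print.kinetic_solution <- function(x, ...) {
  cat(sprintf("kinetic_solution: %d snapshots to t = %g s on %d nodes\n",
              length(x$times), max(x$times), length(x$x)))
  invisible(x)
}

#' Pulse observables of a kinetic solution
#'
#' From the recorded snapshots in `[t_min, max(t)]`: the moving fraction
#' `integral(A) / integral(A + I)`, the propagation speed (slope of a
#' linear fit of the center of mass against time), the peak position,
#' full width at half maximum and the signed asymmetry (mass left of the
#' peak minus mass right, as a fraction of total) of the final profile.
#' The pulse travels towards positive x, so a positive asymmetry means an
#' excess of density in the rear tail.
#'
#' @param sol a [kinetic_solve()] result.
#' @param t_min earliest snapshot used for the speed fit (s).
#' @return List with `moving_fraction`, `speed`, `peak_position`, `width`,
#'   `asymmetry`.
#' @export
pulse_metrics <- function(sol, t_min = 0) {
  keep <- sol$times >= t_min
  if (sum(keep) < 2L) stop("need at least two recorded fields for a speed")
  eta <- sol$A[keep, , drop = FALSE] + sol$I[keep, , drop = FALSE]
  mass <- rowSums(eta) * sol$dx
  if (any(mass <= 0)) stop("zero total mass in recorded field")
  cm <- as.vector(eta %*% sol$x) * sol$dx / mass
  tt <- sol$times[keep]
  speed <- unname(coef(lm(cm ~ tt))[2])
  A_last <- sol$A[nrow(sol$A), ]
  eta_last <- eta[nrow(eta), ]
  mf <- sum(A_last) / sum(eta_last)
  ipk <- which.max(eta_last)
  half <- eta_last[ipk] / 2
  above <- which(eta_last >= half)
  i1 <- min(above); i2 <- max(above)
  # sub-grid full width at half maximum by linear interpolation
  xL <- if (i1 > 1L) sol$x[i1 - 1L] + (half - eta_last[i1 - 1L]) /
    (eta_last[i1] - eta_last[i1 - 1L]) * sol$dx else sol$x[i1]
  xR <- if (i2 < length(eta_last)) sol$x[i2] + (eta_last[i2] - half) /
    (eta_last[i2] - eta_last[i2 + 1L]) * sol$dx else sol$x[i2]
  width <- xR - xL
  m_left <- sum(eta_last[seq_len(ipk - 1)]) + eta_last[ipk] / 2
  m_right <- sum(eta_last[ipk:length(eta_last)]) - eta_last[ipk] / 2
  list(moving_fraction = mf, speed = speed,
       peak_position = sol$x[ipk], width = width,
       asymmetry = (m_left - m_right) / sum(eta_last))
}

#' Finite-group presence histogram sampled from a density profile
#'
#' Emulates the observable computed from stochastic group realizations:
#' draws `n_samples` groups of `group_size` positions i.i.d. from the
#' (normalized) profile, re-centers each group on its own mean, and pools
#' all centered positions. For small groups the sampled center of mass is
#' itself noisy, which symmetrizes the pooled histogram relative to the
#' underlying profile — the finite-size correction needed to compare a
#' continuum profile with small-group data.
#'
#' @param x grid of abscissae (m).
#' @param density non-negative profile on `x` (any normalization).
#' @param group_size positions per sampled group.
#' @param n_samples number of groups.
#' @param seed optional integer seed.
#' @return Numeric vector of `group_size * n_samples` centered positions.
#' @export
sample_groups_from_profile <- function(x, density, group_size, n_samples,
                                       seed = NULL) {
  stopifnot(all(density >= 0), sum(density) > 0)
  if (!is.null(seed)) set.seed(seed)
  dx <- x[2] - x[1]
  n_tot <- group_size * n_samples
  idx <- sample.int(length(x), n_tot, replace = TRUE,
                    prob = density / sum(density))
  pos <- x[idx] + runif(n_tot, -dx / 2, dx / 2)
  g <- matrix(pos, nrow = group_size)
  as.vector(sweep(g, 2, colMeans(g)))
}
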