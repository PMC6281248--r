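#' Partition a focal walker's group-mates into the four reaction pools
#'
#' "Ahead" means strictly greater abscissa; exact position ties are broken
#' by walker index, the lower index counting as behind. This deterministic
#' rule makes replays order-independent.
#'
#' @param focal index (1-based) of the focal walker.
#' @param positions numeric vector of abscissae (m).
#' @param modes integer vector of modes (0 = stopped, 1 = moving).
#' @return A [neighbourhood_counts()] object.
#' @export
partition_neighbours <- function(focal, positions, modes) {
  N <- length(positions)
  stopifnot(length(modes) == N, focal >= 1, focal <= N)
  if (N == 1L) return(neighbourhood_counts(N = 1L))
  others <- setdiff(seq_len(N), focal)
  ahead <- positions[others] > positions[focal] |
    (positions[others] == positions[focal] & others > focal)
  moving <- modes[others] == 1L
  neighbourhood_counts(A_plus = sum(moving & ahead),
                       A_minus = sum(moving & !ahead),
                       I_plus = sum(!moving & ahead),
                       I_minus = sum(!moving & !ahead),
                       N = N)
}

#' Per-walker switching rates for a full group state
#'
#' For each walker, the activation rate if it is stopped or the
#' inactivation rate if it is moving, given everybody's positions and
#' modes. This is the quantity the event-driven simulator recomputes after
#' every switching or overtaking event.
#'
#' @inheritParams partition_neighbours
#' @param params a [behavioural_params()] object with `N == length(positions)`.
#' @param use_cpp use the compiled kernel (default) or the plain R path
#'   built on [partition_neighbours()]; both must agree exactly.
#' @return Numeric vector of rates (s^-1).
#' @export
switching_rates <- function(positions, modes, params, use_cpp = TRUE) {
  stopifnot(params$N == length(positions))
  if (use_cpp) {
    return(.ibm_rates_cpp(as.numeric(positions), as.integer(modes),
                          params$mu_A, spontaneous_stop_rate(params),
                          params$alpha_A, params$beta_A, params$gamma_A,
                          params$alpha_I, params$beta_I, params$gamma_I,
                          params$focal_in_base))
  }
  vapply(seq_along(positions), function(f) {
    cts <- partition_neighbours(f, positions, modes)
    if (modes[f] == 0L) activation_rate(cts, params)
    else inactivation_rate(cts, params)
  }, numeric(1))
}

#' Exact event-driven simulation of coupled intermittent walkers
#'
#' Simulates the continuous-time Markov process of `N` walkers on a line
#' whose per-walker switching rates are [activation_rate()] /
#' [inactivation_rate()] evaluated on the behind/ahead state partition.
#' Rates are piecewise constant between switching events and overtaking
#' instants (a mover's abscissa crossing a stopped walker's); at every such
#' instant all rates are recomputed and waiting times redrawn, which keeps
#' the realization statistically exact (memorylessness). Moving walkers
#' advance at exactly `v` between events; stopped walkers are fixed.
#'
#' @param params a [behavioural_params()] object.
#' @param t_max simulated duration (s).
#' @param record_interval sampling period of the returned trajectory (s).
#' @param seed optional integer seed (recorded in the output).
#' @param positions0,modes0 initial condition; defaults to all walkers
#'   stopped at i.i.d. uniform positions on a 1 m segment (a dense grazing
#'   start).
#' @return An object of class `group_trajectory`: list with `times`
#'   (length-T vector, s), `positions` (T x N matrix, m), `modes` (T x N
#'   0/1 matrix), event counters, `params` and `seed`.
#' @examples
#' traj <- run_gillespie(behavioural_params(N = 4), t_max = 200, seed = 1)
#' group_statistics(traj)$dispersion[nrow(traj$positions)]
#' @export
run_gillespie <- function(params, t_max, record_interval = 1, seed = NULL,
                          positions0 = NULL, modes0 = NULL) {
  stopifnot(t_max > 0, record_interval > 0)
  if (!is.null(seed)) set.seed(seed)
  N <- params$N
  if (is.null(positions0)) positions0 <- runif(N, 0, 1)
  if (is.null(modes0)) modes0 <- rep(0L, N)
  stopifnot(length(positions0) == N, length(modes0) == N,
            all(modes0 %in% c(0L, 1L)))
  out <- .gillespie_cpp(as.numeric(positions0), as.integer(modes0),
                        t_max, record_interval, params$v,
                        params$mu_A, spontaneous_stop_rate(params),
                        params$alpha_A, params$beta_A, params$gamma_A,
                        params$alpha_I, params$beta_I, params$gamma_I,
                        params$focal_in_base)
  structure(list(times = out$times, positions = out$positions,
                 modes = out$modes, n_switches = out$n_switches,
                 n_crossings = out$n_crossings, params = params,
                 seed = seed),
            class = "group_trajectory")
}

#' @export
print.group_trajectory <- function(x, ...) {
  cat(sprintf("group_trajectory: N = %d walkers, %d samples over %.6g s (%g switches, %g overtakings)\n",
              ncol(x$positions), length(x$times), max(x$times),
              x$n_switches, x$n_crossings))
  invisible(x)
}

#' Tidy data frame view of a trajectory
#'
#' @param x a `group_trajectory`.
#' @param ... unused.
#' @return Data frame with columns `time_s`, `walker_id`, `position_m`,
#'   `mode`.
#' @export
as.data.frame.group_trajectory <- function(x, ...) {
  N <- ncol(x$positions)
  data.frame(time_s = rep(x$times, N),
             walker_id = rep(seq_len(N), each = length(x$times)),
             position_m = as.vector(x$positions),
             mode = as.vector(x$modes))
}

#' Group-level summary statistics of a trajectory
#'
#' Computes (i) the internal dispersion, the range of positions divided by
#' `N - 1` (mean distance between abscissa-neighbours, m per sheep), at
#' every recorded time; (ii) the cumulative distance walked by the group
#' center of mass; (iii) the mean group speed (total CM path length over
#' elapsed time); and (iv) the pooled positions relative to the CM, the raw
#' material of presence histograms.
#'
#' @param traj a `group_trajectory`.
#' @param at_times optional times (s) at which to report dispersion; values
#'   are matched to the nearest recorded sample.
#' @return List with elements `times`, `dispersion`, `cm`,
#'   `distance_walked`, `mean_speed` and `rel_positions` (T x N matrix).
#' @export
group_statistics <- function(traj, at_times = NULL) {
  pos <- traj$positions
  N <- ncol(pos)
  if (N < 2L)
    stop("internal dispersion is undefined for a single walker (N = 1)")
  disp <- (apply(pos, 1, max) - apply(pos, 1, min)) / (N - 1)
  cm <- rowMeans(pos)
  dist_walked <- c(0, cumsum(abs(diff(cm))))
  elapsed <- max(traj$times) - min(traj$times)
  mean_speed <- if (elapsed > 0) dist_walked[length(dist_walked)] / elapsed else 0
  res <- list(times = traj$times, dispersion = disp, cm = cm,
              distance_walked = dist_walked, mean_speed = mean_speed,
              rel_positions = pos - cm)
  if (!is.null(at_times)) {
    idx <- vapply(at_times, function(t) which.min(abs(traj$times - t)),
                  integer(1))
    res$at <- data.frame(time_s = traj$times[idx],
                         dispersion = disp[idx],
                         distance_walked = dist_walked[idx])
  }
  res
}

#' Dispersion versus imitation-strength modulation
#'
#' Rescales both imitation strengths `alpha_A`, `alpha_I` by each factor
#' (spontaneous rates held fixed), runs `n_reps` stochastic realizations
#' per factor and reports the mean internal dispersion at `t_eval`. Sweeps
#' the transition from diffusion-dominated spreading (factor -> 0) to tight
#' packing (factor -> infinity).
#'
#' @param params a [behavioural_params()] object.
#' @param factors positive multiplicative factors applied to both alphas.
#' @param n_reps realizations per factor.
#' @param t_eval evaluation time (s).
#' @param seed optional integer seed.
#' @return Data frame with columns `factor`, `mean_dispersion`, `se`.
#' @export
modulation_scan <- function(params, factors, n_reps = 100, t_eval = 1000,
                            seed = NULL) {
  stopifnot(all(factors > 0))
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(factors, function(f) {
    p <- params
    p$alpha_A <- params$alpha_A * f
    p$alpha_I <- params$alpha_I * f
    d <- vapply(seq_len(n_reps), function(i) {
      traj <- run_gillespie(p, t_max = t_eval, record_interval = t_eval)
      pos <- traj$positions[nrow(traj$positions), ]
      (max(pos) - min(pos)) / (p$N - 1)
    }, numeric(1))
    data.frame(factor = f, mean_dispersion = mean(d),
               se = sd(d) / sqrt(n_reps))
  })
  do.call(rbind, rows)
}
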