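#' Specification of a synthetic field-tracking campaign
#'
#' Describes the 1-Hz 2D tracking tables the generator emulates: the study
#' design (group sizes 2, 3, 4 and 8 with 8 replicate groups each, 1800 s
#' per recording, one position per second), the two-mode motion (grazing
#' jitter of order 0.1 m/s versus walking at `v`), and isotropic
#' positional measurement noise.
#'
#' @param group_sizes recorded group sizes.
#' @param n_replicates groups per size.
#' @param duration recording duration (s).
#' @param sample_period sampling period (s).
#' @param grazing_speed characteristic speed of grazing micro-moves
#'   (m s^-1); kept below the binarization threshold by construction.
#' @param noise_sd isotropic positional measurement noise (m, per axis).
#' @param heading_range half-range (radians) of the uniform heading change
#'   drawn at each new collective bout.
#' @param params a [behavioural_params()] object driving the walkers
#'   (its `N` is overridden per group).
#' @param seed integer seed.
#' @return An object of class `field_track_spec`.
#' @export
field_track_spec <- function(group_sizes = c(2L, 3L, 4L, 8L),
                             n_replicates = 8L, duration = 1800,
                             sample_period = 1, grazing_speed = 0.1,
                             noise_sd = 0.05, heading_range = pi / 3,
                             params = behavioural_params(), seed = 1L) {
  stopifnot(sample_period > 0, duration > 0, grazing_speed >= 0,
            noise_sd >= 0, all(group_sizes >= 1))
  structure(list(group_sizes = as.integer(group_sizes),
                 n_replicates = as.integer(n_replicates),
                 duration = duration, sample_period = sample_period,
                 grazing_speed = grazing_speed, noise_sd = noise_sd,
                 heading_range = heading_range, params = params,
                 seed = as.integer(seed)),
            class = "field_track_spec")
}

# Piecewise-straight embedding of 1D abscissae into the plane: one fresh
# heading per collective bout, knots at the group CM abscissa at each bout
# start.
embed_abscissae <- function(S, modes, heading_range) {
  Tn <- nrow(S)
  nmov <- rowSums(modes)
  bout_start <- which(nmov > 0 & c(TRUE, nmov[-Tn] == 0))
  knots <- unique(c(min(S) - 1, sort(rowMeans(S)[bout_start])))
  knots <- knots[c(TRUE, diff(knots) > 1e-9)]
  nseg <- length(knots)
  theta <- numeric(nseg)
  theta[1] <- runif(1, -pi, pi)
  if (nseg > 1)
    theta[-1] <- theta[1] + cumsum(runif(nseg - 1, -heading_range,
                                         heading_range))
  # vertex of segment k at abscissa knots[k]
  vx <- c(0, cumsum(cos(theta[-nseg]) * diff(knots)))
  vy <- c(0, cumsum(sin(theta[-nseg]) * diff(knots)))
  seg <- pmin(findInterval(S, knots), nseg)
  ds <- S - knots[seg]
  list(x = matrix(vx[seg] + cos(theta[seg]) * ds, Tn),
       y = matrix(vy[seg] + sin(theta[seg]) * ds, Tn))
}

#' Generate synthetic 2D field tracking tables
#'
#' Runs the event-driven simulator for every group in the spec, embeds the
#' resulting 1D abscissae into the plane along a piecewise-straight path
#' (one fresh heading per collective bout), superimposes grazing-state
#' jitter (independent isotropic offsets scaled so apparent grazing speeds
#' are of order `grazing_speed`) and isotropic measurement noise, and
#' returns tables in the exact schema the inference pipeline reads. With
#' zero jitter and noise and a single heading, [project_to_curvilinear()]
#' inverts the embedding up to the path origin.
#'
#' @param spec a [field_track_spec()].
#' @return Data frame with columns `time_s`, `sheep_id`, `x_m`, `y_m`,
#'   `group_id`, `group_size`.
#' @export
generate_field_tracks <- function(spec) {
  stopifnot(inherits(spec, "field_track_spec"))
  set.seed(spec$seed)
  out <- list()
  gid <- 0L
  for (N in spec$group_sizes) {
    for (rep_i in seq_len(spec$n_replicates)) {
      gid <- gid + 1L
      p <- spec$params
      p$N <- as.integer(N)
      traj <- run_gillespie(p, t_max = spec$duration,
                            record_interval = spec$sample_period)
      emb <- embed_abscissae(traj$positions, traj$modes,
                             spec$heading_range)
      Tn <- nrow(traj$positions)
      # grazing jitter: independent isotropic offsets while stopped; the
      # step between two offsets is Rayleigh with mean sd*sqrt(pi), so
      # per-axis sd = grazing_speed * sample_period / sqrt(pi) gives
      # apparent grazing speeds averaging grazing_speed
      jit_sd <- spec$grazing_speed * spec$sample_period / sqrt(pi)
      stopped <- traj$modes == 0L
      jx <- matrix(stats::rnorm(Tn * N, 0, jit_sd), Tn) * stopped
      jy <- matrix(stats::rnorm(Tn * N, 0, jit_sd), Tn) * stopped
      nx <- matrix(stats::rnorm(Tn * N, 0, spec$noise_sd), Tn)
      ny <- matrix(stats::rnorm(Tn * N, 0, spec$noise_sd), Tn)
      out[[gid]] <- data.frame(
        time_s = rep(traj$times, N),
        sheep_id = rep(seq_len(N), each = Tn),
        x_m = as.vector(emb$x + jx + nx),
        y_m = as.vector(emb$y + jy + ny),
        group_id = gid, group_size = N)
    }
  }
  do.call(rbind, out)
}

#' Generate a latency dataset from simulated cascades
#'
#' Departure and stop cascades are simulated with the purely temporal
#' cascade model for each requested group size, and converted to latency
#' records carrying their true `(W, R)` annotations — the cascade-level
#' fixture for the estimation pipeline.
#'
#' @param params a [behavioural_params()] object (its `N` is overridden).
#' @param n_events number of events per group size; either a single count
#'   or a vector named by group size (the study yielded 76/58/66/21
#'   departures for N = 2/3/4/8).
#' @param group_sizes group sizes to simulate.
#' @param kinds `"departure"`, `"stop"` or both.
#' @param seed optional integer seed.
#' @return Latency records (data frame) in the [extract_latencies()]
#'   schema.
#' @export
generate_latency_dataset <- function(params, n_events,
                                     group_sizes = c(2L, 3L, 4L, 8L),
                                     kinds = c("departure", "stop"),
                                     seed = NULL) {
  stopifnot(all(n_events >= 1))
  if (!is.null(seed)) set.seed(seed)
  if (length(n_events) == 1L)
    n_events <- setNames(rep(n_events, length(group_sizes)),
                         group_sizes)
  rows <- list()
  for (N in group_sizes) {
    p <- params
    p$N <- as.integer(N)
    ne <- n_events[[as.character(N)]]
    for (kind in kinds) {
      rec <- if (kind == "departure")
        simulate_departure_cascade(p, ne, latencies = TRUE)
      else simulate_stop_cascade(p, ne, latencies = TRUE)
      rows[[length(rows) + 1L]] <- rec
    }
  }
  do.call(rbind, rows)
}
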