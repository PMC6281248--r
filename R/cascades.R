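#' Simulate collective departure cascades
#'
#' Purely temporal simulation of the switching cascade that follows a first
#' spontaneous departure: one initiator is already walking (ahead of the
#' group, so it counts in every stopped walker's stimulating pool A+), the
#' other `N - 1` walkers are stopped, and positions are frozen for the
#' duration of the cascade. At the stage where `W` walkers are already
#' walking, each of the `R = N - W` stopped walkers switches independently
#' at rate \eqn{K_A(W) = \mu_A + \alpha_A W^{\beta_A} (N-W)^{-\gamma_A}},
#' so stage durations are exponential with rate `R * K_A(W)`. The cascade
#' duration runs from first start to last start.
#'
#' @param params a [behavioural_params()] object (`N >= 2`).
#' @param n_events number of independent cascades.
#' @param seed optional integer seed.
#' @param latencies if `TRUE`, return one row per follower switch with its
#'   following latency and the `(W, R)` context when its clock started;
#'   otherwise return the vector of cascade durations.
#' @return Numeric vector of durations (s), or a data frame with columns
#'   `event_id`, `latency`, `W`, `R`, `group_size`, `kind`.
#' @export
simulate_departure_cascade <- function(params, n_events = 1, seed = NULL,
                                       latencies = FALSE) {
  cascade_sim(params, n_events, seed, latencies, kind = "departure")
}

#' Simulate collective stop cascades
#'
#' Mirror of [simulate_departure_cascade()]: one initiator has stopped
#' (behind the group, counting in every mover's stimulating pool I-), the
#' other `N - 1` walkers are moving, positions frozen. At the stage where
#' `W` walkers are already stopped, each of the `R = N - W` movers stops at
#' rate \eqn{K_I(W) = \mu_I + \alpha_I W^{\beta_I} (N-W)^{-\gamma_I}} with
#' \eqn{\mu_I} = [spontaneous_stop_rate()]. Duration runs from first stop
#' to last stop.
#'
#' @inheritParams simulate_departure_cascade
#' @return As for [simulate_departure_cascade()].
#' @export
simulate_stop_cascade <- function(params, n_events = 1, seed = NULL,
                                  latencies = FALSE) {
  cascade_sim(params, n_events, seed, latencies, kind = "stop")
}

cascade_sim <- function(params, n_events, seed, latencies, kind) {
  N <- params$N
  if (N < 2L) stop("a cascade needs N >= 2")
  if (!is.null(seed)) set.seed(seed)
  mu <- if (kind == "departure") params$mu_A else spontaneous_stop_rate(params)
  alpha <- if (kind == "departure") params$alpha_A else params$alpha_I
  beta <- if (kind == "departure") params$beta_A else params$beta_I
  gamma <- if (kind == "departure") params$gamma_A else params$gamma_I
  W <- seq_len(N - 1L)               # already switched when each clock starts
  R <- N - W                         # still at risk
  base <- if (params$focal_in_base) N - W else pmax(N - 1L - W, 1L)
  k_rate <- mu + alpha * pow0(W, beta) * pow0(base, -gamma)
  stage_rate <- R * k_rate
  # one Exp draw per stage per event
  lat <- matrix(rexp(n_events * (N - 1L), rate = rep(stage_rate,
                                                     each = n_events)),
                nrow = n_events)
  if (!latencies) return(rowSums(lat))
  data.frame(event_id = rep(seq_len(n_events), times = N - 1L),
             latency = as.vector(lat),
             W = rep(W, each = n_events),
             R = rep(R, each = n_events),
             group_size = N,
             kind = kind)
}
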