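#' Binarize a speed series into stopped/moving modes
#'
#' A sample is "moving" when its speed strictly exceeds `threshold`
#' (grazing displacements of order 0.1 m/s fall below, walking of order
#' 1 m/s above). A debouncing pass then merges runs shorter than `min_run`
#' samples into the surrounding mode, removing single-sample flickers that
#' the 1-Hz sampling produces around transitions.
#'
#' @param speed non-negative speed series (m s^-1).
#' @param threshold binarization cut (m s^-1); default 0.3, the log-scale
#'   midpoint between the two characteristic speed modes.
#' @param min_run minimum run length (samples) surviving debouncing.
#' @return Integer vector of modes (0 = stopped, 1 = moving).
#' @export
binarize_speed <- function(speed, threshold = 0.3, min_run = 2L) {
  stopifnot(all(speed >= 0), threshold >= 0, min_run >= 1L)
  mode <- as.integer(speed > threshold)
  if (min_run <= 1L || length(mode) == 0L) return(mode)
  repeat {
    r <- rle(mode)
    if (length(r$lengths) <= 1L || all(r$lengths >= min_run)) break
    # flip the shortest offending run (earliest on ties) into the
    # surrounding mode, then re-examine
    short <- which(r$lengths < min_run)
    k <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths)
    idx <- (ends[k] - r$lengths[k] + 1L):ends[k]
    mode[idx] <- 1L - r$values[k]
  }
  mode
}

# Ramer-Douglas-Peucker simplification of a 2D polyline.
rdp_simplify <- function(x, y, tol) {
  n <- length(x)
  if (n <= 2L) return(cbind(x, y))
  keep <- rep(FALSE, n)
  keep[c(1L, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    if (j - i < 2L) next
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    len2 <- dx^2 + dy^2
    mid <- (i + 1L):(j - 1L)
    if (len2 < 1e-24) {
      d2 <- (x[mid] - x[i])^2 + (y[mid] - y[i])^2
    } else {
      # squared distance to the segment's supporting line
      d2 <- (dy * (x[mid] - x[i]) - dx * (y[mid] - y[i]))^2 / len2
    }
    k <- mid[which.max(d2)]
    if (max(d2) > tol^2) {
      keep[k] <- TRUE
      stack <- c(stack, list(c(i, k), c(k, j)))
    }
  }
  cbind(x[keep], y[keep])
}

# Arc-length abscissa of the orthogonal projection of points onto a
# polyline (vertices vx, vy). Ties go to the earliest segment; the first
# and last segments extend beyond their end vertices so walkers ahead of
# (or behind) the path ends keep meaningful abscissae.
project_onto_polyline <- function(px, py, vx, vy) {
  nseg <- length(vx) - 1L
  seg_dx <- diff(vx); seg_dy <- diff(vy)
  seg_len <- sqrt(seg_dx^2 + seg_dy^2)
  cum0 <- c(0, cumsum(seg_len))
  best_d2 <- rep(Inf, length(px))
  best_s <- rep(0, length(px))
  for (k in seq_len(nseg)) {
    if (seg_len[k] < 1e-12) next
    tt <- ((px - vx[k]) * seg_dx[k] + (py - vy[k]) * seg_dy[k]) / seg_len[k]^2
    tt <- pmin(pmax(tt, if (k == 1L) -Inf else 0),
               if (k == nseg) Inf else 1)
    qx <- vx[k] + tt * seg_dx[k]
    qy <- vy[k] + tt * seg_dy[k]
    d2 <- (px - qx)^2 + (py - qy)^2
    upd <- d2 < best_d2 - 1e-15
    best_s[upd] <- cum0[k] + tt[upd] * seg_len[k]
    best_d2[upd] <- d2[upd]
  }
  best_s
}

#' Project 2D tracks onto the group's curvilinear abscissa
#'
#' Reduces synchronized 2D tracks to 1D: builds the polyline of the group
#' center of mass over time, simplifies it to the multi-segment bout path
#' (Ramer-Douglas-Peucker, tolerance `simplify_tol`), and assigns each
#' walker at each time the arc length of the orthogonal projection of its
#' position onto that path. Abscissae increase in the direction of
#' collective travel; a degenerate (zero-length) path yields all-zero
#' abscissae.
#'
#' @param x,y T x N matrices of positions (m), rows synchronized in time.
#' @param simplify_tol path simplification tolerance (m).
#' @return T x N matrix of curvilinear abscissae (m), with the simplified
#'   path stored in attribute `"path"`.
#' @export
project_to_curvilinear <- function(x, y, simplify_tol = 0.5) {
  stopifnot(is.matrix(x), is.matrix(y), all(dim(x) == dim(y)))
  cmx <- rowMeans(x); cmy <- rowMeans(y)
  path <- rdp_simplify(cmx, cmy, simplify_tol)
  if (nrow(path) < 2L ||
      sum(sqrt(diff(path[, 1])^2 + diff(path[, 2])^2)) < 1e-12) {
    out <- matrix(0, nrow(x), ncol(x))
    attr(out, "path") <- path
    return(out)
  }
  s <- project_onto_polyline(as.vector(x), as.vector(y),
                             path[, 1], path[, 2])
  out <- matrix(s, nrow(x), ncol(x))
  attr(out, "path") <- path
  out
}

#' Detect collective departure and stop events in binary mode series
#'
#' A collective departure spans from the first stopped-to-moving switch
#' after an all-stopped period to the last walker's switch, provided the
#' whole group reaches the moving state before falling back; collective
#' stops are the mirror image. Events in which the initiator reverted to
#' its original state before the last follower had switched are flagged
#' invalid and excluded downstream, because the stimuli at work are then
#' not clearly determined.
#'
#' @param modes T x N matrix of 0/1 modes, rows synchronized in time.
#' @param times optional sample times (s); defaults to `0:(T-1)`.
#' @return An object of class `collective_events`: list of events, each
#'   with `kind` ("departure"/"stop"), per-walker `switch_times`,
#'   `initiator`, `start_time`, `end_time` and `valid`; the sampling
#'   interval is stored as attribute `"dt"`.
#' @export
detect_collective_events <- function(modes, times = NULL) {
  stopifnot(is.matrix(modes), all(modes %in% c(0L, 1L)))
  Tn <- nrow(modes); N <- ncol(modes)
  if (is.null(times)) times <- seq_len(Tn) - 1
  stopifnot(length(times) == Tn, all(diff(times) > 0))
  dt <- if (Tn > 1L) stats::median(diff(times)) else 1
  nmov <- rowSums(modes)
  events <- list()
  scan_kind <- function(from_val, to_val, target, kind) {
    anchors_from <- nmov == from_val
    out <- list()
    i <- 1L
    while (i <= Tn) {
      if (!anchors_from[i]) { i <- i + 1L; next }
      j <- i
      while (j < Tn && anchors_from[j + 1L]) j <- j + 1L
      # all-`from` run is [i, j]; look for completion before relapse
      k <- j + 1L
      complete <- NA_integer_
      while (k <= Tn) {
        if (nmov[k] == to_val) { complete <- k; break }
        if (nmov[k] == from_val) break
        k <- k + 1L
      }
      if (!is.na(complete)) {
        win <- (j + 1L):complete
        sw_idx <- vapply(seq_len(N), function(w) {
          win[match(TRUE, modes[win, w] == target)]
        }, integer(1))
        sw <- times[sw_idx]
        initiator <- which.min(sw_idx)
        # validity: the initiator must hold its new state until the last
        # follower has switched
        reverted <- any(modes[sw_idx[initiator]:max(sw_idx),
                              initiator] != target)
        out[[length(out) + 1L]] <-
          list(kind = kind, switch_times = sw, initiator = initiator,
               start_time = min(sw), end_time = max(sw),
               valid = !reverted)
      }
      i <- j + 1L
    }
    out
  }
  dep <- scan_kind(0L, N, 1L, "departure")
  stp <- scan_kind(N, 0L, 0L, "stop")
  events <- c(dep, stp)
  ord <- order(vapply(events, `[[`, numeric(1), "start_time"))
  events <- events[ord]
  attr(events, "dt") <- dt
  class(events) <- "collective_events"
  events
}

#' Following latencies from collective events
#'
#' One record per follower switch in each valid event: the time elapsed
#' between the previous individual's switch and this individual's switch,
#' annotated with the number `W` already in the event's target state and
#' the number `R` still at risk when the latency clock starts. Latencies
#' below the sampling resolution (ties at the same sample) are imputed at
#' half the sampling interval.
#'
#' @param events a [detect_collective_events()] result, or a list of such.
#' @param group_size group size `N` the events come from; defaults to the
#'   length of each event's `switch_times`.
#' @return Data frame with columns `event_id`, `latency`, `W`, `R`,
#'   `group_size`, `kind`.
#' @export
extract_latencies <- function(events, group_size = NULL) {
  dt <- attr(events, "dt")
  if (is.null(dt)) dt <- 1
  rows <- list()
  eid <- 0L
  for (ev in events) {
    if (!isTRUE(ev$valid)) next
    eid <- eid + 1L
    sw <- sort(ev$switch_times)
    N <- if (is.null(group_size)) length(sw) else group_size
    if (length(sw) < 2L) next
    lat <- diff(sw)
    lat[lat <= 0] <- dt / 2
    k <- seq_along(lat) + 1L
    rows[[eid]] <- data.frame(event_id = eid, latency = lat,
                              W = k - 1L, R = N - k + 1L,
                              group_size = N, kind = ev$kind)
  }
  if (!length(rows))
    return(data.frame(event_id = integer(), latency = numeric(),
                      W = integer(), R = integer(), group_size = integer(),
                      kind = character()))
  do.call(rbind, rows)
}

#' Following rates per (R, W) cell
#'
#' The following rate is the inverse of the mean latency in each cell,
#' corrected for the number of individuals at risk: with `R` candidates
#' racing to switch, the pooled waiting time has rate `R * f`, so the
#' per-individual rate is `f(R, W) = 1 / (R * mean latency)`. Cells with
#' fewer than `min_cell_count` latencies are dropped.
#'
#' @param records latency records as returned by [extract_latencies()] or
#'   the cascade simulators (columns `latency`, `W`, `R`).
#' @param min_cell_count minimum observations per retained cell.
#' @return Data frame with columns `R`, `W`, `f`, `n_obs`, `mean_latency`.
#' @export
following_rates <- function(records, min_cell_count = 3L) {
  if (!nrow(records)) stop("no latency records: cannot build a rate table")
  agg <- stats::aggregate(latency ~ R + W, data = records,
                          FUN = function(z) c(m = mean(z), n = length(z)))
  tab <- data.frame(R = agg$R, W = agg$W,
                    mean_latency = agg$latency[, "m"],
                    n_obs = as.integer(agg$latency[, "n"]))
  tab$f <- 1 / (tab$R * tab$mean_latency)
  tab <- tab[tab$n_obs >= min_cell_count, c("R", "W", "f", "n_obs",
                                            "mean_latency")]
  if (!nrow(tab)) stop("no (R, W) cell reaches min_cell_count")
  rownames(tab) <- NULL
  tab
}

mimetic_point_fit <- function(tab, weighted = FALSE) {
  if (length(unique(tab$W)) < 2L || length(unique(tab$R)) < 2L ||
      nrow(tab) < 4L)
    stop("rank-deficient design: need >= 4 cells spanning >= 2 values of ",
         "each of W and R")
  w <- if (weighted) tab$n_obs else NULL
  fit <- stats::lm(log(f) ~ log(W) + log(R), data = tab, weights = w)
  cf <- coef(fit)
  if (anyNA(cf)) stop("rank-deficient design: regression coefficients NA")
  list(alpha = exp(unname(cf[1])), beta = unname(cf[2]),
       gamma = -unname(cf[3]), r_squared = summary(fit)$r.squared,
       lm = fit)
}

#' Estimate imitation strength and exponents by log-domain regression
#'
#' Ordinary least squares of `log f` on `(log W, log R)` across the pooled
#' rate table: `alpha = exp(intercept)`, `beta` is the `log W` coefficient
#' and `gamma` minus the `log R` coefficient. When latency records are
#' supplied, 95% confidence intervals are obtained by a nonparametric
#' bootstrap over the records (the table is rebuilt and refitted per
#' resample).
#'
#' @param x latency records (with a `latency` column; enables the
#'   bootstrap) or a prebuilt rate table from [following_rates()].
#' @param min_cell_count minimum observations per cell.
#' @param n_boot bootstrap resamples (0 disables CIs).
#' @param weighted weight regression cells by observation count.
#' @param conf confidence level.
#' @param seed optional integer seed for the bootstrap.
#' @return An object of class `mimetic_fit`: `alpha`, `beta`, `gamma`,
#'   `ci` (3 x 2 matrix, possibly NA), `r_squared`, `table`, `n_boot`.
#' @export
fit_mimetic_params <- function(x, min_cell_count = 3L, n_boot = 1000L,
                               weighted = FALSE, conf = 0.95, seed = NULL) {
  has_records <- "latency" %in% names(x)
  tab <- if (has_records) following_rates(x, min_cell_count) else x
  pt <- mimetic_point_fit(tab, weighted)
  ci <- matrix(NA_real_, 3, 2,
               dimnames = list(c("alpha", "beta", "gamma"),
                               c("lower", "upper")))
  if (has_records && n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    bs <- matrix(NA_real_, n_boot, 3)
    n <- nrow(x)
    for (b in seq_len(n_boot)) {
      res <- try({
        xb <- x[sample.int(n, n, replace = TRUE), ]
        pb <- mimetic_point_fit(following_rates(xb, min_cell_count),
                                weighted)
        c(pb$alpha, pb$beta, pb$gamma)
      }, silent = TRUE)
      if (!inherits(res, "try-error")) bs[b, ] <- res
    }
    a <- (1 - conf) / 2
    ci[] <- t(apply(bs, 2, quantile, probs = c(a, 1 - a), na.rm = TRUE))
  }
  structure(list(alpha = pt$alpha, beta = pt$beta, gamma = pt$gamma,
                 ci = ci, r_squared = pt$r_squared, table = tab,
                 n_boot = if (has_records) n_boot else 0L),
            class = "mimetic_fit")
}

#' @export
print.mimetic_fit <- function(x, ...) {
  cat("Mimetic rate fit: f(R, W) = alpha * W^beta * R^-gamma\n")
  est <- c(alpha = x$alpha, beta = x$beta, gamma = x$gamma)
  for (k in names(est)) {
    cat(sprintf("  %-5s = %.4g", k, est[[k]]))
    if (!anyNA(x$ci[k, ]))
      cat(sprintf("  [%.4g; %.4g]", x$ci[k, 1], x$ci[k, 2]))
    cat("\n")
  }
  cat(sprintf("  R^2 = %.4f over %d cells\n", x$r_squared, nrow(x$table)))
  invisible(x)
}

#' Estimate the spontaneous stop rate and its group-size scaling
#'
#' The per-group-size spontaneous stop rate is the inverse mean of the
#' durations between the completion of a collective departure and the
#' first individual's stop; the base rate `mu_I_star` is the slope of the
#' regression of these rates on `1/N` through the origin (the scaling
#' `mu_I = mu_I_star / N`).
#'
#' @param durations data frame with columns `duration` (s) and
#'   `group_size`.
#' @return List with `mu_I_star` (s^-1) and `per_N` (data frame of
#'   group-size-specific rates and counts).
#' @export
estimate_mu_I <- function(durations) {
  stopifnot(all(c("duration", "group_size") %in% names(durations)),
            nrow(durations) > 0, all(durations$duration > 0))
  agg <- stats::aggregate(duration ~ group_size, data = durations,
                          FUN = function(z) c(m = mean(z), n = length(z)))
  per_N <- data.frame(group_size = agg$group_size,
                      rate = 1 / agg$duration[, "m"],
                      n = as.integer(agg$duration[, "n"]))
  inv_N <- 1 / per_N$group_size
  mu_star <- sum(per_N$rate * inv_N) / sum(inv_N^2)  # origin regression
  list(mu_I_star = mu_star, per_N = per_N)
}

#' Calibrate the spontaneous departure rate against ranged distances
#'
#' `mu_A` is hard to read off field data directly (aborted departures mix
#' with grazing micro-moves), so it is calibrated by simulation: for each
#' candidate value, the simulator is run over the recording duration and
#' the mean distance walked by the group center of mass is compared to the
#' per-group-size targets; the grid value minimizing the summed squared
#' error is retained.
#'
#' @param targets data frame with columns `group_size` and `distance_m`.
#' @param params a [behavioural_params()] object (its `N` is overridden).
#' @param grid candidate `mu_A` values (s^-1).
#' @param t_max simulated duration per run (s).
#' @param n_reps replicate simulations per group size and candidate.
#' @param seed optional integer seed.
#' @return List with `mu_A` (retained value; on a flat objective, all
#'   tied argmins with a warning), and `objective` (data frame of grid
#'   values and summed squared errors).
#' @export
calibrate_mu_A <- function(targets, params, grid, t_max = 1800,
                           n_reps = 100, seed = NULL) {
  stopifnot(all(c("group_size", "distance_m") %in% names(targets)),
            all(targets$distance_m >= 0), all(grid >= 0))
  if (!is.null(seed)) set.seed(seed)
  sse <- vapply(grid, function(mu) {
    err <- 0
    for (r in seq_len(nrow(targets))) {
      p <- params
      p$mu_A <- mu
      p$N <- as.integer(targets$group_size[r])
      d <- vapply(seq_len(n_reps), function(i) {
        traj <- run_gillespie(p, t_max = t_max, record_interval = t_max / 60)
        gs <- group_statistics(traj)
        gs$distance_walked[length(gs$distance_walked)]
      }, numeric(1))
      err <- err + (mean(d) - targets$distance_m[r])^2
    }
    err
  }, numeric(1))
  best <- which(sse <= min(sse) * (1 + 1e-12))
  if (length(best) > 1L)
    warning("flat calibration objective: returning all tied argmin values")
  list(mu_A = grid[best], objective = data.frame(mu_A = grid, sse = sse))
}

#' Run the full rate-estimation pipeline on 2D tracking tables
#'
#' Chains the whole analysis: per-walker speeds are binarized into modes,
#' tracks are projected onto the group's curvilinear abscissa, collective
#' departure and stop events are detected, following latencies extracted,
#' rate tables built, and the mimetic parameters fitted separately for
#' departures and stops; the spontaneous stop rate is estimated from the
#' durations of collective moves.
#'
#' @param tracks data frame with columns `time_s`, `sheep_id`, `x_m`,
#'   `y_m` and optionally `group_id` (distinct recorded groups).
#' @param threshold,min_run binarization settings, see [binarize_speed()].
#' @param min_cell_count,n_boot,weighted,seed fitting settings, see
#'   [fit_mimetic_params()].
#' @return List with `departure_fit`, `stop_fit` (class `mimetic_fit`),
#'   `mu_I` (from [estimate_mu_I()], `NULL` if no move durations),
#'   `latencies` and `move_durations` data frames.
#' @export
estimate_parameters <- function(tracks, threshold = 0.3, min_run = 2L,
                                min_cell_count = 3L, n_boot = 1000L,
                                weighted = FALSE, seed = NULL) {
  stopifnot(all(c("time_s", "sheep_id", "x_m", "y_m") %in% names(tracks)))
  if (is.null(tracks$group_id)) tracks$group_id <- 1L
  lat_all <- list(); dur_all <- list()
  for (g in unique(tracks$group_id)) {
    tg <- tracks[tracks$group_id == g, ]
    ids <- sort(unique(tg$sheep_id))
    times <- sort(unique(tg$time_s))
    X <- matrix(NA_real_, length(times), length(ids))
    Y <- X
    for (j in seq_along(ids)) {
      tj <- tg[tg$sheep_id == ids[j], ]
      tj <- tj[order(tj$time_s), ]
      X[, j] <- tj$x_m[match(times, tj$time_s)]
      Y[, j] <- tj$y_m[match(times, tj$time_s)]
    }
    if (anyNA(X) || anyNA(Y))
      stop("tracks of group ", g, " are not synchronized on common times")
    dtv <- diff(times)
    spd <- sqrt(diff(X)^2 + diff(Y)^2) / dtv
    modes <- apply(rbind(spd[1, , drop = FALSE], spd), 2, binarize_speed,
                   threshold = threshold, min_run = min_run)
    ev <- detect_collective_events(modes, times)
    lat_all[[length(lat_all) + 1L]] <- extract_latencies(ev)
    md <- collective_move_durations(ev)
    if (nrow(md)) {
      md$group_size <- length(ids)
      dur_all[[length(dur_all) + 1L]] <- md
    }
  }
  lat <- do.call(rbind, lat_all)
  durations <- if (length(dur_all)) do.call(rbind, dur_all) else
    data.frame(duration = numeric(), group_size = integer())
  dep <- lat[lat$kind == "departure", ]
  stp <- lat[lat$kind == "stop", ]
  list(departure_fit = fit_mimetic_params(dep, min_cell_count, n_boot,
                                          weighted, seed = seed),
       stop_fit = fit_mimetic_params(stp, min_cell_count, n_boot,
                                     weighted, seed = seed),
       mu_I = if (nrow(durations)) estimate_mu_I(durations) else NULL,
       latencies = lat, move_durations = durations)
}

#' Durations of collective moves
#'
#' Time from the completion of each valid collective departure (the last
#' walker's start) to the first stop of the following collective stop
#' event; the raw observable behind [estimate_mu_I()].
#'
#' @param events a [detect_collective_events()] result.
#' @return Data frame with column `duration` (s).
#' @export
collective_move_durations <- function(events) {
  durs <- numeric()
  last_dep_end <- NA_real_
  for (ev in events) {
    if (!isTRUE(ev$valid)) { last_dep_end <- NA_real_; next }
    if (ev$kind == "departure") {
      last_dep_end <- ev$end_time
    } else if (!is.na(last_dep_end)) {
      d <- ev$start_time - last_dep_end
      if (d > 0) durs <- c(durs, d)
      last_dep_end <- NA_real_
    }
  }
  data.frame(duration = durs)
}
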