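test_that("speed binarization applies the strict threshold and debouncing", {
  expect_equal(binarize_speed(rep(0, 5)), rep(0L, 5))
  expect_equal(binarize_speed(c(0.05, 0.9, 1.1, 0.1), min_run = 1),
               c(0L, 1L, 1L, 0L))
  # boundary: speed exactly at the threshold counts as stopped
  expect_equal(binarize_speed(rep(0.3, 4), threshold = 0.3), rep(0L, 4))
  # a single-sample flicker is merged into the surrounding mode
  expect_equal(binarize_speed(c(0, 0, 1, 0, 0), min_run = 2), rep(0L, 5))
  expect_equal(binarize_speed(c(1, 1, 0, 1, 1), min_run = 2), rep(1L, 5))
  # short edge runs are merged too
  expect_equal(binarize_speed(c(1, 0, 0, 0, 0), min_run = 2), rep(0L, 5))
})

test_that("curvilinear projection recovers straight-line and cornered paths", {
  # straight motion: abscissa equals signed distance along the line
  tt <- 0:10
  X <- cbind(tt * 0.6, tt * 0.6 + 0.5)
  Y <- cbind(tt * 0.8, tt * 0.8)
  s <- project_to_curvilinear(X, Y)
  # interior samples advance by exactly the walked distance per step
  expect_equal(diff(s[3:11, 1]), rep(1, 8), tolerance = 1e-9)
  # lateral offset projects to its along-path component (0.5, 0) . (0.6, 0.8)
  expect_equal(s[5, 2] - s[5, 1], 0.3, tolerance = 1e-9)
  # stationary group: constant abscissae (degenerate path)
  s0 <- project_to_curvilinear(matrix(1, 5, 2), matrix(2, 5, 2))
  expect_true(all(s0 == 0))
  # L-shaped two-segment path: the corner point maps to the length of the
  # first segment
  vx <- c(0, 3, 3); vy <- c(0, 0, 4)
  s_corner <- sheeppulse:::project_onto_polyline(3, 0, vx, vy)
  expect_equal(s_corner, 3)
  s_mid2 <- sheeppulse:::project_onto_polyline(3.3, 2, vx, vy)
  expect_equal(s_mid2, 5, tolerance = 1e-9)  # orthogonal drop onto leg 2
})

test_that("collective events are delimited and filtered as specified", {
  # two departures and two stops with hand-enumerated switches
  m <- rbind(c(0, 0, 0),
             c(1, 0, 0),   # t1: departure starts (walker 1)
             c(1, 1, 0),
             c(1, 1, 1),   # t3: all moving
             c(1, 1, 1),
             c(0, 1, 1),   # t5: stop starts (walker 1)
             c(0, 0, 1),
             c(0, 0, 0),   # t7: all stopped
             c(0, 1, 0),   # t8: departure 2 (walker 2)
             c(1, 1, 0),
             c(1, 1, 1),   # t10: all moving
             c(1, 1, 0),   # t11: stop 2 (walker 3)
             c(0, 1, 0),
             c(0, 0, 0))   # t13: all stopped
  ev <- detect_collective_events(m)
  kinds <- vapply(ev, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "departure"), 2L)
  expect_equal(sum(kinds == "stop"), 2L)
  expect_true(all(vapply(ev, `[[`, logical(1), "valid")))
  d1 <- ev[[1]]
  expect_equal(d1$switch_times, c(1, 2, 3))
  expect_equal(d1$initiator, 1L)
  s1 <- ev[[2]]
  expect_equal(s1$kind, "stop")
  expect_equal(s1$switch_times, c(5, 6, 7))
  # clean staircase of N starts: one event, N - 1 latencies
  stair <- rbind(c(0, 0, 0, 0), c(1, 0, 0, 0), c(1, 1, 0, 0),
                 c(1, 1, 1, 0), c(1, 1, 1, 1))
  lat <- extract_latencies(detect_collective_events(stair))
  expect_equal(nrow(lat), 3L)
  # initiator reverting before the last follower switches invalidates it
  abort <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                 c(1, 1, 0), c(1, 1, 1))
  ev2 <- detect_collective_events(abort)
  expect_false(ev2[[1]]$valid)
  expect_equal(nrow(extract_latencies(ev2)), 0L)
})

test_that("latencies carry (W, R) at the moment each clock starts", {
  m <- matrix(0L, 8, 3)
  m[2:8, 1] <- 1L   # initiator starts at t = 1
  m[4:8, 2] <- 1L   # follower 1 at t = 3
  m[7:8, 3] <- 1L   # follower 2 at t = 6
  lat <- extract_latencies(detect_collective_events(m))
  expect_equal(lat$latency, c(2, 3))
  expect_equal(lat$W, c(1L, 2L))
  expect_equal(lat$R, c(2L, 1L))
  # stop events produce mirror records with stopped/still-moving counts
  ms <- 1L - m
  lats <- extract_latencies(detect_collective_events(ms))
  expect_equal(lats$kind, c("stop", "stop"))
  expect_equal(lats$latency, c(2, 3))
  expect_equal(lats$W, c(1L, 2L))
})

test_that("following rates apply the at-risk correction 1/(R * mean latency)", {
  rec <- data.frame(latency = c(4, 4, 4, 5, 5, 5),
                    W = c(1L, 1L, 1L, 2L, 2L, 2L),
                    R = c(1L, 1L, 1L, 2L, 2L, 2L))
  tab <- following_rates(rec, min_cell_count = 3)
  expect_equal(tab$f[tab$R == 1], 0.25)
  expect_equal(tab$f[tab$R == 2], 0.1)
  expect_equal(tab$n_obs, c(3L, 3L))
  expect_error(following_rates(rec, min_cell_count = 5), "min_cell_count")
  expect_error(following_rates(rec[0, ]), "no latency records")
})

test_that("first-order-statistic latencies recover the per-individual rate", {
  # with R at risk the pooled waiting time is Exp(R * f0)
  set.seed(31)
  f0 <- 0.4
  for (R in c(1L, 3L)) {
    rec <- data.frame(latency = rexp(4000, R * f0), W = 1L, R = R)
    tab <- following_rates(rec)
    expect_equal(tab$f, f0, tolerance = 0.05)
  }
})

test_that("log-domain regression inverts a noise-free power-law table exactly", {
  cells <- expand.grid(W = 1:3, R = 1:3)
  cells$f <- 0.3 * cells$W^0.6 * cells$R^(-0.7)
  cells$n_obs <- 10L
  fit <- suppressWarnings(fit_mimetic_params(cells))  # exact fit warns in lm
  expect_equal(fit$alpha, 0.3, tolerance = 1e-10)
  expect_equal(fit$beta, 0.6, tolerance = 1e-10)
  expect_equal(fit$gamma, 0.7, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # rank-deficient designs are rejected
  expect_error(fit_mimetic_params(cells[cells$W == 1, ]), "rank-deficient")
})

test_that("doubling every latency halves alpha and leaves the exponents", {
  p <- kept_params(N = 4L)
  p$mu_A <- 0
  rec <- generate_latency_dataset(p, 400, kinds = "departure", seed = 7)
  f1 <- fit_mimetic_params(rec, n_boot = 0)
  rec2 <- rec
  rec2$latency <- 2 * rec$latency
  f2 <- fit_mimetic_params(rec2, n_boot = 0)
  expect_equal(f2$alpha, f1$alpha / 2, tolerance = 1e-10)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-10)
  expect_equal(f2$gamma, f1$gamma, tolerance = 1e-10)
})

test_that("rate estimation is invariant to walker relabelling and time shifts", {
  p <- kept_params(N = 4L)
  rec <- generate_latency_dataset(p, 300, kinds = "departure", seed = 19)
  tab <- following_rates(rec)
  # shuffling record order (relabelling events/walkers) changes nothing
  rec_sh <- rec[sample.int(nrow(rec)), ]
  expect_equal(following_rates(rec_sh), tab)
  # time translation of events leaves latencies, hence rates, unchanged
  m <- matrix(0L, 10, 2); m[3:10, 1] <- 1L; m[6:10, 2] <- 1L
  lat1 <- extract_latencies(detect_collective_events(m, times = 0:9))
  lat2 <- extract_latencies(detect_collective_events(m, times = 100:109))
  expect_equal(lat1$latency, lat2$latency)
})

test_that("mu_I* is recovered from per-group-size move durations", {
  set.seed(23)
  dur <- do.call(rbind, lapply(c(2L, 3L, 4L, 8L), function(N)
    data.frame(duration = rexp(3000, 0.08 / N), group_size = N)))
  est <- estimate_mu_I(dur)
  expect_equal(est$mu_I_star, 0.08, tolerance = 0.05)
  # single group size: mu_I* = N / mean duration
  one <- data.frame(duration = rexp(5000, 0.02), group_size = 4L)
  expect_equal(estimate_mu_I(one)$mu_I_star, 0.08, tolerance = 0.1)
})

test_that("mu_A calibration recovers a self-generated target and handles edge cases", {
  p <- kept_params(N = 3L)
  # targets generated by the simulator at mu_A = 0.006
  set.seed(3)
  p_true <- p; p_true$mu_A <- 0.006
  target <- mean(replicate(60, {
    tr <- run_gillespie(p_true, t_max = 600, record_interval = 50)
    gs <- group_statistics(tr)
    gs$distance_walked[length(gs$distance_walked)]
  }))
  cal <- calibrate_mu_A(data.frame(group_size = 3L, distance_m = target),
                        p, grid = c(0.0015, 0.006, 0.024), t_max = 600,
                        n_reps = 60, seed = 4)
  expect_equal(cal$mu_A, 0.006)
  # zero targets: argmin at the smallest grid value
  cal0 <- calibrate_mu_A(data.frame(group_size = 3L, distance_m = 0),
                         p, grid = c(0.001, 0.01), t_max = 200,
                         n_reps = 10, seed = 5)
  expect_equal(cal0$mu_A, 0.001)
})
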