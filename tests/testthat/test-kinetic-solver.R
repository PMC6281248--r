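test_that("nonlocal rates reduce to the spontaneous rates without coupling", {
  x <- seq(-5, 5, by = 0.1)
  f <- gaussian_field(4, x, sd = 1, moving_fraction0 = 0.3)
  p <- behavioural_params(alpha_A = 0, alpha_I = 0, N = 4L)
  K <- nonlocal_rates(f, p)
  expect_equal(K$K_A, rep(p$mu_A, length(x)))
  expect_equal(K$K_I, rep(spontaneous_stop_rate(p), length(x)))
})

test_that("nonlocal rates match independent quadrature on a piecewise-constant density", {
  dx <- 0.2
  x <- seq(0, 10, by = dx)
  set.seed(51)
  A <- round(runif(length(x), 0, 1.5), 2)
  I <- round(runif(length(x), 0, 1.5), 2)
  Nm <- sum(A + I) * dx
  f <- density_field(x, A, I)
  p <- kept_params(N = 4L)
  K <- nonlocal_rates(f, p)
  # oracle: treat each node as a cell of width dx; integral from x_i of the
  # step density is half the focal cell plus all cells to the right,
  # evaluated by brute-force summation
  for (i in seq(1, length(x), by = 7)) {
    SA <- dx * (A[i] / 2 + sum(A[seq_along(A) > i]))
    KA <- p$mu_A + p$alpha_A * SA^p$beta_A * max(Nm - SA, 1)^(-p$gamma_A)
    expect_equal(K$K_A[i], KA, tolerance = 1e-10)
    SI <- dx * (I[i] / 2 + sum(I[seq_along(I) < i]))
    KI <- spontaneous_stop_rate(p) +
      p$alpha_I * SI^p$beta_I * max(Nm - SI, 1)^(-p$gamma_I)
    expect_equal(K$K_I[i], KI, tolerance = 1e-10)
  }
  # all mass active and ahead: stimulation saturates at N^beta over the
  # clamped base
  f2 <- density_field(x, A = rep(4 / (10 + dx), length(x)),
                      I = rep(0, length(x)))
  K2 <- nonlocal_rates(f2, p)
  # at the left edge the stimulating integral is all the mass except half
  # the focal cell, and the inhibitory base clamps to 1
  S_edge <- f2$N - dx * f2$A[1] / 2
  expect_equal(K2$K_A[1], p$mu_A + p$alpha_A * S_edge^p$beta_A,
               tolerance = 1e-10)
  expect_error(density_field(x, A - 2, I), "non-negative")
})

test_that("pure transport translates a box profile conservatively", {
  dx <- 0.05
  x <- seq(0, 20, by = dx)
  A <- as.numeric(x >= 2 & x <= 4)
  f <- density_field(x, A, I = rep(0, length(x)))
  p <- behavioural_params(mu_A = 0, mu_I_star = 0, alpha_A = 0, alpha_I = 0,
                          v = 1, N = 4L)
  # v dt = dx: the upwind step is an exact one-cell shift
  out <- f
  for (k in 1:40) out <- kinetic_step(out, p, dt = 0.05)
  expect_equal(sum(out$A) * dx, sum(A) * dx, tolerance = 1e-12)
  expect_equal(out$A, c(rep(0, 40), A[seq_len(length(A) - 40)]),
               tolerance = 1e-12)
  # zero densities stay zero
  z <- density_field(x, rep(0, length(x)), rep(0, length(x)))
  expect_equal(kinetic_step(z, p, 0.01)$A, rep(0, length(x)))
  # CFL violation is rejected
  expect_error(kinetic_solve(f, p, t_end = 1, dt = 0.1),
               "stability|CFL")
})

test_that("mass is conserved to 1e-8 N and densities stay non-negative", {
  x <- seq(-20, 60, by = 0.05)
  f <- gaussian_field(4, x, sd = 2)
  p <- kept_params(N = 4L)
  sol <- kinetic_solve(f, p, t_end = 40, dt = 0.01, record_every = 5)
  mass <- rowSums(sol$A + sol$I) * sol$dx
  expect_true(all(abs(mass - 4) < 1e-8 * 4))
  expect_true(all(sol$A >= -1e-14))
  expect_true(all(sol$I >= -1e-14))
})

test_that("without coupling the density moments follow the renewal oracle", {
  # c = v dt / dx = 1 makes transport exact, isolating the reaction part
  mu_A <- 0.2; mu_I <- 0.3; t_end <- 150
  x <- seq(-40, 180, by = 0.05)
  f <- gaussian_field(1, x, sd = 0.2)
  p <- behavioural_params(mu_A = mu_A, mu_I_star = mu_I, alpha_A = 0,
                          alpha_I = 0, N = 1L, scale_mu_I = FALSE)
  sol <- kinetic_solve(f, p, t_end = t_end, dt = 0.05, record_every = t_end)
  eta <- sol$A[nrow(sol$A), ] + sol$I[nrow(sol$I), ]
  w <- eta / sum(eta)
  m1 <- sum(w * x)
  m2 <- sum(w * (x - m1)^2)
  oracle <- walker_moments_oracle(t_end, 1, mu_A, mu_I)
  expect_equal(m1, oracle$mean, tolerance = 0.01)
  expect_equal(m2, oracle$var, tolerance = 0.05)
})

test_that("the minimal model converges to the analytic pulse in shape and speed", {
  p <- behavioural_params(mu_A = 0.02, mu_I_star = 0.08, alpha_A = 0.5,
                          beta_A = 1, gamma_A = 0, alpha_I = 0.5, beta_I = 1,
                          gamma_I = 0, v = 1, N = 4L, scale_mu_I = FALSE)
  x <- seq(-30, 160, by = 0.05)
  sol <- kinetic_solve(gaussian_field(4, x, sd = 3), p, t_end = 600,
                       dt = 0.01, record_every = 100)
  b <- moving_fraction(p, "symmetric")
  pm <- pulse_metrics(sol, t_min = 300)
  expect_equal(pm$speed, p$v * b, tolerance = 0.01)
  expect_equal(pm$moving_fraction, b, tolerance = 0.01)
  # L2 distance to the sech^2 profile decreases and ends below tolerance
  l2 <- vapply(seq_along(sol$times), function(i) {
    eta <- sol$A[i, ] + sol$I[i, ]
    cm <- sum(eta * x) / sum(eta)
    ana <- steady_profile(x - cm, 0, p)
    sqrt(sum((eta - ana)^2)) / sqrt(sum(ana^2))
  }, numeric(1))
  expect_lt(l2[length(l2)], 0.05)
  expect_lt(l2[length(l2)], l2[2])
  # width matches the 1/gamma scale of sech^2 (FWHM = 1.7627 / gamma)
  g <- gamma_shape(p$N, p$alpha_A, p$alpha_I, p$v)
  expect_equal(pm$width, 2 * acosh(sqrt(2)) / g, tolerance = 0.05)
})

test_that("all four canonical initial conditions converge to the same pulse", {
  p <- behavioural_params(mu_A = 0.02, mu_I_star = 0.08, alpha_A = 0.5,
                          beta_A = 1, gamma_A = 0, alpha_I = 0.5, beta_I = 1,
                          gamma_I = 0, v = 1, N = 4L, scale_mu_I = FALSE)
  x <- seq(-40, 150, by = 0.05)
  nx <- length(x)
  box <- function(lo, hi) as.numeric(x >= lo & x <= hi) /
    (sum(x >= lo & x <= hi) * 0.05)
  ics <- list(
    dispersed_stopped = density_field(x, rep(0, nx), 4 * box(-10, 10)),
    dispersed_moving = density_field(x, 4 * box(-10, 10), rep(0, nx)),
    split_movers_ahead = density_field(x, 2 * box(5, 10), 2 * box(-10, -5)),
    split_movers_behind = density_field(x, 2 * box(-10, -5), 2 * box(5, 10)))
  finals <- lapply(ics, function(f0) {
    sol <- kinetic_solve(f0, p, t_end = 500, dt = 0.01, record_every = 250)
    eta <- sol$A[nrow(sol$A), ] + sol$I[nrow(sol$I), ]
    cm <- sum(eta * x) / sum(eta)
    approx(x - cm, eta, xout = seq(-10, 10, by = 0.05))$y
  })
  ref <- finals[[1]]
  for (k in 2:4) {
    rel <- sqrt(sum((finals[[k]] - ref)^2)) / sqrt(sum(ref^2))
    expect_lt(rel, 0.02)
  }
})

test_that("halving dx and dt changes late-time pulse speed and width by < 1%", {
  p <- behavioural_params(mu_A = 0.02, mu_I_star = 0.08, alpha_A = 0.5,
                          beta_A = 1, gamma_A = 0, alpha_I = 0.5, beta_I = 1,
                          gamma_I = 0, v = 1, N = 4L, scale_mu_I = FALSE)
  run <- function(dx, dt) {
    x <- seq(-20, 100, by = dx)
    sol <- kinetic_solve(gaussian_field(4, x, sd = 2), p, t_end = 300,
                         dt = dt, record_every = 50)
    pulse_metrics(sol, t_min = 200)
  }
  # refinement pair at a fixed Courant number near the stability margin,
  # where the first-order upwind scheme's numerical diffusion is smallest;
  # the pair sits in the asymptotic range where halving moves the width
  # by less than 1%
  coarse <- run(0.025, 0.02)
  fine <- run(0.0125, 0.01)
  expect_equal(coarse$speed, fine$speed, tolerance = 0.01)
  expect_equal(coarse$width, fine$width, tolerance = 0.01)
})

test_that("the full model's pulse is left-skewed (rear-tail mass excess)", {
  p <- kept_params(N = 4L)
  x <- seq(-30, 80, by = 0.05)
  sol <- kinetic_solve(gaussian_field(4, x, sd = 1), p, t_end = 400,
                       dt = 0.01, record_every = 100)
  pm <- pulse_metrics(sol, t_min = 200)
  expect_gt(pm$asymmetry, 0.02)
})

test_that("pulse metrics handle exact translations and symmetric profiles", {
  x <- seq(-30, 30, by = 0.05)
  eta0 <- 2 * sech2(1 * x)           # gamma = 1, N = 4 shape
  sol <- list(times = c(0, 10),
              A = rbind(0.2 * eta0, 0.2 * shiftprof(eta0, 40)),
              I = rbind(0.8 * eta0, 0.8 * shiftprof(eta0, 40)),
              x = x, dx = 0.05, N = 4)
  class(sol) <- "kinetic_solution"
  pm <- pulse_metrics(sol)
  expect_equal(pm$speed, 40 * 0.05 / 10, tolerance = 1e-9)
  expect_equal(pm$moving_fraction, 0.2, tolerance = 1e-12)
  expect_equal(pm$asymmetry, 0, tolerance = 0.02)
  expect_equal(pm$width, 2 * acosh(sqrt(2)), tolerance = 0.05)
})

test_that("profile resampling in small groups symmetrizes the observable", {
  x <- seq(-12, 12, by = 0.05)
  # a deliberately skewed profile
  prof <- exp(-((x + 1)^2) / 2) + 0.7 * exp(-((x - 2)^2) / 0.5)
  # pairs: pooled centered positions are symmetric in expectation
  ctr2 <- sample_groups_from_profile(x, prof, 2, 60000, seed = 9)
  expect_lt(abs(mean(ctr2)), 1e-10)
  br2 <- seq(-10, 10, by = 0.5)
  expect_lt(tv_distance(hist_density(ctr2, br2),
                        hist_density(-ctr2, br2), 0.5), 1e-10)
  # large groups: the histogram converges to the centered profile itself
  ctr_big <- sample_groups_from_profile(x, prof, 400, 200, seed = 10)
  mu <- sum(prof * x) / sum(prof)
  br <- seq(-8, 8, by = 0.4)
  mids <- (br[-1] + br[-length(br)]) / 2
  d_prof <- approx(x - mu, prof / (sum(prof) * 0.05), xout = mids,
                   rule = 2)$y
  d_prof <- d_prof / (sum(d_prof) * 0.4)
  expect_lt(tv_distance(hist_density(ctr_big, br), d_prof, 0.4), 0.05)
})
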