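test_that("exit intervals are successive differences of event times", {
  expect_equal(exit_intervals(c(1, 2, 4)), c(1, 2))
  ev <- data.frame(t = seq(0, by = 0.5, length.out = 100), id = 1:100)
  expect_equal(exit_intervals(ev), rep(0.5, 99))
  expect_error(exit_intervals(c(3)), "insufficient")
})

test_that("flow rate matches slope and identity estimator for steady flow", {
  ev <- seq(0.5, 50, by = 0.5)
  fr <- flow_rate(ev, t_start = 0.5, t_end = 50)
  expect_equal(fr$Q, 2, tolerance = 1e-12)
  expect_equal(fr$Q_identity, 2, tolerance = 1e-12)
  expect_true(fr$ci95[1] <= 2 + 1e-9 && 2 - 1e-9 <= fr$ci95[2])

  # flow only in the first half of the window: the regression sees the
  # arrested tail, the identity estimator (flowing half only) does not
  ev2 <- seq(0.1, 25, by = 0.5)
  fr2 <- flow_rate(ev2, t_start = 0, t_end = 50)
  expect_lt(fr2$Q, fr2$Q_identity)

  # empty window: flagged zero-flow result, not an error
  fr3 <- flow_rate(numeric(0), t_start = 0, t_end = 10)
  expect_true(fr3$empty)
  expect_equal(fr3$Q, 0)
})

test_that("flow rate recovers the rate of a Poisson process", {
  set.seed(42)
  tt <- cumsum(rexp(1000, rate = 3))
  fr <- flow_rate(tt, t_start = 0, t_end = max(tt))
  # oracle: a Poisson rate estimate from n events has sd ~ sqrt(n)/T
  se_pois <- sqrt(1000) / max(tt)
  expect_lt(abs(fr$Q - 3), 3 * se_pois)
  expect_lt(abs(fr$Q_identity - 3), 0.3)
})

test_that("power-law MLE matches the closed form at fixed xmin", {
  fit <- fit_power_law(c(exp(1), exp(2)), xmin = 1)
  expect_equal(fit$alpha, 1 + 2 / 3)
  expect_equal(fit$n_tail, 2L)
  expect_error(fit_power_law(rep(2, 50)), "degenerate")
  expect_error(fit_power_law(c(1, 2, 3), min_tail = 10), "insufficient tail")
})

test_that("CSN fit recovers the exponent of synthetic power-law samples", {
  x <- sample_power_law(2.5, x_min = 1, n = 5000, seed = 123)
  fit <- fit_power_law(x)
  expect_gt(fit$alpha, 2.4)
  expect_lt(fit$alpha, 2.6)
  expect_gte(fit$xmin, min(x))

  # exponential samples of equal size fit markedly worse
  set.seed(123)
  xe <- rexp(5000, 1)
  fit_e <- fit_power_law(xe)
  expect_gt(fit_e$ks_distance, 2 * fit$ks_distance)
})

test_that("burst/clog decomposition merges sub-cutoff runs and spans the log", {
  ev <- cumsum(c(0, 0.1, 0.1, 5, 0.1))
  bc <- decompose_bursts_clogs(ev, dt_out_min = 1)
  expect_equal(bc$bursts, c(0.2, 0.1))
  expect_equal(bc$clogs, 5)
  expect_equal(sum(bc$bursts) + sum(bc$clogs), max(ev) - min(ev))

  # all below cutoff: one burst, no clogs
  ev2 <- cumsum(c(0, rep(0.2, 10)))
  bc2 <- decompose_bursts_clogs(ev2, 1)
  expect_equal(length(bc2$bursts), 1L)
  expect_equal(bc2$bursts, 2)
  expect_equal(length(bc2$clogs), 0L)

  # all above cutoff: no bursts
  ev3 <- cumsum(c(0, rep(3, 5)))
  bc3 <- decompose_bursts_clogs(ev3, 1)
  expect_equal(length(bc3$bursts), 0L)
  expect_equal(bc3$clogs, rep(3, 5))
})

test_that("flowing parameter classifies clogged/intermittent/flowing", {
  cl <- flowing_parameter(bursts = 1, clogs = 1, alpha = 3)
  expect_equal(cl$phi, 0.5)
  expect_equal(cl$label, "intermittent")

  # diverging mean clog time: alpha <= 2 forces Phi = 0
  cl2 <- flowing_parameter(bursts = c(5, 5), clogs = c(1, 2), alpha = 1.9)
  expect_equal(cl2$phi, 0)
  expect_equal(cl2$label, "clogged")

  cl3 <- flowing_parameter(bursts = c(1, 2, 3), clogs = numeric(0))
  expect_equal(cl3$phi, 1)
  expect_equal(cl3$label, "flowing")

  cl4 <- flowing_parameter(bursts = numeric(0), clogs = c(4, 4))
  expect_equal(cl4$phi, 0)

  # Phi in [0,1]; adding a clog at least as long as the current clog mean
  # never increases Phi, and any clog added to a clog-free log lowers it
  set.seed(8)
  for (i in 1:20) {
    b <- rexp(sample(1:10, 1)); cl <- rexp(sample(1:10, 1), 1 / 10)
    phi1 <- flowing_parameter(b, cl, alpha = 3)$phi
    expect_gte(phi1, 0); expect_lte(phi1, 1)
    phi2 <- flowing_parameter(b, c(cl, mean(cl) + rexp(1, 1 / 10)), alpha = 3)$phi
    expect_lte(phi2, phi1)
    expect_lt(flowing_parameter(b, rexp(1), alpha = 3)$phi,
              flowing_parameter(b, numeric(0))$phi)
  }
})

test_that("bulk observables match hand-computed values on built frames", {
  # 3 particles: two overlapping by xi = 0.2 inside the region, one free
  fr <- data.frame(t = 0, id = 1:3,
                   x = c(5, 6.8, 15), y = c(5, 5, 20),
                   vx = 0, vy = 0, r = 1)
  bo <- bulk_observables(fr)
  expect_equal(bo$p_free$mean, 1 / 3)
  expect_equal(bo$rho$mean, 3 / 448)
  expect_equal(bo$n_c$mean, 2)
  expect_equal(bo$xi_c$mean, 0.2)

  # contact status counts partners outside the region
  fr2 <- data.frame(t = 0, id = 1:2,
                    x = c(2.5, 1.2), y = c(5, 5), vx = 0, vy = 0, r = 1)
  bo2 <- bulk_observables(fr2)
  expect_equal(bo2$p_free$mean, 0)   # the lone in-region particle touches
  expect_equal(bo2$n_c$mean, 1)
  expect_equal(bo2$xi_c$mean, (2 - 1.3))

  # a full region of non-contacting particles: rho = 1, P_free = 1
  gx <- seq(2.5, 17.5, length.out = 16)
  gy <- seq(2.5, 29.5, length.out = 28)
  g <- expand.grid(x = gx, y = gy)
  fr3 <- data.frame(t = 0, id = seq_len(448), x = g$x, y = g$y,
                    vx = 0, vy = 0, r = 0.4)
  bo3 <- bulk_observables(fr3)
  expect_equal(bo3$rho$mean, 1)
  expect_equal(bo3$p_free$mean, 1)
  expect_equal(bo3$n_c$mean, 0)

  # frames with an empty region are skipped and counted
  fr4 <- rbind(fr, data.frame(t = 1, id = 1, x = 19, y = 50,
                              vx = 0, vy = 0, r = 1))
  bo4 <- bulk_observables(fr4)
  expect_equal(bo4$n_skipped_empty, 1)
  expect_equal(bo4$p_free$mean, 1 / 3)

  expect_error(bulk_observables(fr[0, ]), "insufficient")
})

test_that("resonance amplitude has a single peak at omega0 sqrt(1 - 2 zeta^2)", {
  expect_true(is.infinite(resonance_amplitude(10, 10, 0)))
  # vanishes at large omega
  a <- resonance_amplitude(c(10, 100, 1000, 1e4), omega0 = 10, zeta = 0.3)
  expect_true(all(diff(a) < 0))
  expect_lt(a[4], 1e-7)
  # grid-search oracle for the peak position
  zeta <- 0.2; omega0 <- 22.4
  grid <- seq(0.1, 100, by = 0.001)
  peak <- grid[which.max(resonance_amplitude(grid, omega0, zeta))]
  expect_equal(peak, omega0 * sqrt(1 - 2 * zeta^2), tolerance = 1e-4)
})

test_that("Q * T is consistent with the identity 1/<dt_out> on steady logs", {
  ev <- sample_intermittent_log(mean_burst_gap = 0.1, mean_clog = 0,
                                n_events = 2000, seed = 5)
  fr <- flow_rate(ev, t_start = min(ev$t), t_end = max(ev$t))
  span <- max(ev$t) - min(ev$t)
  expect_equal(fr$Q_identity * span, 1999, tolerance = 1e-9)
  expect_equal(fr$Q, fr$Q_identity, tolerance = 0.02)
})

test_that("analyze_events flags arrested runs and reports exits/T", {
  ev <- data.frame(t = c(10, 11, 12, 13), id = 1:4)
  an <- analyze_events(ev, T = 500, burnin = 0)
  expect_true(an$arrested)
  expect_equal(an$Q_overall, 4 / 500)
})
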