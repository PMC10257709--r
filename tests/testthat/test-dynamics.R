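cfg_ref <- sim_config()

test_that("driving force relaxes the velocity toward v_f in -y", {
  expect_equal(driving_force(c(0, -3.3), cfg_ref), c(0, 0))
  expect_equal(driving_force(c(0, 0), cfg_ref), c(0, -3.3))
  expect_equal(driving_force(c(1, 0), cfg_ref), c(-1, -3.3))
})

test_that("pair overlap is (r_i + r_j) - d and errors on coincident centers", {
  expect_equal(pair_overlap(c(0, 0), c(2, 0), 1, 1), 0)
  expect_equal(pair_overlap(c(0, 0), c(1.8, 0), 1, 1), 0.2)
  expect_equal(pair_overlap(c(0, 0), c(3, 0), 1, 1), -1)
  expect_error(pair_overlap(c(1, 1), c(1, 1), 1, 1), "degenerate")
})

test_that("pair contact force is repulsive, frictional, and zero without overlap", {
  # xi = 0.1, both at rest: pure normal force k_n * xi = 50 from j to i
  f <- contact_force_pair(c(0, 0), c(1.9, 0), c(0, 0), c(0, 0), 1, 1, cfg_ref)
  expect_equal(f, c(-50, 0))
  # relative tangential speed 1: tangential magnitude k_t * xi * 1 = 100
  # e^n = (-1, 0) so e^t = (0, -1); v_j - v_i = (0, -1) gives (v_j-v_i).e^t = 1
  f <- contact_force_pair(c(0, 0), c(1.9, 0), c(0, 0), c(0, -1), 1, 1, cfg_ref)
  expect_equal(f, c(-50, -100))
  # no overlap: exactly zero
  expect_equal(contact_force_pair(c(0, 0), c(2.5, 0), c(1, 2), c(-3, 0), 1, 1,
                                  cfg_ref),
               c(0, 0))
})

test_that("boundary contact force handles walls and orifice lips", {
  geo <- sim_geometry(cfg_ref)
  # overlap 0.1 with the left wall: normal force 50 in +x
  expect_equal(contact_force_boundary(c(0.9, 50), c(0, 0), 1, geo, cfg_ref),
               c(50, 0))
  # far from all boundaries: zero
  expect_equal(contact_force_boundary(c(10, 5), c(0, 0), 1, geo, cfg_ref),
               c(0, 0))
  # lip contact: xi = 0.05, normal magnitude 25 along (center - corner)
  pos <- c(8.6, 0) + 0.95 / sqrt(2)
  f <- contact_force_boundary(pos, c(0, 0), 1, geo, cfg_ref)
  expect_equal(sqrt(sum(f^2)), 500 * 0.05)
  expect_equal(f / sqrt(sum(f^2)), c(1, 1) / sqrt(2))
  # two simultaneous walls sum: deep in the bottom-left corner
  f2 <- contact_force_boundary(c(0.9, 0.9), c(0, 0), 1, geo, cfg_ref)
  expect_equal(f2, c(50, 50))
})

test_that("radii follow the prescribed oscillation", {
  cfg <- sim_config(A = 0)
  expect_equal(update_radii(3.7, c(0, 1, 2), cfg), rep(1, 3))
  cfg <- sim_config(A = 0.15, omega = 0)
  expect_equal(update_radii(99, pi / 2, cfg), 1.15)
  cfg <- sim_config(A = 0.15, omega = 25)
  expect_equal(update_radii(2 * pi / 25, 0, cfg), 1)
})

test_that("a free particle relaxes to v_f(1 - exp(-t/tau))", {
  sc <- make_scenario("free_particle")
  st <- integrate_step(sc$state, sc$config, n_steps = round(1 / sc$config$dt))
  expect_equal(sqrt(sum(st$velocities^2)), 3.3 * (1 - exp(-1)), tolerance = 1e-3)
  # moving straight down
  expect_lt(st$velocities[1, 2], 0)
  expect_equal(st$velocities[1, 1], 0)
})

test_that("compiled forces match the all-pairs R oracle", {
  for (seed in 1:6) {
    cfg <- sim_config(N = 25, A = 0.2, omega = 30, box_height = 30,
                      reinjection_y_range = c(20, 30), T = 1)
    st <- random_state(cfg, seed)
    expect_equal(cpp_total_forces_of(st, cfg), oracle_total_forces(st, cfg),
                 tolerance = 1e-12)
  }
})

test_that("pair forces obey Newton's third law and vanish without overlap", {
  set.seed(11)
  for (rep in 1:20) {
    cfg <- sim_config(N = 2, A = 0.1, omega = 10, v_f = runif(1, 0, 5))
    p <- matrix(runif(4, 5, 15), 2, 2)
    v <- matrix(rnorm(4), 2, 2)
    r <- update_radii(0, runif(2, 0, 2 * pi), cfg)
    f12 <- contact_force_pair(p[1, ], p[2, ], v[1, ], v[2, ], r[1], r[2], cfg)
    f21 <- contact_force_pair(p[2, ], p[1, ], v[2, ], v[1, ], r[2], r[1], cfg)
    expect_equal(f12, -f21)
    xi <- pair_overlap(p[1, ], p[2, ], r[1], r[2])
    if (xi < 0) {
      expect_identical(f12, c(0, 0))
    } else {
      # repulsion-only normal component: positive projection on (x1 - x2)
      expect_gt(sum(f12 * (p[1, ] - p[2, ])), 0)
    }
  }
})

test_that("momentum is conserved for a frictionless pair without driving", {
  cfg <- sim_config(N = 2, A = 0, v_f = 0, k_t = 1e-12)  # k_t must be > 0
  cfg$k_t <- 0  # frictionless
  st <- particle_state(rbind(c(9.05, 75), c(10.95, 75)),
                       rbind(c(0.3, 0), c(-0.3, 0)), c(0, 0), cfg, t = 0)
  st2 <- integrate_step(st, cfg, n_steps = 2000)
  # driving with v_f = 0 damps symmetric momentum; net momentum stays 0
  expect_equal(colSums(st2$velocities), c(0, 0), tolerance = 1e-12)
  # and the pair has separated after bouncing
  expect_gt(abs(diff(st2$positions[, 1])), 1.9)
})

test_that("prescribed radius trace matches the closed form at every frame", {
  sc <- make_scenario("oscillating_singleton")
  cfg <- sc$config
  cfg$T <- 5
  sim <- run_simulation(cfg, state = sc$state)
  expected <- update_radii(sim$frames$t, 0, cfg)
  expect_equal(sim$frames$r, expected, tolerance = 1e-9)
  expect_true(all(sim$frames$r >= cfg$r0 * (1 - cfg$A)))
  expect_true(all(sim$frames$r <= cfg$r0 * (1 + cfg$A)))
})

test_that("initialization places non-overlapping particles inside the box", {
  cfg <- sim_config(N = 1, T = 1)
  set.seed(5)
  st <- initialize_particles(cfg)
  expect_true(all(st$positions[, 1] >= st$radii &
                  st$positions[, 1] <= cfg$box_width - st$radii))
  expect_true(all(st$positions[, 2] >= st$radii &
                  st$positions[, 2] <= cfg$box_height - st$radii))

  cfg <- sim_config(N = 200, T = 1)
  set.seed(9)
  st <- initialize_particles(cfg)
  d <- as.matrix(dist(st$positions))
  xi <- outer(st$radii, st$radii, "+") - d
  diag(xi) <- -Inf
  expect_true(all(xi <= 0))
  expect_equal(nrow(st$positions), 200L)

  # determinism of the initial state
  set.seed(31); a <- initialize_particles(cfg)
  set.seed(31); b <- initialize_particles(cfg)
  expect_identical(a, b)

  # an impossible density errors out
  expect_error({
    set.seed(1)
    initialize_particles(sim_config(N = 300, box_height = 20, T = 1,
                                    reinjection_y_range = c(10, 20),
                                    init_attempt_cap = 200))
  }, "density")
})

test_that("particles below the removal line are reinjected, conserving N", {
  cfg <- scaled_config(N = 8, T = 1, seed = 3)
  set.seed(3)
  st <- initialize_particles(cfg)
  # drop one particle just above the removal line, moving down fast
  st$positions[1, ] <- c(10, -14.999)
  st$velocities[1, ] <- c(0, -5)
  st2 <- integrate_step(st, cfg, n_steps = 100)
  expect_equal(nrow(st2$positions), 8L)
  expect_gte(st2$positions[1, 2], 40)
  expect_lte(st2$positions[1, 2], 60)
  expect_gte(st2$positions[1, 1], 2)
  expect_lte(st2$positions[1, 1], 18)
  # reinjected at rest (default), then accelerating downward
  expect_equal(st2$velocities[1, 1], 0, tolerance = 1e-6)

  # nothing below the line: state evolves but N and ids unchanged
  st3 <- integrate_step(st2, cfg, n_steps = 10)
  expect_equal(nrow(st3$positions), 8L)
})

test_that("run_simulation records frames, events, and is deterministic", {
  cfg <- scaled_config(N = 15, T = 10, A = 0.15, omega = 25, seed = 7)
  s1 <- run_simulation(cfg)
  s2 <- run_simulation(cfg)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$frames, s2$frames)

  # frames every dt_k, N rows each, constant particle count
  counts <- table(s1$frames$t)
  expect_true(all(counts == cfg$N))
  expect_equal(length(counts), cfg$T / cfg$dt_k + 1)
  expect_true(!is.unsorted(s1$events$t))

  # T = 0: a single initial frame and no events
  cfg0 <- scaled_config(N = 5, T = 0, seed = 2)
  s0 <- run_simulation(cfg0)
  expect_equal(nrow(s0$events), 0L)
  expect_equal(unique(s0$frames$t), 0)
  expect_equal(nrow(s0$frames), 5L)
})

test_that("a driven particle falling through the orifice logs one exit event", {
  cfg <- sim_config(N = 1, A = 0, T = 10)
  st <- particle_state(rbind(c(10, 3)), rbind(c(0, 0)), 0, cfg, t = 0)
  sim <- run_simulation(cfg, state = st, record_frames = FALSE)
  expect_equal(nrow(sim$events), 1L)
  expect_equal(sim$events$id, 1L)
  # crossing time for exponential relaxation: y(t) = 3 - v_f (t - tau (1 - e^-t))
  f <- function(t) 3 - 3.3 * (t - (1 - exp(-t)))
  t_star <- uniroot(f, c(0.1, 5))$root
  expect_equal(sim$events$t, t_star, tolerance = 1e-3)
})

test_that("a short dense reference run stays finite and within radius bounds", {
  cfg <- scaled_config(T = 10, A = 0.15, omega = 25, seed = 1)
  sim <- run_simulation(cfg)
  expect_true(all(is.finite(as.matrix(sim$frames[c("x", "y", "vx", "vy")]))))
  expect_true(all(sim$frames$r >= cfg$r0 * (1 - cfg$A) - 1e-12))
  expect_true(all(sim$frames$r <= cfg$r0 * (1 + cfg$A) + 1e-12))
  expect_true(all(table(sim$frames$t) == cfg$N))
})
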