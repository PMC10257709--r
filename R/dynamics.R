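#' Driving force toward the destination
#'
#' The active self-propulsion relaxes the particle velocity toward the
#' free velocity `v_f` in the fixed destination direction `(0, -1)` over
#' the timescale `tau`: `F_d = m (v_f e_d - v) / tau`.
#'
#' @param velocity length-2 velocity vector.
#' @param cfg a [sim_config()].
#' @return Length-2 force vector.
#' @export
#' @examples
#' driving_force(c(0, -3.3), sim_config(N = 1))  # at free velocity: zero
driving_force <- function(velocity, cfg) {
  stopifnot(length(velocity) == 2)
  cfg$m * (cfg$v_f * c(0, -1) - velocity) / cfg$tau
}

#' Pair overlap
#'
#' Interpenetration depth `xi_ij = (r_i + r_j) - d_ij` between two disks;
#' negative when the disks are not in contact.
#'
#' @param pos_i,pos_j length-2 centre coordinates.
#' @param r_i,r_j radii.
#' @return Scalar overlap (may be negative).
#' @export
pair_overlap <- function(pos_i, pos_j, r_i, r_j) {
  d <- sqrt(sum((pos_i - pos_j)^2))
  if (d == 0) stop("degenerate geometry: coincident particle centers")
  (r_i + r_j) - d
}

#' Contact force between two disks
#'
#' Linear repulsion plus velocity-proportional tangential friction,
#' active only when the disks overlap (`xi_ij > 0`):
#' `xi_ij * (k_n e^n + k_t ((v_j - v_i) . e^t) e^t)`, where the normal
#' unit vector `e^n` points from j toward i (repulsive on i) and
#' `e^t = rot90(e^n)`.
#'
#' @param pos_i,pos_j centres; @param vel_i,vel_j velocities;
#' @param r_i,r_j radii; @param cfg a [sim_config()].
#' @return Length-2 force on particle i. The force on j is its negative.
#' @export
contact_force_pair <- function(pos_i, pos_j, vel_i, vel_j, r_i, r_j, cfg) {
  delta <- pos_i - pos_j
  d <- sqrt(sum(delta^2))
  if (d == 0) stop("degenerate geometry: coincident particle centers")
  xi <- (r_i + r_j) - d
  if (xi < 0) return(c(0, 0))
  en <- delta / d
  et <- c(-en[2], en[1])
  vt <- sum((vel_j - vel_i) * et)
  xi * (cfg$k_n * en + cfg$k_t * vt * et)
}

#' Contact force from the boundaries
#'
#' Sums contributions from every wall segment the disk overlaps (a disk can
#' touch up to two boundaries simultaneously), including the orifice lips,
#' which enter as the segment endpoints: `xi_ib * (k_n e^n + k_t
#' (-v_i . e^t) e^t)` with `xi_ib = r_i - d_ib`, `e^n` from the boundary
#' contact point toward the centre.
#'
#' @param pos_i centre; @param vel_i velocity; @param r_i radius.
#' @param geometry a [sim_geometry()]; @param cfg a [sim_config()].
#' @return Length-2 force.
#' @export
contact_force_boundary <- function(pos_i, vel_i, r_i, geometry, cfg) {
  f <- c(0, 0)
  for (k in seq_len(nrow(geometry$segments))) {
    ps <- point_segment(pos_i, geometry$segments[k, ])
    if (ps$dist >= r_i) next
    if (ps$dist == 0) stop("degenerate geometry: particle center on a wall")
    xi <- r_i - ps$dist
    en <- (pos_i - ps$point) / ps$dist
    et <- c(-en[2], en[1])
    vt <- -sum(vel_i * et)
    f <- f + xi * (cfg$k_n * en + cfg$k_t * vt * et)
  }
  f
}

#' Prescribed oscillating radii
#'
#' `r_i(t) = r0 (1 + A sin(omega t + phi_i))`. With `A = 0` the system is
#' monodisperse (all radii `r0`); with `omega = 0` the radii are constant
#' in time but differ across particles (polydisperse).
#'
#' @param t time; @param phases per-particle phases `phi_i`;
#' @param cfg a [sim_config()].
#' @return Numeric vector of radii.
#' @export
update_radii <- function(t, phases, cfg) {
  cfg$r0 * (1 + cfg$A * sin(cfg$omega * t + phases))
}

#' Particle state constructor
#'
#' @param positions N x 2 matrix; @param velocities N x 2 matrix;
#' @param phases length-N oscillation phases; @param cfg a [sim_config()];
#' @param t time at which the state holds (sets the radii).
#' @return A `particle_state`: list with `positions`, `velocities`,
#'   `radii`, `phases`, `t`.
#' @export
particle_state <- function(positions, velocities, phases, cfg, t = 0) {
  positions <- matrix(as.numeric(positions), ncol = 2)
  velocities <- matrix(as.numeric(velocities), ncol = 2)
  stopifnot(nrow(positions) == cfg$N, nrow(velocities) == cfg$N,
            length(phases) == cfg$N)
  structure(list(positions = positions, velocities = velocities,
                 radii = update_radii(t, phases, cfg),
                 phases = as.numeric(phases), t = t),
            class = "particle_state")
}

#' Place particles by rejection sampling
#'
#' Particles are placed sequentially at uniform random positions at least
#' one (current) radius away from every boundary; any candidate overlapping
#' an already placed particle is discarded and redrawn. Phases are drawn
#' uniformly from `[0, 2 pi)` first; initial velocities are zero. Initially
#' no two particles are in contact.
#'
#' @param cfg a [sim_config()]. Uses the current RNG state; call
#'   `set.seed()` (or use [run_simulation()], which seeds from
#'   `cfg$seed`) for reproducibility.
#' @return A [particle_state()] at `t = 0`.
#' @export
initialize_particles <- function(cfg) {
  N <- cfg$N
  phases <- runif(N, 0, 2 * pi)
  r <- update_radii(0, phases, cfg)
  if (2 * max(r) >= min(cfg$box_width, cfg$box_height))
    stop("box too small to place a particle")
  pos <- matrix(NA_real_, N, 2)
  for (i in seq_len(N)) {
    placed <- FALSE
    for (att in seq_len(cfg$init_attempt_cap)) {
      cand <- c(runif(1, r[i], cfg$box_width - r[i]),
                runif(1, r[i], cfg$box_height - r[i]))
      if (i > 1) {
        d <- sqrt(colSums((t(pos[seq_len(i - 1), , drop = FALSE]) - cand)^2))
        if (any((r[seq_len(i - 1)] + r[i]) - d > 0)) next
      }
      pos[i, ] <- cand
      placed <- TRUE
      break
    }
    if (!placed)
      stop("initialization density too high: could not place particle ", i,
           " after ", cfg$init_attempt_cap, " attempts")
  }
  particle_state(pos, matrix(0, N, 2), phases, cfg, t = 0)
}

#' Advance the state by one or more integration steps
#'
#' Velocity-Verlet integration (with a velocity predictor for the
#' velocity-dependent driving and friction terms) of the equation of
#' motion `m dv/dt = F_d + F_c`, with radii refreshed from the prescribed
#' oscillation before every force evaluation. Recycling of particles below
#' `removal_y` draws from R's RNG.
#'
#' @param state a [particle_state()]; @param cfg a [sim_config()];
#' @param n_steps number of steps of size `cfg$dt` (default 1).
#' @return The advanced `particle_state` (time `state$t + n_steps * dt`),
#'   with any exit events that occurred attached as attribute `events`
#'   (a data.frame `t, id`).
#' @export
integrate_step <- function(state, cfg, n_steps = 1) {
  res <- .cpp_run(state$positions[, 1], state$positions[, 2],
                  state$velocities[, 1], state$velocities[, 2],
                  state$phases, state$t, as.integer(n_steps), unclass(cfg),
                  0L, FALSE)
  out <- particle_state(cbind(res$x, res$y), cbind(res$vx, res$vy),
                        state$phases, cfg, t = res$t)
  attr(out, "events") <- order_events(res$events_t, res$events_id)
  out
}

# event log ordered by (interpolated) crossing time
order_events <- function(t, id) {
  o <- order(t)
  data.frame(t = t[o], id = id[o])
}

#' Run a full simulation
#'
#' Seeds the RNG from `cfg$seed`, initialises particles by rejection
#' sampling, integrates `T / dt` steps, records trajectory frames every
#' `dt_k`, logs an exit event whenever a particle centre crosses the exit
#' line moving downward (crossing time linearly interpolated within the
#' step), and recycles particles below `removal_y` back to the reinjection
#' region, conserving `N`. Identical `(cfg, seed)` give identical output.
#'
#' @param cfg a [sim_config()].
#' @param record_frames record trajectory frames (default TRUE; turn off to
#'   save memory when only the event log is needed).
#' @param state optional initial [particle_state()] overriding the seeded
#'   rejection-sampling initialisation.
#' @return An object of class `oscflow_sim`: list with `events`
#'   (data.frame `t, id`, ordered by `t`), `frames` (data.frame
#'   `t, id, x, y, vx, vy, r` or NULL), `final_state`, `config`,
#'   `n_recycled`, `n_recycle_deferred`.
#' @export
#' @examples
#' cfg <- scaled_config(N = 5, T = 2, seed = 1)
#' sim <- run_simulation(cfg)
#' nrow(sim$frames)  # 5 frames per particle: t = 0, 0.5, ..., 2
run_simulation <- function(cfg, record_frames = TRUE, state = NULL) {
  validate_config(cfg)
  set.seed(cfg$seed)
  if (is.null(state)) state <- initialize_particles(cfg)
  n_steps <- as.integer(round(cfg$T / cfg$dt))
  record_every <- if (record_frames) as.integer(round(cfg$dt_k / cfg$dt)) else 0L
  res <- .cpp_run(state$positions[, 1], state$positions[, 2],
                  state$velocities[, 1], state$velocities[, 2],
                  state$phases, state$t, n_steps, unclass(cfg),
                  record_every, TRUE)
  final <- particle_state(cbind(res$x, res$y), cbind(res$vx, res$vy),
                          state$phases, cfg, t = res$t)
  structure(list(events = order_events(res$events_t, res$events_id),
                 frames = res$frames,
                 final_state = final,
                 config = cfg,
                 n_recycled = res$n_recycled,
                 n_recycle_deferred = res$n_recycle_deferred),
            class = "oscflow_sim")
}

#' @export
print.oscflow_sim <- function(x, ...) {
  cat("<oscflow_sim>\n")
  cat(sprintf("  N = %d, T = %g, A = %g, omega = %g, k_n = %g, seed = %d\n",
              x$config$N, x$config$T, x$config$A, x$config$omega,
              x$config$k_n, x$config$seed))
  cat(sprintf("  exits: %d, recycled: %g\n", nrow(x$events), x$n_recycled))
  if (!is.null(x$frames))
    cat(sprintf("  frames: %d (every dt_k = %g)\n",
                length(unique(x$frames$t)), x$config$dt_k))
  invisible(x)
}
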