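# Independent R-level oracles built from the exported scalar primitives;
# used to cross-check the compiled neighbour-list force kernel.

# all-pairs + all-walls total force on every particle
oracle_total_forces <- function(state, cfg, t = state$t) {
  geo <- sim_geometry(cfg)
  N <- cfg$N
  r <- update_radii(t, state$phases, cfg)
  f <- matrix(0, N, 2)
  for (i in seq_len(N)) {
    f[i, ] <- driving_force(state$velocities[i, ], cfg) +
      contact_force_boundary(state$positions[i, ], state$velocities[i, ],
                             r[i], geo, cfg)
  }
  if (N >= 2) {
    for (i in seq_len(N - 1)) {
      for (j in (i + 1):N) {
        fij <- contact_force_pair(state$positions[i, ], state$positions[j, ],
                                  state$velocities[i, ], state$velocities[j, ],
                                  r[i], r[j], cfg)
        f[i, ] <- f[i, ] + fij
        f[j, ] <- f[j, ] - fij
      }
    }
  }
  f
}

cpp_total_forces_of <- function(state, cfg, t = state$t) {
  oscflow:::.cpp_total_forces(state$positions[, 1], state$positions[, 2],
                              state$velocities[, 1], state$velocities[, 2],
                              state$phases, t, unclass(cfg))
}

# random mid-box state with some particles pushed against walls/corners
random_state <- function(cfg, seed) {
  set.seed(seed)
  N <- cfg$N
  pos <- cbind(runif(N, 0.5, cfg$box_width - 0.5),
               runif(N, -2, cfg$box_height))
  vel <- matrix(rnorm(2 * N), N, 2)
  phases <- runif(N, 0, 2 * pi)
  particle_state(pos, vel, phases, cfg, t = runif(1, 0, 10))
}
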