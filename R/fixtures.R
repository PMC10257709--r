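#' Deterministic micro-scenarios
#'
#' Small hand-built initial conditions used to test the dynamics in
#' milliseconds. Registered names:
#' \describe{
#'   \item{free_particle}{one particle at rest mid-box, no oscillation:
#'     pure velocity relaxation toward `v_f` (closed form
#'     `|v(t)| = v_f (1 - exp(-t/tau))`).}
#'   \item{head_on_pair}{two particles overlapping by `xi = 0.1` on a
#'     horizontal axis, `v_f = 0`: equal and opposite normal forces of
#'     magnitude `k_n * xi`.}
#'   \item{wall_press}{one particle overlapping the left wall by 0.1 at
#'     rest, `v_f = 0`.}
#'   \item{corner_touch}{one particle overlapping the left orifice lip by
#'     0.05, `v_f = 0`.}
#'   \item{arch_at_orifice}{three rigid (`A = 0`) particles hand-placed to
#'     span the `D = 2.8` orifice: two disks wedged between the lips plus
#'     one on top. Under the contact law and the reference driving force
#'     they relax into a force-balanced symmetric arch that blocks the
#'     exit (verified over at least 50 time units; the symmetric arch is
#'     an unstable equilibrium, so it eventually collapses on much longer
#'     horizons).}
#'   \item{oscillating_singleton}{one particle with `A = 0.15`,
#'     `omega = 25`, `phi = 0`: kinematic radius-trace check.}
#' }
#'
#' @param name one of the registered scenario names.
#' @return List of class `scenario` with `name`, `config`
#'   (a [sim_config()]) and `state` (a [particle_state()]).
#' @export
#' @examples
#' sc <- make_scenario("free_particle")
#' st <- integrate_step(sc$state, sc$config, n_steps = 10)
make_scenario <- function(name) {
  registry <- c("free_particle", "head_on_pair", "wall_press",
                "corner_touch", "arch_at_orifice", "oscillating_singleton")
  if (!name %in% registry)
    stop("unknown scenario '", name, "'; registered: ",
         paste(registry, collapse = ", "))
  sc <- switch(name,
    free_particle = {
      cfg <- sim_config(N = 1, A = 0, T = 10)
      list(cfg = cfg, pos = rbind(c(10, 75)), phases = 0)
    },
    head_on_pair = {
      cfg <- sim_config(N = 2, A = 0, v_f = 0, T = 10)
      list(cfg = cfg, pos = rbind(c(9.05, 75), c(10.95, 75)), phases = c(0, 0))
    },
    wall_press = {
      cfg <- sim_config(N = 1, A = 0, v_f = 0, T = 10)
      list(cfg = cfg, pos = rbind(c(0.9, 50)), phases = 0)
    },
    corner_touch = {
      cfg <- sim_config(N = 1, A = 0, v_f = 0, T = 10)
      # left lip at (8.6, 0); centre 0.95 away along (1,1)/sqrt(2)
      lip <- c(cfg$orifice_cx - cfg$D / 2, 0)
      list(cfg = cfg, pos = rbind(lip + 0.95 / sqrt(2)), phases = 0)
    },
    arch_at_orifice = {
      cfg <- sim_config(N = 3, A = 0, T = 50)
      list(cfg = cfg, pos = .arch_coords, phases = c(0, 0, 0))
    },
    oscillating_singleton = {
      cfg <- sim_config(N = 1, A = 0.15, omega = 25, T = 10)
      list(cfg = cfg, pos = rbind(c(10, 75)), phases = 0)
    })
  state <- particle_state(sc$pos, matrix(0, nrow(sc$pos), 2), sc$phases,
                          sc$cfg, t = 0)
  structure(list(name = name, config = sc$cfg, state = state),
            class = "scenario")
}

# Three-particle arch over the D = 2.8 orifice (gap x in [8.6, 11.4]):
# two disks wedged symmetrically between the lips, one resting on top.
# Relaxes under the contact law + driving force to a force-balanced arch
# at ((9.001, 0.904), (10.999, 0.904), (10.000, 2.633)) with residual
# speeds < 2e-5, blocking the exit for at least 50 time units.
.arch_coords <- rbind(
  c(9.30, 0.20),
  c(10.70, 0.20),
  c(10.00, 1.40))

#' Inverse-CDF power-law sampler
#'
#' Draws from the continuous power law `p(x) ~ x^(-alpha)`, `x >= x_min`,
#' via `x = x_min * u^(-1/(alpha-1))` with `u ~ Uniform(0, 1)`.
#'
#' @param alpha exponent (> 1, else the density is non-normalisable).
#' @param x_min lower cutoff.
#' @param n sample size (>= 1).
#' @param seed optional seed (sets the global RNG).
#' @return Numeric vector of length `n`.
#' @export
sample_power_law <- function(alpha, x_min = 1, n, seed = NULL) {
  if (alpha <= 1) stop("non-normalizable: need alpha > 1")
  if (n < 1) stop("need n >= 1")
  stopifnot(x_min > 0)
  if (!is.null(seed)) set.seed(seed)
  x_min * runif(n)^(-1 / (alpha - 1))
}

#' Synthetic intermittent exit-event log
#'
#' Builds an event log alternating bursts (runs of `n_per_burst`
#' exponential inter-exit gaps with mean `mean_burst_gap`) and clogs
#' (single power-law distributed gaps with exponent `clog_alpha`),
#' emulating the empirical burst/clog phenomenology with known ground
#' truth, for end-to-end testing of the flow statistics. For
#' `clog_alpha > 2` the clog cutoff is set so the mean clog duration is
#' `mean_clog`; for `clog_alpha <= 2` the mean diverges and `mean_clog`
#' is used as the cutoff directly. `mean_clog = 0` requests a clog-free
#' (purely flowing) log.
#'
#' @param mean_burst_gap mean exponential gap within bursts.
#' @param mean_clog mean clog duration (or the cutoff when
#'   `clog_alpha <= 2`); 0 for no clogs.
#' @param clog_alpha clog power-law exponent (> 1).
#' @param n_events total number of exit events.
#' @param seed optional seed.
#' @param n_per_burst exits per burst (default 20).
#' @return data.frame `t, id` with attribute `truth`: a list holding the
#'   generating parameters, the clog cutoff `xmin_clog`, the analytic
#'   mean burst duration, and `phi_true` (NA when the clog mean
#'   diverges).
#' @export
sample_intermittent_log <- function(mean_burst_gap = 0.1, mean_clog = 10,
                                    clog_alpha = 3, n_events = 1000,
                                    seed = NULL, n_per_burst = 20) {
  stopifnot(mean_burst_gap > 0, mean_clog >= 0, clog_alpha > 1,
            n_events >= 2, n_per_burst >= 1)
  if (!is.null(seed)) set.seed(seed)
  gaps <- numeric(0)
  while (length(gaps) < n_events - 1) {
    gaps <- c(gaps, rexp(n_per_burst, rate = 1 / mean_burst_gap))
    if (mean_clog > 0) {
      xmin_clog <- if (clog_alpha > 2)
        mean_clog * (clog_alpha - 2) / (clog_alpha - 1) else mean_clog
      gaps <- c(gaps, sample_power_law(clog_alpha, xmin_clog, 1))
    }
  }
  gaps <- gaps[seq_len(n_events - 1)]
  times <- cumsum(c(0, gaps))
  mean_burst_true <- n_per_burst * mean_burst_gap
  xmin_clog <- if (mean_clog == 0) NA_real_
               else if (clog_alpha > 2) mean_clog * (clog_alpha - 2) / (clog_alpha - 1)
               else mean_clog
  phi_true <- if (mean_clog == 0) 1
              else if (clog_alpha <= 2) NA_real_
              else mean_burst_true / (mean_clog + mean_burst_true)
  out <- data.frame(t = times, id = seq_along(times))
  attr(out, "truth") <- list(mean_burst_gap = mean_burst_gap,
                             mean_clog = mean_clog, clog_alpha = clog_alpha,
                             n_per_burst = n_per_burst,
                             xmin_clog = xmin_clog,
                             mean_burst = mean_burst_true,
                             phi_true = phi_true)
  out
}
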