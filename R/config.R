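#' Simulation configuration
#'
#' Builds a validated configuration for the disk-flow simulator. The
#' defaults are the reference system: `N = 200` disks of rest radius
#' `r0 = 1` and mass `m = 1` (dimensionless units, `tau = 1`), normal
#' stiffness `k_n = 500` with tangential stiffness `k_t = 2 k_n`, free
#' speed `v_f = 3.3`, in a 20 x 150 box whose bottom wall has a centred
#' orifice of width `D = 2.8`. Radii oscillate as
#' `r_i(t) = r0 (1 + A sin(omega t + phi_i))` with a fixed random phase
#' per particle. Particles whose centre falls below `removal_y` are
#' reinjected at a random non-overlapping position in
#' `reinjection_x_range x reinjection_y_range`, conserving `N`.
#'
#' @param N number of particles.
#' @param m particle mass.
#' @param r0 rest radius.
#' @param tau velocity relaxation time of the driving force.
#' @param k_n normal (elastic) stiffness of contacts.
#' @param k_t tangential (frictional) stiffness; defaults to `2 * k_n`.
#' @param v_f free speed toward the destination direction (0, -1).
#' @param A radius oscillation amplitude, in `[0, 1)`.
#' @param omega radius oscillation angular frequency.
#' @param box_width,box_height box dimensions.
#' @param D orifice width; must satisfy `0 < D < box_width`.
#' @param orifice_cx x-position of the orifice centre (default: centred).
#' @param exit_y y-coordinate of the exit line (bottom wall).
#' @param removal_y y below which particles are recycled.
#' @param reinjection_x_range,reinjection_y_range reinjection box.
#' @param dt integration time step.
#' @param dt_k recording interval for trajectory frames.
#' @param T total simulated time.
#' @param seed RNG seed used for initialisation and recycling.
#' @param recycle_keep_velocity keep (TRUE) or zero (FALSE, default) the
#'   velocity of reinjected particles.
#' @param recycle_cap rejection-sampling attempts per recycled particle and
#'   step before it is parked below `removal_y` and retried next step.
#' @param init_attempt_cap rejection-sampling attempts per particle at
#'   initialisation before an error is raised.
#'
#' @return An object of class `sim_config` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(N = 10, T = 1)
#' cfg$D
sim_config <- function(N = 200, m = 1, r0 = 1, tau = 1,
                       k_n = 500, k_t = 2 * k_n, v_f = 3.3,
                       A = 0.15, omega = 25,
                       box_width = 20, box_height = 150,
                       D = 2.8, orifice_cx = box_width / 2,
                       exit_y = 0, removal_y = -15,
                       reinjection_x_range = c(2, 18),
                       reinjection_y_range = c(100, 150),
                       dt = 1e-4, dt_k = 0.5, T = 5000, seed = 1L,
                       recycle_keep_velocity = FALSE,
                       recycle_cap = 10000L,
                       init_attempt_cap = 10000L) {
  cfg <- list(N = as.integer(N), m = m, r0 = r0, tau = tau,
              k_n = k_n, k_t = k_t, v_f = v_f, A = A, omega = omega,
              box_width = box_width, box_height = box_height,
              D = D, orifice_cx = orifice_cx,
              exit_y = exit_y, removal_y = removal_y,
              reinjection_x_range = as.numeric(reinjection_x_range),
              reinjection_y_range = as.numeric(reinjection_y_range),
              dt = dt, dt_k = dt_k, T = T, seed = as.integer(seed),
              recycle_keep_velocity = isTRUE(recycle_keep_velocity),
              recycle_cap = as.integer(recycle_cap),
              init_attempt_cap = as.integer(init_attempt_cap))
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  N = %d, m = %g, r0 = %g, tau = %g\n", x$N, x$m, x$r0, x$tau))
  cat(sprintf("  k_n = %g, k_t = %g, v_f = %g\n", x$k_n, x$k_t, x$v_f))
  cat(sprintf("  A = %g, omega = %g\n", x$A, x$omega))
  cat(sprintf("  box %g x %g, orifice D = %g at x = %g\n",
              x$box_width, x$box_height, x$D, x$orifice_cx))
  cat(sprintf("  dt = %g, dt_k = %g, T = %g, seed = %d\n",
              x$dt, x$dt_k, x$T, x$seed))
  invisible(x)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with(cfg, {
    if (!(D > 0 && D < box_width)) stop("require 0 < D < box_width")
    if (!(dt > 0 && dt < dt_k && (T == 0 || dt_k <= T)))
      stop("require dt < dt_k <= T (or T = 0)")
    if (!(A >= 0 && A < 1)) stop("require 0 <= A < 1 (radius must stay positive)")
    if (!all(c(k_n, k_t, m, tau, r0) > 0)) stop("k_n, k_t, m, tau, r0 must be > 0")
    if (v_f < 0) stop("v_f must be >= 0")
    if (N < 1) stop("N must be >= 1")
    if (omega < 0) stop("omega must be >= 0")
    if (removal_y >= exit_y) stop("removal_y must lie below exit_y")
    if (orifice_cx - D / 2 <= 0 || orifice_cx + D / 2 >= box_width)
      stop("orifice must lie strictly inside the bottom wall")
    if (diff(reinjection_x_range) <= 0 || diff(reinjection_y_range) <= 0)
      stop("reinjection ranges must be increasing")
  })
  invisible(cfg)
}

#' Scaled-down configuration
#'
#' A smaller system preserving the constriction physics (same `D`, `k_n`,
#' `v_f`, `dt`, particle properties) at roughly 20x lower cost: `N = 60`
#' particles in a 20 x 60 box with reinjection at y in (40, 60). Used for
#' fast, repeatable experiments; full-scale parameters remain the
#' [sim_config()] defaults.
#'
#' @param ... overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
scaled_config <- function(...) {
  args <- list(...)
  base <- list(N = 60, box_height = 60, reinjection_y_range = c(40, 60),
               T = 1000)
  base[names(args)] <- args
  do.call(sim_config, base)
}

#' Read / write a configuration file
#'
#' Configurations are stored as YAML key-value files mirroring the
#' [sim_config()] field names; missing keys take the reference defaults, so
#' an empty file reproduces the reference system.
#'
#' @param path file path.
#' @return `read_config()` returns a `sim_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  # a bare, unquoted N is a YAML 1.1 boolean literal; map it back
  names(vals)[names(vals) == "FALSE"] <- "N"
  names(vals)[names(vals) == "TRUE"] <- "T"
  known <- names(formals(sim_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  do.call(sim_config, vals)
}

#' @param cfg a `sim_config`.
#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
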