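#' Read and write exit-event logs
#'
#' Exit events are stored as CSV with header `t,id`, strictly ordered by
#' `t`. Any conforming CSV from another source is accepted.
#'
#' @param events data.frame with columns `t`, `id`.
#' @param path file path.
#' @return `read_events()` returns the data.frame ordered by `t`.
#' @export
write_events <- function(events, path) {
  stopifnot(all(c("t", "id") %in% names(events)))
  write.csv(events[order(events$t), c("t", "id")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- read.csv(path)
  stopifnot(all(c("t", "id") %in% names(ev)))
  ev[order(ev$t), c("t", "id")]
}

#' Read and write trajectory frames
#'
#' Columnar CSV with header `t,id,x,y,vx,vy,r`: one row per particle per
#' recorded frame.
#'
#' @param frames trajectory data.frame from [run_simulation()].
#' @param path file path.
#' @return `read_trajectory()` returns the data.frame.
#' @export
write_trajectory <- function(frames, path) {
  cols <- c("t", "id", "x", "y", "vx", "vy", "r")
  stopifnot(all(cols %in% names(frames)))
  write.csv(frames[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  fr <- read.csv(path)
  stopifnot(all(c("t", "id", "x", "y", "vx", "vy", "r") %in% names(fr)))
  fr
}

#' Write a run manifest
#'
#' YAML metadata for a completed simulation: configuration, seed, package
#' version, and event/frame counts.
#'
#' @param sim an `oscflow_sim` from [run_simulation()].
#' @param path file path.
#' @export
write_manifest <- function(sim, path) {
  stopifnot(inherits(sim, "oscflow_sim"))
  yaml::write_yaml(list(
    package = "oscflow",
    version = as.character(packageVersion("oscflow")),
    config = unclass(sim$config),
    n_events = nrow(sim$events),
    n_frames = if (!is.null(sim$frames)) length(unique(sim$frames$t)) else 0L,
    n_recycled = sim$n_recycled,
    n_recycle_deferred = sim$n_recycle_deferred), path)
  invisible(path)
}
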