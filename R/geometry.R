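#' Box geometry with a bottom orifice
#'
#' Builds the wall description used by the contact model: the left and
#' right side walls and the two bottom segments flanking the orifice. The
#' orifice lips (the inner endpoints of the bottom segments) act as corner
#' contact points: a disk touching a lip feels a normal force along the
#' line from the lip to its centre, with the same `k_n`/`k_t` contact law.
#'
#' @param cfg a [sim_config()].
#' @return An object of class `sim_geometry` with elements `segments`
#'   (a 4 x 4 matrix of `x1, y1, x2, y2` rows) and `lips` (a 2 x 2 matrix
#'   of orifice corner coordinates).
#' @export
sim_geometry <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  gl <- cfg$orifice_cx - cfg$D / 2
  gr <- cfg$orifice_cx + cfg$D / 2
  segs <- rbind(
    left   = c(0, 0, 0, cfg$box_height),
    right  = c(cfg$box_width, 0, cfg$box_width, cfg$box_height),
    bottom_left  = c(0, 0, gl, 0),
    bottom_right = c(gr, 0, cfg$box_width, 0))
  colnames(segs) <- c("x1", "y1", "x2", "y2")
  lips <- rbind(left = c(gl, 0), right = c(gr, 0))
  colnames(lips) <- c("x", "y")
  structure(list(segments = segs, lips = lips), class = "sim_geometry")
}

# distance from point p to segment s (x1,y1,x2,y2), plus the closest point
point_segment <- function(p, s) {
  d <- c(s[3] - s[1], s[4] - s[2])
  L2 <- sum(d^2)
  t <- ((p[1] - s[1]) * d[1] + (p[2] - s[2]) * d[2]) / L2
  t <- min(max(t, 0), 1)
  cp <- unname(c(s[1], s[2]) + t * d)
  list(dist = sqrt(sum((p - cp)^2)), point = cp)
}
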