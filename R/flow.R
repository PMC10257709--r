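as_event_times <- function(events) {
  t <- if (is.data.frame(events)) events$t else as.numeric(events)
  if (is.unsorted(t)) t <- sort(t)
  t
}

#' Inter-exit time intervals
#'
#' Successive differences `dt_out` of exit-event times: the time between
#' consecutive particles passing through the exit, regardless of flow
#' state.
#'
#' @param events exit-event log: a data.frame with column `t` (as produced
#'   by [run_simulation()]) or a numeric vector of event times.
#' @return Numeric vector of length `n_events - 1`, all positive.
#' @export
exit_intervals <- function(events) {
  t <- as_event_times(events)
  if (length(t) < 2)
    stop("insufficient data: need at least 2 exit events")
  diff(t)
}

#' Flow rate with 95% confidence interval
#'
#' Fits a least-squares line to the cumulative exit count versus time over
#' `[t_start, t_end]`; the slope is the flow rate `Q` and the standard 95%
#' confidence interval of the slope is reported. The identity estimator
#' `1 / mean(dt_out)` over the same window is also returned; for a steady
#' flow the two agree.
#'
#' @param events exit-event log (see [exit_intervals()]).
#' @param t_start,t_end analysis window. `t_start` defaults to the later
#'   of `burnin` and the first exit; `t_end` to the last exit.
#' @param burnin default start of the window, discarding the filling
#'   transient (time units; default 100).
#' @return A list of class `flow_rate` with `Q`, `ci95` (length 2),
#'   `Q_identity`, `n_events`, `window`, and `empty` (TRUE when fewer than
#'   2 events fall in the window, in which case `Q = 0`).
#' @export
flow_rate <- function(events, t_start = NULL, t_end = NULL, burnin = 100) {
  t_all <- as_event_times(events)
  if (is.null(t_start))
    t_start <- if (length(t_all)) max(burnin, t_all[1]) else burnin
  if (is.null(t_end))
    t_end <- if (length(t_all)) t_all[length(t_all)] else t_start
  tw <- t_all[t_all >= t_start & t_all <= t_end]
  if (length(tw) < 2) {
    out <- list(Q = 0, ci95 = c(0, 0), Q_identity = 0, n_events = length(tw),
                window = c(t_start, t_end), empty = TRUE)
    class(out) <- "flow_rate"
    return(out)
  }
  nw <- length(tw)
  q_ident <- 1 / mean(diff(tw))
  cum <- seq_along(tw)
  # anchor the cumulative curve at the window edges so clogged stretches
  # before the first / after the last exit lower the slope
  if (t_start < tw[1]) { tw <- c(t_start, tw); cum <- c(0, cum) }
  n_in <- cum[length(cum)]
  if (t_end > tw[length(tw)]) { tw <- c(tw, t_end); cum <- c(cum, n_in) }
  fit <- lm(cum ~ tw)
  # a perfectly steady flow gives an exact fit; that is a valid input here
  ci <- suppressWarnings(confint(fit, "tw", level = 0.95))
  out <- list(Q = unname(coef(fit)["tw"]),
              ci95 = as.numeric(ci),
              Q_identity = q_ident,
              n_events = nw,
              window = c(t_start, t_end),
              empty = FALSE)
  class(out) <- "flow_rate"
  out
}

#' @export
print.flow_rate <- function(x, ...) {
  cat(sprintf("Q = %.4g  [95%% CI %.4g, %.4g]  (identity 1/<dt_out> = %.4g, n = %d)\n",
              x$Q, x$ci95[1], x$ci95[2], x$Q_identity, x$n_events))
  invisible(x)
}

#' Power-law fit of the inter-exit-time tail (Clauset-Shalizi-Newman)
#'
#' Fits `p(x) ~ x^(-alpha)` for `x >= x_min` by continuous maximum
#' likelihood, `alpha = 1 + n / sum(log(x_i / x_min))`, selecting `x_min`
#' as the sample value minimising the Kolmogorov-Smirnov distance between
#' the tail empirical distribution and the fitted power law. Candidate
#' `x_min` values are the unique sample values whose tail holds at least
#' `min_tail` points; KS ties are broken toward smaller `x_min` (larger
#' tail). An optional parametric bootstrap gives a goodness-of-fit
#' p-value.
#'
#' @param samples positive numeric sample (e.g. `dt_out` intervals).
#' @param xmin fix the lower cutoff instead of estimating it.
#' @param min_tail minimum tail size for candidate cutoffs (default 10).
#' @param gof_bootstrap number of parametric bootstrap replicates for the
#'   goodness-of-fit p-value; 0 (default) skips it.
#' @return Object of class `powerlaw_fit`: `alpha`, `xmin`, `n_tail`,
#'   `ks_distance`, `alpha_se` (asymptotic `(alpha - 1)/sqrt(n)`), and
#'   `gof_p` when bootstrapped.
#' @export
fit_power_law <- function(samples, xmin = NULL, min_tail = 10,
                          gof_bootstrap = 0) {
  x <- as.numeric(samples)
  x <- x[is.finite(x) & x > 0]
  if (length(unique(x)) < 2)
    stop("degenerate sample: all values identical")
  if (!is.null(xmin)) {
    fit <- .pl_fit_at(x, xmin)
    if (fit$n < 2) stop("insufficient tail: fewer than 2 samples >= xmin")
  } else {
    xs <- sort(x)
    n <- length(xs)
    logx <- log(xs)
    suf <- rev(cumsum(rev(logx)))  # suffix sums of log(x)
    first_idx <- which(!duplicated(xs))             # first index of each unique value
    first_idx <- first_idx[n - first_idx + 1 >= max(min_tail, 2)]
    if (!length(first_idx))
      stop("insufficient tail: no cutoff leaves at least ", min_tail, " samples")
    best <- NULL
    for (k in first_idx) {
      m <- n - k + 1
      slog <- suf[k] - m * logx[k]
      if (slog <= 0) next
      alpha <- 1 + m / slog
      tail <- xs[k:n]
      Fx <- 1 - (tail / xs[k])^(1 - alpha)
      i <- seq_len(m)
      ks <- max(pmax(abs(Fx - i / m), abs(Fx - (i - 1) / m)))
      if (is.null(best) || ks < best$ks)  # strict <: ties go to smaller xmin
        best <- list(alpha = alpha, xmin = xs[k], n = m, ks = ks)
    }
    if (is.null(best)) stop("degenerate sample: power-law MLE undefined")
    fit <- best
  }
  out <- list(alpha = fit$alpha, xmin = fit$xmin, n_tail = fit$n,
              ks_distance = fit$ks,
              alpha_se = (fit$alpha - 1) / sqrt(fit$n))
  if (gof_bootstrap > 0) {
    ks_boot <- replicate(gof_bootstrap, {
      xs <- fit$xmin * runif(fit$n)^(-1 / (fit$alpha - 1))
      .pl_fit_at(xs, fit$xmin)$ks
    })
    out$gof_p <- mean(ks_boot >= fit$ks)
  }
  class(out) <- "powerlaw_fit"
  out
}

.pl_fit_at <- function(x, xmin) {
  tail <- sort(x[x >= xmin])
  n <- length(tail)
  slog <- sum(log(tail / xmin))
  alpha <- if (slog > 0) 1 + n / slog else Inf
  # KS distance between the tail ECDF and the fitted CDF
  Fx <- 1 - (tail / xmin)^(1 - alpha)
  ks <- max(pmax(abs(Fx - seq_len(n) / n), abs(Fx - (seq_len(n) - 1) / n)))
  list(alpha = alpha, xmin = xmin, n = n, ks = ks)
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("power law: alpha = %.3f (se %.3f), xmin = %.4g, tail n = %d, KS = %.4f\n",
              x$alpha, x$alpha_se, x$xmin, x$n_tail, x$ks_distance))
  if (!is.null(x$gof_p)) cat(sprintf("  bootstrap GoF p = %.3f\n", x$gof_p))
  invisible(x)
}

#' Decompose the event log into bursts and clogs
#'
#' Every inter-exit interval at least as long as the power-law cutoff
#' `dt_out_min` is a clog of that duration; maximal runs of consecutive
#' shorter intervals are merged into single bursts whose duration is their
#' sum. Bursts and clogs interleave, and their total duration equals the
#' time spanned by the event log exactly.
#'
#' @param events exit-event log (see [exit_intervals()]).
#' @param dt_out_min clog threshold, normally the fitted `xmin` from
#'   [fit_power_law()].
#' @return List with `bursts` and `clogs` (numeric duration vectors).
#' @export
decompose_bursts_clogs <- function(events, dt_out_min) {
  iv <- exit_intervals(events)
  is_clog <- iv >= dt_out_min
  clogs <- iv[is_clog]
  r <- rle(!is_clog)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  bursts <- vapply(which(r$values),
                   function(k) sum(iv[starts[k]:ends[k]]), 0)
  list(bursts = as.numeric(bursts), clogs = as.numeric(clogs))
}

#' Flowing parameter and flow-state classification
#'
#' `Phi = <dt_f> / (<dt_c> + <dt_f>)`, the long-run fraction of time the
#' constriction is flowing. When the clog-time power-law exponent
#' `alpha <= 2` the mean clog time diverges, so `Phi` is forced to 0:
#' the system is clogged in the limit of infinitely long runs even if it
#' shows flowing periods. Labels: clogged (`Phi = 0`), intermittent
#' (`0 < Phi < 1`), flowing (`Phi = 1`, no clogs).
#'
#' @param bursts,clogs duration vectors from [decompose_bursts_clogs()].
#' @param alpha fitted clog-tail exponent (optional; supply it whenever
#'   clogs are present so the diverging-mean rule can apply).
#' @return List of class `flow_classification`: `phi`, `mean_burst`,
#'   `mean_clog`, `label`.
#' @export
flowing_parameter <- function(bursts, clogs, alpha = NULL) {
  mean_burst <- if (length(bursts)) mean(bursts) else 0
  mean_clog <- if (length(clogs)) mean(clogs) else 0
  phi <- if (!length(clogs)) 1
         else if (!length(bursts)) 0
         else mean_burst / (mean_clog + mean_burst)
  if (length(clogs) && !is.null(alpha) && is.finite(alpha) && alpha <= 2)
    phi <- 0
  label <- if (phi == 0) "clogged" else if (phi == 1) "flowing" else "intermittent"
  structure(list(phi = phi, mean_burst = mean_burst, mean_clog = mean_clog,
                 label = label),
            class = "flow_classification")
}

#' @export
print.flow_classification <- function(x, ...) {
  cat(sprintf("Phi = %.3f (%s); <dt_f> = %.3g, <dt_c> = %.3g\n",
              x$phi, x$label, x$mean_burst, x$mean_clog))
  invisible(x)
}

#' Bulk measurement region
#'
#' The rectangular bulk region above the orifice in which contact
#' observables are measured; defaults to `x in [2, 18]`, `y in [2, 30]`
#' (area 16 x 28 = 448).
#'
#' @param x_range,y_range region bounds.
#' @return List with `x_range`, `y_range`, `area`.
#' @export
measurement_region <- function(x_range = c(2, 18), y_range = c(2, 30)) {
  stopifnot(diff(x_range) > 0, diff(y_range) > 0)
  list(x_range = as.numeric(x_range), y_range = as.numeric(y_range),
       area = diff(x_range) * diff(y_range))
}

#' Bulk contact observables
#'
#' For each recorded frame, particles whose centres lie in the measurement
#' region are counted (`n`), and each is classified as contact-free or
#' contacting. Contact status uses all contacts, including partners
#' outside the region. Per frame: contactless probability
#' `P_free = n_free / n`, density `rho = n / area`, number of contacting
#' particles `n_c = n - n_free`, and mean overlap
#' `xi_c = (1/n_c) sum_i xi_i` where `xi_i` is the summed overlap of
#' contacting in-region particle i with all its partners (each contacting
#' pair inside the region thus contributes its overlap once per member).
#' Time averages and standard deviations over frames are returned; frames
#' with no in-region particle are skipped for `P_free` (and counted), and
#' frames with no contacting particle are skipped for `xi_c`.
#'
#' @param frames trajectory data.frame `t, id, x, y, vx, vy, r` from
#'   [run_simulation()] (or [read_trajectory()]).
#' @param region a [measurement_region()].
#' @return List of class `bulk_observables`: `p_free`, `rho`, `n_c`,
#'   `xi_c` (each a list with `mean` and `sd`), `n_frames`,
#'   `n_skipped_empty`, `n_skipped_nocontact`.
#' @export
bulk_observables <- function(frames, region = measurement_region()) {
  if (is.null(frames) || !nrow(frames))
    stop("insufficient data: no trajectory frames")
  per <- lapply(split(frames[c("x", "y", "r")], frames$t), function(fr) {
    inreg <- fr$x >= region$x_range[1] & fr$x <= region$x_range[2] &
             fr$y >= region$y_range[1] & fr$y <= region$y_range[2]
    n <- sum(inreg)
    np <- nrow(fr)
    contacting <- rep(FALSE, np)
    xi_sum <- rep(0, np)
    if (np >= 2) {
      d <- as.matrix(stats::dist(cbind(fr$x, fr$y)))
      xi <- outer(fr$r, fr$r, "+") - d
      diag(xi) <- -Inf
      pos <- xi > 0
      contacting <- rowSums(pos) > 0
      xi[!pos] <- 0
      xi_sum <- rowSums(xi)
    }
    n_free <- sum(inreg & !contacting)
    n_c <- n - n_free
    c(n = n,
      p_free = if (n > 0) n_free / n else NA_real_,
      rho = n / region$area,
      n_c = n_c,
      xi_c = if (n_c > 0) sum(xi_sum[inreg & contacting]) / n_c else NA_real_)
  })
  m <- do.call(rbind, per)
  msd <- function(v) {
    v <- v[is.finite(v)]
    list(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0)
  }
  structure(list(p_free = msd(m[, "p_free"]),
                 rho = msd(m[, "rho"]),
                 n_c = msd(m[, "n_c"]),
                 xi_c = msd(m[, "xi_c"]),
                 n_frames = nrow(m),
                 n_skipped_empty = sum(m[, "n"] == 0),
                 n_skipped_nocontact = sum(!is.finite(m[, "xi_c"]))),
            class = "bulk_observables")
}

#' @export
print.bulk_observables <- function(x, ...) {
  cat(sprintf("bulk observables over %d frames:\n", x$n_frames))
  cat(sprintf("  <P_free> = %.4f (sd %.4f)\n", x$p_free$mean, x$p_free$sd))
  cat(sprintf("  <rho>    = %.4f (sd %.4f)\n", x$rho$mean, x$rho$sd))
  cat(sprintf("  <n_c>    = %.2f (sd %.2f)\n", x$n_c$mean, x$n_c$sd))
  cat(sprintf("  <xi_c>   = %.4f (sd %.4f)\n", x$xi_c$mean, x$xi_c$sd))
  invisible(x)
}

#' Driven-oscillator resonance amplitude
#'
#' Relative steady-state amplitude of a damped harmonic oscillator of
#' natural frequency `omega0` driven at `omega`:
#' `1 / sqrt((2 omega omega0 zeta)^2 + (omega^2 - omega0^2)^2)`. A single
#' resonance peak at `omega0 sqrt(1 - 2 zeta^2)` (for `zeta < 1/sqrt(2)`),
#' vanishing as `omega -> Inf`; used to compare measured flow-rate curves
#' against driven-oscillator theory.
#'
#' @param omega driving frequency (vectorised).
#' @param omega0 natural frequency (> 0).
#' @param zeta damping ratio (>= 0).
#' @return Numeric vector; `Inf` (with attribute `divergent = TRUE`) at
#'   the undamped resonance `omega = omega0`, `zeta = 0`.
#' @export
resonance_amplitude <- function(omega, omega0, zeta) {
  stopifnot(omega0 > 0, zeta >= 0)
  denom2 <- (2 * omega * omega0 * zeta)^2 + (omega^2 - omega0^2)^2
  out <- ifelse(denom2 == 0, Inf, 1 / sqrt(denom2))
  if (any(is.infinite(out))) attr(out, "divergent") <- TRUE
  out
}

#' Full event-log analysis
#'
#' Convenience wrapper combining [flow_rate()], [fit_power_law()],
#' [decompose_bursts_clogs()] and [flowing_parameter()] for one run. For
#' runs that arrest (last exit before `0.9 * T`) the flow rate is also
#' reported as total exits over the full duration, with an `arrested`
#' flag.
#'
#' @param events exit-event log; @param T total simulated time;
#' @param burnin regression burn-in (see [flow_rate()]);
#' @param min_tail minimum power-law tail size (see [fit_power_law()]).
#' @return List of class `flow_analysis` with `Q`, `ci95`, `Q_identity`,
#'   `Q_overall` (exits / T), `arrested`, `alpha`, `dt_out_min`, `phi`,
#'   `label`, `n_events`.
#' @export
analyze_events <- function(events, T, burnin = 100, min_tail = 10) {
  t <- as_event_times(events)
  n <- length(t)
  arrested <- n == 0 || t[n] < 0.9 * T
  fr <- flow_rate(events, burnin = burnin)
  fit <- tryCatch(fit_power_law(exit_intervals(events), min_tail = min_tail),
                  error = function(e) NULL)
  cls <- if (!is.null(fit)) {
    bc <- decompose_bursts_clogs(events, fit$xmin)
    flowing_parameter(bc$bursts, bc$clogs, fit$alpha)
  } else NULL
  structure(list(Q = fr$Q, ci95 = fr$ci95, Q_identity = fr$Q_identity,
                 Q_overall = n / T, arrested = arrested,
                 alpha = if (!is.null(fit)) fit$alpha else NA_real_,
                 dt_out_min = if (!is.null(fit)) fit$xmin else NA_real_,
                 phi = if (!is.null(cls)) cls$phi else NA_real_,
                 label = if (!is.null(cls)) cls$label else NA_character_,
                 n_events = n),
            class = "flow_analysis")
}

#' @export
print.flow_analysis <- function(x, ...) {
  cat(sprintf("flow analysis: %d exits%s\n", x$n_events,
              if (x$arrested) " (arrested)" else ""))
  cat(sprintf("  Q = %.4g [%.4g, %.4g], exits/T = %.4g\n",
              x$Q, x$ci95[1], x$ci95[2], x$Q_overall))
  cat(sprintf("  alpha = %.3g, dt_out_min = %.3g, Phi = %.3g (%s)\n",
              x$alpha, x$dt_out_min, x$phi, x$label))
  invisible(x)
}
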