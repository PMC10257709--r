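#' Parameter sweep specification
#'
#' Describes a sweep of one model parameter over a grid, with several
#' replicate seeds per grid point. When `k_n` is swept, the tangential
#' stiffness is coupled as `k_t = 2 k_n` so the friction force stays
#' approximately constant (the overlap shrinks as `k_n` grows).
#' Per-run seeds are derived deterministically from the master seed and
#' the grid/replicate indices.
#'
#' @param base a [sim_config()] providing all non-swept parameters.
#' @param param swept parameter name: one of `"A"`, `"omega"`, `"v_f"`,
#'   `"k_n"`.
#' @param values numeric grid, strictly increasing.
#' @param n_seeds replicate seeds per grid point.
#' @param master_seed master seed from which per-run seeds are derived.
#' @return Object of class `sweep_spec`.
#' @export
sweep_spec <- function(base, param = c("A", "omega", "v_f", "k_n"),
                       values, n_seeds = 3, master_seed = 1L) {
  param <- match.arg(param)
  validate_config(base)
  values <- as.numeric(values)
  if (!length(values) || is.unsorted(values, strictly = TRUE))
    stop("values must be a non-empty, strictly increasing grid")
  structure(list(base = base, param = param, values = values,
                 n_seeds = as.integer(n_seeds),
                 master_seed = as.integer(master_seed)),
            class = "sweep_spec")
}

sweep_seed <- function(master_seed, grid_index, seed_index, n_seeds) {
  # deterministic, distinct per (point, replicate); kept below 2^31
  as.integer((as.numeric(master_seed) * 10007 +
                (grid_index - 1) * n_seeds + seed_index) %% 2147483647)
}

sweep_run_config <- function(spec, value, seed) {
  cfg <- spec$base
  cfg[[spec$param]] <- value
  if (spec$param == "k_n") cfg$k_t <- 2 * value
  cfg$seed <- as.integer(seed)
  validate_config(cfg)
  cfg
}

#' Run a parameter sweep
#'
#' Runs one simulation per (grid point, seed), analyses each event log
#' with [analyze_events()] (and optionally [bulk_observables()]), and
#' aggregates per grid point. Individual run failures are recorded and the
#' sweep continues. With `out_dir` set, per-run results are written as CSV
#' and completed runs are skipped on re-invocation (resumable).
#'
#' @param spec a [sweep_spec()].
#' @param collect_bulk also compute bulk contact observables (requires
#'   recording frames; slower).
#' @param region measurement region for bulk observables.
#' @param burnin flow-rate regression burn-in (see [flow_rate()]).
#' @param out_dir optional directory for per-run CSVs and resumability.
#' @param quiet suppress progress messages.
#' @return List of class `sweep_result`: `raw` (one row per run) and
#'   `aggregate` (one row per grid point: seed-means and sd of Q, and the
#'   other statistics), plus the `spec`.
#' @export
run_sweep <- function(spec, collect_bulk = FALSE,
                      region = measurement_region(), burnin = 100,
                      out_dir = NULL, quiet = TRUE) {
  stopifnot(inherits(spec, "sweep_spec"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  rows <- list()
  for (gi in seq_along(spec$values)) {
    for (si in seq_len(spec$n_seeds)) {
      value <- spec$values[gi]
      seed <- sweep_seed(spec$master_seed, gi, si, spec$n_seeds)
      tag <- sprintf("%s_%g_seed%d", spec$param, value, seed)
      cache <- if (!is.null(out_dir)) file.path(out_dir, paste0(tag, ".csv"))
      if (!is.null(cache) && file.exists(cache)) {
        rows[[tag]] <- read.csv(cache)
        next
      }
      if (!quiet) message("run ", tag)
      row <- tryCatch({
        cfg <- sweep_run_config(spec, value, seed)
        sim <- run_simulation(cfg, record_frames = collect_bulk)
        an <- analyze_events(sim$events, cfg$T, burnin = burnin)
        r <- data.frame(param = spec$param, value = value, seed = seed,
                        Q = an$Q, ci_lo = an$ci95[1], ci_hi = an$ci95[2],
                        Q_identity = an$Q_identity, Q_overall = an$Q_overall,
                        arrested = an$arrested, alpha = an$alpha,
                        dt_out_min = an$dt_out_min, phi = an$phi,
                        label = an$label, n_events = an$n_events,
                        failed = FALSE, error = NA_character_)
        if (collect_bulk) {
          bo <- bulk_observables(sim$frames, region)
          r$p_free <- bo$p_free$mean; r$p_free_sd <- bo$p_free$sd
          r$rho <- bo$rho$mean;       r$rho_sd <- bo$rho$sd
          r$n_c <- bo$n_c$mean;       r$n_c_sd <- bo$n_c$sd
          r$xi_c <- bo$xi_c$mean;     r$xi_c_sd <- bo$xi_c$sd
        }
        r
      }, error = function(e) {
        data.frame(param = spec$param, value = value, seed = seed,
                   Q = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                   Q_identity = NA_real_, Q_overall = NA_real_,
                   arrested = NA, alpha = NA_real_, dt_out_min = NA_real_,
                   phi = NA_real_, label = NA_character_,
                   n_events = NA_integer_, failed = TRUE,
                   error = conditionMessage(e))
      })
      if (!is.null(cache)) write.csv(row, cache, row.names = FALSE)
      rows[[tag]] <- row
    }
  }
  raw <- do.call(rbind, c(rows, make.row.names = FALSE))
  ok <- raw[!raw$failed, , drop = FALSE]
  agg <- do.call(rbind, lapply(split(ok, ok$value), function(g) {
    data.frame(param = g$param[1], value = g$value[1], n_runs = nrow(g),
               Q = mean(g$Q), Q_sd = sd_or_zero(g$Q),
               Q_identity = mean(g$Q_identity),
               Q_overall = mean(g$Q_overall),
               frac_arrested = mean(g$arrested),
               alpha = mean(g$alpha, na.rm = TRUE),
               phi = mean(g$phi, na.rm = TRUE))
  }))
  agg <- agg[order(agg$value), , drop = FALSE]
  rownames(agg) <- NULL
  structure(list(raw = raw, aggregate = agg, spec = spec),
            class = "sweep_result")
}

sd_or_zero <- function(x) if (length(x) > 1) sd(x) else 0

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s over %d points x %d seeds\n",
              x$spec$param, length(x$spec$values), x$spec$n_seeds))
  print(x$aggregate, digits = 4)
  invisible(x)
}

#' Locate the optimal oscillation frequency
#'
#' Finds the frequency maximising the seed-mean flow rate on the sweep
#' grid. The uncertainty combines, in quadrature, half the local grid
#' spacing at the argmax with the bootstrap standard deviation of the
#' argmax over seed resamples. Ties are broken toward lower frequency.
#' Flags: `boundary` when the argmax sits on a grid end, and
#' `no_resonance` when the maximum mean is within the combined 95%
#' confidence band of the minimum mean (flat response).
#'
#' @param sweep a `sweep_result` from an omega sweep, or a data.frame with
#'   columns `value` (omega), `seed`, `Q`.
#' @param n_boot bootstrap replicates over seeds (default 200).
#' @return List of class `resonance_result`: `omega_star`,
#'   `omega_star_se`, `Q_max`, `table` (mean Q per omega), `boundary`,
#'   `no_resonance`.
#' @export
find_omega_star <- function(sweep, n_boot = 200) {
  raw <- if (inherits(sweep, "sweep_result")) sweep$raw else sweep
  raw <- raw[is.finite(raw$Q), , drop = FALSE]
  omegas <- sort(unique(raw$value))
  if (length(omegas) < 3) stop("need at least 3 distinct omega grid points")
  qs <- split(raw$Q, factor(raw$value, levels = omegas))
  meanQ <- vapply(qs, mean, 0)
  seQ <- vapply(qs, function(v) sd_or_zero(v) / sqrt(length(v)), 0)
  pick <- function(mq) which(mq == max(mq))[1]  # ties -> lower omega
  k <- pick(meanQ)
  omega_star <- omegas[k]
  # half the local grid spacing at the argmax
  gaps <- diff(omegas)
  half_gap <- if (k == 1) gaps[1] / 2
              else if (k == length(omegas)) gaps[length(gaps)] / 2
              else mean(gaps[c(k - 1, k)]) / 2
  boot <- replicate(n_boot, {
    mq <- vapply(qs, function(v) mean(sample(v, length(v), replace = TRUE)), 0)
    omegas[pick(mq)]
  })
  se <- sqrt(half_gap^2 + sd_or_zero(boot)^2)
  j <- which.min(meanQ)
  no_res <- (meanQ[k] - meanQ[j]) <= 1.96 * sqrt(seQ[k]^2 + seQ[j]^2)
  structure(list(omega_star = omega_star, omega_star_se = se,
                 Q_max = unname(meanQ[k]),
                 table = data.frame(omega = omegas, Q = unname(meanQ),
                                    Q_se = unname(seQ)),
                 boundary = k == 1L || k == length(omegas),
                 no_resonance = unname(no_res)),
            class = "resonance_result")
}

#' @export
print.resonance_result <- function(x, ...) {
  cat(sprintf("omega* = %g +/- %.3g (Q_max = %.4g)%s%s\n",
              x$omega_star, x$omega_star_se, x$Q_max,
              if (x$boundary) " [boundary]" else "",
              if (x$no_resonance) " [no resonance detected]" else ""))
  invisible(x)
}

#' Fit the omega*-k_n scaling law
#'
#' Fits the optimal frequency against the normal stiffness on log-log
#' axes. Three fits are reported: the one-parameter power law
#' `omega* = k_n^gamma` (zero intercept in log space; the headline form),
#' the two-parameter form `omega* = c k_n^gamma`, and the fixed-exponent
#' prefactor of `omega* = c sqrt(k_n)`.
#'
#' @param k_n stiffness values (>= 3, spanning at least a factor 3).
#' @param omega_star corresponding optimal frequencies.
#' @return List of class `scaling_fit`: `gamma` and `gamma_se`
#'   (one-parameter), `gamma2`, `gamma2_se`, `c2` (two-parameter),
#'   `c_sqrt` (fixed `gamma = 0.5`), and `n`.
#' @export
fit_scaling <- function(k_n, omega_star) {
  stopifnot(length(k_n) == length(omega_star))
  if (length(k_n) < 3) stop("insufficient data: need at least 3 (k_n, omega*) pairs")
  if (max(k_n) / min(k_n) < 3)
    warning("k_n values span less than a factor 3; scaling fit is weakly constrained")
  lk <- log(k_n); lw <- log(omega_star)
  # one-parameter: lw = gamma * lk
  gamma1 <- sum(lw * lk) / sum(lk^2)
  res1 <- lw - gamma1 * lk
  g1_se <- if (length(lk) > 1)
    sqrt(sum(res1^2) / (length(lk) - 1) / sum(lk^2)) else NA_real_
  # two-parameter: lw = log(c) + gamma * lk
  fit2 <- lm(lw ~ lk)
  sm <- suppressWarnings(summary(fit2))$coefficients  # noiseless input is fine
  # fixed gamma = 0.5: log(c) = mean(lw - 0.5 lk)
  c_sqrt <- exp(mean(lw - 0.5 * lk))
  structure(list(gamma = gamma1, gamma_se = g1_se,
                 gamma2 = unname(coef(fit2)["lk"]),
                 gamma2_se = unname(sm["lk", "Std. Error"]),
                 c2 = exp(unname(coef(fit2)["(Intercept)"])),
                 c_sqrt = c_sqrt, n = length(k_n)),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("omega* = k_n^gamma: gamma = %.3f +/- %.3f (n = %d)\n",
              x$gamma, x$gamma_se, x$n))
  cat(sprintf("  two-parameter: omega* = %.3g * k_n^%.3f (se %.3f)\n",
              x$c2, x$gamma2, x$gamma2_se))
  cat(sprintf("  fixed exponent: omega* = %.3f * sqrt(k_n)\n", x$c_sqrt))
  invisible(x)
}
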