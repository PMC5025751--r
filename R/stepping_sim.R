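# Synthetic single-molecule data: signed step-size mixtures, noisy stepping
# traces with exponential (or Erlang-2) dwells, truncated-exponential run
# lengths, and stopped-flow-like kinetic transients. Everything downstream
# is testable against the ground truth recorded here.

#' Signed Gaussian mixture of step sizes
#'
#' @param weights,means_nm,sds_nm component weights (must sum to 1), signed
#'   means (negative = backward step) and standard deviations, nm.
#' @return an object of class `mixture_spec`.
#' @examples
#' mixture_spec(c(.3, .7), c(-26, 36), c(15, 14))
#' @export
mixture_spec <- function(weights, means_nm, sds_nm) {
  stopifnot(length(weights) == length(means_nm),
            length(weights) == length(sds_nm))
  if (any(weights <= 0)) stop_domain("mixture weights must be > 0")
  if (abs(sum(weights) - 1) > 1e-8) stop_domain("mixture weights must sum to 1")
  if (any(sds_nm < 0)) stop_domain("mixture sds must be >= 0")
  structure(
    list(weights = as.numeric(weights), means_nm = as.numeric(means_nm),
         sds_nm = as.numeric(sds_nm)),
    class = "mixture_spec"
  )
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat(sprintf("Step-size mixture, %d component(s):\n", length(x$weights)))
  for (k in seq_along(x$weights)) {
    cat(sprintf("  w=%.3f  mean=%+.1f nm  sd=%.1f nm\n",
                x$weights[k], x$means_nm[k], x$sds_nm[k]))
  }
  invisible(x)
}

#' Published step-size mixtures for myosin X constructs
#'
#' Signed Gaussian mixtures fitted to measured step-size distributions of
#' the full-length (FL) and zippered-dimer (HMM) constructs on single
#' F-actin filaments and on fascin-bundled F-actin. Component means/s.d.
#' are the published fit values; the component weights were not published
#' and default to 30% total backward mass with equal forward splits
#' (FL/HMM on filaments: 0.3/0.7) or equal weights for the four-component
#' HMM/bundle distribution. The attribute `n` carries the published sample
#' size of each data set.
#'
#' @param which one of `"fl_single"` (-26+-15, 36+-14; N=214),
#'   `"fl_bundle"` (-33+-14, 19+-7, 38+-7, 52+-5; N=393),
#'   `"hmm_single"` (-33+-15, 39+-13; N=238),
#'   `"hmm_bundle"` (-28+-18, 17+-6, 40+-9, 57+-2; N=178), or
#'   `"hmm_bundle_backsplit"` (backward mass split -49+-6 / -20+-11).
#' @return a [mixture_spec()] with attribute `n` (published sample size).
#' @export
step_mixture <- function(which = c("fl_single", "fl_bundle", "hmm_single",
                                   "hmm_bundle", "hmm_bundle_backsplit")) {
  which <- match.arg(which)
  spec <- switch(which,
    fl_single = list(w = c(0.3, 0.7), m = c(-26, 36), s = c(15, 14),
                     n = 214L),
    fl_bundle = list(w = c(0.3, 0.7 / 3, 0.7 / 3, 0.7 / 3),
                     m = c(-33, 19, 38, 52), s = c(14, 7, 7, 5), n = 393L),
    hmm_single = list(w = c(0.3, 0.7), m = c(-33, 39), s = c(15, 13),
                      n = 238L),
    hmm_bundle = list(w = rep(0.25, 4), m = c(-28, 17, 40, 57),
                      s = c(18, 6, 9, 2), n = 178L),
    hmm_bundle_backsplit = list(
      w = c(0.125, 0.125, 0.25, 0.25, 0.25),
      m = c(-49, -20, 17, 40, 57), s = c(6, 11, 6, 9, 2), n = 178L)
  )
  out <- mixture_spec(spec$w, spec$m, spec$s)
  attr(out, "n") <- spec$n
  attr(out, "dataset") <- which
  out
}

#' Draw signed step sizes from a mixture
#'
#' @param mix a [mixture_spec()].
#' @param n number of draws.
#' @param seed optional integer seed (reproducible; caller's RNG state is
#'   untouched).
#' @return numeric vector of n signed step sizes, nm.
#' @export
sample_steps <- function(mix, n, seed = NULL) {
  stopifnot(inherits(mix, "mixture_spec"))
  check_number(n, "n", lower = 1)
  with_seed(seed, {
    comp <- sample.int(length(mix$weights), n, replace = TRUE,
                       prob = mix$weights)
    stats::rnorm(n, mean = mix$means_nm[comp], sd = mix$sds_nm[comp])
  })
}

#' Trace-simulation parameters
#'
#' Emulates a FIONA-style localization assay: a motor steps at rate
#' `k_step_per_s` (exponential dwells, or Erlang-2 when `erlang = TRUE`),
#' positions are sampled at `frame_rate_hz` with Gaussian localization
#' noise of `noise_sd_nm` per frame, and the run may terminate with
#' per-step probability `p_detach`.
#'
#' @param frame_rate_hz camera frame rate, Hz (default 50).
#' @param noise_sd_nm localization noise per frame, nm (default 3).
#' @param k_step_per_s stepping rate, 1/s.
#' @param n_steps number of steps to simulate (ignored if `duration_s` set).
#' @param duration_s optional fixed trace duration, s.
#' @param p_detach per-step detachment probability in \[0, 1).
#' @param erlang if TRUE, dwells are Erlang-2 with the same mean.
#' @param seed optional integer seed.
#' @return an object of class `trace_params`.
#' @export
trace_params <- function(frame_rate_hz = 50, noise_sd_nm = 3,
                         k_step_per_s = 5, n_steps = 50, duration_s = NULL,
                         p_detach = 0, erlang = FALSE, seed = NULL) {
  check_number(frame_rate_hz, "frame_rate_hz", lower = 0, strict_lower = TRUE)
  check_number(noise_sd_nm, "noise_sd_nm", lower = 0)
  check_number(k_step_per_s, "k_step_per_s", lower = 0, strict_lower = TRUE)
  if (!is.null(duration_s)) {
    check_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  } else {
    check_number(n_steps, "n_steps", lower = 1)
  }
  check_number(p_detach, "p_detach", lower = 0, upper = 1, strict_upper = TRUE)
  structure(
    list(frame_rate_hz = frame_rate_hz, noise_sd_nm = noise_sd_nm,
         k_step_per_s = k_step_per_s, n_steps = n_steps,
         duration_s = duration_s, p_detach = p_detach,
         erlang = isTRUE(erlang), seed = seed),
    class = "trace_params"
  )
}

#' Simulate a noisy stepping trace
#'
#' Piecewise-constant position signal: dwell times are i.i.d.
#' Exponential(`k_step_per_s`) (or Erlang-2 with the same mean), step
#' increments are drawn from `mix`, per-frame Gaussian localization noise
#' is added, and the ground-truth step times/sizes are recorded.
#'
#' @param tp a [trace_params()].
#' @param mix a [mixture_spec()].
#' @return an object of class `step_trace` with fields `times_s`,
#'   `positions_nm`, `true_step_times`, `true_step_sizes`, `empty` flag,
#'   and the generating parameters.
#' @export
simulate_trace <- function(tp, mix) {
  stopifnot(inherits(tp, "trace_params"), inherits(mix, "mixture_spec"))
  with_seed(tp$seed, {
    rdwell <- function(m) {
      if (tp$erlang) stats::rgamma(m, shape = 2, rate = 2 * tp$k_step_per_s)
      else stats::rexp(m, rate = tp$k_step_per_s)
    }
    if (is.null(tp$duration_s)) {
      n <- tp$n_steps
      dwells <- rdwell(n + 1)       # last dwell trails the final step
      if (tp$p_detach > 0) {
        det <- stats::rgeom(1, tp$p_detach) + 1
        if (det <= n) { n <- det; dwells <- dwells[seq_len(n + 1)] }
      }
      step_times <- cumsum(dwells[seq_len(n)])
      duration <- sum(dwells)
    } else {
      duration <- tp$duration_s
      step_times <- numeric(0)
      t_acc <- rdwell(1)
      while (t_acc < duration) {
        step_times <- c(step_times, t_acc)
        if (tp$p_detach > 0 && stats::runif(1) < tp$p_detach) break
        t_acc <- t_acc + rdwell(1)
      }
      n <- length(step_times)
    }
    sizes <- if (n > 0) sample_steps(mix, n) else numeric(0)
    dt <- 1 / tp$frame_rate_hz
    times <- seq(0, duration, by = dt)
    true_pos <- vapply(times, function(t) sum(sizes[step_times <= t]),
                       numeric(1))
    positions <- true_pos + stats::rnorm(length(times), 0, tp$noise_sd_nm)
    structure(
      list(times_s = times, positions_nm = positions,
           true_step_times = step_times, true_step_sizes = sizes,
           empty = n == 0, params = tp, mixture = mix),
      class = "step_trace"
    )
  })
}

#' @export
print.step_trace <- function(x, ...) {
  cat(sprintf(
    "Stepping trace: %d frames over %.2f s, %d true step(s)%s\n",
    length(x$times_s), max(x$times_s), length(x$true_step_times),
    if (x$empty) " [empty]" else ""))
  invisible(x)
}

#' Simulate processive runs with truncated-exponential lengths
#'
#' Run lengths are `X0 + Exponential(lambda)`, the generative counterpart
#' of fitting the cumulative run-length distribution above a detection
#' cutoff `X0` to `1 - exp(-(X - X0)/lambda)`. Durations are drawn from a
#' per-run velocity (Gaussian, truncated positive) so that
#' `velocity = run_length / duration` holds record by record.
#'
#' @param lambda_um length constant, um.
#' @param X0_um detection cutoff, um.
#' @param n number of runs.
#' @param seed optional integer seed.
#' @param velocity_um_s,velocity_sd mean and s.d. of per-run velocity,
#'   um/s.
#' @return an object of class `run_set`: data-frame-like list with
#'   `run_lengths_um`, `durations_s`, `velocities_um_per_s`.
#' @export
simulate_runs <- function(lambda_um, X0_um, n, seed = NULL,
                          velocity_um_s = 0.66, velocity_sd = 0.1) {
  check_number(lambda_um, "lambda_um", lower = 0, strict_lower = TRUE)
  check_number(X0_um, "X0_um", lower = 0)
  check_number(n, "n", lower = 1)
  with_seed(seed, {
    lens <- X0_um + stats::rexp(n, rate = 1 / lambda_um)
    v <- stats::rnorm(n, velocity_um_s, velocity_sd)
    v <- pmax(v, velocity_um_s / 10)  # keep velocities positive
    run_set(lens, lens / v)
  })
}

#' Construct a run set from lengths and durations
#'
#' @param run_lengths_um,durations_s positive numeric vectors of equal
#'   length; velocities are derived as length/duration.
#' @return an object of class `run_set`.
#' @export
run_set <- function(run_lengths_um, durations_s) {
  stopifnot(length(run_lengths_um) == length(durations_s))
  if (any(run_lengths_um <= 0) || any(durations_s <= 0)) {
    stop_domain("run lengths and durations must be positive")
  }
  structure(
    list(run_lengths_um = as.numeric(run_lengths_um),
         durations_s = as.numeric(durations_s),
         velocities_um_per_s = as.numeric(run_lengths_um / durations_s)),
    class = "run_set"
  )
}

#' @export
print.run_set <- function(x, ...) {
  cat(sprintf(
    "Run set: n=%d, mean run %.2f um, mean velocity %.2f um/s\n",
    length(x$run_lengths_um), mean(x$run_lengths_um),
    mean(x$velocities_um_per_s)))
  invisible(x)
}

#' Published motility statistics (run length and velocity)
#'
#' Pooled run-length and velocity statistics for the full-length (FL) and
#' zippered-dimer (HMM) myosin X constructs on single and fascin-bundled
#' F-actin, as published: pooled mean/s.d./s.e./N, the truncated-
#' exponential length constant lambda with its s.e., and the velocity
#' statistics. Used as generative ground truth for the synthetic run sets.
#'
#' @return a data frame with one row per construct/track combination.
#' @export
motility_table <- function() {
  data.frame(
    dataset = c("fl_single", "hmm_single", "fl_bundle", "hmm_bundle"),
    construct = c("FL", "HMM", "FL", "HMM"),
    track = c("single", "single", "bundle", "bundle"),
    run_mean_um = c(0.81, 0.64, 1.95, 1.80),
    run_sd_um = c(0.51, 0.71, 1.71, 2.11),
    run_se_um = c(0.03, 0.03, 0.10, 0.07),
    run_n = c(283L, 768L, 285L, 889L),
    lambda_um = c(0.60, 0.32, 1.16, 1.18),
    lambda_se_um = c(0.19, 0.08, 0.24, 0.13),
    vel_mean_um_s = c(0.31, 0.41, 0.66, 0.68),
    vel_sd_um_s = c(0.08, 0.20, 0.20, 0.55),
    vel_se_um_s = c(0.02, 0.01, 0.01, 0.05),
    vel_n = c(160L, 768L, 285L, 103L),
    stringsAsFactors = FALSE
  )
}

#' Simulate a stopped-flow-like kinetic transient
#'
#' Sum of decaying exponentials plus Gaussian noise, emulating e.g. the
#' quench of mant-ADP fluorescence or of pyrene-actin fluorescence after
#' rapid mixing.
#'
#' @param rates list (or 2-column matrix) of `(amplitude, k_per_s)` pairs.
#' @param t_grid time grid, s.
#' @param noise_sd Gaussian noise s.d. (signal units).
#' @param seed optional integer seed.
#' @return data frame with columns `time_s`, `signal`.
#' @export
simulate_transient <- function(rates, t_grid, noise_sd = 0, seed = NULL) {
  if (is.matrix(rates)) rates <- asplit(rates, 1)
  stopifnot(length(rates) >= 1)
  amps <- vapply(rates, `[[`, numeric(1), 1)
  ks <- vapply(rates, `[[`, numeric(1), 2)
  if (any(ks <= 0)) stop_domain("transient rates must be > 0")
  check_number(noise_sd, "noise_sd", lower = 0)
  sig <- rowSums(vapply(seq_along(ks),
                        function(i) amps[i] * exp(-ks[i] * t_grid),
                        numeric(length(t_grid))))
  with_seed(seed, {
    data.frame(time_s = t_grid,
               signal = sig + stats::rnorm(length(t_grid), 0, noise_sd))
  })
}
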