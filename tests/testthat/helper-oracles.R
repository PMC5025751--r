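# Independent oracles used by the test suite. These re-derive expected
# results by brute force / closed form, independently of the package code
# paths they check.

# Brute-force accessibility oracle: plain loop over subunits, no shared
# code with zones_one_filament().
oracle_accessible <- function(rise, twist, tol, band_min, band_max,
                              phase = 0, axial_offset = 0, n_max = 60) {
  out <- data.frame(subunit = integer(0), axial = numeric(0))
  for (n in 1:n_max) {
    axial <- n * rise + axial_offset
    az <- (n * twist - phase) %% 360
    if (az > 180) az <- az - 360
    if (az == -180) az <- 180
    if (axial >= band_min && axial <= band_max && abs(az) <= tol) {
      out <- rbind(out, data.frame(subunit = n, axial = axial))
    }
  }
  out
}

# Grid-search maximizer of the 2-component mixture likelihood on a small
# sample: exhaustive over a coarse parameter grid.
oracle_grid_mixture2 <- function(x, mu_grid, sd_grid, w_grid) {
  best <- list(loglik = -Inf)
  for (m1 in mu_grid) for (m2 in mu_grid) {
    if (m2 <= m1) next
    for (s1 in sd_grid) for (s2 in sd_grid) for (w in w_grid) {
      ll <- sum(log(w * dnorm(x, m1, s1) + (1 - w) * dnorm(x, m2, s2)))
      if (ll > best$loglik) {
        best <- list(loglik = ll, mu = c(m1, m2), sd = c(s1, s2),
                     w = c(w, 1 - w))
      }
    }
  }
  best
}

# Maximum-likelihood estimator for the truncated-exponential length
# constant: closed form, mean of the excesses.
oracle_lambda_ml <- function(x, X0) mean(x[x >= X0] - X0)

# Build a noiseless staircase trace directly (independent of
# simulate_trace): steps at known frame indices.
make_staircase <- function(step_frames, sizes, n_frames, dt = 0.02,
                           noise_sd = 0, seed = NULL) {
  pos <- numeric(n_frames)
  lvl <- 0
  j <- 1
  for (i in seq_len(n_frames)) {
    while (j <= length(step_frames) && i > step_frames[j]) {
      lvl <- lvl + sizes[j]
      j <- j + 1
    }
    pos[i] <- lvl
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    pos <- pos + rnorm(n_frames, 0, noise_sd)
  }
  structure(
    list(times_s = (seq_len(n_frames) - 1) * dt, positions_nm = pos,
         true_step_times = (step_frames - 0.5) * dt, true_step_sizes = sizes,
         empty = FALSE, params = NULL, mixture = NULL),
    class = "step_trace"
  )
}

# Fraction of true steps that have a detected step within `frames` frames,
# and the mean absolute size error over those matched pairs.
match_steps <- function(true_times, true_sizes, fit, dt, frames = 1) {
  if (length(fit$step_times_s) == 0) {
    return(c(frac = 0, size_err = NA_real_))
  }
  hit <- numeric(0)
  err <- numeric(0)
  for (i in seq_along(true_times)) {
    d <- abs(fit$step_times_s - true_times[i])
    j <- which.min(d)
    if (d[j] <= frames * dt + 1e-9) {
      hit <- c(hit, i)
      err <- c(err, abs(fit$step_sizes_nm[j] - true_sizes[i]))
    }
  }
  c(frac = length(hit) / length(true_times), size_err = mean(err))
}
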