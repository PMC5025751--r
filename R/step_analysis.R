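# Statistical pipeline for stepping traces: chi-square step finding with
# counter-fit model selection, signed Gaussian-mixture fitting by EM with
# cross-validated component-count selection, truncated-exponential
# run-length fitting, and pooled velocity statistics.

# ---------------------------------------------------------------------------
# Step finding

# Internal: best split of positions[lo..hi] into two plateaus, respecting a
# minimum dwell. Returns c(index_of_last_frame_of_left_plateau, rss_drop)
# or NULL if the segment cannot be split.
best_split <- function(cs, cs2, lo, hi, min_dwell) {
  len <- hi - lo + 1
  if (len < 2 * min_dwell) return(NULL)
  j <- (lo + min_dwell - 1):(hi - min_dwell)   # last index of left plateau
  nl <- j - lo + 1
  nr <- hi - j
  sl <- cs[j + 1] - cs[lo]
  sr <- cs[hi + 1] - cs[j + 1]
  # RSS of a constant fit = sum(x^2) - sum(x)^2 / n, per side
  rss <- (cs2[hi + 1] - cs2[lo]) - sl^2 / nl - sr^2 / nr
  i <- which.min(rss)
  c(j[i], rss[i])
}

segment_rss <- function(cs, cs2, lo, hi) {
  n <- hi - lo + 1
  (cs2[hi + 1] - cs2[lo]) - (cs[hi + 1] - cs[lo])^2 / n
}

# Internal: total RSS of a piecewise-constant fit with plateau boundaries
# `bounds` (sorted last-frame indices of all but the final plateau).
fit_rss <- function(cs, cs2, n, bounds) {
  edges <- c(0L, sort(bounds), n)
  sum(vapply(seq_len(length(edges) - 1), function(i) {
    segment_rss(cs, cs2, edges[i] + 1L, edges[i + 1])
  }, numeric(1)))
}

#' Detect steps in a position trace
#'
#' Greedy chi-square step fitter with counter-fit model selection. Steps
#' are inserted one at a time, each at the change point that maximally
#' reduces the residual sum of squares of a piecewise-constant fit. For
#' each candidate step count k the quality factor is the ratio of the
#' counter-fit chi-square (steps forced to the plateau midpoints of the
#' k-step fit) to the fit chi-square; the returned step count maximizes
#' this factor, which peaks when the inserted steps coincide with real
#' ones and the counter-fit is maximally wrong.
#'
#' @param trace a `step_trace` (from [simulate_trace()] or [read_trace()]).
#' @param max_steps maximum number of steps to consider (default: estimated
#'   from trace length and `min_dwell_frames`).
#' @param min_dwell_frames minimum plateau length in frames (default 2).
#' @return an object of class `step_fit` with fields `step_times_s`,
#'   `plateau_levels_nm`, `step_sizes_nm`, `residual_ss`, `quality`
#'   (counter-fit quality per candidate step count), `n_steps`.
#' @export
find_steps <- function(trace, max_steps = NULL, min_dwell_frames = 2) {
  stopifnot(inherits(trace, "step_trace"))
  x <- trace$positions_nm
  tt <- trace$times_s
  n <- length(x)
  check_number(min_dwell_frames, "min_dwell_frames", lower = 1)
  if (n < 2 * min_dwell_frames) {
    stop_domain("trace shorter than 2 x min_dwell_frames")
  }
  if (is.null(max_steps)) {
    max_steps <- min(200L, floor(n / (2 * min_dwell_frames)))
  }
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))

  empty_fit <- function(flag) {
    structure(
      list(step_times_s = numeric(0), plateau_levels_nm = mean(x),
           step_sizes_nm = numeric(0),
           residual_ss = segment_rss(cs, cs2, 1L, n),
           quality = numeric(0), quality_undefined = flag, n_steps = 0L,
           times_s = tt),
      class = "step_fit"
    )
  }
  if (segment_rss(cs, cs2, 1L, n) < 1e-12 * max(1, mean(x)^2)) {
    return(empty_fit(TRUE))   # flat trace: zero steps, quality undefined
  }

  # greedy insertion; fits are nested so we record the insertion order
  bounds <- integer(0)
  rss_k <- numeric(0)
  quality <- numeric(0)
  bounds_by_k <- vector("list", max_steps)
  for (k in seq_len(max_steps)) {
    edges <- c(0L, sort(bounds), n)
    best <- NULL
    for (i in seq_len(length(edges) - 1)) {
      sp <- best_split(cs, cs2, edges[i] + 1L, edges[i + 1], min_dwell_frames)
      if (is.null(sp)) next
      drop <- segment_rss(cs, cs2, edges[i] + 1L, edges[i + 1]) - sp[2]
      if (is.null(best) || drop > best[2]) best <- c(sp[1], drop)
    }
    if (is.null(best)) break
    # stop once additional steps no longer reduce the residual (already a
    # perfect piecewise-constant fit, e.g. noiseless staircases)
    if (best[2] <= 1e-10 * (cs2[n + 1] / n + 1)) break
    bounds <- c(bounds, as.integer(best[1]))
    bounds_by_k[[k]] <- sort(bounds)
    rss_k[k] <- fit_rss(cs, cs2, n, bounds)
    # counter-fit: same number of steps, at the midpoints of the plateaus
    edges_k <- c(0L, bounds_by_k[[k]], n)
    mids <- floor((edges_k[-length(edges_k)] + edges_k[-1]) / 2)
    mids <- unique(pmin(pmax(mids, 1L), n - 1L))
    counter <- fit_rss(cs, cs2, n, mids[seq_len(min(k, length(mids)))])
    quality[k] <- counter / max(rss_k[k], .Machine$double.eps)
  }
  if (length(rss_k) == 0) return(empty_fit(TRUE))

  k_best <- which.max(quality)
  b <- bounds_by_k[[k_best]]
  edges <- c(0L, b, n)
  levels <- vapply(seq_len(length(edges) - 1), function(i) {
    mean(x[(edges[i] + 1L):edges[i + 1]])
  }, numeric(1))
  structure(
    list(
      step_times_s = (tt[b] + tt[b + 1L]) / 2,
      plateau_levels_nm = levels,
      step_sizes_nm = diff(levels),
      residual_ss = rss_k[k_best],
      quality = quality,
      quality_undefined = FALSE,
      n_steps = k_best,
      times_s = tt
    ),
    class = "step_fit"
  )
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf("Step fit: %d step(s), residual SS %.3g\n",
              x$n_steps, x$residual_ss))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Gaussian mixture by EM

log_sum_exp_rows <- function(m) {
  mx <- m[, 1]
  for (k in seq_len(ncol(m))[-1]) mx <- pmax(mx, m[, k])
  mx + log(rowSums(exp(m - mx)))
}

# Weighted log-density matrix (n x K) of a Gaussian mixture.
mixture_logdens <- function(x, w, mu, sd) {
  n <- length(x)
  K <- length(mu)
  d <- outer(x, mu, "-") / rep(sd, each = n)
  rep(log(w) - log(sd) - 0.5 * log(2 * pi), each = n) - 0.5 * d * d
}

# One EM run from a given initialization. Returns params + loglik trace.
em_run <- function(x, w, mu, sd, tol, sd_floor, max_iter = 500) {
  n <- length(x)
  K <- length(mu)
  ll_old <- -Inf
  ll_trace <- numeric(max_iter)
  for (it in seq_len(max_iter)) {
    lg <- mixture_logdens(x, w, mu, sd)
    lse <- log_sum_exp_rows(lg)
    ll <- sum(lse)
    ll_trace[it] <- ll
    resp <- exp(lg - lse)
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sd <- sqrt(colSums(resp * (outer(x, mu, "-"))^2) / nk)
    sd <- pmax(sd, sd_floor)
    if (is.finite(ll) && is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * (abs(ll_old) + tol)) break
    ll_old <- ll
  }
  degenerate <- any(w < 1 / n) || any(sd <= sd_floor & w < 2 / n)
  list(w = w, mu = mu, sd = sd, loglik = ll,
       ll_trace = ll_trace[seq_len(it)],
       converged = it < max_iter, degenerate = degenerate)
}

#' Fit a signed Gaussian mixture to step sizes by EM
#'
#' Univariate K-component Gaussian mixture fitted by expectation-
#' maximization (the `normalMixEM` family of fits), best of `n_restarts`
#' random restarts by log-likelihood. The first restart initializes
#' component means at the data quantiles; later restarts jitter the
#' initialization. Components are reported sorted by mean; backward steps
#' are components with negative means in the same fit.
#'
#' @param steps numeric vector of signed step sizes, nm.
#' @param K number of components.
#' @param n_restarts number of EM restarts (default 10).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param sd_floor lower bound on component s.d., nm (default 1).
#' @param seed optional integer seed (controls the restart jitter).
#' @return an object of class `gaussian_mixture_fit` with fields `K`,
#'   `weights`, `means_nm`, `sds_nm`, `loglik`, `loglik_trace`,
#'   `converged`, `n_restarts`.
#' @export
fit_gaussian_mixture <- function(steps, K, n_restarts = 10, tol = 1e-8,
                                 sd_floor = 1, seed = NULL) {
  x <- as.numeric(steps)
  check_number(K, "K", lower = 1)
  K <- as.integer(K)
  if (length(x) < 3 * K) stop_domain("need at least 3*K step observations")
  with_seed(seed, {
    best <- NULL
    sd0 <- max(stats::sd(x), sd_floor)
    for (r in seq_len(n_restarts)) {
      probs <- (seq_len(K) - 0.5) / K
      if (r > 1) probs <- sort(stats::runif(K))
      mu0 <- as.numeric(stats::quantile(x, probs, type = 7))
      fit <- em_run(x, rep(1 / K, K), mu0, rep(sd0, K), tol, sd_floor)
      better <- is.null(best) ||
        (best$degenerate && !fit$degenerate) ||
        (fit$degenerate == best$degenerate && fit$loglik > best$loglik)
      if (better) best <- fit
    }
    ord <- order(best$mu)
    structure(
      list(K = K, weights = best$w[ord], means_nm = best$mu[ord],
           sds_nm = best$sd[ord], loglik = best$loglik,
           loglik_trace = best$ll_trace, converged = best$converged,
           degenerate = best$degenerate, n_restarts = n_restarts),
      class = "gaussian_mixture_fit"
    )
  })
}

#' @export
print.gaussian_mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit: K=%d, loglik=%.2f%s\n", x$K, x$loglik,
              if (!x$converged) " [not converged]" else ""))
  for (k in seq_len(x$K)) {
    cat(sprintf("  w=%.3f  mean=%+.1f nm  sd=%.1f nm\n",
                x$weights[k], x$means_nm[k], x$sds_nm[k]))
  }
  invisible(x)
}

# log-likelihood of data under a fitted mixture
mixture_loglik <- function(fit, x) {
  lg <- mixture_logdens(x, fit$weights, fit$means_nm, fit$sds_nm)
  sum(log_sum_exp_rows(lg))
}

#' Select the number of mixture components by cross-validation
#'
#' K-fold cross-validation of the held-out log-likelihood: for each
#' candidate K the mixture is fitted on the training folds and scored on
#' the held-out fold; the selected K maximizes the mean held-out
#' log-likelihood per observation, with ties resolved toward the smaller K.
#'
#' @param steps numeric vector of signed step sizes, nm.
#' @param K_range candidate component counts (default 1:5).
#' @param folds number of folds (default 5); reduced with a warning when a
#'   training fold would hold fewer than `3 * max(K_range)` points.
#' @param seed optional integer seed (fold assignment and EM restarts).
#' @param ... passed to [fit_gaussian_mixture()].
#' @return an object of class `cv_selection` with fields `K_range`,
#'   `cv_loglik` (mean held-out log-likelihood per observation per K),
#'   `K_selected`.
#' @export
select_K_cv <- function(steps, K_range = 1:5, folds = 5, seed = NULL, ...) {
  x <- as.numeric(steps)
  check_number(folds, "folds", lower = 2)
  folds <- as.integer(folds)
  K_range <- sort(unique(as.integer(K_range)))
  need <- 3L * max(K_range)
  if (folds > 2 &&
      (floor(length(x) / folds) < max(K_range) ||
       floor(length(x) * (folds - 1) / folds) < need)) {
    while (folds > 2 &&
           (floor(length(x) / folds) < max(K_range) ||
            floor(length(x) * (folds - 1) / folds) < need)) {
      folds <- folds - 1L
    }
    warning("reducing folds: folds too small for max(K_range)")
  }
  if (floor(length(x) * (folds - 1) / folds) < need) {
    stop_domain("too few steps for cross-validated selection over K_range")
  }
  with_seed(seed, {
    fold_id <- sample(rep_len(seq_len(folds), length(x)))
    cv <- vapply(K_range, function(K) {
      ho <- vapply(seq_len(folds), function(f) {
        train <- x[fold_id != f]
        test <- x[fold_id == f]
        fit <- fit_gaussian_mixture(train, K, ...)
        mixture_loglik(fit, test) / length(test)
      }, numeric(1))
      mean(ho)
    }, numeric(1))
    K_sel <- K_range[which.max(cv)]  # which.max takes the first (smallest K)
    structure(
      list(K_range = K_range, cv_loglik = cv, K_selected = K_sel),
      class = "cv_selection"
    )
  })
}

#' @export
print.cv_selection <- function(x, ...) {
  cat("Cross-validated component selection:\n")
  for (i in seq_along(x$K_range)) {
    cat(sprintf("  K=%d  held-out loglik/obs = %.4f%s\n", x$K_range[i],
                x$cv_loglik[i],
                if (x$K_range[i] == x$K_selected) "  <- selected" else ""))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Run lengths and velocities

#' Fit the run-length constant by a truncated-exponential CDF
#'
#' Least-squares fit of the empirical cumulative distribution of run
#' lengths at or above the detection cutoff `X0` to
#' `1 - exp(-(X - X0)/lambda)`. Empirical CDF values use the (i - 0.5)/n
#' plotting positions. The standard error of lambda is estimated by a
#' nonparametric bootstrap.
#'
#' @param runs a `run_set` (or numeric vector of run lengths, um).
#' @param X0 detection cutoff, um.
#' @param n_boot bootstrap resamples for the s.e. (default 200; 0 skips).
#' @param seed optional integer seed for the bootstrap.
#' @return an object of class `run_length_fit` with `lambda_um`,
#'   `lambda_se`, `X0_um`, `n`.
#' @export
fit_run_length <- function(runs, X0 = 0, n_boot = 200, seed = NULL) {
  x <- if (inherits(runs, "run_set")) runs$run_lengths_um else as.numeric(runs)
  check_number(X0, "X0", lower = 0)
  x <- x[x >= X0]
  if (length(x) == 0) stop_domain("X0 lies above all run lengths")
  if (length(x) < 10) stop_domain("need at least 10 runs at or above X0")

  lambda_hat <- function(xs) {
    xs <- sort(xs)
    n <- length(xs)
    Fi <- (seq_len(n) - 0.5) / n
    obj <- function(lam) sum((Fi - (1 - exp(-(xs - X0) / lam)))^2)
    lam0 <- mean(xs - X0)
    stats::optimize(obj, c(lam0 / 20, lam0 * 20))$minimum
  }
  lam <- lambda_hat(x)
  se <- NA_real_
  if (n_boot > 0) {
    se <- with_seed(seed, {
      stats::sd(vapply(seq_len(n_boot), function(b) {
        lambda_hat(sample(x, replace = TRUE))
      }, numeric(1)))
    })
  }
  structure(
    list(lambda_um = lam, lambda_se = se, X0_um = X0, n = length(x)),
    class = "run_length_fit"
  )
}

#' @export
print.run_length_fit <- function(x, ...) {
  cat(sprintf("Run-length fit: lambda = %.3f um (s.e. %.3f), X0 = %.2f um, n = %d\n",
              x$lambda_um, x$lambda_se, x$X0_um, x$n))
  invisible(x)
}

#' Pooled run-length and velocity statistics
#'
#' Pooled mean/s.d./s.e./N for run length and per-run velocity
#' (net displacement / duration), the same column semantics as a motility
#' summary table.
#'
#' @param runs a `run_set`.
#' @return list with `run_length` and `velocity`, each a named vector
#'   `(mean, sd, se, n)`.
#' @export
summarize_runs <- function(runs) {
  stopifnot(inherits(runs, "run_set"))
  stat <- function(v) {
    n <- length(v)
    s <- if (n > 1) stats::sd(v) else 0
    c(mean = mean(v), sd = s, se = s / sqrt(n), n = n)
  }
  list(run_length = stat(runs$run_lengths_um),
       velocity = stat(runs$velocities_um_per_s))
}
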