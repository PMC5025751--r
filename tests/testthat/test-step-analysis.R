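# Step detection, mixture fitting, component selection, run-length fits.

test_that("step finder is exact on noiseless staircases", {
  frames <- c(40, 90, 120, 180, 230)
  sizes <- c(36, -28, 36, 57, 17)
  tr <- make_staircase(frames, sizes, 300)
  f <- find_steps(tr)
  expect_equal(f$n_steps, 5L)
  expect_equal(f$step_sizes_nm, sizes, tolerance = 1e-9)
  expect_equal(f$step_times_s, tr$true_step_times, tolerance = 1e-9)
  expect_lt(f$residual_ss, 1e-12)
})

test_that("flat traces yield zero steps with the quality flag set", {
  tr <- make_staircase(integer(0), numeric(0), 100)
  f <- find_steps(tr)
  expect_equal(f$n_steps, 0L)
  expect_true(f$quality_undefined)
  expect_length(f$step_sizes_nm, 0)
})

test_that("step finder recovers noisy 36 nm staircases", {
  # 50 steps of 36 nm, noise sd 3 nm, 20-frame dwells
  stats <- vapply(1:10, function(s) {
    set.seed(s)
    frames <- cumsum(sample(15:25, 50, replace = TRUE))
    tr <- make_staircase(frames, rep(36, 50), max(frames) + 20,
                         noise_sd = 3, seed = s + 100)
    f <- find_steps(tr)
    match_steps(tr$true_step_times, tr$true_step_sizes, f, dt = 0.02)
  }, numeric(2))
  expect_gte(mean(stats["frac", ]), 0.95)
  expect_lt(mean(stats["size_err", ]), 2)
})

test_that("K=1 mixture fit equals the closed-form Gaussian MLE", {
  set.seed(12)
  x <- rnorm(80, 10, 4)
  f <- fit_gaussian_mixture(x, 1, seed = 1)
  expect_equal(f$means_nm, mean(x), tolerance = 1e-6)
  expect_equal(f$sds_nm, sd(x) * sqrt((length(x) - 1) / length(x)),
               tolerance = 1e-6)
  expect_equal(f$weights, 1)
})

test_that("EM matches a brute-force grid maximizer on small samples", {
  set.seed(31)
  x <- c(rnorm(18, -20, 4), rnorm(22, 35, 5))  # 40 points, well separated
  f <- fit_gaussian_mixture(x, 2, seed = 2)
  oracle <- oracle_grid_mixture2(
    x, mu_grid = seq(-30, 45, by = 1), sd_grid = seq(2, 8, by = 0.5),
    w_grid = seq(0.2, 0.8, by = 0.05))
  # EM attains at least the best gridded likelihood, at nearby parameters
  expect_gte(f$loglik, oracle$loglik - 1e-6)
  expect_equal(f$means_nm, oracle$mu, tolerance = 1)
  expect_equal(f$sds_nm, oracle$sd, tolerance = 0.5)
  expect_equal(f$weights, oracle$w, tolerance = 0.05)
})

test_that("EM log-likelihood is monotone non-decreasing and label-sorted", {
  for (s in 1:5) {
    x <- sample_steps(step_mixture("hmm_bundle"), 150, seed = s)
    f <- fit_gaussian_mixture(x, 3, seed = s)
    expect_true(all(diff(f$loglik_trace) >= -1e-7 * abs(f$loglik)))
    expect_false(is.unsorted(f$means_nm))
    expect_equal(sum(f$weights), 1, tolerance = 1e-9)
    expect_true(all(f$sds_nm >= 1))  # sd floor
  }
  expect_error(fit_gaussian_mixture(rnorm(5), 2), "3\\*K")
})

test_that("mixture component means are recovered from published-parameter data", {
  # two-component data (N=214): forward peak near 36
  fwd <- vapply(1:6, function(s) {
    x <- sample_steps(step_mixture("fl_single"), 214, seed = s)
    fit_gaussian_mixture(x, 2, seed = s)$means_nm[2]
  }, numeric(1))
  expect_lt(abs(mean(fwd) - 36), 3)

  # four-component data (N=178): sharp 57 +- 2 component
  top <- vapply(1:6, function(s) {
    x <- sample_steps(step_mixture("hmm_bundle"), 178, seed = s)
    max(fit_gaussian_mixture(x, 4, seed = s)$means_nm)
  }, numeric(1))
  expect_lt(abs(mean(top) - 57), 2)
})

test_that("cross-validation selects K = 1 for pure Gaussian data", {
  set.seed(5)
  x <- rnorm(200, 30, 5)
  sel <- select_K_cv(x, K_range = 1:3, seed = 9)
  expect_equal(sel$K_selected, 1L)
  expect_equal(sel$K_range[which.max(sel$cv_loglik)], sel$K_selected)
})

test_that("cross-validation reduces folds when data are scarce", {
  x <- sample_steps(step_mixture("fl_single"), 15, seed = 1)
  expect_warning(sel <- select_K_cv(x, K_range = 1:2, folds = 10, seed = 1),
                 "reducing folds")
  expect_true(sel$K_selected %in% 1:2)
})

test_that("run-length fit recovers lambda from exact exponential quantiles", {
  n <- 200
  X0 <- 0.4
  lam <- 1.16
  x <- X0 + lam * (-log(1 - (seq_len(n) - 0.5) / n))
  f <- fit_run_length(x, X0 = X0, n_boot = 0)
  expect_equal(f$lambda_um, lam, tolerance = 1e-4)
  expect_equal(f$n, n)
})

test_that("run-length NLS agrees with the closed-form ML estimator", {
  rs <- simulate_runs(1.16, 0.4, 285, seed = 21)
  f <- fit_run_length(rs, X0 = 0.4, n_boot = 50, seed = 1)
  lam_ml <- oracle_lambda_ml(rs$run_lengths_um, 0.4)
  expect_lt(abs(f$lambda_um - lam_ml) / lam_ml, 0.1)
  expect_true(is.finite(f$lambda_se) && f$lambda_se > 0)
  expect_error(fit_run_length(rs, X0 = 100), "above all")
})

test_that("pooled run summaries match their definitions", {
  rs <- run_set(1, 2)
  s <- summarize_runs(rs)
  expect_equal(s$run_length[["mean"]], 1)
  expect_equal(s$velocity[["mean"]], 0.5)

  rs2 <- simulate_runs(0.6, 0.2, 1e4, seed = 3)
  s2 <- summarize_runs(rs2)
  expect_lt(abs(s2$run_length[["mean"]] - 0.8), 3 * 0.6 / sqrt(1e4))
  expect_equal(s2$run_length[["se"]],
               s2$run_length[["sd"]] / sqrt(1e4), tolerance = 1e-12)
})
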