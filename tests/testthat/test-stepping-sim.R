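# Synthetic-data generator: mixtures, traces, runs, transients.

test_that("mixture validation and presets", {
  expect_error(mixture_spec(c(0.5, 0.4), c(0, 1), c(1, 1)), "sum to 1")
  expect_error(mixture_spec(c(-0.5, 1.5), c(0, 1), c(1, 1)), "> 0")
  m <- step_mixture("hmm_bundle")
  expect_equal(m$means_nm, c(-28, 17, 40, 57))
  expect_equal(m$sds_nm, c(18, 6, 9, 2))
  expect_equal(m$weights, rep(0.25, 4))
  expect_identical(attr(m, "n"), 178L)
  expect_equal(sum(step_mixture("fl_bundle")$weights), 1)
  expect_equal(step_mixture("hmm_bundle_backsplit")$means_nm[1:2], c(-49, -20))
})

test_that("sample_steps draws from the mixture and is seed-deterministic", {
  # zero-variance single component
  m0 <- mixture_spec(1, 36, 1e-12)
  expect_equal(sample_steps(m0, 5, seed = 1), rep(36, 5), tolerance = 1e-9)

  # sample mean within 3 s.e. of the analytic mixture mean
  m <- step_mixture("fl_single")
  mu <- sum(m$weights * m$means_nm)
  v <- sum(m$weights * (m$sds_nm^2 + m$means_nm^2)) - mu^2
  x <- sample_steps(m, 1e5, seed = 7)
  expect_lt(abs(mean(x) - mu), 3 * sqrt(v / 1e5))

  # determinism, and no disturbance of the caller's RNG stream
  expect_identical(sample_steps(m, 100, seed = 11),
                   sample_steps(m, 100, seed = 11))
  set.seed(42); a <- runif(1)
  set.seed(42); invisible(sample_steps(m, 10, seed = 3)); b <- runif(1)
  expect_identical(a, b)
})

test_that("simulated traces have exponential or Erlang dwells and true steps", {
  # noiseless: step detection recovers all 10 steps of 36 nm exactly
  tr0 <- simulate_trace(trace_params(50, 0, 1, 10, seed = 5),
                        mixture_spec(1, 36, 1e-12))
  f0 <- find_steps(tr0)
  expect_equal(f0$n_steps, 10L)
  expect_equal(f0$step_sizes_nm, rep(36, 10), tolerance = 1e-6)

  # empirical mean dwell within 3 s.e. of 1/k
  tr <- simulate_trace(trace_params(50, 3, 5, 1000, seed = 1),
                       mixture_spec(1, 36, 1))
  d <- diff(tr$true_step_times)
  expect_lt(abs(mean(d) - 0.2), 3 * 0.2 / sqrt(length(d)))

  # Erlang-2 dwells: same mean, CV ~ 1/sqrt(2)
  tre <- simulate_trace(trace_params(50, 3, 5, 2000, erlang = TRUE, seed = 2),
                        mixture_spec(1, 36, 1))
  de <- diff(tre$true_step_times)
  expect_lt(abs(mean(de) - 0.2), 3 * 0.2 / sqrt(2 * length(de)))
  expect_equal(sd(de) / mean(de), 1 / sqrt(2), tolerance = 0.1)

  # structural invariants
  expect_true(all(diff(tr$times_s) > 0))
  expect_length(tr$true_step_sizes, length(tr$true_step_times))
  expect_identical(
    simulate_trace(trace_params(50, 3, 5, 20, seed = 9), step_mixture("fl_single"))$positions_nm,
    simulate_trace(trace_params(50, 3, 5, 20, seed = 9), step_mixture("fl_single"))$positions_nm)
})

test_that("duration-limited traces can be empty without erroring", {
  tr <- simulate_trace(trace_params(50, 1, 0.001, duration_s = 0.2, seed = 3),
                       mixture_spec(1, 36, 1))
  expect_true(tr$empty)
  expect_length(tr$true_step_times, 0)
})

test_that("simulated run lengths are truncated-exponential", {
  # sample mean ~ X0 + lambda
  rs <- simulate_runs(1.16, 0.4, 1e5, seed = 4)
  expect_lt(abs(mean(rs$run_lengths_um) - 1.56), 3 * 1.16 / sqrt(1e5))
  expect_true(all(rs$run_lengths_um >= 0.4))
  # velocity = run_length / duration, record by record
  expect_equal(rs$velocities_um_per_s,
               rs$run_lengths_um / rs$durations_s, tolerance = 1e-12)

  # degenerate limit: lambda -> 0 collapses all runs onto X0
  rs0 <- simulate_runs(1e-9, 0.4, 100, seed = 5)
  expect_equal(rs0$run_lengths_um, rep(0.4, 100), tolerance = 1e-6)
})

test_that("published motility table has self-consistent columns", {
  tab <- motility_table()
  expect_setequal(tab$dataset, c("fl_single", "hmm_single", "fl_bundle",
                                 "hmm_bundle"))
  # s.e. = s.d./sqrt(N) within rounding of the printed values
  expect_equal(tab$run_se_um, tab$run_sd_um / sqrt(tab$run_n),
               tolerance = 0.35)
  # bundles support roughly twice the velocity of single filaments
  expect_gt(tab$vel_mean_um_s[tab$dataset == "fl_bundle"] /
              tab$vel_mean_um_s[tab$dataset == "fl_single"], 1.5)
})

test_that("simulated transients are sums of decaying exponentials", {
  tg <- sort(c(seq(0, 0.2, by = 1e-3), 1 / 60))
  # analytic value at t = 1/k
  s <- simulate_transient(list(c(2, 60)), tg)
  expect_equal(s$signal[which(tg == 1 / 60)], 2 / exp(1), tolerance = 1e-9)
  # half-lives scale as 1/k
  s19 <- simulate_transient(list(c(1, 19)), seq(0, 1, 1e-4))
  s34 <- simulate_transient(list(c(1, 34)), seq(0, 1, 1e-4))
  t_half <- function(s) s$time_s[which.min(abs(s$signal - 0.5))]
  expect_equal(t_half(s19) / t_half(s34), 34 / 19, tolerance = 0.02)
  # seeded noise is reproducible
  expect_identical(simulate_transient(list(c(1, 60)), tg, 0.05, seed = 8),
                   simulate_transient(list(c(1, 60)), tg, 0.05, seed = 8))
  expect_error(simulate_transient(list(c(1, -2)), tg), "> 0")
})
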