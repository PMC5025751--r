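# Configuration, file I/O and the end-to-end pipeline: simulate (or load)
# traces -> step finding -> pooled step sizes -> cross-validated mixture
# fit -> run-length and velocity statistics -> serializable report.

config_schema <- list(
  simulation = c("mixture", "n_traces", "k_step_per_s", "noise_sd_nm",
                 "frame_rate_hz", "steps_per_trace", "erlang"),
  runs = c("lambda_um", "X0_um", "n", "velocity_um_s", "velocity_sd"),
  analysis = c("kmax", "folds", "X0_um", "min_dwell_frames", "max_steps",
               "n_restarts"),
  seed = NULL,
  name = NULL,
  traces_dir = NULL
)

#' Build and validate an analysis configuration
#'
#' @param config named list (or path to a YAML file) with blocks
#'   `simulation` (mixture name or weights/means/sds, `n_traces`,
#'   `k_step_per_s`, `noise_sd_nm`, `frame_rate_hz`, `steps_per_trace`,
#'   `erlang`), `runs` (`lambda_um`, `X0_um`, `n`, `velocity_um_s`,
#'   `velocity_sd`), `analysis` (`kmax`, `folds`, `X0_um`,
#'   `min_dwell_frames`, `max_steps`, `n_restarts`), plus `seed`, `name`
#'   and optionally `traces_dir` (load measured traces instead of
#'   simulating). Unknown keys are rejected.
#' @return a validated object of class `analysis_config`.
#' @seealso [demo_config()] for ready-made configurations.
#' @export
analysis_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(config_schema))
  if (length(unknown)) {
    stop_domain("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (blk in c("simulation", "runs", "analysis")) {
    if (!is.null(config[[blk]])) {
      bad <- setdiff(names(config[[blk]]), config_schema[[blk]])
      if (length(bad)) {
        stop_domain(sprintf("unknown key(s) in `%s`: %s", blk,
                            paste(bad, collapse = ", ")))
      }
    }
  }
  defaults <- list(
    name = "unnamed",
    seed = 1L,
    simulation = list(mixture = "fl_single", n_traces = 10L,
                      k_step_per_s = 2, noise_sd_nm = 3, frame_rate_hz = 50,
                      steps_per_trace = 20L, erlang = FALSE),
    runs = list(lambda_um = 0.60, X0_um = 0.4, n = 200L,
                velocity_um_s = 0.31, velocity_sd = 0.08),
    analysis = list(kmax = 5L, folds = 5L, X0_um = 0.4,
                    min_dwell_frames = 2L, max_steps = NULL,
                    n_restarts = 10L)
  )
  out <- utils::modifyList(defaults, config)
  check_number(out$seed, "seed")
  if (is.character(out$simulation$mixture)) {
    out$simulation$mixture <- step_mixture(out$simulation$mixture)
  } else if (is.list(out$simulation$mixture)) {
    m <- out$simulation$mixture
    out$simulation$mixture <- mixture_spec(m$weights, m$means_nm, m$sds_nm)
  }
  structure(out, class = "analysis_config")
}

#' Ready-made demonstration configurations
#'
#' `"fl_single"`: full-length construct on single filaments — two-component
#' step mixture, ~214 pooled steps, run lengths with lambda 0.60 um.
#' `"hmm_bundle"`: zippered dimer on fascin bundles — four-component
#' mixture, ~178 pooled steps, lambda 1.18 um.
#'
#' @param name `"fl_single"` or `"hmm_bundle"`.
#' @param seed root seed for every stochastic stage.
#' @return an `analysis_config`.
#' @export
demo_config <- function(name = c("fl_single", "hmm_bundle"), seed = 1L) {
  name <- match.arg(name)
  tab <- motility_table()
  row <- tab[tab$dataset == name, ]
  n_steps_target <- attr(step_mixture(name), "n")
  per_trace <- 18L
  analysis_config(list(
    name = name,
    seed = seed,
    simulation = list(mixture = name,
                      n_traces = as.integer(round(n_steps_target / per_trace)),
                      k_step_per_s = 2, noise_sd_nm = 3, frame_rate_hz = 50,
                      steps_per_trace = per_trace),
    runs = list(lambda_um = row$lambda_um, X0_um = 0.4,
                n = row$run_n, velocity_um_s = row$vel_mean_um_s,
                velocity_sd = row$vel_sd_um_s / 2),
    analysis = list(kmax = 5L, folds = 5L, X0_um = 0.4,
                    min_dwell_frames = 2L, max_steps = NULL,
                    n_restarts = 10L)
  ))
}

#' Read a position-versus-time trace
#'
#' TSV/CSV with header columns `time_s` and `position_nm` (extra columns
#' ignored, `#` comment lines skipped).
#'
#' @param path file path.
#' @return a `step_trace` (without ground truth).
#' @export
read_trace <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                      stringsAsFactors = FALSE),
    error = function(e) stop_domain("malformed trace file: ", conditionMessage(e))
  )
  miss <- setdiff(c("time_s", "position_nm"), names(df))
  if (length(miss)) {
    stop_domain("trace file missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(!is.finite(df$time_s) | !is.finite(df$position_nm))
  if (length(bad)) {
    stop_domain("non-numeric trace rows at line(s): ",
                paste(bad + 1L, collapse = ", "))
  }
  if (any(diff(df$time_s) <= 0)) {
    stop_domain("trace times must be strictly increasing")
  }
  structure(
    list(times_s = df$time_s, positions_nm = df$position_nm,
         true_step_times = NULL, true_step_sizes = NULL,
         empty = FALSE, params = NULL, mixture = NULL),
    class = "step_trace"
  )
}

#' Write a trace as TSV
#'
#' @param trace a `step_trace`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "step_trace"))
  df <- data.frame(time_s = trace$times_s, position_nm = trace$positions_nm)
  utils::write.table(format(df, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) stepping traces, detects steps, pools the detected
#' step sizes, selects the mixture component count by cross-validation,
#' fits the selected mixture, simulates and fits run lengths, and returns
#' a serializable report. Fully deterministic for a given config + seed;
#' each stage draws from its own named substream of the root seed.
#'
#' @param config an [analysis_config()] (or list/path coercible to one).
#' @return an object of class `analysis_report`.
#' @examples
#' \donttest{
#' rep <- run_pipeline(demo_config("fl_single"))
#' print(rep)
#' }
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "analysis_config")) config <- analysis_config(config)
  sim <- config$simulation
  ana <- config$analysis

  # --- traces
  if (!is.null(config$traces_dir)) {
    files <- list.files(config$traces_dir, pattern = "\\.(tsv|csv)$",
                        full.names = TRUE)
    traces <- lapply(files, read_trace)
  } else if (sim$n_traces > 0) {
    seeds <- substream_seed(config$seed, "traces") + seq_len(sim$n_traces)
    traces <- lapply(seeds, function(s) {
      simulate_trace(
        trace_params(frame_rate_hz = sim$frame_rate_hz,
                     noise_sd_nm = sim$noise_sd_nm,
                     k_step_per_s = sim$k_step_per_s,
                     n_steps = sim$steps_per_trace,
                     erlang = isTRUE(sim$erlang), seed = s),
        sim$mixture)
    })
  } else {
    traces <- list()
  }
  if (length(traces) == 0) {
    warning("no traces: returning empty report")
    return(structure(list(name = config$name, seed = config$seed,
                          n_traces = 0L, empty = TRUE),
                     class = "analysis_report"))
  }

  # --- step detection and pooling
  fits <- lapply(traces, find_steps, max_steps = ana$max_steps,
                 min_dwell_frames = ana$min_dwell_frames)
  pooled <- unlist(lapply(fits, `[[`, "step_sizes_nm"))

  # --- mixture selection and fit
  cv <- select_K_cv(pooled, K_range = seq_len(ana$kmax), folds = ana$folds,
                    seed = substream_seed(config$seed, "cv"),
                    n_restarts = ana$n_restarts)
  mix_fit <- fit_gaussian_mixture(pooled, cv$K_selected,
                                  n_restarts = ana$n_restarts,
                                  seed = substream_seed(config$seed, "em"))

  # --- runs
  runs <- simulate_runs(config$runs$lambda_um, config$runs$X0_um,
                        config$runs$n,
                        seed = substream_seed(config$seed, "runs"),
                        velocity_um_s = config$runs$velocity_um_s,
                        velocity_sd = config$runs$velocity_sd)
  rl_fit <- fit_run_length(runs, X0 = ana$X0_um, n_boot = 200,
                           seed = substream_seed(config$seed, "boot"))
  run_stats <- summarize_runs(runs)

  structure(
    list(
      name = config$name,
      seed = config$seed,
      n_traces = length(traces),
      n_steps_pooled = length(pooled),
      empty = FALSE,
      K_selected = cv$K_selected,
      cv_loglik = cv$cv_loglik,
      mixture_fit = list(K = mix_fit$K, weights = mix_fit$weights,
                         means_nm = mix_fit$means_nm,
                         sds_nm = mix_fit$sds_nm, loglik = mix_fit$loglik),
      run_length = list(lambda_um = rl_fit$lambda_um,
                        lambda_se = rl_fit$lambda_se,
                        X0_um = rl_fit$X0_um, n = rl_fit$n,
                        mean = run_stats$run_length[["mean"]],
                        sd = run_stats$run_length[["sd"]],
                        se = run_stats$run_length[["se"]]),
      velocity = as.list(run_stats$velocity)
    ),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("Analysis report '%s' (seed %d)\n", x$name, x$seed))
  if (isTRUE(x$empty)) { cat("  [empty: no traces]\n"); return(invisible(x)) }
  cat(sprintf("  %d traces, %d pooled steps; selected K = %d\n",
              x$n_traces, x$n_steps_pooled, x$K_selected))
  for (k in seq_len(x$mixture_fit$K)) {
    cat(sprintf("    w=%.2f mean=%+.1f nm sd=%.1f nm\n",
                x$mixture_fit$weights[k], x$mixture_fit$means_nm[k],
                x$mixture_fit$sds_nm[k]))
  }
  cat(sprintf("  run length: mean %.2f um, lambda %.2f um (s.e. %.2f, n=%d)\n",
              x$run_length$mean, x$run_length$lambda_um,
              x$run_length$lambda_se, x$run_length$n))
  cat(sprintf("  velocity: %.2f +- %.2f um/s (n=%d)\n",
              x$velocity$mean, x$velocity$sd, x$velocity$n))
  invisible(x)
}

#' Write / read an analysis report as JSON
#'
#' Round-trips through JSON without loss (`digits = NA`).
#'
#' @param report an `analysis_report`.
#' @param path output path.
#' @return `path` invisibly (write); an `analysis_report` (read).
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "analysis_report")
}
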