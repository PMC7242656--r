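#' Experiment configuration
#'
#' Settings for the three experiment drivers: per-cost optimization sweep,
#' optimizer-vs-random comparison, and convergence study.
#'
#' @param model [arm_model()] (or path to a YAML config readable by
#'   [read_model_config()])
#' @param costs cost names to sweep
#' @param mode task duration mode: `"free"` or `"fixed_1s"`
#' @param maxIter optimization iterations per run
#' @param n_init random initialization samples
#' @param beta UCB tradeoff
#' @param restarts acquisition restarts
#' @param n_repeats repeated runs (comparison / convergence)
#' @param seed base seed; per-run seeds are derived deterministically
#' @param out_dir output directory, or `NULL` for no files
#' @param reference optional [generate_reference_set()] result; generated from
#'   `seed` when `NULL`
#' @return object of class `experiment_config`
#' @export
experiment_config <- function(model = default_model(), costs = cost_names(),
                              mode = c("free", "fixed_1s"), maxIter = 600,
                              n_init = 10, beta = 0.01, restarts = 30,
                              n_repeats = 3, seed = 1, out_dir = NULL,
                              reference = NULL) {
  mode <- match.arg(mode)
  if (is.character(model)) model <- read_model_config(model)
  stopifnot(maxIter >= 1, n_init >= 1, n_repeats >= 1)
  costs <- vapply(costs, normalize_cost_name, character(1))
  structure(list(model = model, costs = unname(costs), mode = mode,
                 maxIter = maxIter, n_init = n_init, beta = beta,
                 restarts = restarts, n_repeats = n_repeats, seed = seed,
                 out_dir = out_dir, reference = reference),
            class = "experiment_config")
}

# model with the task switched to the configured duration mode
config_model <- function(config) {
  model <- config$model
  if (config$mode == "fixed_1s") {
    tk <- unclass(model$task)
    tk$duration_mode <- "fixed"
    tk$T_fixed <- 1.0
    model$task <- do.call(task_spec, tk)
  }
  model
}

config_reference <- function(config, model) {
  if (!is.null(config$reference)) return(config$reference)
  generate_reference_set(seed = config$seed, model = model)
}

#' Cost callable over the stimulation box for a model and cost
#'
#' Wraps [simulate_reach()] + [total_cost()] into the black-box function the
#' optimizer queries, with per-model memoization keyed by the rounded
#' stimulation vector (simulations are deterministic, so repeated queries are
#' served from the cache).
#'
#' @param model [arm_model()]
#' @param cost cost name or [cost_spec()]
#' @return function `u -> J_total`
#' @export
make_cost_callable <- function(model, cost) {
  spec <- if (inherits(cost, "cost_spec")) cost else cost_spec(cost)
  cache <- model$cache
  function(u) {
    key <- paste0("J_", spec$name, "_", model$task$duration_mode, "_",
                  paste(signif(u, 12), collapse = ","))
    if (!is.null(cache[[key]])) return(cache[[key]])
    traj <- simulate_reach(u, model)
    y <- total_cost(traj, model$task, spec)$J_total
    cache[[key]] <- y
    y
  }
}

#' Per-cost optimization sweep
#'
#' For each configured cost function: one Bayesian-optimization run, the five
#' best stimulation vectors re-simulated, and trajectory metrics against the
#' reference set.  A failure in one cost isolates that cost; the sweep
#' continues and failures are summarized in the result.
#'
#' @param config [experiment_config()]
#' @param k number of best solutions kept per cost
#' @return named list per cost: `run` (`bo_result`), `best` ([best_k()]),
#'   `trajectories`, `metrics`, or an `error` entry for failed costs
#' @export
run_cost_sweep <- function(config, k = 5) {
  model <- config_model(config)
  reference <- config_reference(config, model)
  cfg_id <- config_hash(list(seed = config$seed, mode = config$mode,
                             maxIter = config$maxIter))
  out <- list()
  for (ci in seq_along(config$costs)) {
    cost <- config$costs[ci]
    res <- tryCatch({
      callable <- make_cost_callable(model, cost)
      run <- run_bayesopt(callable, maxIter = config$maxIter,
                          n_init = config$n_init, beta = config$beta,
                          seed = config$seed + 1000 * ci,
                          restarts = config$restarts)
      bk <- best_k(run$dataset, k = min(k, length(run$dataset$y)))
      trajs <- lapply(seq_len(nrow(bk$U)), function(j)
        simulate_reach(bk$U[j, ], model))
      mets <- lapply(trajs, trajectory_metrics, reference = reference)
      if (!is.null(config$out_dir)) {
        cdir <- file.path(config$out_dir, tolower(cost))
        dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
        for (j in seq_along(trajs))
          write_trajectory(trajs[[j]],
                           file.path(cdir, sprintf("best_%d.csv", j)),
                           config_id = cfg_id)
        write_run_result(run, file.path(cdir, "run.json"), config_id = cfg_id)
        jsonlite::write_json(
          lapply(seq_along(mets), function(j) {
            m <- mets[[j]]
            prof <- velocity_profile(trajs[[j]])
            c(m[c("endpoint_error", "curvature_error",
                  "peak_velocity_error", "skewness_error")],
              list(v_peak = prof$v_peak, t_peak = prof$t_peak))
          }),
          file.path(cdir, "metrics.json"), auto_unbox = TRUE, digits = NA)
      }
      list(run = run, best = bk, trajectories = trajs, metrics = mets)
    }, error = function(e) list(error = conditionMessage(e)))
    out[[cost]] <- res
  }
  failed <- names(out)[vapply(out, function(x) !is.null(x$error), logical(1))]
  if (length(failed) > 0)
    message("cost sweep finished with failures: ",
            paste(failed, collapse = ", "))
  attr(out, "reference") <- reference
  out
}

#' Optimizer-versus-random comparison
#'
#' `n_repeats` Bayesian-optimization runs against `n_repeats` random-search
#' runs with the same per-run evaluation budget on one cost; the pooled
#' total-cost observations of the two arms are compared with a two-sample
#' t-test, and boxplot summaries (median, IQR, 1.5 IQR whiskers/outliers) are
#' reported.
#'
#' @param config [experiment_config()]
#' @param cost cost to compare on (default the jerk+energy hybrid)
#' @param cost_callable optional explicit callable (e.g. a toy cost); when
#'   given, `cost` is only a label
#' @return list with `runs_bo`, `runs_random`, `test` ([compare_runs()]) and
#'   `boxplots`
#' @export
run_bo_vs_random <- function(config, cost = "JE", cost_callable = NULL) {
  if (is.null(cost_callable)) {
    model <- config_model(config)
    cost_callable <- make_cost_callable(model, cost)
  }
  runs_bo <- lapply(seq_len(config$n_repeats), function(r)
    run_bayesopt(cost_callable, maxIter = config$maxIter,
                 n_init = config$n_init, beta = config$beta,
                 seed = config$seed + r, restarts = config$restarts))
  runs_rd <- lapply(seq_len(config$n_repeats), function(r)
    run_random_search(cost_callable, maxIter = config$maxIter + config$n_init,
                      seed = config$seed + config$n_repeats + r))
  y_bo <- unlist(lapply(runs_bo, function(r) r$dataset$y))
  y_rd <- unlist(lapply(runs_rd, function(r) r$dataset$y))
  test <- compare_runs(y_rd, y_bo)
  res <- list(runs_bo = runs_bo, runs_random = runs_rd, test = test,
              boxplots = list(random = boxplot_summary(y_rd),
                              bo = boxplot_summary(y_bo)),
              cost = if (is.character(cost)) cost else "custom")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(t = test$t, p = test$p,
           medians = list(random = res$boxplots$random$median,
                          bo = res$boxplots$bo$median),
           IQRs = list(random = res$boxplots$random$iqr,
                       bo = res$boxplots$bo$iqr)),
      file.path(config$out_dir, "comparison.json"),
      auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Convergence study over repeated optimization runs
#'
#' `n_repeats` Bayesian-optimization runs; the per-iteration mean and
#' standard deviation of the running-minimum curves are returned and
#' optionally written as CSV.
#'
#' @param config [experiment_config()]
#' @param cost cost to run on
#' @param cost_callable optional explicit callable
#' @return list with `runs` and `stats` ([convergence_stats()])
#' @export
run_convergence <- function(config, cost = "JE", cost_callable = NULL) {
  if (is.null(cost_callable)) {
    model <- config_model(config)
    cost_callable <- make_cost_callable(model, cost)
  }
  runs <- lapply(seq_len(config$n_repeats), function(r)
    run_bayesopt(cost_callable, maxIter = config$maxIter,
                 n_init = config$n_init, beta = config$beta,
                 seed = config$seed + r, restarts = config$restarts))
  stats_ <- convergence_stats(runs)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(data.frame(iteration = stats_$iteration, mean = stats_$mean,
                         sd = stats_$sd),
              file.path(config$out_dir, "convergence.csv"), row.names = FALSE)
  }
  list(runs = runs, stats = stats_)
}
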