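# Defaults for each experiment's configuration block.
config_defaults <- function() {
  list(
    experiment = "interval_pe",
    seed = 1L,
    basis = list(kind = "microstimulus", D = 50L, sigma = 0.08, rho = 0.985,
                 steps_per_second = 20L),
    learner = list(alpha = 0.01, gamma = 0.98, lambda = 0.95),
    actor = list(eta = 0.1),
    task = list(intervals_s = c(1, 2, 4, 8, 16), n_trials = 100L,
                iti_steps = 500L, fi_s = 20, probe_fraction = 0.25,
                short_s = 2, long_s = 8, n_probe_durations = 5L),
    semi_markov = list(weber_k = 0.15, exponent_p = 1, floor_c = -0.1,
                       n_samples = 1e5)
  )
}

EXPERIMENTS <- c("interval_pe", "pavlovian", "peak", "bisection",
                 "interval_scaling")

#' Load and validate an experiment configuration
#'
#' Reads a YAML or JSON configuration file, fills unspecified fields with
#' defaults (the standard microstimulus parameterization: alpha = 0.01,
#' gamma = 0.98, lambda = 0.95, D = 50, sigma = 0.08, 20 steps/s, 500-step
#' ITI, 100 trials), validates ranges, and rejects unknown keys. An empty
#' file yields the all-defaults `interval_pe` experiment.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated config list of class `experiment_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  validate_config(raw)
}

#' @rdname load_config
#' @param config A (possibly partial) configuration list.
#' @export
validate_config <- function(config) {
  def <- config_defaults()
  bad <- setdiff(names(config), names(def))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (blk in c("basis", "learner", "actor", "task", "semi_markov")) {
    extra <- setdiff(names(config[[blk]]), names(def[[blk]]))
    if (length(extra))
      stop("unknown key(s) in `", blk, "`: ", paste(extra, collapse = ", "))
  }
  cfg <- modifyList(def, config)
  if (!cfg$experiment %in% EXPERIMENTS)
    stop("`experiment` must be one of: ", paste(EXPERIMENTS, collapse = ", "))
  # range checks via the constructors
  do.call(basis_config, cfg$basis)
  do.call(learner_config, cfg$learner)
  actor_config(eta = cfg$actor$eta)
  do.call(rectified_pe_config, cfg$semi_markov)
  if (any(cfg$task$intervals_s <= 0) || cfg$task$n_trials < 0 ||
      cfg$task$probe_fraction < 0 || cfg$task$probe_fraction > 1)
    stop("invalid task block")
  structure(cfg, class = "experiment_config")
}

#' Save a configuration
#'
#' Writes a config as YAML (or JSON if the path ends in `.json`);
#' `load_config()` of the result round-trips.
#'
#' @param config An `experiment_config` (or plain list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  cfg <- unclass(config)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Run a configured experiment and write its artifacts
#'
#' Dispatches on `config$experiment`:
#' * `"interval_pe"`: Pavlovian sessions over `task$intervals_s`; summary
#'   CSV has one row per interval (cue and reward prediction errors).
#' * `"pavlovian"`: a single Pavlovian session at the first interval, with
#'   per-step records.
#' * `"peak"`: [run_peak_experiment()] at `task$fi_s`.
#' * `"bisection"`: [run_bisection_experiment()].
#' * `"interval_scaling"`: [interval_scaling_experiment()] under the
#'   `semi_markov` block.
#'
#' When `output_dir` is given, writes `summary.csv`, per-step records
#' (`steps.csv`, where applicable) and a JSON `manifest.json` echoing the
#' config, seed and package version; a rerun with the same config and seed
#' reproduces the outputs.
#'
#' @param config An `experiment_config` from [load_config()] /
#'   [validate_config()].
#' @param output_dir Output directory (`NULL` = do not write files).
#' @param quiet Suppress progress messages.
#' @return List with `summary` (data frame) and, where applicable, the
#'   underlying experiment object.
#' @export
run_experiment <- function(config, output_dir = NULL, quiet = FALSE) {
  cfg <- validate_config(unclass(config))
  if (!is.null(output_dir) &&
      !dir.exists(output_dir) &&
      !dir.create(output_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", output_dir)
  say <- function(...) if (!quiet) message(...)
  basis <- do.call(basis_config, cfg$basis)
  learner <- do.call(learner_config, cfg$learner)
  t0 <- Sys.time()

  steps <- NULL
  obj <- NULL
  if (cfg$experiment == "interval_pe") {
    say("interval_pe: ", length(cfg$task$intervals_s), " intervals x ",
        cfg$task$n_trials, " trials")
    summary <- run_interval_pe_experiment(cfg$task$intervals_s,
                                          cfg$task$n_trials, basis, learner)
  } else if (cfg$experiment == "pavlovian") {
    T1 <- cfg$task$intervals_s[1]
    task <- make_pavlovian_task(T1, cfg$task$n_trials,
                                iti_steps = cfg$task$iti_steps,
                                steps_per_second = basis$steps_per_second)
    obj <- run_pavlovian_session(task, basis, learner, record = "all")
    steps <- obj$steps
    summary <- event_pe_summary(list(obj), k_last = 1)
  } else if (cfg$experiment == "peak") {
    say("peak: FI ", cfg$task$fi_s, " s, ", cfg$task$n_trials, " trials")
    obj <- run_peak_experiment(cfg$task$fi_s, cfg$task$n_trials,
                               probe_fraction = cfg$task$probe_fraction,
                               learner = learner,
                               actor = actor_config(eta = cfg$actor$eta),
                               seed = cfg$seed)
    summary <- data.frame(fi_s = cfg$task$fi_s,
                          peak_time_s = obj$stats$peak_time_s,
                          spread_s = obj$stats$spread_s,
                          fit_quality = obj$stats$fit_quality)
    steps <- cbind(obj$curve)
  } else if (cfg$experiment == "bisection") {
    say("bisection: anchors ", cfg$task$short_s, "/", cfg$task$long_s, " s")
    obj <- run_bisection_experiment(cfg$task$short_s, cfg$task$long_s,
                                    n_trials = cfg$task$n_trials,
                                    n_probe_durations = cfg$task$n_probe_durations,
                                    probe_fraction = cfg$task$probe_fraction,
                                    learner = learner, eta = cfg$actor$eta,
                                    seed = cfg$seed)
    summary <- obj$psychometric$table
    summary$indifference_s <- obj$psychometric$indifference_s
  } else { # interval_scaling
    pe_cfg <- do.call(rectified_pe_config, cfg$semi_markov)
    summary <- interval_scaling_experiment(cfg$task$intervals_s, pe_cfg,
                                           seed = cfg$seed)
  }

  if (!is.null(output_dir)) {
    write.csv(summary, file.path(output_dir, "summary.csv"),
              row.names = FALSE)
    if (!is.null(steps))
      write.csv(steps, file.path(output_dir, "steps.csv"), row.names = FALSE)
    manifest <- list(
      experiment = cfg$experiment, seed = cfg$seed, config = unclass(cfg),
      package_version = as.character(utils::packageVersion("microtd")),
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("wrote ", output_dir)
  }
  invisible(list(summary = summary, experiment = obj))
}
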