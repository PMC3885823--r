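#' Trace decay matched to a task's criterion duration
#'
#' The microstimulus trace decays as `y(t) = rho^t`, so the temporal
#' resolution of the representation at elapsed time `t` -- how far the
#' trace moves per step relative to the receptive-field width -- is
#' `|dy/dt| = y(t) * log(1/rho)`. For a task whose difficulty concentrates
#' at one criterion duration `L` (the fixed interval of a peak procedure,
#' the long anchor of a bisection), resolution at `L` is maximized by
#' `log(1/rho) = 1/L`, i.e. the trace reaches `1/e` at the criterion
#' duration. This helper returns that decay. Because the rule is
#' scale-invariant, bases built with it produce timed responding whose
#' spread grows in proportion to the interval (the scalar property). The
#' package default `rho = 0.985` is this same rule anchored at 3.3 s, the
#' middle of the 1--16 s conditioning range.
#'
#' @param criterion_steps The criterion duration in steps.
#' @return The per-step decay `rho = exp(-1/criterion_steps)`.
#' @examples
#' trace_decay_for_interval(20 * 20)  # FI-20 s at 20 steps/s
#' @export
trace_decay_for_interval <- function(criterion_steps) {
  if (criterion_steps < 1) stop("`criterion_steps` must be >= 1")
  exp(-1 / criterion_steps)
}

#' Cue/reward prediction errors as a function of the cue-reward interval
#'
#' Runs one Pavlovian TD(lambda) session per interval under the
#' microstimulus basis and standard parameters (alpha = 0.01, gamma = 0.98,
#' lambda = 0.95, D = 50, sigma = 0.08, 20 steps/s, 100 trials, 500-step
#' ITI), then reads out the final-trial prediction error at the cue and at
#' the reward. Reproduces the signature pattern: the reward response
#' *increases* with the interval (temporal imprecision of long-delay
#' predictions) while the cue response *decreases* (temporal discounting).
#'
#' @param intervals_s Cue-reward intervals in seconds.
#' @param n_trials Training trials per interval.
#' @param basis,learner Configurations (defaults as above).
#' @param k_last Final trials to average in the read-out.
#' @return Data frame from [event_pe_summary()], one row per interval.
#' @examples
#' \donttest{run_interval_pe_experiment(c(1, 4, 16))}
#' @export
run_interval_pe_experiment <- function(intervals_s = c(1, 2, 4, 8, 16),
                                       n_trials = 100,
                                       basis = basis_config(),
                                       learner = learner_config(),
                                       k_last = 1) {
  sessions <- lapply(intervals_s, function(T) {
    task <- make_pavlovian_task(T, n_trials,
                                steps_per_second = basis$steps_per_second)
    run_pavlovian_session(task, basis, learner, record = "none")
  })
  event_pe_summary(sessions, k_last = k_last)
}

#' Train and analyze a peak-procedure simulation
#'
#' Trains the microstimulus actor-critic on a fixed-interval peak task and
#' summarizes probe-trial responding. The trace decay is matched to the
#' fixed interval via [trace_decay_for_interval()] unless a basis is
#' supplied. The response
#' curve is computed from sampled actions on the probe trials of the second
#' half of training (post-acquisition responding), then summarized by a
#' Gaussian fit.
#'
#' @param fi_s Fixed interval in seconds.
#' @param n_trials Training trials (reinforced + probe).
#' @param probe_fraction Fraction of probe trials.
#' @param probe_multiple Probe duration as a multiple of the FI.
#' @param basis `NULL` for the interval-matched default microstimulus basis.
#' @param learner,actor Configurations.
#' @param gains Optional gains applied throughout training and probes.
#' @param seed Integer seed (task interleaving and action sampling).
#' @param bin_s Response-curve bin width (seconds).
#' @param analyze_fraction Fraction of the session (from the end) whose
#'   probe trials enter the response curve.
#' @return List of class `peak_experiment`: `session`, `curve`
#'   ([response_curve()]), `stats` ([peak_statistics()]), `fi_s`, `basis`.
#' @examples
#' \donttest{
#' pk <- run_peak_experiment(20, n_trials = 500, seed = 1)
#' pk$stats
#' }
#' @export
run_peak_experiment <- function(fi_s = 20, n_trials = 2000,
                                probe_fraction = 0.25, probe_multiple = 3,
                                basis = NULL, learner = learner_config(),
                                actor = actor_config(), gains = NULL,
                                seed = 1, bin_s = 1,
                                analyze_fraction = 0.5) {
  sps <- if (is.null(basis)) 20L else basis$steps_per_second
  if (is.null(basis))
    basis <- basis_config(rho = trace_decay_for_interval(fi_s * sps),
                          steps_per_second = sps)
  task <- make_peak_task(fi_s, n_trials, probe_fraction = probe_fraction,
                         probe_multiple = probe_multiple,
                         steps_per_second = sps, seed = seed)
  session <- run_instrumental_session(task, basis, learner, actor,
                                      gains = gains, record = "probe",
                                      seed = seed + 1L)
  from <- floor((1 - analyze_fraction) * n_trials) + 1L
  curve <- response_curve(session, bin_s = bin_s,
                          trials = seq.int(from, n_trials))
  stats <- peak_statistics(curve)
  structure(list(session = session, curve = curve, stats = stats,
                 fi_s = fi_s, basis = basis, seed = seed),
            class = "peak_experiment")
}

#' @export
print.peak_experiment <- function(x, ...) {
  cat(sprintf("<peak_experiment> FI %g s: ", x$fi_s))
  print(x$stats)
  invisible(x)
}

#' Probe responding under a dopamine-manipulation gain profile
#'
#' Models an acute pharmacological challenge: the trained critic and policy
#' from a [run_peak_experiment()] are frozen and probe trials are re-run
#' with a gain profile applied to the feature stream (e.g. `gain_early <
#' 1` for a D2 antagonist, `> 1` for an agonist). Returns the resulting
#' probe response curve and its peak statistics.
#'
#' @param trained A `peak_experiment`.
#' @param gains A [gain_profile()] (applied to the cue microstimuli), a
#'   gains list, or `NULL` for a drug-free control run.
#' @param n_probes Number of evaluation probe trials.
#' @param seed Integer seed for action sampling.
#' @param bin_s Response-curve bin width.
#' @return List with `curve`, `stats`, `gains`.
#' @export
evaluate_peak_response <- function(trained, gains = NULL, n_probes = 200,
                                   seed = 1, bin_s = 1) {
  stopifnot(inherits(trained, "peak_experiment"))
  sps <- trained$basis$steps_per_second
  task <- make_peak_task(trained$fi_s, n_probes, probe_fraction = 1,
                         steps_per_second = sps, seed = seed)
  session <- run_instrumental_session(
    task, trained$basis, trained$session$learner, trained$session$actor,
    gains = if (inherits(gains, "gain_profile")) list(cue = gains) else gains,
    init_critic = trained$session$critic,
    init_policy = trained$session$policy, learn = FALSE, record = "probe",
    seed = seed)
  curve <- response_curve(session, bin_s = bin_s)
  list(curve = curve, stats = peak_statistics(curve), gains = gains)
}

#' Dopamine-manipulation experiment on the peak procedure
#'
#' Trains a drug-free peak-procedure model, then evaluates probe responding
#' under acute gain manipulations of the early (striatal) microstimulus
#' channel. The early/late boundary is placed at the trace strength reached
#' at the trained interval (`theta = exp(-1)` under the interval-matched
#' basis): the striatal channel is taken to carry the features traversed
#' *before* the trained reward time, which is what lets its attenuation
#' bias reward predictions -- and responding -- later, and its enhancement
#' earlier.
#'
#' @param fi_s Fixed interval (seconds).
#' @param gain_early Vector of early-channel gains to evaluate; 1 is the
#'   drug-free control, `< 1` models D2 antagonism / Parkinsonian
#'   depletion, `> 1` dopamine agonists.
#' @param n_trials Training trials.
#' @param n_probes Evaluation probe trials per condition.
#' @param seed Integer seed (training and evaluation).
#' @param ... Passed to [run_peak_experiment()].
#' @return Data frame with one row per gain: `gain_early`, `peak_time_s`,
#'   `spread_s`, `fit_quality`; the trained experiment is attached as
#'   attribute `trained`.
#' @export
run_dopamine_manipulation_experiment <- function(fi_s = 20,
                                                 gain_early = c(0.5, 1, 2),
                                                 n_trials = 2000,
                                                 n_probes = 200, seed = 1,
                                                 ...) {
  trained <- run_peak_experiment(fi_s, n_trials = n_trials, seed = seed, ...)
  theta <- trained$basis$rho^(fi_s * trained$basis$steps_per_second)
  rows <- lapply(gain_early, function(g) {
    ev <- evaluate_peak_response(
      trained, gain_profile(theta = theta, gain_early = g),
      n_probes = n_probes, seed = seed + 1000L)
    data.frame(gain_early = g, peak_time_s = ev$stats$peak_time_s,
               spread_s = ev$stats$spread_s,
               fit_quality = ev$stats$fit_quality)
  })
  structure(do.call(rbind, rows), trained = trained)
}

#' Train and analyze a temporal-bisection simulation
#'
#' Trains the microstimulus actor-critic to classify the short and long
#' anchor durations, then builds the psychometric function from the
#' unreinforced probe trials of the second half of training.
#'
#' @param short_s,long_s Anchor durations (seconds).
#' @param n_trials Total trials; the default provides roughly 160 probe
#'   presentations per probe duration after the acquisition half is
#'   discarded, enough for a stable psychometric function.
#' @param n_probe_durations Intermediate probe durations.
#' @param probe_fraction Fraction of probe trials.
#' @param basis `NULL` for the default basis with trace decay matched to
#'   the long anchor via [trace_decay_for_interval()] (the hardest
#'   discrimination in the task).
#' @param learner Critic configuration.
#' @param eta Actor learning rate. The default is larger than the peak
#'   procedure's because choice states are visited for only a few steps
#'   per trial.
#' @param seed Integer seed.
#' @param analyze_fraction Fraction of the session (from the end) whose
#'   probes enter the psychometric function.
#' @return List of class `bisection_experiment`: `session`, `psychometric`
#'   ([psychometric()]), `short_s`, `long_s`.
#' @export
run_bisection_experiment <- function(short_s = 2, long_s = 8,
                                     n_trials = 4000, n_probe_durations = 5,
                                     probe_fraction = 0.2, basis = NULL,
                                     learner = learner_config(), eta = 0.3,
                                     seed = 1, analyze_fraction = 0.5) {
  sps <- if (is.null(basis)) 20L else basis$steps_per_second
  window_s <- 2
  if (is.null(basis))
    basis <- basis_config(rho = trace_decay_for_interval(long_s * sps),
                          steps_per_second = sps)
  task <- make_bisection_task(short_s, long_s, n_probe_durations, n_trials,
                              probe_fraction = probe_fraction,
                              window_s = window_s, steps_per_second = sps,
                              seed = seed)
  actor <- actor_config(eta = eta, actions = attr(task, "meta")$actions)
  session <- run_instrumental_session(task, basis, learner, actor,
                                      record = "none", seed = seed + 1L)
  from <- floor((1 - analyze_fraction) * n_trials) + 1L
  keep <- session$trials$trial >= from
  session_late <- session
  session_late$trials <- session$trials[keep, , drop = FALSE]
  psy <- psychometric(session_late)
  structure(list(session = session, psychometric = psy, short_s = short_s,
                 long_s = long_s, seed = seed),
            class = "bisection_experiment")
}

#' @export
print.bisection_experiment <- function(x, ...) {
  cat(sprintf("<bisection_experiment> anchors %g/%g s\n", x$short_s, x$long_s))
  print(x$psychometric)
  invisible(x)
}

#' Early-reward and omission probe comparison
#'
#' Trains the microstimulus model and a CSC control on the same Pavlovian
#' fixed-interval task, then probes each with (i) a reward delivered
#' earlier than usual and (ii) reward omission, with learning frozen on the
#' probes. Under the microstimulus basis the positive weights on late cue
#' microstimuli are offset by negative weights on early reward
#' microstimuli, so an early reward produces almost no prediction error at
#' the usual reward time; omission produces a small, temporally extended
#' dip rather than the CSC's single large negative spike.
#'
#' @param interval_s Training cue-reward interval (seconds).
#' @param shift_s How much earlier the early-probe reward arrives.
#' @param n_trials Training trials.
#' @param basis Microstimulus [basis_config()].
#' @param learner Critic configuration for the microstimulus model.
#' @param csc_learner Critic configuration for the CSC control (a larger
#'   alpha is the conventional choice for the tabular one-hot code).
#' @return List of class `probe_experiment` with per-step probe records
#'   (`ms_early`, `ms_omission`, `csc_omission`), the usual reward step,
#'   and scalar summaries: `ms_early_delta_at_usual`,
#'   `csc_omission_delta_at_usual`, `ms_omission_min_delta`.
#' @export
run_probe_experiment <- function(interval_s = 2, shift_s = 1,
                                 n_trials = 500, basis = basis_config(),
                                 learner = learner_config(),
                                 csc_learner = learner_config(alpha = 0.1)) {
  sps <- basis$steps_per_second
  task <- make_pavlovian_task(interval_s, n_trials, steps_per_second = sps)
  base_tl <- task[[1]]
  usual <- base_tl$reward_step

  probe_task <- function(tl) new_task(list(tl), sps, attr(task, "iti_steps"))
  early_tl <- make_probe_trial(base_tl, "probe_early", shift_s = shift_s,
                               steps_per_second = sps)
  omit_tl <- make_probe_trial(base_tl, "probe_omission")

  probe_run <- function(bas, lrn, critic, tl)
    run_pavlovian_session(probe_task(tl), bas, lrn, init_critic = critic,
                          learn = FALSE, record = "all")$steps

  ms <- run_pavlovian_session(task, basis, learner, record = "none")
  ms_early <- probe_run(basis, learner, ms$critic, early_tl)
  ms_omit <- probe_run(basis, learner, ms$critic, omit_tl)

  csc_basis <- basis_config("csc", steps_per_second = sps,
                            horizon = base_tl$duration_steps)
  csc <- run_pavlovian_session(task, csc_basis, csc_learner, record = "none")
  csc_omit <- probe_run(csc_basis, csc_learner, csc$critic, omit_tl)

  at <- function(df, s) df$delta[df$step == s]
  structure(list(ms_early = ms_early, ms_omission = ms_omit,
                 csc_omission = csc_omit, usual_reward_step = usual,
                 interval_s = interval_s,
                 ms_early_delta_at_usual = at(ms_early, usual),
                 csc_omission_delta_at_usual = at(csc_omit, usual),
                 ms_omission_min_delta = min(ms_omit$delta),
                 ms_critic = ms$critic, csc_critic = csc$critic,
                 basis = basis, csc_basis = csc_basis),
            class = "probe_experiment")
}
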