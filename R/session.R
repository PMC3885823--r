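# Shared driver: validates configs, resolves the CSC horizon and gain
# vectors, calls the C++ engine, and wraps its output.
run_session <- function(task, basis, learner, actor = NULL, gains = NULL,
                        init_critic = NULL, init_policy = NULL, learn = TRUE,
                        record = c("all", "probe", "none"), seed = NULL) {
  stopifnot(inherits(task, "timing_task"), inherits(basis, "basis_config"),
            inherits(learner, "learner_config"))
  record <- match.arg(record)
  sched <- task_schedule(task)
  horizon <- if (basis$kind == "csc") {
    if (is.null(basis$horizon)) max(sched[, "duration"]) else basis$horizon
  } else basis$D
  block <- if (basis$kind == "microstimulus") basis$D else horizon
  M <- 2L * block
  g <- resolve_gains(gains, basis, horizon)

  w0 <- if (is.null(init_critic)) numeric(M) else init_critic$weights
  if (length(w0) != M) stop("initial critic has the wrong dimension")
  use_actor <- !is.null(actor)
  if (use_actor) {
    stopifnot(inherits(actor, "actor_config"))
    n_actions <- length(actor$actions)
    u0 <- if (is.null(init_policy)) matrix(0, n_actions, M) else init_policy$preferences
    if (!all(dim(u0) == c(n_actions, M)))
      stop("initial policy has the wrong dimension")
    eta <- actor$eta
  } else {
    n_actions <- 0L; u0 <- matrix(0, 0, 0); eta <- 0
  }

  types <- task_trial_types(task)
  record_trial <- switch(record,
    all = rep(TRUE, nrow(sched)),
    probe = grepl("probe", types),
    none = rep(FALSE, nrow(sched)))

  rew_mag <- vapply(task, function(tr) tr$reward_magnitude, numeric(1))
  post_steps <- attr(task, "meta")$post_steps %||%
    (2L * task_steps_per_second(task))

  res <- with_seed(seed, function()
    cpp_run_session(sched, rew_mag, if (basis$kind == "microstimulus") 0L else 1L,
                    basis$D, basis$sigma, basis$rho, horizon,
                    g$cue, g$reward, learner$alpha, learner$gamma,
                    learner$lambda, use_actor, eta, n_actions, w0, u0,
                    learn, record_trial, post_steps))

  sps <- task_steps_per_second(task)
  steps <- as.data.frame(res$steps, stringsAsFactors = FALSE)
  if (nrow(steps)) {
    steps$time_s <- steps$step / sps
    steps$trial_type <- types[steps$trial]
    if (use_actor) steps$action <- actor$actions[steps$action + 1L]
  }
  trials <- data.frame(trial = seq_along(task), trial_type = types,
                       duration_steps = sched[, "duration"],
                       cue_onset = sched[, "cue_onset"],
                       scheduled_reward_step = ifelse(sched[, "reward_step"] < 0,
                                                      NA, sched[, "reward_step"]),
                       as.data.frame(res$trials))
  if (use_actor)
    trials$choice <- ifelse(is.na(trials$choice), NA_character_,
                            actor$actions[trials$choice + 1L])

  critic <- critic_state(M)
  critic$weights <- res$weights
  policy <- NULL
  if (use_actor) {
    policy <- policy_state(n_actions, M)
    policy$preferences <- res$preferences
    rownames(policy$preferences) <- actor$actions
  }

  structure(list(steps = steps, trials = trials, critic = critic,
                 policy = policy, basis = basis, learner = learner,
                 actor = actor, gains = g, task_meta = attr(task, "meta"),
                 steps_per_second = sps, horizon = horizon, seed = seed),
            class = "session_result")
}

task_steps_per_second <- function(task) attr(task, "steps_per_second")

#' Run a Pavlovian conditioning session
#'
#' Simulates online TD(lambda) over the trials of a Pavlovian task: at each
#' step the features, the value of the current and successor state (both
#' under the current weights), and the prediction error are computed, then
#' eligibility traces and weights are updated. Traces are reset at trial
#' start; the inter-trial interval carries no features or rewards and is
#' therefore skipped (every ITI step would have `delta = 0`).
#'
#' @param task A `timing_task` from [make_pavlovian_task()] (possibly with
#'   probe trials spliced in).
#' @param basis A [basis_config()].
#' @param learner A [learner_config()].
#' @param gains Optional dopamine-manipulation gains (see
#'   [assemble_features()]).
#' @param init_critic Optional starting [critic_state()] (e.g. a trained
#'   one).
#' @param learn If `FALSE`, weights are frozen (evaluation only).
#' @param record Which trials to keep per-step records for: `"all"`,
#'   `"probe"`, or `"none"` (per-trial summaries are always kept).
#' @param seed Unused for Pavlovian tasks (they are deterministic); kept for
#'   interface symmetry.
#' @return A `session_result` with elements `steps` (per-step records:
#'   trial, step, time_s, value, delta, reward), `trials` (per-trial
#'   summaries incl. `cue_delta`, the prediction error at the transition
#'   into the cue state, and `reward_delta`, the prediction error at the
#'   actual -- or, on omission, scheduled -- reward step), and the final
#'   `critic`.
#' @examples
#' task <- make_pavlovian_task(1, n_trials = 20)
#' s <- run_pavlovian_session(task, basis_config(), learner_config())
#' tail(s$trials$reward_delta, 1)  # prediction error at reward, trial 20
#' @export
run_pavlovian_session <- function(task, basis, learner, gains = NULL,
                                  init_critic = NULL, learn = TRUE,
                                  record = "all", seed = NULL) {
  run_session(task, basis, learner, actor = NULL, gains = gains,
              init_critic = init_critic, learn = learn, record = record,
              seed = seed)
}

#' Run an instrumental (actor-critic) session
#'
#' As [run_pavlovian_session()], plus a softmax actor: at each step action
#' probabilities are computed from the current features, an action is
#' sampled, the task contingency decides the reward (e.g. first "respond"
#' at or after the fixed interval), and both the critic and the taken
#' action's preferences are updated from the prediction error. Probe trials
#' never deliver reward.
#'
#' @inheritParams run_pavlovian_session
#' @param actor An [actor_config()].
#' @param init_policy Optional starting [policy_state()].
#' @param seed Integer seed making the sampled action sequence reproducible.
#' @return A `session_result`; `steps` additionally records the sampled
#'   `action` and `p_first` (probability of the first action, e.g.
#'   "respond"), and `trials` records the `choice` on bisection trials.
#' @export
run_instrumental_session <- function(task, basis, learner, actor,
                                     gains = NULL, init_critic = NULL,
                                     init_policy = NULL, learn = TRUE,
                                     record = "probe", seed = NULL) {
  stopifnot(inherits(actor, "actor_config"))
  run_session(task, basis, learner, actor = actor, gains = gains,
              init_critic = init_critic, init_policy = init_policy,
              learn = learn, record = record, seed = seed)
}

#' @export
print.session_result <- function(x, ...) {
  cat("<session_result> ", nrow(x$trials), " trials, ",
      nrow(x$steps), " recorded steps", sep = "")
  if (!is.null(x$policy)) cat(", actor-critic")
  cat("\n")
  invisible(x)
}

#' Evaluate the learned value function along a trial
#'
#' Computes `V(t) = w . x_t` for every step of a timeline under a trained
#' critic, with no learning. Useful for comparing learned values against
#' closed-form targets.
#'
#' @param critic A [critic_state()] (e.g. `session$critic`).
#' @param timeline A [trial_timeline()].
#' @param basis The [basis_config()] the critic was trained with.
#' @param gains Optional gains, as in [assemble_features()].
#' @param horizon CSC horizon used in training (defaults to the trained
#'   critic's block size).
#' @return Data frame with `step`, `time_s` and `value`.
#' @export
value_curve <- function(critic, timeline, basis, gains = NULL,
                        horizon = NULL) {
  stopifnot(inherits(critic, "critic_state"))
  if (basis$kind == "csc" && is.null(basis$horizon)) {
    basis$horizon <- if (is.null(horizon)) length(critic$weights) %/% 2L else horizon
  }
  steps <- seq.int(0L, timeline$duration_steps - 1L)
  v <- vapply(steps, function(t)
    predict_value(critic, assemble_features(timeline, t, basis, gains)),
    numeric(1))
  data.frame(step = steps, time_s = steps / basis$steps_per_second, value = v)
}
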