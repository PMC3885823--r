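# Trial-type codes shared with the C++ engine.
TRIAL_TYPES <- c(train = 0L, probe_early = 0L, probe_omission = 0L,
                 probe_extended = 0L, peak_fi = 1L, peak_probe = 2L,
                 bisection_train = 3L, bisection_probe = 4L)

#' A single discretized trial
#'
#' Event schedule for one trial, in time steps. Step 0 is a blank pre-cue
#' step: the cue comes on at `cue_onset` (default 1) so that the prediction
#' error generated by the (unpredictable) cue onset is observable as the
#' transition into the cue state.
#'
#' @param duration_steps Trial length in steps.
#' @param cue_onset Step of cue onset (>= 1 so a pre-cue step exists).
#' @param reward_step Step of reward delivery, or `NA` for none. For
#'   instrumental trial types this is the *scheduled* time only; actual
#'   delivery is decided by the contingency at run time.
#' @param reward_magnitude Reward size (default 1).
#' @param trial_type One of `"train"`, `"probe_early"`, `"probe_omission"`,
#'   `"probe_extended"`, `"peak_fi"`, `"peak_probe"`, `"bisection_train"`,
#'   `"bisection_probe"`.
#' @param fi_step For `"peak_fi"`: first step at which a response is
#'   rewarded.
#' @param choice_open,choice_close For bisection trials: the choice window.
#' @param correct_action For `"bisection_train"`: index (0-based) of the
#'   rewarded action.
#' @return An object of class `trial_timeline`.
#' @export
trial_timeline <- function(duration_steps, cue_onset = 1L, reward_step = NA,
                           reward_magnitude = 1, trial_type = "train",
                           fi_step = NA, choice_open = NA, choice_close = NA,
                           correct_action = NA) {
  trial_type <- match.arg(trial_type, names(TRIAL_TYPES))
  duration_steps <- as.integer(duration_steps)
  if (duration_steps < 2L) stop("`duration_steps` must be at least 2")
  if (cue_onset < 1L || cue_onset >= duration_steps)
    stop("`cue_onset` must lie in [1, duration_steps)")
  if (!is.na(reward_step)) {
    if (reward_step <= cue_onset || reward_step >= duration_steps)
      stop("`reward_step` must lie strictly between cue onset and trial end")
    if (grepl("probe", trial_type) && trial_type != "probe_early")
      stop("probe trials of type ", trial_type, " cannot carry a reward")
  }
  structure(
    list(duration_steps = duration_steps, cue_onset = as.integer(cue_onset),
         reward_step = if (is.na(reward_step)) NA_integer_ else as.integer(reward_step),
         reward_magnitude = reward_magnitude, trial_type = trial_type,
         fi_step = if (is.na(fi_step)) NA_integer_ else as.integer(fi_step),
         choice_open = if (is.na(choice_open)) NA_integer_ else as.integer(choice_open),
         choice_close = if (is.na(choice_close)) NA_integer_ else as.integer(choice_close),
         correct_action = if (is.na(correct_action)) NA_integer_ else as.integer(correct_action)),
    class = "trial_timeline")
}

new_task <- function(trials, steps_per_second, iti_steps, meta = list()) {
  structure(trials, class = "timing_task",
            steps_per_second = steps_per_second, iti_steps = iti_steps,
            meta = meta)
}

#' @export
print.timing_task <- function(x, ...) {
  types <- table(vapply(x, function(tr) tr$trial_type, character(1)))
  cat("<timing_task> ", length(x), " trials (",
      paste(names(types), types, sep = ": ", collapse = ", "), "); ",
      attr(x, "steps_per_second"), " steps/s, ITI ",
      attr(x, "iti_steps"), " steps\n", sep = "")
  invisible(x)
}

#' Pavlovian fixed-interval conditioning task
#'
#' Each trial presents a cue followed by a reward exactly `interval_s`
#' seconds later, plus a post-reward window so that post-reward prediction
#' errors are observable. Trials are separated by an inter-trial interval
#' that carries no stimuli or rewards; with per-trial trace resets and
#' all-zero ITI features every ITI step has zero prediction error, so the
#' session runner can skip ITI steps without changing any learned quantity.
#'
#' @param interval_s Cue-reward interval in seconds, > 0.
#' @param n_trials Number of trials.
#' @param iti_steps Inter-trial interval in steps (metadata; see above).
#' @param steps_per_second Time discretization.
#' @param post_s Post-reward recording window in seconds.
#' @param reward_magnitude Reward size.
#' @return A `timing_task`: list of [trial_timeline()]s.
#' @examples
#' task <- make_pavlovian_task(2, n_trials = 100)
#' task[[1]]$reward_step - task[[1]]$cue_onset  # 40 steps = 2 s
#' @export
make_pavlovian_task <- function(interval_s, n_trials, iti_steps = 500,
                                steps_per_second = 20, post_s = 2,
                                reward_magnitude = 1) {
  if (interval_s <= 0) stop("`interval_s` must be > 0")
  int_steps <- as.integer(round(interval_s * steps_per_second))
  if (int_steps < 1L) stop("`interval_s` rounds to zero steps at this resolution")
  post <- as.integer(round(post_s * steps_per_second))
  tl <- trial_timeline(duration_steps = 1L + int_steps + post + 1L,
                       cue_onset = 1L, reward_step = 1L + int_steps,
                       reward_magnitude = reward_magnitude, trial_type = "train")
  new_task(rep(list(tl), n_trials), steps_per_second, iti_steps,
           meta = list(interval_s = interval_s))
}

#' Derive a probe trial from a training trial
#'
#' @param base A [trial_timeline()] with a scheduled reward.
#' @param kind `"probe_early"` (reward moved earlier by `shift_s`),
#'   `"probe_omission"` (reward removed), or `"probe_extended"` (reward
#'   removed and the trial extended by `extend_s`).
#' @param shift_s Earlier shift in seconds (for `"probe_early"`).
#' @param extend_s Extension in seconds (for `"probe_extended"`).
#' @param steps_per_second Time discretization of `base`.
#' @return A [trial_timeline()] of the requested probe type.
#' @export
make_probe_trial <- function(base, kind = c("probe_early", "probe_omission",
                                            "probe_extended"),
                             shift_s = 0, extend_s = 2, steps_per_second = 20) {
  kind <- match.arg(kind)
  stopifnot(inherits(base, "trial_timeline"))
  if (is.na(base$reward_step)) stop("`base` must have a scheduled reward")
  tl <- base
  tl$trial_type <- kind
  if (kind == "probe_early") {
    shift <- as.integer(round(shift_s * steps_per_second))
    if (base$reward_step - shift <= base$cue_onset)
      stop("early shift must leave the reward after cue onset")
    tl$reward_step <- base$reward_step - shift
  } else if (kind == "probe_omission") {
    tl$reward_step <- NA_integer_
  } else {
    tl$reward_step <- NA_integer_
    tl$duration_steps <- base$duration_steps +
      as.integer(round(extend_s * steps_per_second))
  }
  tl
}

#' Peak-procedure task
#'
#' Seeded random interleaving of fixed-interval trials (reward delivered at
#' the first "respond" action at or after the FI) and unreinforced probe
#' trials lasting `probe_multiple` times the FI.
#'
#' @param fi_s Fixed interval in seconds.
#' @param n_trials Total number of trials.
#' @param probe_fraction Fraction of trials that are probes.
#' @param probe_multiple Probe duration as a multiple of the FI.
#' @param steps_per_second Time discretization.
#' @param post_s Post-reward window (seconds) on reinforced trials.
#' @param iti_steps Inter-trial interval (metadata).
#' @param seed Integer seed for the interleaving order (`NULL` = use the
#'   current RNG state).
#' @return A `timing_task` whose meta carries `fi_s` and `fi_step`.
#' @export
make_peak_task <- function(fi_s, n_trials, probe_fraction = 0.25,
                           probe_multiple = 3, steps_per_second = 20,
                           post_s = 2, iti_steps = 500, seed = NULL) {
  if (fi_s <= 0) stop("`fi_s` must be > 0")
  if (probe_fraction < 0 || probe_fraction > 1)
    stop("`probe_fraction` must lie in [0, 1]")
  fi <- as.integer(round(fi_s * steps_per_second))
  post <- as.integer(round(post_s * steps_per_second))
  fi_step <- 1L + fi                       # cue at step 1
  fi_tl <- trial_timeline(duration_steps = 1L + 2L * fi + post + 1L,
                          cue_onset = 1L, trial_type = "peak_fi",
                          fi_step = fi_step)
  probe_tl <- trial_timeline(duration_steps = 1L + probe_multiple * fi,
                             cue_onset = 1L, trial_type = "peak_probe")
  n_probe <- round(probe_fraction * n_trials)
  is_probe <- c(rep(TRUE, n_probe), rep(FALSE, n_trials - n_probe))
  is_probe <- with_seed(seed, function() sample(is_probe))
  trials <- lapply(is_probe, function(p) if (p) probe_tl else fi_tl)
  new_task(trials, steps_per_second, iti_steps,
           meta = list(fi_s = fi_s, fi_step = fi_step, post_steps = post,
                       probe_duration_steps = probe_tl$duration_steps))
}

#' Temporal bisection task
#'
#' Training trials present a cue of either the short or the long anchor
#' duration; a choice window opens at cue offset, during which choosing the
#' anchor-consistent action ("short" for the short anchor, "long" for the
#' long) is rewarded. Probe trials use durations geometrically spaced
#' strictly between the anchors and are never reinforced. During the cue no
#' actions are available (as when choice levers extend only at cue offset);
#' within the window the decaying cue trace is what carries duration
#' information.
#'
#' @param short_s,long_s Anchor durations in seconds, `0 < short_s < long_s`.
#' @param n_probe_durations Number of intermediate probe durations.
#' @param n_trials Total number of trials.
#' @param probe_fraction Fraction of trials that are probes (split evenly
#'   over probe durations).
#' @param window_s Choice-window length in seconds.
#' @param steps_per_second Time discretization.
#' @param post_s Post-outcome window (seconds).
#' @param iti_steps Inter-trial interval (metadata).
#' @param seed Integer seed for trial-order randomization.
#' @return A `timing_task`; meta carries the anchor and probe durations and
#'   the action labels `c("short", "long", "withhold")`.
#' @export
make_bisection_task <- function(short_s, long_s, n_probe_durations = 5,
                                n_trials = 2000, probe_fraction = 0.25,
                                window_s = 2, steps_per_second = 20,
                                post_s = 2, iti_steps = 500, seed = NULL) {
  if (!(short_s > 0 && long_s > short_s))
    stop("need 0 < short_s < long_s")
  win <- as.integer(round(window_s * steps_per_second))
  post <- as.integer(round(post_s * steps_per_second))
  make_trial <- function(dur_s, type, correct) {
    L <- as.integer(round(dur_s * steps_per_second))
    open <- 1L + L
    trial_timeline(duration_steps = open + win + post + 1L, cue_onset = 1L,
                   trial_type = type, choice_open = open,
                   choice_close = open + win - 1L, correct_action = correct)
  }
  probe_s <- if (n_probe_durations > 0)
    exp(seq(log(short_s), log(long_s), length.out = n_probe_durations + 2L))[
      seq_len(n_probe_durations) + 1L]
  else numeric(0)

  n_probe <- round(probe_fraction * n_trials)
  if (n_probe_durations == 0) n_probe <- 0
  n_anchor <- n_trials - n_probe
  anchor_tls <- list(make_trial(short_s, "bisection_train", 0L),
                     make_trial(long_s, "bisection_train", 1L))
  probe_tls <- lapply(probe_s, make_trial, type = "bisection_probe",
                      correct = NA)
  # balanced anchor halves; probes split evenly over durations
  idx_anchor <- rep_len(1:2, n_anchor)
  idx_probe <- if (n_probe > 0) rep_len(seq_along(probe_tls), n_probe) else integer(0)
  pool <- c(lapply(idx_anchor, function(i) anchor_tls[[i]]),
            lapply(idx_probe, function(i) probe_tls[[i]]))
  dur_s_pool <- c(c(short_s, long_s)[idx_anchor], probe_s[idx_probe])
  ord <- with_seed(seed, function() sample(length(pool)))
  task <- new_task(pool[ord], steps_per_second, iti_steps,
                   meta = list(short_s = short_s, long_s = long_s,
                               probe_durations_s = probe_s, post_steps = post,
                               actions = c("short", "long", "withhold"),
                               duration_s = dur_s_pool[ord]))
  task
}

# Convert a timing_task to the integer schedule matrix the engine expects.
task_schedule <- function(task) {
  stopifnot(inherits(task, "timing_task"))
  if (length(task) == 0L) stop("task contains no trials")
  enc <- function(v) ifelse(is.na(v), -1L, v)
  m <- t(vapply(task, function(tr) {
    c(tr$duration_steps, tr$cue_onset, enc(tr$reward_step),
      TRIAL_TYPES[[tr$trial_type]], enc(tr$fi_step), enc(tr$choice_open),
      enc(tr$choice_close), enc(tr$correct_action))
  }, integer(8)))
  colnames(m) <- c("duration", "cue_onset", "reward_step", "type", "fi_step",
                   "choice_open", "choice_close", "correct_action")
  m
}

task_trial_types <- function(task) vapply(task, function(tr) tr$trial_type, character(1))
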