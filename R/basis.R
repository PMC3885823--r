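#' Temporal basis configuration
#'
#' Defines how elapsed time since stimulus onset is turned into a feature
#' vector. Two representations are supported:
#'
#' * `"microstimulus"`: each stimulus leaves a memory trace `y_t` that is set
#'   to 1 at onset and decays by a factor `rho` per time step. A bank of `D`
#'   Gaussian temporal receptive fields with centers at `d/D` (d = 1..D) and
#'   width `sigma` reads out the trace: feature `d` at time `t` is
#'   `y_t * dnorm((y_t - d/D) / sigma)`. Because the trace starts at 1 and
#'   decays toward 0, receptive fields with centers near 1 are active *early*
#'   after onset and centers near 0 are active *late*; later-peaking
#'   microstimuli are more dispersed in time, which is what degrades timing
#'   precision at long delays.
#' * `"csc"` (complete serial compound): one indicator feature per
#'   post-onset time step up to `horizon` steps -- a perfect clock.
#'
#' @param kind `"microstimulus"` or `"csc"`.
#' @param D Number of microstimuli per stimulus (ignored for CSC).
#' @param sigma Receptive-field width (trace units), > 0.
#' @param rho Per-step trace decay in (0, 1). The default 0.985 at 20 steps/s
#'   gives a trace that spans roughly 1--16 s cue-reward intervals.
#' @param steps_per_second Time discretization (steps per second).
#' @param horizon CSC horizon in steps; `NULL` means "use the longest trial
#'   duration of the task" (resolved when a session is run).
#' @return An object of class `basis_config`.
#' @examples
#' basis_config()                      # Gaussian microstimulus defaults
#' basis_config("csc", horizon = 100)  # perfect-clock representation
#' @export
basis_config <- function(kind = c("microstimulus", "csc"), D = 50,
                         sigma = 0.08, rho = 0.985, steps_per_second = 20,
                         horizon = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(D) || length(D) != 1L || D < 1 || D != round(D))
    stop("`D` must be a positive integer")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("`sigma` must be > 0")
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0 || rho >= 1)
    stop("`rho` must lie strictly in (0, 1)")
  if (!is.numeric(steps_per_second) || steps_per_second < 1 ||
      steps_per_second != round(steps_per_second))
    stop("`steps_per_second` must be a positive integer")
  if (!is.null(horizon) &&
      (!is.numeric(horizon) || horizon < 1 || horizon != round(horizon)))
    stop("`horizon` must be a positive integer or NULL")
  structure(
    list(kind = kind, D = as.integer(D), sigma = sigma, rho = rho,
         steps_per_second = as.integer(steps_per_second),
         horizon = if (is.null(horizon)) NULL else as.integer(horizon)),
    class = "basis_config")
}

#' @export
print.basis_config <- function(x, ...) {
  cat("<basis_config> ", x$kind, "\n", sep = "")
  if (x$kind == "microstimulus")
    cat(sprintf("  D = %d, sigma = %g, rho = %g, %d steps/s\n",
                x$D, x$sigma, x$rho, x$steps_per_second))
  else
    cat(sprintf("  horizon = %s steps, %d steps/s\n",
                if (is.null(x$horizon)) "task" else x$horizon,
                x$steps_per_second))
  invisible(x)
}

#' Stimulus trace strength
#'
#' Strength of the decaying memory trace `t` steps after stimulus onset:
#' `rho^t`. The trace is 1 at onset and 0 before the stimulus has occurred
#' (signalled by `NA` or a negative `t_since_onset`).
#'
#' @param t_since_onset Integer step count since onset; `NA` or negative
#'   values mean the stimulus has not occurred and give 0. Vectorized.
#' @param rho Per-step decay in (0, 1).
#' @return Trace strength in `[0, 1]`, same length as `t_since_onset`.
#' @examples
#' trace_strength(0, 0.985)   # 1 at onset
#' trace_strength(20, 0.985)  # one second later at 20 steps/s
#' @export
trace_strength <- function(t_since_onset, rho) {
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0 || rho >= 1)
    stop("`rho` must lie strictly in (0, 1)")
  y <- rho^t_since_onset
  y[is.na(t_since_onset) | t_since_onset < 0] <- 0
  y
}

#' Microstimulus feature block
#'
#' Evaluates the `D` Gaussian temporal receptive fields at trace strength
#' `y`: `x(d) = y * dnorm((y - d/D) / sigma)`. All entries are nonnegative,
#' bounded by `y * dnorm(0)`, and the block is identically zero when `y = 0`.
#'
#' @param y Trace strength in `[0, 1]` (see [trace_strength()]).
#' @param D Number of microstimuli.
#' @param sigma Receptive-field width, > 0.
#' @return Numeric vector of length `D` (centers `1/D, ..., 1`).
#' @examples
#' x <- microstimulus_features(1, D = 50, sigma = 0.08)
#' which.max(x)  # the center-1.0 microstimulus fires at onset
#' @export
microstimulus_features <- function(y, D, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("`sigma` must be > 0")
  if (!is.numeric(y) || length(y) != 1L || y < 0 || y > 1)
    stop("`y` must be a single value in [0, 1]")
  centers <- seq_len(D) / D
  y * dnorm((y - centers) / sigma)
}

#' Complete-serial-compound feature block
#'
#' One-hot encoding of elapsed time: entry `k` is 1 iff `t_since_onset ==
#' k - 1` and `t_since_onset < horizon`. Before onset (negative or `NA`
#' `t_since_onset`) and beyond the horizon the block is all zero.
#'
#' @param t_since_onset Integer steps since onset (scalar).
#' @param horizon Number of represented post-onset steps.
#' @return 0/1 numeric vector of length `horizon`.
#' @export
csc_features <- function(t_since_onset, horizon) {
  if (!is.numeric(horizon) || horizon < 1 || horizon != round(horizon))
    stop("`horizon` must be a positive integer")
  x <- numeric(horizon)
  if (!is.na(t_since_onset) && t_since_onset >= 0 && t_since_onset < horizon)
    x[t_since_onset + 1L] <- 1
  x
}

#' Gain profile over early vs. late microstimuli
#'
#' Models dopaminergic manipulations of the striatal ("early") microstimulus
#' channel. Microstimuli whose receptive-field center `d/D` is at or above
#' `theta` are the early ones (they fire soon after onset, while the trace is
#' still near 1) and are scaled by `gain_early`; the remainder (late, centers
#' near 0) are scaled by `gain_late`. `gain_early < 1` models D2 antagonism
#' or Parkinsonian dopamine depletion (attenuated early channel, responses
#' shifted later); `gain_early > 1` models dopamine agonists (enhanced early
#' channel, responses shifted earlier).
#'
#' @param theta Center threshold in `[0, 1]` separating early (`d/D >=
#'   theta`) from late microstimuli.
#' @param gain_early,gain_late Nonnegative multiplicative gains.
#' @return An object of class `gain_profile`.
#' @examples
#' gain_profile(gain_early = 0.5)  # D2-antagonist-like attenuation
#' @export
gain_profile <- function(theta = 0.5, gain_early = 1, gain_late = 1) {
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta > 1)
    stop("`theta` must lie in [0, 1]")
  if (!is.numeric(gain_early) || gain_early < 0 ||
      !is.numeric(gain_late) || gain_late < 0)
    stop("gains must be nonnegative")
  structure(list(theta = theta, gain_early = gain_early,
                 gain_late = gain_late), class = "gain_profile")
}

#' @export
print.gain_profile <- function(x, ...) {
  cat(sprintf("<gain_profile> early (d/D >= %g): x%g, late: x%g\n",
              x$theta, x$gain_early, x$gain_late))
  invisible(x)
}

#' Per-microstimulus gain vector
#'
#' Expands a [gain_profile()] into one multiplicative gain per microstimulus
#' of a basis: entry `d` equals `gain_early` when the receptive-field center
#' `d/D >= theta`, else `gain_late`. Defined for microstimulus bases only;
#' the early/late channel hypothesis is stated in terms of microstimuli, so
#' a CSC basis raises an error.
#'
#' @param profile A [gain_profile()].
#' @param config A microstimulus [basis_config()].
#' @return Numeric vector of length `config$D`.
#' @export
gain_vector <- function(profile, config) {
  stopifnot(inherits(profile, "gain_profile"), inherits(config, "basis_config"))
  if (config$kind != "microstimulus")
    stop("gain profiles are defined for microstimulus bases only")
  centers <- seq_len(config$D) / config$D
  ifelse(centers >= profile$theta, profile$gain_early, profile$gain_late)
}

# Resolve per-stimulus gain vectors (list with $cue, $reward) to plain
# numeric vectors of block length; NULL -> all ones.
resolve_gains <- function(gains, config, horizon) {
  block <- if (config$kind == "microstimulus") config$D else horizon
  expand <- function(g) {
    if (is.null(g)) return(rep(1, block))
    if (inherits(g, "gain_profile")) return(gain_vector(g, config))
    if (is.numeric(g) && length(g) == block) return(as.numeric(g))
    stop("gain must be NULL, a gain_profile, or a numeric vector of block length")
  }
  if (is.null(gains)) gains <- list()
  if (inherits(gains, "gain_profile")) gains <- list(cue = gains)
  list(cue = expand(gains$cue), reward = expand(gains$reward))
}

#' Assemble the full feature vector for one time step of a trial
#'
#' Concatenates the cue feature block and the reward feature block (in that
#' fixed order), each scaled entrywise by its gain vector. The reward block
#' is active from the reward-delivery step onward (rewards elicit their own
#' microstimuli). Steps before any onset give an all-zero vector.
#'
#' @param timeline A [trial_timeline()].
#' @param t Step index within the trial (0-based).
#' @param config A [basis_config()].
#' @param gains `NULL` (no manipulation), a [gain_profile()] applied to the
#'   cue block, or a list with elements `cue` and/or `reward`, each a
#'   [gain_profile()] or numeric gain vector.
#' @param reward_onset Step at which the reward was actually delivered
#'   (`NA` if not/not yet). Defaults to the timeline's scheduled
#'   `reward_step`, which is right for Pavlovian trials.
#' @return Numeric feature vector (length `2 * D` or `2 * horizon`).
#' @export
assemble_features <- function(timeline, t, config, gains = NULL,
                              reward_onset = timeline$reward_step) {
  stopifnot(inherits(timeline, "trial_timeline"), inherits(config, "basis_config"))
  if (t < 0 || t >= timeline$duration_steps)
    stop("`t` must lie within the trial duration")
  horizon <- if (config$kind == "csc") {
    if (is.null(config$horizon)) timeline$duration_steps else config$horizon
  } else config$D
  g <- resolve_gains(gains, config, horizon)
  block <- function(onset, gain) {
    dt <- if (is.na(onset)) NA_integer_ else t - onset
    if (config$kind == "microstimulus")
      microstimulus_features(trace_strength(dt, config$rho), config$D,
                             config$sigma) * gain
    else
      csc_features(dt, horizon) * gain
  }
  rew_on <- if (!is.na(reward_onset) && t >= reward_onset) reward_onset else NA_integer_
  c(block(timeline$cue_onset, g$cue), block(rew_on, g$reward))
}
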