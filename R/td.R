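#' Learner (critic) configuration
#'
#' @param alpha Learning rate, > 0.
#' @param gamma Discount factor in `[0, 1]`.
#' @param lambda Eligibility-trace decay in `[0, 1]`; `lambda = 0` gives
#'   TD(0).
#' @return An object of class `learner_config`. Defaults are the standard
#'   microstimulus-model parameterization (`alpha = 0.01`, `gamma = 0.98`,
#'   `lambda = 0.95`).
#' @export
learner_config <- function(alpha = 0.01, gamma = 0.98, lambda = 0.95) {
  if (!is.numeric(alpha) || alpha <= 0) stop("`alpha` must be > 0")
  if (!is.numeric(gamma) || gamma < 0 || gamma > 1)
    stop("`gamma` must lie in [0, 1]")
  if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
    stop("`lambda` must lie in [0, 1]")
  structure(list(alpha = alpha, gamma = gamma, lambda = lambda),
            class = "learner_config")
}

#' @export
print.learner_config <- function(x, ...) {
  cat(sprintf("<learner_config> alpha = %g, gamma = %g, lambda = %g\n",
              x$alpha, x$gamma, x$lambda))
  invisible(x)
}

#' Initialize a critic state
#'
#' Value weights and eligibility traces, both starting at zero.
#'
#' @param n_features Feature-vector length.
#' @return An object of class `critic_state` with elements `weights` and
#'   `traces`.
#' @export
critic_state <- function(n_features) {
  structure(list(weights = numeric(n_features), traces = numeric(n_features)),
            class = "critic_state")
}

#' Linear value prediction
#'
#' The estimated value of the current state is the weighted sum of its
#' features, `sum(w * x)`.
#'
#' @param state A [critic_state()].
#' @param x Feature vector.
#' @return Scalar value estimate.
#' @export
predict_value <- function(state, x) {
  if (length(state$weights) != length(x))
    stop("feature vector length does not match the critic dimension")
  sum(state$weights * x)
}

#' Temporal-difference prediction error
#'
#' `delta = r + gamma * v_next - v_curr`: the discrepancy between received
#' plus discounted-predicted reward and the current prediction; the modeled
#' correlate of phasic dopamine.
#'
#' @param r Reward at this step.
#' @param v_next Value estimate of the successor state.
#' @param v_curr Value estimate of the current state.
#' @param gamma Discount factor in `[0, 1]`.
#' @return The prediction error (scalar).
#' @export
td_error <- function(r, v_next, v_curr, gamma) {
  if (gamma < 0 || gamma > 1) stop("`gamma` must lie in [0, 1]")
  r + gamma * v_next - v_curr
}

#' Eligibility-trace update
#'
#' `e <- gamma * lambda * e + x`. With `lambda = 0` the trace reduces to the
#' current feature vector (TD(0)).
#'
#' @param state A [critic_state()].
#' @param x Feature vector at the current step.
#' @param gamma,lambda Discount and trace-decay parameters.
#' @return The updated `critic_state`.
#' @export
update_traces <- function(state, x, gamma, lambda) {
  if (length(state$traces) != length(x))
    stop("feature vector length does not match the critic dimension")
  state$traces <- gamma * lambda * state$traces + x
  state
}

#' TD weight update
#'
#' `w <- w + alpha * delta * e`, crediting each feature in proportion to its
#' eligibility.
#'
#' @param state A [critic_state()].
#' @param alpha Learning rate.
#' @param delta Prediction error for this step.
#' @param traces Eligibility traces (defaults to the state's own).
#' @return The updated `critic_state`.
#' @export
update_weights <- function(state, alpha, delta, traces = state$traces) {
  if (!is.finite(delta)) stop("non-finite prediction error")
  if (length(state$weights) != length(traces))
    stop("trace length does not match the critic dimension")
  state$weights <- state$weights + alpha * delta * traces
  state
}
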