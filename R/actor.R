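#' Actor configuration
#'
#' @param eta Actor learning rate, > 0.
#' @param actions Ordered action labels; at least two. The default
#'   `c("respond", "withhold")` fits the peak procedure; bisection tasks use
#'   `c("short", "long", "withhold")` (the *last* action is always the
#'   non-choice on choice tasks).
#' @return An object of class `actor_config`.
#' @export
actor_config <- function(eta = 0.1, actions = c("respond", "withhold")) {
  if (!is.numeric(eta) || eta <= 0) stop("`eta` must be > 0")
  if (length(actions) < 2) stop("need at least 2 actions")
  structure(list(eta = eta, actions = as.character(actions)),
            class = "actor_config")
}

#' @export
print.actor_config <- function(x, ...) {
  cat(sprintf("<actor_config> eta = %g; actions: %s\n", x$eta,
              paste(x$actions, collapse = ", ")))
  invisible(x)
}

#' Initialize a policy state
#'
#' Per-action linear preference weights `u(a, d)` over the same features as
#' the critic, starting at zero (uniform policy).
#'
#' @param n_actions Number of actions.
#' @param n_features Feature-vector length.
#' @return An object of class `policy_state` with a `preferences` matrix
#'   (`n_actions` x `n_features`).
#' @export
policy_state <- function(n_actions, n_features) {
  structure(list(preferences = matrix(0, n_actions, n_features)),
            class = "policy_state")
}

#' Softmax action probabilities
#'
#' Each action's preference is the linear form `f(a) = sum_d u(a, d) x(d)`;
#' probabilities are `softmax(f)`, computed with max-subtraction so they are
#' overflow-safe, strictly positive, and sum to 1.
#'
#' @param policy A [policy_state()].
#' @param x Feature vector.
#' @return Probability vector over actions.
#' @export
action_probabilities <- function(policy, x) {
  u <- policy$preferences
  if (ncol(u) != length(x))
    stop("feature vector length does not match the policy dimension")
  f <- drop(u %*% x)
  if (any(!is.finite(f))) stop("non-finite action preference")
  z <- exp(f - max(f))
  z / sum(z)
}

#' Sample an action
#'
#' Categorical draw from a probability vector, using R's RNG (so it is
#' reproducible under `set.seed`).
#'
#' @param probs Probability vector (must sum to 1 within 1e-6).
#' @return The sampled action index (1-based).
#' @export
sample_action <- function(probs) {
  if (abs(sum(probs) - 1) > 1e-6 || any(probs < 0))
    stop("`probs` is not a probability vector")
  u <- runif(1)
  i <- findInterval(u, cumsum(probs)) + 1L
  min(i, length(probs))
}

#' Actor preference update
#'
#' For the taken action only, `u(a, d) <- u(a, d) + eta * delta *
#' (1 - p(a)) * x(d)`: the critic's prediction error reinforces (or
#' punishes) the tendency to take that action in states resembling the
#' current one, with the `1 - p` factor saturating updates for already
#' near-certain actions. For one-hot features this reduces to the tabular
#' rule `f <- f + eta * delta * (1 - p)`.
#'
#' @param policy A [policy_state()].
#' @param action Index (1-based) of the taken action.
#' @param prob_taken Its probability at selection time, in `(0, 1]`.
#' @param delta Prediction error.
#' @param x Feature vector at selection time.
#' @param eta Actor learning rate.
#' @return The updated `policy_state`.
#' @export
update_policy <- function(policy, action, prob_taken, delta, x, eta) {
  if (prob_taken <= 0 || prob_taken > 1)
    stop("`prob_taken` must lie in (0, 1]")
  if (ncol(policy$preferences) != length(x))
    stop("feature vector length does not match the policy dimension")
  policy$preferences[action, ] <- policy$preferences[action, ] +
    eta * delta * (1 - prob_taken) * x
  policy
}
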