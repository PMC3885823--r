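# Independently coded TD(lambda) reference session, built only from the
# exported per-step primitives. Used to cross-check the compiled engine.
reference_pavlovian <- function(task, basis, learner) {
  tl <- task[[1]]
  M <- length(assemble_features(tl, 0, basis))
  critic <- critic_state(M)
  steps <- list()
  for (tr in seq_along(task)) {
    tl <- task[[tr]]
    critic$traces <- numeric(M)
    for (t in seq.int(0, tl$duration_steps - 1L)) {
      x <- assemble_features(tl, t, basis)
      v <- predict_value(critic, x)
      v_next <- if (t + 1L < tl$duration_steps)
        predict_value(critic, assemble_features(tl, t + 1L, basis)) else 0
      r <- if (!is.na(tl$reward_step) && t == tl$reward_step)
        tl$reward_magnitude else 0
      delta <- td_error(r, v_next, v, learner$gamma)
      critic <- update_traces(critic, x, learner$gamma, learner$lambda)
      critic <- update_weights(critic, learner$alpha, delta)
      steps[[length(steps) + 1L]] <-
        data.frame(trial = tr, step = t, value = v, delta = delta, reward = r)
    }
  }
  list(steps = do.call(rbind, steps), critic = critic)
}

# Microstimulus time course of one receptive field over a step horizon.
ms_time_course <- function(d, D = 50, sigma = 0.08, rho = 0.985,
                           horizon = 2000) {
  y <- trace_strength(seq.int(0, horizon - 1L), rho)
  y * dnorm((y - d / D) / sigma)
}
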