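test_that("value prediction and TD error follow their defining forms", {
  st <- critic_state(2)
  expect_identical(predict_value(st, c(0.3, 9)), 0)
  st$weights <- c(1, 2)
  expect_identical(predict_value(st, c(0.5, 0.25)), 1)
  expect_error(predict_value(st, c(1, 2, 3)), "dimension")

  expect_identical(td_error(1, 0, 0, 0.98), 1)
  expect_equal(td_error(0, 1, 0.98, 0.98), 0)
  expect_identical(td_error(0, 0, 1, 0.98), -1)
})

test_that("trace and weight updates implement TD(lambda) exactly", {
  st <- critic_state(2)
  # lambda = 0 reduces the trace to the current features
  st$traces <- c(5, 5)
  st <- update_traces(st, c(0.2, 0.4), gamma = 0.98, lambda = 0)
  expect_identical(st$traces, c(0.2, 0.4))
  # gamma * lambda decay
  st$traces <- c(1, 1)
  st <- update_traces(st, c(0, 0), gamma = 0.98, lambda = 0.95)
  expect_equal(st$traces, c(0.931, 0.931))

  st <- critic_state(2)
  st$traces <- c(1, 0)
  st <- update_weights(st, alpha = 0.01, delta = 1)
  expect_identical(st$weights, c(0.01, 0))
  st2 <- update_weights(st, 0.01, 0)
  expect_identical(st2$weights, st$weights)
  # linearity: two updates equal one update of the summed delta
  a <- update_weights(update_weights(critic_state(1), 0.1, 2, traces = 1),
                      0.1, 3, traces = 1)
  b <- update_weights(critic_state(1), 0.1, 5, traces = 1)
  expect_equal(a$weights, b$weights)
  expect_error(update_weights(st, 0.01, NaN), "finite")
})

test_that("the compiled session engine matches the R reference step for step", {
  task <- make_pavlovian_task(1, n_trials = 15)
  for (lam in c(0, 0.95)) {
    for (kind in c("microstimulus", "csc")) {
      basis <- if (kind == "csc")
        basis_config("csc", horizon = task[[1]]$duration_steps)
      else basis_config(D = 10, sigma = 0.1)
      learner <- learner_config(alpha = 0.05, gamma = 0.98, lambda = lam)
      eng <- run_pavlovian_session(task, basis, learner, record = "all")
      ref <- reference_pavlovian(task, basis, learner)
      expect_equal(eng$steps$value, ref$steps$value, tolerance = 1e-12)
      expect_equal(eng$steps$delta, ref$steps$delta, tolerance = 1e-12)
      expect_equal(eng$critic$weights, ref$critic$weights, tolerance = 1e-12)
    }
  }
})

test_that("a zero-trial task is rejected and weights persist across trials", {
  empty <- structure(list(), class = "timing_task",
                     steps_per_second = 20L, iti_steps = 500L)
  expect_error(run_pavlovian_session(empty, basis_config(), learner_config()),
               "no trials")
  task1 <- make_pavlovian_task(1, 1)
  task <- make_pavlovian_task(1, 2)
  s1 <- run_pavlovian_session(task1, basis_config(), learner_config())
  s2 <- run_pavlovian_session(task, basis_config(), learner_config())
  # second trial starts from the first trial's weights, so deltas differ
  expect_false(isTRUE(all.equal(s2$trials$reward_delta[2],
                                s2$trials$reward_delta[1])))
  expect_equal(s2$trials$reward_delta[1], s1$trials$reward_delta[1])
})

test_that("CSC values converge to the discounted closed form on a fixed interval", {
  task <- make_pavlovian_task(2, 500)
  basis <- basis_config("csc", horizon = task[[1]]$duration_steps)
  s <- run_pavlovian_session(task, basis, learner_config(alpha = 0.1),
                             record = "none")
  tl <- task[[1]]
  vc <- value_curve(s$critic, tl, basis)
  idx <- vc$step >= tl$cue_onset & vc$step <= tl$reward_step
  target <- 0.98^(tl$reward_step - vc$step[idx])
  expect_lt(max(abs(vc$value[idx] - target)), 0.01)
  expect_lt(abs(tail(s$trials$reward_delta, 1)), 0.01)
})

test_that("cue-onset prediction error falls with the interval after training", {
  pe <- run_interval_pe_experiment(c(1, 4, 16), n_trials = 100)
  expect_true(all(diff(pe$cue_delta) < 0))
  expect_true(all(diff(pe$reward_delta) > 0))
})

test_that("long simulations stay finite at the standard parameters", {
  s <- run_pavlovian_session(make_pavlovian_task(16, 100), basis_config(),
                             learner_config(), record = "all")
  expect_true(all(is.finite(s$steps$value)))
  expect_true(all(is.finite(s$steps$delta)))
  expect_true(all(is.finite(s$critic$weights)))
})
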