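test_that("softmax action probabilities are normalized and shift-invariant", {
  pol <- policy_state(2, 3)
  expect_equal(action_probabilities(pol, c(1, 1, 1)), c(0.5, 0.5))
  # hand-computed two-action softmax at preferences (1, 0)
  pol$preferences[1, 1] <- 1
  p <- action_probabilities(pol, c(1, 0, 0))
  expect_equal(p, c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # adding a constant to every action's preference changes nothing
  pol2 <- pol
  pol2$preferences <- pol$preferences + 7
  expect_equal(action_probabilities(pol2, c(1, 0, 0)), p, tolerance = 1e-12)
  # overflow guard
  pol$preferences[1, 1] <- 2000
  expect_equal(action_probabilities(pol, c(1, 0, 0)), c(1, 0))
  pol$preferences[1, 1] <- NaN
  expect_error(action_probabilities(pol, c(1, 0, 0)), "finite")
})

test_that("action sampling is categorical, seeded, and frequency-consistent", {
  expect_identical(sample_action(c(1, 0)), 1L)
  expect_identical(sample_action(c(0, 1)), 2L)
  set.seed(11)
  draws <- replicate(1e4, sample_action(c(0.5, 0.5)))
  expect_lt(abs(mean(draws == 1) - 0.5), 3 * sqrt(0.25 / 1e4))
  set.seed(42); a <- replicate(50, sample_action(c(0.3, 0.3, 0.4)))
  set.seed(42); b <- replicate(50, sample_action(c(0.3, 0.3, 0.4)))
  expect_identical(a, b)
  expect_error(sample_action(c(0.5, 0.1)), "probability")
})

test_that("policy updates credit only the taken action", {
  pol <- policy_state(2, 2)
  x <- c(1, 0)
  expect_identical(update_policy(pol, 1, 0.5, 0, x, 0.1)$preferences,
                   pol$preferences)
  expect_identical(update_policy(pol, 1, 1, 5, x, 0.1)$preferences,
                   pol$preferences)   # saturated: 1 - p factor vanishes
  up <- update_policy(pol, 1, 0.5, 1, x, 0.1)
  expect_equal(up$preferences[1, ], c(0.05, 0))
  expect_identical(up$preferences[2, ], c(0, 0))
  expect_error(update_policy(pol, 1, 0, 1, x, 0.1), "prob_taken")
})

test_that("instrumental sessions are reproducible and probe trials unrewarded", {
  task <- make_peak_task(2, 60, probe_fraction = 0.25, seed = 5)
  basis <- basis_config(rho = trace_decay_for_interval(40))
  s1 <- run_instrumental_session(task, basis, learner_config(),
                                 actor_config(), record = "all", seed = 9)
  s2 <- run_instrumental_session(task, basis, learner_config(),
                                 actor_config(), record = "all", seed = 9)
  expect_identical(s1$steps, s2$steps)
  expect_identical(s1$policy$preferences, s2$policy$preferences)
  probes <- s1$trials$trial_type == "peak_probe"
  expect_true(all(is.na(s1$trials$reward_step[probes])))
  expect_true(all(s1$steps$reward[s1$steps$trial_type == "peak_probe"] == 0))
  # reinforced trials only deliver reward at or after the FI
  fi_step <- attr(task, "meta")$fi_step
  got <- s1$trials$reward_step[!probes]
  expect_true(all(is.na(got) | got >= fi_step))
  # an empty action log is an error for response_curve
  s3 <- run_instrumental_session(task, basis, learner_config(),
                                 actor_config(), record = "none", seed = 1)
  expect_error(response_curve(s3), "no recorded action")
})

test_that("peak responding spreads with the interval (scalar property)", {
  p20 <- run_peak_experiment(20, n_trials = 800, seed = 2)
  p40 <- run_peak_experiment(40, n_trials = 800, seed = 2)
  expect_gt(p40$stats$spread_s, p20$stats$spread_s)
  expect_gt(p40$stats$peak_time_s, p20$stats$peak_time_s)
})

test_that("bisection choices favor 'long' more often for longer probes", {
  b <- run_bisection_experiment(2, 8, n_trials = 1200, seed = 4)
  tab <- b$psychometric$table
  expect_gt(tab$p_long[nrow(tab)], tab$p_long[1])
  expect_true(all(tab$p_long >= 0 & tab$p_long <= 1))
})
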