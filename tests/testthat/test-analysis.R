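test_that("response curves are empirical frequencies with binomial error", {
  # frozen uniform policy: p(respond) = 0.5 everywhere
  task <- make_peak_task(2, 80, probe_fraction = 1, seed = 6)
  s <- run_instrumental_session(task, basis_config(), learner_config(),
                                actor_config(), learn = FALSE,
                                record = "probe", seed = 8)
  cv <- response_curve(s, bin_s = 1)
  expect_true(all(cv$rate >= 0 & cv$rate <= 1))
  expect_true(all(abs(cv$rate - 0.5) < 3 * sqrt(0.25 / cv$n_obs)))
  # total responses are conserved between log and curve
  expect_identical(sum(cv$rate * cv$n_obs),
                   as.numeric(sum(s$steps$action == "respond", na.rm = TRUE)))
  expect_error(response_curve(s, trial_types = "bisection_probe"),
               "no matching")
})

test_that("peak statistics recover known Gaussian curve parameters", {
  t <- seq(0.5, 59.5, by = 1)
  mk <- function(m, s, b = 0.1, a = 0.6) b + a * exp(-(t - m)^2 / (2 * s^2))
  curve <- data.frame(bin_center_s = t, rate = mk(20, 5))
  st <- peak_statistics(curve)
  expect_equal(st$peak_time_s, 20, tolerance = 0.05)
  expect_equal(st$spread_s, 5, tolerance = 0.05)
  expect_gt(st$fit_quality, 0.999)
  # time-stretched curve doubles the fitted spread
  t2 <- seq(1, 119, by = 2)
  curve2 <- data.frame(bin_center_s = t2,
                       rate = 0.1 + 0.6 * exp(-(t2 - 40)^2 / (2 * 10^2)))
  st2 <- peak_statistics(curve2)
  expect_equal(st2$spread_s, 10, tolerance = 0.1)
  # constant baseline shift leaves the peak time unchanged
  curve3 <- data.frame(bin_center_s = t, rate = mk(20, 5, b = 0.4))
  expect_equal(peak_statistics(curve3)$peak_time_s, st$peak_time_s,
               tolerance = 0.05)
  # noisy curve: recovery within 5%
  set.seed(2)
  curve4 <- data.frame(bin_center_s = t,
                       rate = pmin(1, pmax(0, mk(22, 6) + rnorm(60, 0, 0.02))))
  expect_lt(abs(peak_statistics(curve4)$peak_time_s - 22) / 22, 0.05)
  expect_error(peak_statistics(data.frame(bin_center_s = t, rate = t * 0)),
               "all-zero")
})

fake_bisection_session <- function(durations, p_long, n_per = 50) {
  trials <- do.call(rbind, lapply(seq_along(durations), function(i) {
    ch <- rep(c("long", "short"),
              c(round(p_long[i] * n_per), n_per - round(p_long[i] * n_per)))
    data.frame(trial_type = "bisection_probe", choice = ch)
  }))
  trials$trial <- seq_len(nrow(trials))
  structure(list(trials = trials,
                 task_meta = list(duration_s = rep(durations, each = n_per))),
            class = "session_result")
}

test_that("psychometric indifference interpolates in log duration", {
  dur <- 2 * 2^(0:3)   # 2, 4, 8, 16
  s <- fake_bisection_session(dur, c(0, 0, 1, 1))
  ps <- psychometric(s)
  expect_equal(ps$table$p_long, c(0, 0, 1, 1))
  expect_equal(ps$indifference_s, sqrt(4 * 8), tolerance = 1e-9)
  # all-long responding: no crossing, no extrapolation
  expect_true(is.na(psychometric(
    fake_bisection_session(dur, c(1, 1, 1, 1)))$indifference_s))
  # exact 0.5 duration is taken as the indifference point
  ps2 <- psychometric(fake_bisection_session(dur, c(0, 0.5, 1, 1)))
  expect_equal(ps2$indifference_s, 4, tolerance = 1e-9)
})

test_that("event PE summary reads the untrained and trained signatures", {
  task <- make_pavlovian_task(2, 1)
  s0 <- run_pavlovian_session(task, basis_config(), learner_config(),
                              learn = FALSE, record = "none")
  pe0 <- event_pe_summary(s0)
  expect_identical(pe0$reward_delta, 1)   # naive model: full surprise
  expect_identical(pe0$cue_delta, 0)
  expect_error(event_pe_summary(s0, k_last = 5), "k_last")
  s <- run_pavlovian_session(make_pavlovian_task(2, 200), basis_config(),
                             learner_config(), record = "none")
  pe <- event_pe_summary(s)
  expect_lt(pe$reward_delta, 1)
  expect_gt(pe$cue_delta, 0)
})
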