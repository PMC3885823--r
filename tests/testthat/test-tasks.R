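test_that("Pavlovian tasks place the reward exactly one interval after the cue", {
  task <- make_pavlovian_task(1, 100)
  expect_length(task, 100)
  tl <- task[[1]]
  expect_identical(tl$reward_step - tl$cue_onset, 20L)
  expect_identical(make_pavlovian_task(16, 1)[[1]]$reward_step -
                     make_pavlovian_task(16, 1)[[1]]$cue_onset, 320L)
  # events strictly inside the trial
  expect_lt(tl$reward_step, tl$duration_steps)
  expect_error(make_pavlovian_task(0.01, 1), "zero steps")
  expect_error(make_pavlovian_task(-1, 1), "interval_s")
})

test_that("probe trials modify the schedule as requested", {
  base <- make_pavlovian_task(2, 1)[[1]]
  om <- make_probe_trial(base, "probe_omission")
  expect_true(is.na(om$reward_step))
  expect_identical(om$duration_steps, base$duration_steps)
  ey0 <- make_probe_trial(base, "probe_early", shift_s = 0)
  expect_identical(ey0$reward_step, base$reward_step)
  ey <- make_probe_trial(base, "probe_early", shift_s = 1)
  expect_identical(ey$reward_step, base$reward_step - 20L)
  ext <- make_probe_trial(base, "probe_extended", extend_s = 3)
  expect_true(is.na(ext$reward_step))
  expect_identical(ext$duration_steps, base$duration_steps + 60L)
  expect_error(make_probe_trial(base, "probe_early", shift_s = 2), "after cue")
})

test_that("peak tasks interleave probes reproducibly at the requested fraction", {
  t1 <- make_peak_task(20, 200, probe_fraction = 0.25, seed = 3)
  t2 <- make_peak_task(20, 200, probe_fraction = 0.25, seed = 3)
  expect_identical(task_trial_types <- vapply(t1, `[[`, "", "trial_type"),
                   vapply(t2, `[[`, "", "trial_type"))
  expect_identical(sum(task_trial_types == "peak_probe"), 50L)
  expect_true(any(task_trial_types != sort(task_trial_types)))  # shuffled
  # probe duration = probe_multiple x FI
  probe <- t1[[which(task_trial_types == "peak_probe")[1]]]
  expect_identical(probe$duration_steps, 1L + 3L * 400L)
  expect_true(is.na(probe$reward_step))
  all_fi <- make_peak_task(5, 10, probe_fraction = 0, seed = 1)
  expect_true(all(vapply(all_fi, `[[`, "", "trial_type") == "peak_fi"))
  all_pr <- make_peak_task(5, 10, probe_fraction = 1, seed = 1)
  expect_true(all(vapply(all_pr, `[[`, "", "trial_type") == "peak_probe"))
})

test_that("bisection tasks use geometric probe spacing inside the anchors", {
  task <- make_bisection_task(2, 8, n_probe_durations = 5, n_trials = 100,
                              seed = 2)
  meta <- attr(task, "meta")
  pr <- meta$probe_durations_s
  expect_length(pr, 5)
  expect_true(all(pr > 2 & pr < 8))
  # geometric spacing: constant ratio, symmetric about the geometric mean 4
  expect_equal(diff(log(pr)), rep(diff(log(pr))[1], 4), tolerance = 1e-12)
  expect_equal(pr[3], 4, tolerance = 1e-12)
  # all trials open a choice window after cue offset
  for (tr in task) {
    expect_false(is.na(tr$choice_open))
    expect_gt(tr$choice_open, tr$cue_onset)
  }
  # probes carry no reward contingency
  probes <- vapply(task, `[[`, "", "trial_type") == "bisection_probe"
  expect_true(all(vapply(task[probes], function(x) is.na(x$correct_action),
                         TRUE)))
  anchors_only <- make_bisection_task(2, 8, n_probe_durations = 0,
                                      n_trials = 10, seed = 1)
  expect_true(all(vapply(anchors_only, `[[`, "", "trial_type") ==
                    "bisection_train"))
  expect_error(make_bisection_task(8, 2, n_trials = 10), "short_s < long_s")
})

test_that("timelines validate their event ordering", {
  expect_error(trial_timeline(10, cue_onset = 0), "cue_onset")
  expect_error(trial_timeline(10, reward_step = 12), "strictly between")
  expect_error(trial_timeline(10, reward_step = 5,
                              trial_type = "probe_omission"), "cannot carry")
})
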