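test_that("trace strength is 1 at onset and decays geometrically", {
  expect_identical(trace_strength(0, 0.985), 1)
  expect_identical(trace_strength(1, 0.985), 0.985)
  # closed-form power agrees with repeated multiplication
  expect_equal(trace_strength(20, 0.985), Reduce(`*`, rep(0.985, 20)),
               tolerance = 1e-15)
  # absent onset / pre-onset sentinel gives zero
  expect_identical(trace_strength(NA, 0.985), 0)
  expect_identical(trace_strength(-3, 0.985), 0)
  y <- trace_strength(0:500, 0.5 + runif(1) * 0.49)
  expect_true(all(diff(y) < 0))
  expect_error(trace_strength(1, 1.0), "rho")
  expect_error(trace_strength(1, 0), "rho")
})

test_that("microstimulus features follow the Gaussian receptive-field form", {
  # at onset (y = 1) the center-1 field fires at the standard normal mode
  x <- microstimulus_features(1, D = 50, sigma = 0.08)
  expect_equal(x[50], 1 / sqrt(2 * pi), tolerance = 1e-12)
  # far-from-center suppression: center 0.5 is 6.25 widths away
  expect_equal(x[25], exp(-6.25^2 / 2) / sqrt(2 * pi), tolerance = 1e-12)
  expect_lt(x[25], 2e-9)
  # zero trace silences the whole block
  expect_identical(microstimulus_features(0, 50, 0.08), numeric(50) * 0 +
                     microstimulus_features(0, 50, 0.08))
  expect_true(all(microstimulus_features(0, 50, 0.08) == 0))
  # all entries nonnegative and bounded by the Gaussian mode
  for (y in c(0.1, 0.33, 0.7, 1)) {
    x <- microstimulus_features(y, 50, 0.08)
    expect_true(all(x >= 0))
    expect_true(all(x <= dnorm(0) + 1e-12))
  }
  expect_error(microstimulus_features(1, 50, -1), "sigma")
})

test_that("CSC features are a one-hot clock with bounded horizon", {
  expect_identical(csc_features(0, 5), c(1, 0, 0, 0, 0))
  expect_identical(csc_features(3, 5), c(0, 0, 0, 1, 0))
  expect_identical(csc_features(7, 5), numeric(5))
  expect_identical(csc_features(NA, 5), numeric(5))
  expect_identical(csc_features(-1, 5), numeric(5))
})

test_that("microstimulus time courses are unimodal and later ones disperse more", {
  fwhm <- function(v) {
    half <- max(v) / 2
    idx <- range(which(v >= half))
    idx[2] - idx[1]
  }
  widths <- numeric(0)
  for (d in c(40, 20, 10, 5, 2)) {   # decreasing center = later peak
    v <- ms_time_course(d, horizon = 2000)
    peak <- which.max(v)
    expect_true(all(diff(v[seq_len(peak)]) >= 0))
    expect_true(all(diff(v[seq.int(peak, length(v))]) <= 0))
    # peak occurs where the trace lies within one field width of the center
    y <- trace_strength(0:1999, 0.985)
    expect_lt(abs(y[peak] - d / 50), 0.08)
    widths <- c(widths, fwhm(v))
  }
  expect_true(all(diff(widths) > 0))
})

test_that("gain vectors split early and late microstimuli at the center threshold", {
  cfg <- basis_config(D = 4)
  # centers {0.25, 0.5, 0.75, 1}; d/D >= theta is the early (striatal) side
  expect_identical(gain_vector(gain_profile(0.5, 0.5, 1), cfg),
                   c(1, 0.5, 0.5, 0.5))
  cfg2 <- basis_config(D = 2)
  expect_identical(gain_vector(gain_profile(1.0, 2, 1), cfg2), c(1, 2))
  expect_identical(gain_vector(gain_profile(), basis_config(D = 7)), rep(1, 7))
  expect_error(gain_profile(gain_early = -1), "nonnegative")
  expect_error(gain_vector(gain_profile(), basis_config("csc", horizon = 10)),
               "microstimulus")
})

test_that("assembled features concatenate cue and reward blocks correctly", {
  tl <- trial_timeline(60, cue_onset = 1, reward_step = 41)
  ms <- basis_config()
  # before any onset: all zero
  expect_identical(assemble_features(tl, 0, ms), numeric(100))
  # at cue onset the cue block equals the onset microstimuli, reward silent
  x <- assemble_features(tl, 1, ms)
  expect_equal(x[1:50], microstimulus_features(1, 50, 0.08))
  expect_identical(x[51:100], numeric(50))
  # at the reward step both blocks are active with their own traces
  x <- assemble_features(tl, 45, ms)
  expect_equal(x[1:50],
               microstimulus_features(trace_strength(44, 0.985), 50, 0.08))
  expect_equal(x[51:100],
               microstimulus_features(trace_strength(4, 0.985), 50, 0.08))
  # CSC: one-hot at position 1 of the cue block at onset
  csc <- basis_config("csc", horizon = 60)
  expect_identical(assemble_features(tl, 1, csc)[1], 1)
  expect_identical(sum(assemble_features(tl, 1, csc)), 1)
  # unit gains leave the features bit-identical
  g1 <- list(cue = gain_profile(0.5, 1, 1), reward = gain_profile(0.5, 1, 1))
  for (t in c(0, 1, 20, 41, 59))
    expect_identical(assemble_features(tl, t, ms, gains = g1),
                     assemble_features(tl, t, ms))
  # attenuation scales exactly the early-center entries
  ga <- list(cue = gain_profile(0.5, 0.25, 1))
  x0 <- assemble_features(tl, 5, ms)
  xa <- assemble_features(tl, 5, ms, gains = ga)
  centers <- (1:50) / 50
  expect_equal(xa[1:50], x0[1:50] * ifelse(centers >= 0.5, 0.25, 1))
  expect_identical(xa[51:100], x0[51:100])
  expect_error(assemble_features(tl, 60, ms), "duration")
})

test_that("basis and profile constructors validate their invariants", {
  expect_error(basis_config(sigma = 0), "sigma")
  expect_error(basis_config(rho = 1), "rho")
  expect_error(basis_config(D = 0), "D")
  expect_error(gain_profile(theta = 2), "theta")
  expect_equal(trace_decay_for_interval(66), 0.98496, tolerance = 1e-4)
})
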