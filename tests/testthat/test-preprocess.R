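test_that("median filter matches the brute-force sliding-window oracle", {
  set.seed(42)
  for (w in c(3, 5, 8)) {
    x <- rnorm(200)
    expect_equal(median_filter(x, w), oracle_median_filter(x, w))
  }
})

test_that("median filter removes isolated spikes and preserves constants", {
  expect_equal(median_filter(rep(3.5, 50), 8), rep(3.5, 50))
  expect_equal(median_filter(c(0, 0, 0, 10, 0, 0, 0), 3), rep(0, 7))
})

test_that("median filter output is bounded and idempotent on monotone series", {
  set.seed(7)
  x <- rnorm(300)
  y <- median_filter(x, 8)
  expect_true(all(y >= min(x) & y <= max(x)))
  mono <- sort(rnorm(100))
  once <- median_filter(mono, 5)
  expect_equal(median_filter(once, 5), once)
})

test_that("cubic resampling is exact on polynomials up to degree 3", {
  t <- seq(0, 2, by = 1 / 30)
  for (f in list(function(z) 2 * z + 1, function(z) z^3 - z^2 + 0.5)) {
    rs <- resample_cubic(f(t), t, 50)
    expect_lt(max(abs(rs$x - f(rs$timestamps))), 1e-9)
  }
})

test_that("resampling preserves endpoints and is the identity at shared knots", {
  t <- seq(0, 1, by = 1 / 50)
  x <- sin(2 * pi * t)
  rs <- resample_cubic(x, t, 50)
  expect_equal(rs$timestamps[1], t[1])
  expect_equal(rs$timestamps[length(rs$timestamps)], t[length(t)])
  expect_equal(rs$x, x, tolerance = 1e-12)
})

test_that("a 1 Hz sine resampled 30 -> 50 Hz tracks the analytic sine", {
  t <- seq(0, 3, by = 1 / 30)
  rs <- resample_cubic(sin(2 * pi * t), t, 50)
  expect_lt(max(abs(rs$x - sin(2 * pi * rs$timestamps))), 1e-4)
})

test_that("resampling excludes flagged samples and needs 4 finite points", {
  t <- seq(0, 1, by = 1 / 30)
  x <- 2 * t + 1
  x[10] <- NaN
  rs <- resample_cubic(x, t, 50)
  expect_lt(max(abs(rs$x - (2 * rs$timestamps + 1))), 1e-9)
  expect_error(resample_cubic(c(1, NA, NA, 2, NA), 1:5, 50), "4 finite")
})

test_that("Butterworth stage has exact unity DC gain", {
  x <- rep(2.37, 120)
  expect_equal(butterworth_lowpass(x, 50), x, tolerance = 1e-12)
  expect_equal(butterworth_lowpass(x, 50, zero_phase = FALSE), x,
               tolerance = 1e-12)
})

test_that("Butterworth attenuation matches the analytic digital response", {
  rate <- 50
  t <- seq(0, 20, by = 1 / rate)
  mid <- seq(200, length(t) - 200)
  for (zp in c(TRUE, FALSE)) {
    y <- butterworth_lowpass(sin(2 * pi * 15 * t), rate, zero_phase = zp)
    amp <- tone_amplitude(y[mid], rate, 15)
    expect_equal(amp, butterworth_gain(15, rate, zero_phase = zp),
                 tolerance = 0.02)
  }
  # passband: 2 Hz essentially untouched
  y2 <- butterworth_lowpass(sin(2 * pi * 2 * t), rate)
  expect_gte(tone_amplitude(y2[mid], rate, 2), 0.99)
})

test_that("zero-phase filtering introduces no lag", {
  rate <- 50
  t <- seq(0, 10, by = 1 / rate)
  x <- sin(2 * pi * 1.5 * t)
  y <- butterworth_lowpass(x, rate)
  cc <- stats::ccf(y, x, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("cutoff at or above Nyquist is rejected", {
  expect_error(butterworth_lowpass(rnorm(100), 50, cutoff = 25), "Nyquist")
  expect_error(preprocess_config(butter_cutoff = 30), "butter_cutoff")
})

test_that("full chain recovers noise-free ROM within 0.5 degrees", {
  tr <- simulate_trial(motion_spec("PIANO", duration = 20), noise_free(),
                       seed = 2)
  pp <- preprocess_trajectory(tr)
  jt <- default_joint_table()
  s <- joint_angle_series(pp$trajectory,
                          as.list(jt[jt$name == "ARM_ANG_L", ]))
  truth_rom <- diff(range(tr$ground_truth$ARM_ANG_L))
  expect_lt(abs(range_of_motion(s) - truth_rom), 0.5)
})

test_that("full chain suppresses injected 12 Hz tremor power by >= 95%", {
  ns <- noise_spec(jitter_sd = 0, spike_rate = 0, tremor_amp = 0.01,
                   tremor_freq = 12)
  tr <- simulate_trial(motion_spec("GYM_LATERAL", duration = 20,
                                   mode = "SIM"),
                       ns, seed = 8)
  wrist <- match("left_wrist", pose_landmark_names())
  raw <- tr$trajectory$positions[, wrist, 1]
  amp_before <- tone_amplitude(raw, 30, 12)
  pp <- preprocess_trajectory(tr)
  amp_after <- tone_amplitude(pp$trajectory$positions[, wrist, 1],
                              pp$trajectory$nominal_fps, 12)
  expect_lt(amp_after^2 / amp_before^2, 0.05)
})

test_that("constant posture with spikes comes out constant", {
  m <- motion_spec("PIANO", amplitude = 0, duration = 10)
  tr <- simulate_trial(m, noise_spec(jitter_sd = 0, spike_rate = 1,
                                     spike_magnitude = 0.3, tremor_amp = 0),
                       seed = 4)
  pp <- preprocess_trajectory(tr)
  jt <- default_joint_table()
  s <- joint_angle_series(pp$trajectory,
                          as.list(jt[jt$name == "ARM_ANG_L", ]))
  expect_lt(diff(range(s)), 0.2)
})

test_that("preprocessing replaces timestamps but leaves events untouched", {
  tr <- make_random_trial(31, duration = 5)
  pp <- preprocess_trajectory(tr)
  expect_equal(pp$trajectory$nominal_fps, 50)
  expect_equal(pp$events, tr$events)
  expect_equal(length(pp$trajectory$flagged), 0)
  dt <- diff(pp$trajectory$timestamps)
  expect_lt(diff(range(dt)), 1e-12)
})
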