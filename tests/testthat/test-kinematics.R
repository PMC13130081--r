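test_that("segment_angle reproduces closed-form angles", {
  expect_equal(segment_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(segment_angle(c(2, 0, 0), c(5, 0, 0)), 0)
  expect_equal(segment_angle(c(1, 0, 0), c(1, 1, 0)), 45)
  expect_error(segment_angle(c(0, 0, 0), c(1, 0, 0)), "non-zero")
})

test_that("segment_angle is symmetric, scale-invariant, and in [0, 180]", {
  set.seed(12)
  for (k in 1:25) {
    v1 <- rnorm(3)
    v2 <- rnorm(3)
    a <- segment_angle(v1, v2)
    expect_equal(a, segment_angle(v2, v1))
    expect_equal(a, segment_angle(3.7 * v1, 0.2 * v2))
    expect_gte(a, 0)
    expect_lte(a, 180)
  }
})

test_that("symmetry index follows its definition and invariances", {
  expect_equal(symmetry_index(2, 2), 0)
  expect_equal(symmetry_index(3, 2), 0.5)
  set.seed(3)
  for (k in 1:20) {
    pr <- runif(1, 0.1, 5)
    pl <- runif(1, 0.1, 5)
    a <- runif(1, 0.1, 10)
    expect_equal(symmetry_index(a * pr, a * pl), symmetry_index(pr, pl))
    expect_equal(symmetry_index(pr, pr), 0)
  }
  expect_error(symmetry_index(1, 0), "zero")
})

test_that("joint angle series recover simulator ground truth exactly when noise-free", {
  jt <- default_joint_table()
  tr <- simulate_trial(motion_spec("GYM_LATERAL", duration = 8,
                                   asymmetry_ratio = 1.3, mode = "ALT"),
                       noise_free(), seed = 6)
  for (side in c("R", "L")) {
    s <- joint_angle_series(tr$trajectory,
                            as.list(jt[jt$name == paste0("ARM_ANG_", side), ]))
    expect_lt(max(abs(s - tr$ground_truth[[paste0("ARM_ANG_", side)]])), 1e-6)
  }
  ski <- simulate_trial(motion_spec("SKI", duration = 8), noise_free(),
                        seed = 6)
  for (nm in c("KNEE_ANG_R", "KNEE_ANG_L", "LEG_ANG_R", "LEG_ANG_L")) {
    s <- joint_angle_series(ski$trajectory, as.list(jt[jt$name == nm, ]))
    expect_lt(max(abs(s - ski$ground_truth[[nm]])), 1e-6)
  }
})

test_that("an upright trunk gives a zero trunk angle", {
  tr <- simulate_trial(motion_spec("PIANO", duration = 4), noise_free(),
                       seed = 1)
  jt <- default_joint_table()
  s <- joint_angle_series(tr$trajectory, as.list(jt[jt$name == "T_ANG", ]))
  expect_lt(max(abs(s)), 1e-8)
})

test_that("range_of_motion follows its definition", {
  expect_equal(range_of_motion(rep(42, 10)), 0)
  s <- c(30, 60, 120, 80, 30)
  expect_equal(range_of_motion(s), 90)
  expect_error(range_of_motion(numeric()), "empty")
})

test_that("angular velocity matches exact derivatives", {
  expect_equal(angular_velocity(rep(5, 10), 50), rep(0, 10))
  t <- seq(0, 2, by = 1 / 50)
  ramp <- 30 * t
  v <- angular_velocity(ramp, 50)
  expect_equal(v[2:(length(v) - 1)], rep(30, length(v) - 2))
  x <- 40 * sin(2 * pi * 0.5 * t)
  vmax <- max(abs(angular_velocity(x, 50)))
  expect_lt(abs(vmax - 2 * pi * 0.5 * 40) / (2 * pi * 0.5 * 40), 0.02)
  expect_error(angular_velocity(c(1, 2), 50), "3 samples")
})

test_that("repetition peaks respect prominence and separation", {
  t <- seq(0, 10, by = 0.02)
  x <- 45 + 30 * sin(2 * pi * 0.5 * t)
  pk <- find_repetition_peaks(x, 50)
  expect_equal(length(pk), 5)
  # sub-prominence wiggles are ignored
  x2 <- x + 2 * sin(2 * pi * 3 * t)
  expect_equal(length(find_repetition_peaks(x2, 50)), 5)
  expect_equal(length(find_repetition_peaks(rep(10, 100), 50)), 0)
})

test_that("each exergame profile yields exactly its reported column set", {
  cols <- list(
    AIRPLANE = c("ARM_ANG", "ELB_ANG", "ARM_SI", "ELB_SI", "T_ANG"),
    SKI = c("LEG_ANG", "KNEE_ANG", "LEG_SI", "KNEE_SI", "T_ANG"),
    PIANO = c("ARM_ANG", "T_ANG"),
    GYM_FRONTAL = c("ROM_ANG", "ARM_VEL", "ANG_SI", "VEL_SI")
  )
  for (game in names(cols)) {
    m <- motion_spec(game, duration = 6)
    tr <- simulate_trial(m, noise_free(), seed = 2)
    mfp <- extract_mfp(preprocess_trajectory(tr))
    expect_identical(names(mfp), cols[[game]])
    expect_true(all(mfp[grepl("_SI$", names(mfp))] >= 0))
  }
})

test_that("a symmetric trial has near-zero symmetry indices", {
  tr <- simulate_trial(motion_spec("GYM_FRONTAL", duration = 12,
                                   asymmetry_ratio = 1, mode = "SIM"),
                       noise_free(), seed = 9)
  mfp <- extract_mfp(preprocess_trajectory(tr))
  expect_lt(mfp[["ANG_SI"]], 1e-6)
  expect_lt(mfp[["VEL_SI"]], 1e-6)
})

test_that("amplitude asymmetry r = 1.2 is recovered as SI 0.2 through the chain", {
  tr <- simulate_trial(motion_spec("GYM_LATERAL", duration = 20,
                                   asymmetry_ratio = 1.2, mode = "SIM"),
                       noise_free(), seed = 10)
  mfp <- extract_mfp(preprocess_trajectory(tr))
  expect_lt(abs(mfp[["ANG_SI"]] - 0.2), 0.02)
  expect_lt(abs(mfp[["VEL_SI"]] - 0.2), 0.02)
})

test_that("GYM ROM at amplitude 50 is recovered within 1 degree of 100", {
  m <- motion_spec("GYM_LATERAL", amplitude = 50, duration = 20,
                   mode = "SIM")
  tr <- simulate_trial(m, noise_free(), seed = 11)
  # the raise waveform spans [baseline, baseline + A]: per-side ROM = A;
  # a full up-down sinusoidal elevation spans 2A
  m2 <- motion_spec("SKI", amplitude = 50, frequency = 0.25, duration = 20)
  tr2 <- simulate_trial(m2, noise_free(), seed = 11)
  jt <- default_joint_table()
  s <- joint_angle_series(preprocess_trajectory(tr2)$trajectory,
                          as.list(jt[jt$name == "KNEE_ANG_L", ]))
  expect_lt(abs(range_of_motion(s) - 100), 1)
  mfp <- extract_mfp(preprocess_trajectory(tr))
  expect_lt(abs(mfp[["ROM_ANG"]] - 50), 1)
})

test_that("missing joint definitions raise a configuration error", {
  tr <- simulate_trial(motion_spec("PIANO", duration = 4), noise_free(),
                       seed = 1)
  jt <- default_joint_table()
  prof <- exergame_profile("PIANO", joint_table = jt[jt$name != "T_ANG", ])
  expect_error(extract_mfp(preprocess_trajectory(tr), prof),
               "joint definition missing")
})
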