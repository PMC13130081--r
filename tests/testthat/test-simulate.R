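test_that("equal seeds reproduce trials exactly; specs validate", {
  m <- motion_spec("SKI", duration = 5)
  a <- simulate_trial(m, noise_spec(), seed = 123)
  b <- simulate_trial(m, noise_spec(), seed = 123)
  expect_identical(a$trajectory$positions, b$trajectory$positions)
  expect_identical(a$events, b$events)
  c_ <- simulate_trial(m, noise_spec(), seed = 124)
  expect_false(identical(a$trajectory$positions, c_$trajectory$positions))

  expect_error(motion_spec("SKI", duration = 0.5), "at least 1 s")
  expect_error(motion_spec("SKI", frequency = 3), "frequency")
  expect_error(motion_spec("SKI", asymmetry_ratio = 0), "asymmetry_ratio")
  expect_error(noise_spec(tremor_amp = 0.01, tremor_freq = 5), "7.5")
})

test_that("zero amplitude gives constant joint-angle series", {
  m <- motion_spec("GYM_LATERAL", amplitude = 0, duration = 4, mode = "SIM")
  tr <- simulate_trial(m, noise_free(), seed = 1)
  jt <- default_joint_table()
  for (nm in c("ARM_ANG_R", "ARM_ANG_L", "T_ANG")) {
    s <- joint_angle_series(tr$trajectory, as.list(jt[jt$name == nm, ]))
    expect_lt(diff(range(s)), 1e-9)
  }
})

test_that("a sinusoidal elevation of amplitude 45 spans a 90 degree ROM", {
  m <- motion_spec("SKI", amplitude = 45, frequency = 0.25, duration = 20)
  tr <- simulate_trial(m, noise_free(), seed = 2)
  expect_equal(diff(range(tr$ground_truth$KNEE_ANG_L)), 90, tolerance = 1e-3)
  jt <- default_joint_table()
  s <- joint_angle_series(tr$trajectory,
                          as.list(jt[jt$name == "KNEE_ANG_L", ]))
  expect_equal(diff(range(s)), 90, tolerance = 1e-3)
})

test_that("event log is consistent with the waveform repetitions", {
  m <- motion_spec("PIANO", frequency = 0.25, duration = 20)
  tr <- simulate_trial(m, noise_free(), seed = 3)
  expect_equal(sum(tr$events$kind == "movement_valid"), 5)
  expect_equal(sum(tr$events$kind == "key_press"), 5)
  expect_equal(tr$ground_truth$n_reps, 5)
})

test_that("asymmetry ratio propagates exactly to the ground-truth SI", {
  for (r in c(0.8, 1, 1.2, 1.5)) {
    m <- motion_spec("GYM_FRONTAL", asymmetry_ratio = r, duration = 4,
                     mode = "SIM")
    tr <- simulate_trial(m, noise_free(), seed = 5)
    expect_equal(tr$ground_truth$si_amplitude, abs(r - 1))
    expect_equal(unname(tr$ground_truth$rom["R"] / tr$ground_truth$rom["L"]),
                 r)
  }
})

test_that("noiseless impairment link is monotone: milder reaches max earlier", {
  co <- simulate_cohort(cohort_spec(n_subjects = 2, impairment = c(0, 1),
                                    link_noise_sd = 0, seed = 1))
  pr <- co$progression
  for (g in unique(pr$game)) {
    mild <- pr[pr$game == g & pr$subject_id == "S01", ]
    severe <- pr[pr$game == g & pr$subject_id == "S02", ]
    expect_gte(severe$first_session, mild$first_session)
    expect_lte(severe$max_level, mild$max_level)
    expect_equal(mild$first_session, 1L)  # impairment 0 masters in session 1
  }
})

test_that("cohort generation is deterministic under a fixed seed", {
  s <- cohort_spec(n_subjects = 14, seed = 31)
  a <- simulate_cohort(s)
  b <- simulate_cohort(s)
  expect_identical(a$trials, b$trials)
  expect_identical(a$progression, b$progression)
  expect_identical(a$questionnaire, b$questionnaire)
  expect_identical(lapply(a$clinical, `[[`, "items"),
                   lapply(b$clinical, `[[`, "items"))
})

test_that("cohort structure matches the protocol shape", {
  co <- simulate_cohort(cohort_spec(n_subjects = 14, seed = 6))
  expect_equal(length(unique(co$trials$subject_id)), 14)
  expect_true(all(co$trials$session_index >= 1 & co$trials$session_index <= 10))
  n_sess <- co$trials |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(n = max(session_index), .groups = "drop")
  expect_true(all(n_sess$n %in% c(5L, 7L, 10L)))
  gym <- co$trials[startsWith(co$trials$exergame, "GYM"), ]
  expect_true(all(gym$mode %in% c("SING", "ALT", "SIM")))
  expect_true(all(is.na(co$trials$mode[!startsWith(co$trials$exergame, "GYM")])))
  # UPDRS totals rise with impairment
  ss <- cohort_subscores(co$clinical)
  ord <- order(co$impairment)
  expect_gt(cor(co$impairment, ss$UPDRSIII_SCORE[match(names(co$impairment),
                                                       ss$subject_id)]), 0.9)
})

test_that("materialized cohort trials carry valid trajectories", {
  co <- simulate_cohort(cohort_spec(n_subjects = 2, max_sessions = 2,
                                    trial_duration = 4,
                                    with_trajectories = TRUE, seed = 11))
  expect_equal(length(co$records), nrow(co$trials))
  tr <- co$records[[1]]
  expect_s3_class(tr, "trial_record")
  expect_equal(tr$subject_id, co$trials$subject_id[1])
  expect_equal(length(tr$trajectory$timestamps), 4 * 30 + 1)
})
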