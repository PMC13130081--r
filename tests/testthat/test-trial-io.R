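test_that("a minimal hand-built trial round-trips through JSON", {
  tr <- make_minimal_trial(n_frames = 2, n_events = 0)
  path <- withr::local_tempfile(fileext = ".json")
  write_trial(tr, path)
  back <- read_trial(path)
  expect_equal(length(back$trajectory$timestamps), 2)
  expect_equal(nrow(back$events), 0)
  expect_equal(back$subject_id, tr$subject_id)
  expect_equal(back$trajectory$positions, tr$trajectory$positions)
})

test_that("trials with empty event logs keep an empty event array on reload", {
  tr <- make_minimal_trial(n_frames = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_trial(tr, path)
  txt <- paste(readLines(path), collapse = "")
  expect_match(txt, '"events":\\s*\\[\\]')
  expect_equal(nrow(read_trial(path)$events), 0)
})

test_that("read-write is the identity on simulator trials (property)", {
  for (seed in c(11, 23, 47)) {
    tr <- make_random_trial(seed)
    path <- withr::local_tempfile(fileext = ".json")
    write_trial(tr, path)
    back <- read_trial(path)
    # positions carry NaN-free frames exactly; flagged frames stay flagged
    expect_equal(back$trajectory$timestamps, tr$trajectory$timestamps,
                 tolerance = 1e-12)
    expect_lt(max(abs(back$trajectory$positions - tr$trajectory$positions),
                  na.rm = TRUE), 1e-9)
    expect_equal(back$trajectory$flagged, tr$trajectory$flagged)
    expect_equal(back$events$kind, tr$events$kind)
    expect_equal(back$events$t, tr$events$t, tolerance = 1e-12)
    expect_equal(back$level, tr$level)
    expect_equal(back$session_index, tr$session_index)
  }
})

test_that("loading retains and flags non-finite frames instead of dropping them", {
  tr <- make_random_trial(5)
  tr$trajectory$positions[4, 7, 1] <- NaN
  tr$trajectory <- landmark_trajectory(tr$trajectory$timestamps,
                                       tr$trajectory$positions)
  path <- withr::local_tempfile(fileext = ".json")
  write_trial(tr, path)
  back <- read_trial(path)
  n_in <- length(tr$trajectory$timestamps)
  qr <- trial_quality_report(back)
  expect_equal(length(back$trajectory$timestamps), n_in)
  expect_equal(qr$frame, 4L)
})

test_that("schema violations name the offending field", {
  tr <- make_minimal_trial()
  path <- withr::local_tempfile(fileext = ".json")
  write_trial(tr, path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)

  bad <- doc
  bad$landmarks[[2]]$xyz <- bad$landmarks[[2]]$xyz[1:32]
  p2 <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(bad, auto_unbox = TRUE, digits = NA), p2)
  expect_error(read_trial(p2), "frame 2.*32 landmarks")

  bad <- doc
  bad$landmarks[[2]]$t <- bad$landmarks[[1]]$t
  p3 <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(bad, auto_unbox = TRUE, digits = NA), p3)
  expect_error(read_trial(p3), "strictly increasing")

  bad <- doc
  bad$meta$exergame <- NULL
  p4 <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(bad, auto_unbox = TRUE, digits = NA), p4)
  expect_error(read_trial(p4), "meta\\.exergame")
})

test_that("a long synthetic trial reloads to within 1e-9 per coordinate", {
  m <- motion_spec("GYM_FRONTAL", duration = 33.3, mode = "ALT")
  tr <- simulate_trial(m, noise_spec(), seed = 99)
  expect_gte(length(tr$trajectory$timestamps), 1000)
  path <- withr::local_tempfile(fileext = ".json")
  write_trial(tr, path)
  back <- read_trial(path)
  expect_lt(max(abs(back$trajectory$positions - tr$trajectory$positions)),
            1e-9)
})

test_that("cohort tables validate counts and score ranges", {
  co <- simulate_cohort(cohort_spec(n_subjects = 14, seed = 3))
  ccsv <- withr::local_tempfile(fileext = ".csv")
  qcsv <- withr::local_tempfile(fileext = ".csv")
  write_cohort_tables(co$clinical, co$questionnaire, ccsv, qcsv)
  tabs <- read_cohort_tables(ccsv, qcsv)
  expect_length(tabs$clinical, 14)
  expect_equal(nrow(tabs$questionnaire), nrow(co$questionnaire))

  # out-of-range clinical score cites the row
  cl <- utils::read.csv(ccsv, check.names = FALSE)
  cl$`item_3_10`[3] <- 5
  utils::write.csv(cl, ccsv, row.names = FALSE)
  expect_error(read_cohort_tables(ccsv, qcsv), "row 3.*3\\.10")

  # out-of-range questionnaire answer cites the row
  write_cohort_tables(co$clinical, co$questionnaire, ccsv, qcsv)
  qu <- utils::read.csv(qcsv)
  qu$q2[7] <- 6
  utils::write.csv(qu, qcsv, row.names = FALSE)
  expect_error(read_cohort_tables(ccsv, qcsv), "row 7.*q2")
})

test_that("pause events must alternate and events must lie in the time span", {
  tr <- make_minimal_trial(n_frames = 60)
  expect_error(game_events(c("pause_start", "pause_start"), c(0.1, 0.2)),
               "alternate")
  expect_error(game_events("pause_end", 0.1), "alternate")
  t_end <- tr$trajectory$timestamps[60]
  expect_error(
    trial_record("T01", "AIRPLANE", 0, 1, TRUE, tr$trajectory,
                 game_events("point", t_end + 5)),
    "time span")
})

test_that("trial invariants reject bad identity fields", {
  traj <- make_minimal_trial()$trajectory
  expect_error(trial_record("X", "AIRPLANE", 9, 1, TRUE, traj),
               "theoretical max")
  expect_error(trial_record("X", "AIRPLANE", 0, 0, TRUE, traj),
               "session_index")
  expect_error(trial_record("X", "GYM_FRONTAL", 0, 1, TRUE, traj),
               "mode")
  expect_error(trial_record("X", "SKI", 0, 1, TRUE, traj, mode = "SIM"),
               "only GYM")
})

test_that("validate_trial_dir reports per-file quality", {
  dir <- withr::local_tempdir()
  write_trial(make_minimal_trial(), file.path(dir, "ok.json"))
  writeLines("{\"meta\": {}}", file.path(dir, "bad.json"))
  rep <- validate_trial_dir(dir)
  expect_equal(nrow(rep), 2)
  expect_false(rep$ok[rep$file == "bad.json"])
  expect_true(rep$ok[rep$file == "ok.json"])
})
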