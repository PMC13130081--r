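#' Game-based metrics of a trial
#'
#' Pure function of the event log and the trial time span. Counts point,
#' error, and pause events; `TIME` is the wall-clock trial duration (last
#' event or last frame minus first frame), pauses included; the
#' pause-adjusted duration is exposed separately as `TIME_ACTIVE`.
#' `KEY_TIME` is the mean interval between consecutive key presses (`NA`
#' with fewer than two); `MOV_OK` the percentage of valid movements among
#' movement events (`NA` when there are none). Peaks-per-minute is
#' trajectory-derived and computed separately ([peaks_per_minute()]).
#'
#' @param trial a `trial_record`
#' @return named numeric vector: POINT, ERROR, PAUSE, TIME, TIME_ACTIVE,
#'   KEY_TIME, MOV_OK
#' @export
compute_gbm <- function(trial) {
  ev <- trial$events
  check_pause_pairing(ev)
  ts <- trial$trajectory$timestamps
  t0 <- ts[1]
  t_end <- max(ts[length(ts)], if (nrow(ev)) max(ev$t) else -Inf)
  time_total <- t_end - t0

  n_of <- function(kind) sum(ev$kind == kind)
  paused <- 0
  if (n_of("pause_start")) {
    paused <- sum(ev$t[ev$kind == "pause_end"] - ev$t[ev$kind == "pause_start"])
  }
  keys <- sort(ev$t[ev$kind == "key_press"])
  key_time <- if (length(keys) >= 2) mean(diff(keys)) else NA_real_
  n_valid <- n_of("movement_valid")
  n_invalid <- n_of("movement_invalid")
  mov_ok <- if (n_valid + n_invalid > 0) {
    100 * n_valid / (n_valid + n_invalid)
  } else {
    NA_real_
  }
  c(POINT = n_of("point"), ERROR = n_of("error"), PAUSE = n_of("pause_start"),
    TIME = time_total, TIME_ACTIVE = time_total - paused,
    KEY_TIME = key_time, MOV_OK = mov_ok)
}

#' Peaks per minute
#'
#' Repetition rate of a rhythmic movement: repetition peaks of the
#' conditioned angle series (see [find_repetition_peaks()]) scaled to a
#' per-minute rate.
#'
#' @param series conditioned angle series in degrees
#' @param rate sampling rate in Hz
#' @param duration trial duration in seconds (> 0)
#' @param min_prominence,min_separation peak-detection thresholds
#' @return peaks per minute
#' @export
peaks_per_minute <- function(series, rate, duration, min_prominence = 10,
                             min_separation = 0.4) {
  if (duration <= 0) stop("duration must be positive")
  peaks <- find_repetition_peaks(series, rate, min_prominence, min_separation)
  length(peaks) * 60 / duration
}

#' Extract all per-trial features
#'
#' Convenience wrapper: conditions the trajectory (unless already done),
#' extracts the MFP set and the GBM set, and adds the trajectory-derived
#' PPM metric for GYM trials (peaks of the driving arm angle over the trial
#' duration).
#'
#' @param trial a `trial_record`
#' @param config a [preprocess_config()]
#' @param profile an [exergame_profile()]
#' @return named numeric vector of MFPs followed by GBMs
#' @export
extract_features <- function(trial, config = preprocess_config(),
                             profile = exergame_profile(trial$exergame)) {
  if (!isTRUE(trial$preprocessed)) {
    trial <- preprocess_trajectory(trial, config)
  }
  mfp <- extract_mfp(trial, profile)
  gbm <- compute_gbm(trial)
  if (progression_game(trial$exergame) == "GYM") {
    tr <- trial$trajectory
    jt <- profile$joint_table
    sr <- joint_angle_series(tr, joint_row(jt, "ARM_ANG_R"))
    sl <- joint_angle_series(tr, joint_row(jt, "ARM_ANG_L"))
    drive <- if (diff(range(sr, na.rm = TRUE)) >= diff(range(sl, na.rm = TRUE))) sr else sl
    gbm <- c(gbm, PPM = peaks_per_minute(drive, tr$nominal_fps,
                                         gbm[["TIME"]],
                                         profile$min_prominence,
                                         profile$min_separation))
  }
  c(mfp, gbm)
}

#' Aggregate per-trial features into per-level summary tables
#'
#' One row per (exergame, mode, level): trial count, mean and sample SD for
#' motor functional parameters, mean only for symmetry indices and
#' game-based metrics (the reporting convention of the study tables).
#' Aggregation conserves trials: the `n_trials` column sums to the number of
#' input rows per exergame.
#'
#' @param features tibble with identity columns (`exergame`, `level`,
#'   optionally `mode`) and one column per feature
#' @param mfp_cols character vector naming the columns to report as
#'   mean +/- SD; all other feature columns are reported as means. Defaults
#'   to non-SI MFP column names found in the table.
#' @return tibble with columns `exergame`, `mode`, `level`, `n_trials`,
#'   `<mfp>_mean`, `<mfp>_sd`, `<other>_mean`
#' @export
aggregate_by_level <- function(features, mfp_cols = NULL) {
  features <- tibble::as_tibble(features)
  if (!"mode" %in% names(features)) features$mode <- NA_character_
  id_cols <- c("subject_id", "session_index", "exergame", "mode", "level",
               "completed", "trial_id")
  feat_cols <- setdiff(names(features), id_cols)
  if (is.null(mfp_cols)) {
    mfp_cols <- intersect(
      c("ARM_ANG", "ELB_ANG", "LEG_ANG", "KNEE_ANG", "T_ANG", "ROM_ANG",
        "ARM_VEL", "PPM"),
      feat_cols)
  }
  mean_cols <- setdiff(feat_cols, mfp_cols)
  features |>
    dplyr::group_by(.data$exergame, .data$mode, .data$level) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      dplyr::across(dplyr::all_of(mfp_cols),
                    list(mean = ~mean(.x, na.rm = TRUE),
                         sd = ~stats::sd(.x[!is.na(.x)]))),
      dplyr::across(dplyr::all_of(mean_cols),
                    list(mean = ~mean(.x, na.rm = TRUE))),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$exergame, .data$mode, .data$level)
}

#' Task completion rate
#'
#' Percentage of completed tasks among valid recordings, reported to two
#' decimals.
#'
#' @param n_completed number of completed tasks (0 <= n_completed <= n_valid)
#' @param n_valid number of valid recordings (> 0)
#' @return completion rate in percent, rounded to 2 decimals
#' @export
completion_rate <- function(n_completed, n_valid) {
  if (any(n_valid <= 0)) stop("n_valid must be positive")
  if (any(n_completed < 0 | n_completed > n_valid)) {
    stop("n_completed must lie in [0, n_valid]")
  }
  round(100 * n_completed / n_valid, 2)
}
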