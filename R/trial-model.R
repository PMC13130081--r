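#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
NULL

EXERGAMES <- c("AIRPLANE", "SKI", "PIANO", "GYM_FRONTAL", "GYM_LATERAL")
GYM_MODES <- c("SING", "ALT", "SIM")
EVENT_KINDS <- c("point", "error", "pause_start", "pause_end", "key_press",
                 "movement_valid", "movement_invalid", "level_complete",
                 "abort")

#' Construct a landmark trajectory
#'
#' A trajectory is the time series of 3D world coordinates of the 33 pose
#' landmarks recorded during one exergame trial (nominally 30 fps). Frames
#' containing any non-finite coordinate are retained but flagged; downstream
#' pre-processing interpolates over them.
#'
#' @param timestamps numeric vector of frame times in seconds, strictly
#'   increasing
#' @param positions numeric array of dim `length(timestamps) x 33 x 3`,
#'   world coordinates in meters (right-handed, y-up)
#' @param nominal_fps nominal acquisition rate in Hz
#' @param landmark_names landmark identifiers, defaults to the pose topology
#'   order
#' @return object of class `landmark_trajectory` with fields `timestamps`,
#'   `positions`, `nominal_fps`, `landmark_names`, and `flagged` (indices of
#'   frames with non-finite coordinates)
#' @export
landmark_trajectory <- function(timestamps, positions, nominal_fps = 30,
                                landmark_names = pose_landmark_names()) {
  timestamps <- as.numeric(timestamps)
  if (length(dim(positions)) != 3L) {
    stop("positions must be an L x 33 x 3 array")
  }
  d <- dim(positions)
  if (d[2] != n_pose_landmarks() || d[3] != 3L) {
    stop("positions must have 33 landmarks and 3 coordinates per frame, got ",
         d[2], " x ", d[3])
  }
  if (d[1] != length(timestamps)) {
    stop("timestamps length (", length(timestamps),
         ") must equal frame count (", d[1], ")")
  }
  if (length(timestamps) > 1 && any(diff(timestamps) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  if (length(landmark_names) != n_pose_landmarks()) {
    stop("landmark_names must have length 33")
  }
  flagged <- which(apply(!is.finite(positions), 1, any))
  structure(
    list(timestamps = timestamps, positions = positions,
         nominal_fps = nominal_fps, landmark_names = landmark_names,
         flagged = as.integer(flagged)),
    class = "landmark_trajectory"
  )
}

#' Construct a game event table
#'
#' Events are recorded by the game engine during a trial. `pause_start` and
#' `pause_end` events must strictly alternate (start first).
#'
#' @param kind character vector of event kinds (see `EVENT_KINDS` in the
#'   package source: point, error, pause_start, pause_end, key_press,
#'   movement_valid, movement_invalid, level_complete, abort)
#' @param t numeric vector of event times in seconds
#' @param payload optional list of per-event detail lists
#' @return tibble with columns `kind`, `t`, `payload`
#' @export
game_events <- function(kind = character(), t = numeric(), payload = NULL) {
  if (length(kind) != length(t)) stop("kind and t must have equal length")
  bad <- setdiff(unique(kind), EVENT_KINDS)
  if (length(bad)) stop("unknown event kind(s): ", paste(bad, collapse = ", "))
  if (is.null(payload)) payload <- rep(list(NULL), length(kind))
  ev <- tibble(kind = as.character(kind), t = as.numeric(t),
               payload = payload)
  ev <- ev[order(ev$t), , drop = FALSE]
  check_pause_pairing(ev)
  ev
}

check_pause_pairing <- function(events) {
  ps <- events$kind[events$kind %in% c("pause_start", "pause_end")]
  if (!length(ps)) return(invisible(TRUE))
  expected <- rep(c("pause_start", "pause_end"), length.out = length(ps))
  if (length(ps) %% 2 != 0 || any(ps != expected)) {
    stop("pause_start/pause_end events must strictly alternate, ",
         "starting with pause_start")
  }
  invisible(TRUE)
}

#' Construct a trial record
#'
#' One exergame attempt: the landmark trajectory, the game event log, and
#' the trial identity (subject, game, difficulty level, session).
#'
#' @param subject_id subject identifier (character)
#' @param exergame one of AIRPLANE, SKI, PIANO, GYM_FRONTAL, GYM_LATERAL
#' @param level difficulty level, integer >= 0 and <= the game's theoretical
#'   maximum
#' @param session_index gaming session number, integer in 1..10
#' @param completed logical, whether the trial was completed (not aborted)
#' @param trajectory a `landmark_trajectory`
#' @param events a tibble from [game_events()]
#' @param mode GYM coordination mode (SING, ALT, SIM); must be given for GYM
#'   trials and absent otherwise
#' @param theoretical_max named vector of per-game maximum levels used for
#'   validation (defaults to [default_theoretical_max()])
#' @return object of class `trial_record`
#' @export
trial_record <- function(subject_id, exergame, level, session_index,
                         completed, trajectory, events = game_events(),
                         mode = NULL,
                         theoretical_max = default_theoretical_max()) {
  exergame <- match.arg(exergame, EXERGAMES)
  level <- as.integer(level)
  session_index <- as.integer(session_index)
  if (level < 0) stop("level must be >= 0")
  tmax <- theoretical_max[[progression_game(exergame)]]
  if (!is.null(tmax) && level > tmax) {
    stop("level ", level, " exceeds theoretical max ", tmax,
         " for ", exergame)
  }
  if (session_index < 1) stop("session_index must be >= 1")
  is_gym <- exergame %in% c("GYM_FRONTAL", "GYM_LATERAL")
  if (is_gym) {
    if (is.null(mode)) stop("GYM trials must carry a mode (SING/ALT/SIM)")
    mode <- match.arg(mode, GYM_MODES)
  } else if (!is.null(mode)) {
    stop("only GYM trials carry a mode")
  }
  if (!inherits(trajectory, "landmark_trajectory")) {
    stop("trajectory must be a landmark_trajectory")
  }
  if (nrow(events)) {
    t0 <- trajectory$timestamps[1]
    t1 <- trajectory$timestamps[length(trajectory$timestamps)]
    if (any(events$t < t0 - 1e-9 | events$t > t1 + 1e-9)) {
      stop("event times must lie within the trial time span [",
           signif(t0, 6), ", ", signif(t1, 6), "]")
    }
  }
  structure(
    list(subject_id = as.character(subject_id), exergame = exergame,
         level = level, session_index = session_index,
         mode = mode, completed = isTRUE(completed),
         trajectory = trajectory, events = events),
    class = "trial_record"
  )
}

#' @export
print.trial_record <- function(x, ...) {
  cat("<trial_record> ", x$subject_id, " ", x$exergame,
      if (!is.null(x$mode)) paste0("/", x$mode), " level ", x$level,
      " session ", x$session_index,
      if (x$completed) " (completed)" else " (not completed)", "\n", sep = "")
  cat("  frames: ", length(x$trajectory$timestamps),
      " (", length(x$trajectory$flagged), " flagged), events: ",
      nrow(x$events), "\n", sep = "")
  invisible(x)
}

#' Frame-quality report of a trial
#'
#' Loading never silently drops frames: every recorded frame is either
#' retained clean or listed here as flagged (non-finite coordinates).
#'
#' @param trial a `trial_record`
#' @return tibble with one row per flagged frame (`frame`, `t`)
#' @export
trial_quality_report <- function(trial) {
  fl <- trial$trajectory$flagged
  tibble(frame = fl, t = trial$trajectory$timestamps[fl])
}

#' Construct a clinical assessment record
#'
#' Baseline MDS-UPDRS Part III motor examination at sub-item granularity
#' (laterality and body-part sub-items), plus the Hoehn & Yahr stage.
#'
#' @param subject_id subject identifier
#' @param hy Hoehn & Yahr stage (1-5, halves allowed)
#' @param items named numeric vector of item scores in 0..4; names follow
#'   [updrs_item_ids()]
#' @return object of class `clinical_assessment`
#' @export
clinical_assessment <- function(subject_id, hy, items) {
  items <- unlist(items)
  if (is.null(names(items)) || any(names(items) == "")) {
    stop("items must be a named vector of MDS-UPDRS Part III sub-item scores")
  }
  unknown <- setdiff(names(items), updrs_item_ids())
  if (length(unknown)) {
    stop("unknown MDS-UPDRS item id(s): ", paste(unknown, collapse = ", "))
  }
  if (any(!is.finite(items)) || any(items < 0 | items > 4)) {
    stop("all MDS-UPDRS item scores must lie in [0, 4]")
  }
  structure(
    list(subject_id = as.character(subject_id), hy = as.numeric(hy),
         items = items),
    class = "clinical_assessment"
  )
}

#' Canonical MDS-UPDRS Part III sub-item identifiers
#'
#' Items 3.1-3.18 at sub-item granularity: item 3.3 (rigidity) over five body
#' parts, items 3.4-3.8 and 3.15-3.16 by side, item 3.17 (rest tremor
#' amplitude) over four limbs plus lip/jaw. 33 sub-items, each scored 0-4
#' (theoretical total maximum 132).
#'
#' @return character vector of 33 identifiers
#' @export
updrs_item_ids <- function() {
  c("3.1", "3.2",
    paste0("3.3_", c("neck", "rue", "lue", "rle", "lle")),
    paste0(rep(c("3.4", "3.5", "3.6", "3.7", "3.8"), each = 2), c("_r", "_l")),
    "3.9", "3.10", "3.11", "3.12", "3.13", "3.14",
    paste0(rep(c("3.15", "3.16"), each = 2), c("_r", "_l")),
    paste0("3.17_", c("rue", "lue", "rle", "lle", "lipjaw")),
    "3.18")
}

#' Construct questionnaire responses
#'
#' Five-item post-session Likert questionnaire (1 = low, 5 = high):
#' Q1 pre-session well-being, Q2 satisfaction, Q3 willingness to repeat
#' (engagement), Q4 post-session fatigue, Q5 ease of interaction (usability).
#'
#' @param subject_id,session_index identifiers (vectorized)
#' @param q1,q2,q3,q4,q5 integer answers in 1..5
#' @return tibble of class `questionnaire_response`
#' @export
questionnaire_response <- function(subject_id, session_index,
                                   q1, q2, q3, q4, q5) {
  ans <- cbind(q1, q2, q3, q4, q5)
  if (any(!is.finite(ans)) || any(ans < 1 | ans > 5)) {
    stop("all questionnaire answers must lie in [1, 5]")
  }
  tibble(subject_id = as.character(subject_id),
         session_index = as.integer(session_index),
         q1 = as.integer(q1), q2 = as.integer(q2), q3 = as.integer(q3),
         q4 = as.integer(q4), q5 = as.integer(q5))
}

# Map a trial-level exergame label to the game used in progression analysis
# (the two GYM directions contribute a single combined GYM game).
progression_game <- function(exergame) {
  ifelse(exergame %in% c("GYM_FRONTAL", "GYM_LATERAL"), "GYM", exergame)
}
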