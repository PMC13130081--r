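#' Published per-subject progression table of the pilot study
#'
#' Maximum difficulty level reached by each of the 14 analyzed participants
#' in each exergame, with the session in which that maximum was first
#' achieved, transcribed from the study's summary table. These printed values
#' are inputs to the progression and NEI analyses (per-trial recordings are
#' not required to reproduce them).
#'
#' @return tibble with columns `subject_id`, `game` (AIRPLANE/SKI/PIANO/GYM),
#'   `max_level`, `first_session`
#' @export
study_progression_table <- function() {
  subj <- c("S01", "S02", "S05", "S06", "S07", "S10", "S13", "S14",
            "S17", "S18", "S19", "S20", "S21", "S22")
  # columns: airplane (level, session), ski, piano, gym
  m <- matrix(c(
    8, 5,  11, 5,  2, 4,  3, 4,
    7, 9,  11, 10, 2, 4,  3, 9,
    7, 9,  10, 9,  2, 7,  3, 7,
    8, 10, 10, 9,  1, 9,  3, 7,
    0, 1,  11, 6,  2, 5,  2, 2,
    7, 9,  11, 9,  2, 5,  3, 5,
    8, 8,  11, 5,  2, 3,  3, 5,
    8, 4,  11, 4,  2, 2,  3, 3,
    0, 1,  1, 9,   1, 8,  2, 7,
    8, 7,  11, 5,  2, 2,  3, 4,
    3, 5,  0, 1,   2, 5,  1, 2,
    8, 10, 11, 10, 2, 5,  3, 6,
    8, 9,  11, 9,  1, 2,  3, 6,
    8, 7,  11, 6,  2, 4,  3, 5
  ), ncol = 8, byrow = TRUE)
  games <- c("AIRPLANE", "SKI", "PIANO", "GYM")
  rows <- lapply(seq_along(games), function(g) {
    tibble(subject_id = subj, game = games[g],
           max_level = as.integer(m[, 2 * g - 1]),
           first_session = as.integer(m[, 2 * g]))
  })
  dplyr::bind_rows(rows)
}

#' Published per-level mean game scores
#'
#' Difficulty level indices and the corresponding per-level mean game-based
#' metrics for the Airplane and Ski exergames (mean POINT per trial) and the
#' Piano exergame (mean ERROR per trial), transcribed from the study's
#' summary tables. Used as inputs for the level-vs-score correlation
#' analysis.
#'
#' @return tibble with columns `exergame`, `level`, `metric`, `value`
#' @export
study_level_scores <- function() {
  dplyr::bind_rows(
    tibble(exergame = "AIRPLANE", level = c(0:5, 7, 8), metric = "POINT",
           value = c(5.40, 5.61, 5.13, 7.00, 6.21, 6.55, 9.08, 9.23)),
    tibble(exergame = "SKI", level = c(0, 1, 2, 4, 5, 7, 8, 10, 11),
           metric = "POINT",
           value = c(7.33, 7.96, 8.00, 7.58, 10.00, 8.19, 9.00, 8.58, 9.43)),
    tibble(exergame = "PIANO", level = 0:2, metric = "ERROR",
           value = c(4.08, 3.00, 1.88))
  )
}

#' Published trial-count and completion summary
#'
#' Failed recordings, valid recordings, and completed tasks per exergame,
#' transcribed from the study's technical-reliability table. Inputs to the
#' completion-rate computation.
#'
#' @return tibble with columns `exergame`, `failed`, `valid`, `completed`
#' @export
study_completion_counts <- function() {
  tibble(
    exergame = c("AIRPLANE", "SKI", "PIANO", "GYM_FRONTAL", "GYM_LATERAL"),
    failed = c(2L, 25L, 0L, 1L, 0L),
    valid = c(349L, 194L, 279L, 482L, 486L),
    completed = c(314L, 184L, 279L, 482L, 486L)
  )
}
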